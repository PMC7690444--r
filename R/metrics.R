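## Imbalance-insensitive evaluation metrics: every class counts equally,
## regardless of its sample size.

#' Confusion matrix from label vectors
#'
#' @param true,pred integer label vectors in 0..M-1, equal length.
#' @param M number of classes (default 5, mRS 0..4).
#' @return M x M integer matrix, rows = true class, columns = predicted,
#'   dimnames = class labels.
#' @export
confusionMatrix <- function(true, pred, M = 5L) {
  if (length(true) != length(pred))
    stop("true and pred must have equal length")
  lv <- 0:(M - 1L)
  cm <- table(factor(true, levels = lv), factor(pred, levels = lv))
  m <- matrix(as.integer(cm), M, M, dimnames = list(lv, lv))
  m
}

#' Macro-averaged mean absolute error (MAE^M)
#'
#' The within-class mean absolute deviation |y - yhat|, averaged with equal
#' weight over the classes present in `true`; range \[0, M-1\]. Classes absent
#' from `true` are dropped from the average (their within-class mean is
#' undefined) with a warning.
#'
#' @param true,pred label vectors in 0..M-1 (pred may be continuous for
#'   regression-style baselines).
#' @param M number of classes.
#' @return MAE^M as a numeric scalar.
#' @export
macroMAE <- function(true, pred, M = 5L) {
  if (length(true) != length(pred))
    stop("true and pred must have equal length")
  classes <- 0:(M - 1L)
  present <- classes[classes %in% true]
  if (length(present) < length(classes))
    warning("class(es) absent from truth excluded from MAE^M: ",
            paste(setdiff(classes, present), collapse = ", "))
  mean(vapply(present, function(m)
    mean(abs(true[true == m] - pred[true == m])), 0))
}

#' Per-class precision and recall from a confusion matrix
#'
#' `P_m = diag/colsum`, `R_m = diag/rowsum`, with the 0/0 convention of 0
#' (a class never predicted has precision 0; a class never seen has recall
#' 0). Per-class "accuracy" in this evaluation scheme is identical to
#' per-class recall.
#'
#' @param confusion square count matrix (rows true, cols predicted).
#' @return `list(precision = , recall = )`, numeric vectors named by class.
#' @export
perClassPR <- function(confusion) {
  dg <- diag(confusion)
  cs <- colSums(confusion)
  rs <- rowSums(confusion)
  P <- ifelse(cs > 0, dg / cs, 0)
  R <- ifelse(rs > 0, dg / rs, 0)
  names(P) <- names(R) <- colnames(confusion)
  list(precision = P, recall = R)
}

#' Macro precision, recall and F1
#'
#' Pmacro and Rmacro are unweighted means of the per-class values; F1macro is
#' the harmonic mean of the two macro values (the printed definition this
#' evaluation follows — not the mean of per-class F1), with 0 when
#' `Pmacro + Rmacro = 0`.
#'
#' @param precision,recall per-class vectors of equal length.
#' @return Named numeric: precision, recall, f1.
#' @export
macroPRF <- function(precision, recall) {
  stopifnot(length(precision) == length(recall), length(precision) >= 1L)
  P <- mean(precision)
  R <- mean(recall)
  f1 <- if (P + R > 0) 2 * P * R / (P + R) else 0
  c(precision = P, recall = R, f1 = f1)
}

#' Multiclass Matthews correlation coefficient (Gorodkin)
#'
#' `MCC = (c s - sum_k p_k t_k) / sqrt((s^2 - sum p_k^2)(s^2 - sum t_k^2))`
#' with c the trace, s the total count, t_k the row (true) sums and p_k the
#' column (predicted) sums; defined as 0 when either radicand vanishes.
#' Coincides with the classical binary MCC on 2 x 2 tables.
#'
#' @param confusion square count matrix.
#' @return MCC in \[-1, 1\].
#' @export
mccMulticlass <- function(confusion) {
  s <- sum(confusion)
  if (s <= 0) stop("confusion matrix must have positive total")
  cc <- sum(diag(confusion))
  t_k <- rowSums(confusion)
  p_k <- colSums(confusion)
  num <- cc * s - sum(p_k * t_k)
  r1 <- s^2 - sum(p_k^2)
  r2 <- s^2 - sum(t_k^2)
  if (r1 <= 0 || r2 <= 0) return(0)
  num / sqrt(r1 * r2)
}

#' Per-class one-vs-rest AUC
#'
#' Rank-based (Mann-Whitney) AUC per class, ties counted 1/2. A class without
#' both a positive and a negative example gets `NA`.
#'
#' @param scores numeric matrix, one row per case, one column per class
#'   (scores in \[0, 1\], e.g. per-class max similarity).
#' @param true integer label vector (one per row).
#' @return Numeric vector of per-class AUCs, named by class column.
#' @export
perClassAUC <- function(scores, true) {
  stopifnot(nrow(scores) == length(true))
  cls <- colnames(scores)
  if (is.null(cls)) cls <- as.character(seq_len(ncol(scores)) - 1L)
  auc <- vapply(seq_len(ncol(scores)), function(j) {
    pos <- true == as.integer(cls[j])
    s <- scores[, j]
    keep <- !is.na(s)
    pos <- pos[keep]; s <- s[keep]
    n1 <- sum(pos); n0 <- sum(!pos)
    if (n1 == 0L || n0 == 0L) return(NA_real_)
    r <- rank(s)
    (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  }, 0)
  names(auc) <- cls
  auc
}

#' Assemble a full evaluation report
#'
#' Computes the complete imbalance-insensitive metric suite from per-case
#' truths, predictions and (optionally) per-class scores.
#'
#' @param true,pred integer label vectors.
#' @param scores optional per-case per-class score matrix for AUC.
#' @param folds optional data.frame (case_id, true, pred, tie).
#' @param M number of classes.
#' @return An [EvaluationReport-class].
#' @export
evaluationReport <- function(true, pred, scores = NULL, folds = NULL, M = 5L) {
  cm <- confusionMatrix(true, pred, M)
  pr <- perClassPR(cm)
  if (is.null(scores))
    scores <- matrix(NA_real_, length(true), M,
                     dimnames = list(NULL, colnames(cm)))
  auc <- perClassAUC(scores, true)
  per_class <- data.frame(class = 0:(M - 1L),
                          precision = unname(pr$precision),
                          recall = unname(pr$recall),
                          accuracy = unname(pr$recall),
                          auc = unname(auc))
  if (is.null(folds)) folds <- emptyFoldsFrame()
  new("EvaluationReport", confusion = cm, perClass = per_class,
      macro = macroPRF(pr$precision, pr$recall),
      maeMacro = macroMAE(true, pred, M),
      mcc = mccMulticlass(cm), folds = folds, scores = scores)
}
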