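# naive oracles
binaryMCC <- function(tp, fn, fp, tn) {
  num <- tp * tn - fp * fn
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  if (den == 0) 0 else num / den
}
aucPairCount <- function(scores, pos) {
  sp <- scores[pos]; sn <- scores[!pos]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}
handMacroMAE <- function(true, pred, M) {
  vals <- c()
  for (m in 0:(M - 1)) {
    idx <- which(true == m)
    if (length(idx)) vals <- c(vals, sum(abs(true[idx] - pred[idx])) / length(idx))
  }
  sum(vals) / length(vals)
}

test_that("macroMAE evaluates the per-class deviation formula", {
  expect_identical(macroMAE(c(0, 1, 2, 3), c(0, 1, 2, 3), M = 4L), 0)
  # M = 3: class 0 contributes 0, class 1 -> 1, class 2 -> 2; mean = 1.0
  expect_identical(macroMAE(c(0, 0, 1, 2), c(0, 0, 2, 0), M = 3L), 1)
  # upper bound M - 1 attained
  expect_warning(
    got <- macroMAE(rep(0, 6), rep(4, 6), M = 5L), "absent")
  expect_identical(got, 4)
  expect_error(macroMAE(c(0, 1), c(0), M = 2L), "length")
})

test_that("macroMAE ignores class sample sizes (macro property)", {
  set.seed(5)
  true <- sample(0:2, 30, replace = TRUE)
  pred <- sample(0:2, 30, replace = TRUE)
  base <- macroMAE(true, pred, M = 3L)
  # duplicate every class-1 sample: the macro value must not move
  idx <- which(true == 1)
  expect_equal(macroMAE(c(true, true[idx]), c(pred, pred[idx]), M = 3L),
               base, tolerance = 1e-12)
})

test_that("per-class precision/recall follow the diagonal conventions", {
  cm <- diag(c(3L, 2L, 4L))
  dimnames(cm) <- list(0:2, 0:2)
  pr <- perClassPR(cm)
  expect_true(all(pr$precision == 1) && all(pr$recall == 1))
  # a class never predicted has precision 0 by convention
  cm2 <- matrix(c(0L, 0L, 2L, 3L), 2, 2, dimnames = list(0:1, 0:1))
  pr2 <- perClassPR(cm2)
  expect_identical(unname(pr2$precision[1]), 0)
})

test_that("the printed per-class recalls arise from the leave-one-out
           confusion row ratios", {
  # cohort rows: 4, 18, 11, 7, 3 cases; diagonal 0, 11, 3, 0, 2 reproduces
  # the reported per-class recall/accuracy (0, 0.61, 0.27, 0, 0.67)
  cm <- matrix(0L, 5, 5, dimnames = list(0:4, 0:4))
  cm[1, 2] <- 4L
  cm[2, ] <- c(2L, 11L, 4L, 1L, 0L)
  cm[3, ] <- c(0L, 5L, 3L, 2L, 1L)
  cm[4, ] <- c(0L, 3L, 3L, 0L, 1L)
  cm[5, ] <- c(0L, 0L, 1L, 0L, 2L)
  pr <- perClassPR(cm)
  expect_identical(unname(round(pr$recall, 2)), c(0, 0.61, 0.27, 0, 0.67))
})

test_that("macroPRF is the harmonic mean of the macro averages", {
  # all classes at the same value c is a fixed point
  got <- macroPRF(rep(0.4, 5), rep(0.4, 5))
  expect_equal(unname(got), rep(0.4, 3), tolerance = 1e-12)
  # zero macro precision and recall give F1 = 0
  expect_identical(unname(macroPRF(0, 0)["f1"]), 0)
  # consistency identity on arbitrary values
  set.seed(2)
  P <- runif(5); R <- runif(5)
  g <- macroPRF(P, R)
  expect_equal(unname(g["f1"]),
               2 * g[["precision"]] * g[["recall"]] /
                 (g[["precision"]] + g[["recall"]]), tolerance = 1e-12)
})

test_that("multiclass MCC matches the binary formula on 2x2 tables", {
  expect_identical(mccMulticlass(diag(c(5L, 7L, 3L))), 1)
  # outer product of marginals: predictions independent of truth -> 0
  ind <- outer(c(2L, 4L), c(3L, 3L)) / 3L
  storage.mode(ind) <- "integer"
  expect_equal(mccMulticlass(ind), 0, tolerance = 1e-12)
  set.seed(9)
  for (i in 1:100) {
    tab <- matrix(rpois(4, 5), 2, 2)
    if (sum(tab) == 0) next
    expect_equal(mccMulticlass(tab),
                 binaryMCC(tab[2, 2], tab[2, 1], tab[1, 2], tab[1, 1]),
                 tolerance = 1e-12)
  }
})

test_that("per-class AUC equals Mann-Whitney pair counting", {
  # perfect ranking
  s <- matrix(c(0.9, 0.8, 0.2, 0.1), ncol = 1, dimnames = list(NULL, "1"))
  expect_identical(unname(perClassAUC(s, c(1, 1, 0, 0))), 1)
  # uninformative scores
  s2 <- matrix(rep(0.5, 4), ncol = 1, dimnames = list(NULL, "1"))
  expect_identical(unname(perClassAUC(s2, c(1, 1, 0, 0))), 0.5)
  # the worked 4-case example
  s3 <- matrix(c(0.9, 0.8, 0.7, 0.6), ncol = 1, dimnames = list(NULL, "1"))
  expect_identical(unname(perClassAUC(s3, c(1, 0, 1, 0))), 0.75)
  # random-vector equivalence with the pair-counting oracle
  set.seed(12)
  for (i in 1:50) {
    n <- sample(6:15, 1)
    sc <- round(runif(n), 2)            # ties likely
    lab <- sample(c(0L, 1L), n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    m <- matrix(sc, ncol = 1, dimnames = list(NULL, "1"))
    expect_equal(unname(perClassAUC(m, lab)), aucPairCount(sc, lab == 1L),
                 tolerance = 1e-12)
  }
  # class without positives is NA
  s4 <- matrix(runif(6), ncol = 2, dimnames = list(NULL, c("0", "1")))
  expect_true(is.na(perClassAUC(s4, c(0, 0, 0))[2]))
  # cross-check against an established ROC implementation
  set.seed(13)
  sc <- runif(30)
  lab <- sample(c(0L, 1L), 30, replace = TRUE)
  want <- as.numeric(pROC::auc(pROC::roc(lab, sc, quiet = TRUE,
                                         direction = "<")))
  got <- perClassAUC(matrix(sc, ncol = 1, dimnames = list(NULL, "1")), lab)
  expect_equal(unname(got), want, tolerance = 1e-12)
})

test_that("macroMAE agrees with the hand formula on random label vectors", {
  set.seed(33)
  for (i in 1:100) {
    n <- sample(5:40, 1)
    true <- sample(0:4, n, replace = TRUE)
    pred <- sample(0:4, n, replace = TRUE)
    got <- suppressWarnings(macroMAE(true, pred, M = 5L))
    expect_equal(got, handMacroMAE(true, pred, 5L), tolerance = 1e-12)
  }
})

test_that("evaluationReport assembles a coherent metric suite", {
  set.seed(3)
  true <- sample(0:4, 25, replace = TRUE)
  pred <- sample(0:4, 25, replace = TRUE)
  rep <- suppressWarnings(evaluationReport(true, pred))
  expect_identical(sum(rep@confusion), 25L)
  expect_identical(unname(rowSums(rep@confusion)),
                   vapply(0:4, function(m) sum(true == m), 0L) * 1)
  expect_equal(rep@perClass$accuracy, rep@perClass$recall)
  m <- rep@macro
  expect_equal(unname(m["f1"]),
               2 * m[["precision"]] * m[["recall"]] /
                 max(m[["precision"]] + m[["recall"]], 1e-12),
               tolerance = 1e-9)
  expect_true(rep@mcc >= -1 && rep@mcc <= 1)
})
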