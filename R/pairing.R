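## Stage-2 balancing: the training pair set. All unordered within-class pairs
## (label 1) plus, for each of the Z unordered label pairs, exactly
## floor(S/Z) cross-class pairs (label 0), so that dissimilar label pairs are
## equally emphasized during training.

#' Number of same-class pairs S
#'
#' `S = sum_m C(n_m, 2)` — the count of unordered within-class pairs over all
#' classes (classes with fewer than two samples contribute none).
#'
#' @param class_counts non-negative integer vector of per-class counts.
#' @return Integer S.
#' @export
countSamePairs <- function(class_counts) {
  stopifnot(all(class_counts >= 0))
  as.integer(sum(choose(class_counts, 2)))
}

#' Unordered label pairs LP and their count Z
#'
#' `Z = C(l, 2)` unique unordered pairs of distinct class labels.
#'
#' @param labels vector of at least two distinct class labels.
#' @return `list(LP = <2 x Z matrix of label pairs>, Z = <integer>)`.
#' @export
labelPairs <- function(labels) {
  labels <- sort(unique(labels))
  if (length(labels) < 2L) stop("need at least two distinct labels")
  LP <- utils::combn(labels, 2L)
  list(LP = LP, Z = ncol(LP))
}

#' Build the balanced training pair set
#'
#' Requires a stage-1-balanced sample list (equal class counts). Same-class
#' pairs SP are ALL unordered within-class pairs (|SP| = S); dissimilar pairs
#' DP take exactly `floor(S/Z)` distinct cross-class pairs per label pair,
#' sampled uniformly without replacement, so every one of the Z label pairs
#' gets an identical allocation. The combined list is shuffled. Fully seeded.
#'
#' @param samples list of [PreparedSample-class] with equal per-class counts.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return A [PairSet-class].
#' @export
buildPairs <- function(samples, seed = NULL) {
  labs <- vapply(samples, mrs, 0L)
  classes <- sort(unique(labs))
  counts <- vapply(classes, function(l) sum(labs == l), 0L)
  if (length(classes) < 2L) stop("need samples from at least two classes")
  if (length(unique(counts)) != 1L)
    stop("class counts must be equal (run stage-1 balancing first); got ",
         paste(counts, collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  S <- countSamePairs(counts)
  lp <- labelPairs(classes)
  alloc <- S %/% lp$Z
  if (alloc == 0L)
    warning("floor(S/Z) = 0: no dissimilar pairs can be allocated ",
            "(degenerate pair set; S = ", S, ", Z = ", lp$Z, ")")
  # SP: all within-class pairs
  sp <- do.call(rbind, lapply(classes, function(l) {
    idx <- which(labs == l)
    if (length(idx) < 2L) return(NULL)
    t(utils::combn(idx, 2L))
  }))
  pairs <- if (is.null(sp)) {
    data.frame(a = integer(0), b = integer(0), label = integer(0))
  } else data.frame(a = sp[, 1L], b = sp[, 2L], label = 1L)
  # DP: floor(S/Z) distinct cross pairs per label pair
  if (alloc > 0L) {
    dp <- do.call(rbind, lapply(seq_len(lp$Z), function(z) {
      iu <- which(labs == lp$LP[1L, z])
      iv <- which(labs == lp$LP[2L, z])
      navail <- length(iu) * length(iv)
      if (alloc > navail)
        stop("allocation ", alloc, " exceeds available cross pairs ", navail,
             " for label pair (", lp$LP[1L, z], ",", lp$LP[2L, z], ")")
      pick <- sample.int(navail, alloc) - 1L
      cbind(iu[pick %% length(iu) + 1L], iv[pick %/% length(iu) + 1L])
    }))
    pairs <- rbind(pairs,
                   data.frame(a = dp[, 1L], b = dp[, 2L], label = 0L))
  }
  pairs <- pairs[sample.int(nrow(pairs)), , drop = FALSE]
  rownames(pairs) <- NULL
  new("PairSet", samples = samples, pairs = pairs,
      counts = list(S = S, Z = lp$Z, perPair = alloc,
                    D = as.integer(alloc * lp$Z)))
}

#' Stratified 7:3 train/validation split of a pair set
#'
#' Splits the pairs into disjoint training and validation subsets totalling
#' `round(ratio * n)` training pairs, allocated across the two pair labels by
#' floor plus largest fractional remainder so each label is split 7:3 up to
#' rounding. Seeded.
#'
#' @param pairset a [PairSet-class] with at least two pairs.
#' @param ratio training fraction (default 0.7).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return `list(train = <pair data.frame>, val = <pair data.frame>)`, both
#'   referencing `pairset@samples` by index.
#' @export
splitTrainVal <- function(pairset, ratio = 0.7, seed = NULL) {
  p <- pairset@pairs
  if (nrow(p) < 2L) stop("need at least two pairs to split")
  if (!is.null(seed)) set.seed(seed)
  n_train <- round(ratio * nrow(p))
  strata <- split(seq_len(nrow(p)), p$label)
  quota <- vapply(strata, function(ix) ratio * length(ix), 0)
  base <- floor(quota)
  rem <- n_train - sum(base)
  if (rem > 0) {
    ord <- order(quota - base, decreasing = TRUE)
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  train_idx <- unlist(lapply(seq_along(strata), function(k) {
    ix <- strata[[k]]
    if (base[k] >= length(ix)) ix else sample(ix, base[k])
  }), use.names = FALSE)
  val_idx <- setdiff(seq_len(nrow(p)), train_idx)
  list(train = p[sort(train_idx), , drop = FALSE],
       val = p[sort(val_idx), , drop = FALSE])
}
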