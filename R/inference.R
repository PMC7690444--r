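## Test-time classification and the leave-one-case-out (LOCO) harness.
##
## A held-out sample is paired with EVERY original (non-augmented) training
## sample; the class of the most similar original is the prediction, with
## exact ties broken uniformly at random. The harness re-runs the whole
## pipeline from scratch inside every fold: augmentation, pair construction,
## mean centering and training all see only the 42 remaining cases.

#' Classify one prepared sample by maximum similarity
#'
#' @param model a trained [SiameseModel-class].
#' @param test a centered [PreparedSample-class].
#' @param originals non-empty list of centered [PreparedSample-class], all
#'   with provenance "original" (augmented samples must never appear in the
#'   reference set).
#' @return A list ("FoldResult"): `case_id`, `true`, `pred`, `scores` (named
#'   per-class max similarity; `NA` for classes with no originals), `tie`
#'   (logical), `similarities` (per-original).
#' @export
predictCase <- function(model, test, originals) {
  if (!length(originals)) stop("reference set of originals is empty")
  prov <- vapply(originals, provenance, "")
  if (any(prov != "original"))
    stop("augmented samples must not enter the test-time reference set")
  E <- embedSamples(model, c(list(test), originals))
  u <- E[1L, ]
  sims <- vapply(seq_along(originals), function(i)
    normalizedCosine(u, E[i + 1L, ]), 0)
  labs <- vapply(originals, mrs, 0L)
  scores <- vapply(mrsLabels(), function(m) {
    s <- sims[labs == m]
    if (length(s)) max(s) else NA_real_
  }, 0)
  names(scores) <- as.character(mrsLabels())
  best <- which(sims == max(sims))
  tie <- length(best) > 1L
  pick <- if (tie) best[sample.int(length(best), 1L)] else best
  structure(list(case_id = test@caseId, true = test@mrs,
                 pred = labs[pick], scores = scores, tie = tie,
                 similarities = sims),
            class = c("FoldResult", "list"))
}

#' Leave-one-case-out evaluation of the full pipeline
#'
#' For each case in turn: hold it out; augment the remaining cases to balance
#' (stage 1); mean-center with the fold's training mean; build the balanced
#' pair set (stage 2) and its 7:3 train/validation split; train the siamese
#' network from scratch; classify the held-out case against the fold's
#' originals. Aggregates all folds into an [EvaluationReport-class]. Every
#' random choice derives deterministically from `seed`.
#'
#' A fold whose held-out class has no remaining training exemplar still runs
#' (its prediction can then never be correct) and is flagged in the fold
#' table.
#'
#' @param dataset a [StrokeDataset-class] with at least two classes.
#' @param backbone "toy" (desk-scale) or "vgg16".
#' @param prep_target working grid for [prepareCase()]; the branch input
#'   becomes `prep_target[1:2] x 3`.
#' @param toy_filters per-block filters of the toy backbone.
#' @param policy an [AugmentationPolicy-class].
#' @param config a [trainConfig()] (its `seed` field is ignored; the harness
#'   seeds each fold).
#' @param seed integer master seed.
#' @param keep_fold_details if TRUE, attach per-fold sample provenance
#'   bookkeeping (used by leakage checks) as attribute "fold_details".
#' @return An [EvaluationReport-class].
#' @export
locoEvaluate <- function(dataset, backbone = "toy",
                         prep_target = c(150L, 150L, 21L),
                         toy_filters = c(8L, 16L),
                         policy = augmentationPolicy(),
                         config = trainConfig(), seed = 1L,
                         keep_fold_details = FALSE) {
  n <- length(dataset)
  if (n < 3L) stop("need at least 3 cases")
  labs <- vapply(cases(dataset), mrs, 0L)
  if (length(unique(labs)) < 2L) stop("need at least two classes")
  set.seed(seed)
  fold_seeds <- sample.int(2^20, n)
  prepared <- lapply(cases(dataset), prepareCase, target = prep_target)
  input_shape <- c(prep_target[1:2], 3L)
  results <- vector("list", n)
  details <- vector("list", n)
  for (i in seq_len(n)) {
    set.seed(fold_seeds[i])
    tr <- prepared[-i]
    aug <- augmentToBalance(tr, policy, seed = NULL)
    centered <- foldMeanCenter(aug, prepared[[i]])
    pairset <- buildPairs(centered$train, seed = NULL)
    split <- splitTrainVal(pairset, 0.7, seed = NULL)
    model <- buildSiamese(backbone, input_shape = input_shape,
                          toy_filters = toy_filters,
                          init_sd = config$init_sd, conv_sd = config$conv_sd,
                          seed = NULL)
    model <- trainSiamese(model, pairset@samples, split$train, split$val,
                          config)
    origs <- Filter(function(s) provenance(s) == "original", centered$train)
    results[[i]] <- predictCase(model, centered$test, origs)
    if (keep_fold_details)
      details[[i]] <- list(
        held_out = prepared[[i]]@caseId,
        train_ids = vapply(centered$train, caseId, ""),
        train_sources = vapply(centered$train,
                               function(s) s@sourceCaseId, ""),
        train_provenance = vapply(centered$train, provenance, ""),
        reference_provenance = vapply(origs, provenance, ""),
        structural_miss = !(prepared[[i]]@mrs %in%
                              vapply(origs, mrs, 0L)),
        history = model@history)
  }
  true <- vapply(results, function(r) r$true, 0L)
  pred <- vapply(results, function(r) r$pred, 0L)
  scores <- do.call(rbind, lapply(results, function(r) r$scores))
  folds <- data.frame(
    case_id = vapply(results, function(r) r$case_id, ""),
    true = true, pred = pred,
    tie = vapply(results, function(r) r$tie, TRUE),
    stringsAsFactors = FALSE)
  report <- suppressWarnings(
    evaluationReport(true, pred, scores = scores, folds = folds, M = 5L))
  if (keep_fold_details) attr(report, "fold_details") <- details
  report
}
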