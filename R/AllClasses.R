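#' @import methods
#' @importFrom Rcpp evalCpp
#' @useDynLib pmfesn, .registration = TRUE
NULL

#' Canonical modality names
#'
#' The six co-registered MRI parameter maps used per case: apparent diffusion
#' coefficient and the five perfusion-derived maps. All volume lists and slab
#' lists in the package are named by, and ordered as, this vector.
#'
#' @return Character vector of length 6.
#' @export
#' @examples
#' pmfesnModalities()
pmfesnModalities <- function() c("ADC", "MTT", "TTP", "Tmax", "CBV", "CBF")

#' Modified Rankin Scale labels handled by the package
#'
#' The ordinal outcome labels 0--4 (the range spanned by the target cohort).
#'
#' @return Integer vector 0:4.
#' @export
mrsLabels <- function() 0:4

#' StrokeCase: one patient's co-registered multi-parametric volumes
#'
#' Holds the six aligned 3D parameter maps of a single case together with the
#' three-month modified Rankin Scale label. Clinical covariates (time since
#' stroke, time to treatment, TICI grade) are carried for completeness but
#' never consumed by the model.
#'
#' @slot caseId character scalar identifier.
#' @slot volumes named list of six 3D arrays (ADC, MTT, TTP, Tmax, CBV, CBF),
#'   all of identical dimension (the maps are co-registered).
#' @slot mrs integer outcome label in 0..4.
#' @slot clinical list of optional covariates (tss_minutes, ttt_minutes,
#'   tici_grade); may be empty.
#' @export
setClass("StrokeCase",
  representation(caseId = "character", volumes = "list", mrs = "integer",
                 clinical = "list"),
  prototype(clinical = list()))

setValidity("StrokeCase", function(object) {
  mods <- pmfesnModalities()
  if (length(object@caseId) != 1L || !nzchar(object@caseId))
    return("caseId must be a non-empty string")
  missing <- setdiff(mods, names(object@volumes))
  if (length(missing))
    return(paste0("missing modality volume(s): ", paste(missing, collapse = ", ")))
  if (length(object@volumes) != 6L)
    return("exactly 6 modality volumes required")
  dims <- lapply(object@volumes, dim)
  if (any(vapply(dims, length, 1L) != 3L))
    return("all volumes must be 3D arrays")
  ref <- dims[[1L]]
  for (m in mods[-1L]) {
    if (!identical(dims[[m]], ref))
      return(sprintf("volume shape mismatch: %s is %s but %s is %s",
                     mods[1L], paste(ref, collapse = "x"),
                     m, paste(dims[[m]], collapse = "x")))
  }
  if (length(object@mrs) != 1L || is.na(object@mrs) ||
      object@mrs < 0L || object@mrs > 4L)
    return("mrs must be a single integer in 0..4")
  TRUE
})

#' StrokeDataset: an ordered collection of StrokeCase objects
#'
#' @slot cases list of [StrokeCase-class] objects; order is meaningful
#'   (manifest order) and preserved by all operations.
#' @export
setClass("StrokeDataset", representation(cases = "list"))

setValidity("StrokeDataset", function(object) {
  if (!all(vapply(object@cases, is, TRUE, "StrokeCase")))
    return("all elements of cases must be StrokeCase objects")
  ids <- vapply(object@cases, function(x) x@caseId, "")
  if (anyDuplicated(ids))
    return(paste0("duplicate case_id: ",
                  paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  TRUE
})

#' PreparedSample: the fixed-size network input derived from one case
#'
#' Six per-modality slabs, each height x width x 3 (three middle axial slices
#' as channels), plus provenance tracking so augmented samples can always be
#' distinguished from originals (augmented samples must never enter the
#' test-time reference set).
#'
#' @slot caseId sample identifier (augmented samples get a derived id).
#' @slot slabs named list of six H x W x 3 arrays, same H/W for all six.
#' @slot mrs integer label 0..4.
#' @slot provenance "original" or "augmented".
#' @slot sourceCaseId id of the original case this sample derives from; equals
#'   caseId when provenance is "original".
#' @slot transform the [GeometricTransform] applied (empty list for originals).
#' @export
setClass("PreparedSample",
  representation(caseId = "character", slabs = "list", mrs = "integer",
                 provenance = "character", sourceCaseId = "character",
                 transform = "list"),
  prototype(provenance = "original", transform = list()))

setValidity("PreparedSample", function(object) {
  mods <- pmfesnModalities()
  if (!identical(sort(names(object@slabs)), sort(mods)))
    return("slabs must be named by the six canonical modalities")
  dims <- lapply(object@slabs, dim)
  if (any(vapply(dims, length, 1L) != 3L) ||
      any(vapply(dims, function(d) d[3L], 1L) != 3L))
    return("each slab must be an H x W x 3 array")
  if (length(unique(lapply(dims, function(d) d[1:2]))) != 1L)
    return("all six slabs must share the same in-plane shape")
  if (!object@provenance %in% c("original", "augmented"))
    return("provenance must be 'original' or 'augmented'")
  if (object@provenance == "original" &&
      !identical(object@caseId, object@sourceCaseId))
    return("original samples must have sourceCaseId == caseId")
  if (object@mrs < 0L || object@mrs > 4L)
    return("mrs must be in 0..4")
  TRUE
})

#' PairSet: the balanced training pair set
#'
#' Stores the pool of prepared samples once and references them by index in
#' the pair table, so pairs are cheap.
#'
#' @slot samples list of [PreparedSample-class] objects.
#' @slot pairs data.frame with integer columns `a`, `b` (indices into
#'   `samples`) and `label` (1 = same class, 0 = dissimilar).
#' @slot counts list with elements S (same-class pairs), Z (label pairs),
#'   perPair (allocation per dissimilar label pair), D (dissimilar pairs).
#' @export
setClass("PairSet",
  representation(samples = "list", pairs = "data.frame", counts = "list"))

setValidity("PairSet", function(object) {
  p <- object@pairs
  if (!all(c("a", "b", "label") %in% names(p)))
    return("pairs must have columns a, b, label")
  if (nrow(p)) {
    if (any(p$a == p$b)) return("self-pairs are not allowed")
    if (!all(p$label %in% c(0L, 1L))) return("pair labels must be 0 or 1")
    lab <- vapply(object@samples, function(s) s@mrs, 0L)
    same <- lab[p$a] == lab[p$b]
    if (any(same != (p$label == 1L)))
      return("pair_label must be 1 exactly when the two samples share a class")
  }
  TRUE
})

#' AugmentationPolicy: bounds for random geometric transforms
#'
#' The transform families come from the balancing stage of the method (zoom,
#' rotation, translation, shear, horizontal/vertical flip); the magnitudes are
#' configurable package defaults.
#'
#' @slot rotationMaxDeg max |rotation| in degrees.
#' @slot zoomRange length-2 numeric (low, high) scale factors.
#' @slot translateMaxFrac max |translation| as a fraction of slab size.
#' @slot shearMax max |shear| coefficient.
#' @slot hflip,vflip logical; whether the flip is allowed (drawn Bernoulli 0.5).
#' @export
setClass("AugmentationPolicy",
  representation(rotationMaxDeg = "numeric", zoomRange = "numeric",
                 translateMaxFrac = "numeric", shearMax = "numeric",
                 hflip = "logical", vflip = "logical"),
  prototype(rotationMaxDeg = 10, zoomRange = c(0.9, 1.1),
            translateMaxFrac = 0.1, shearMax = 0.1, hflip = TRUE, vflip = TRUE))

setValidity("AugmentationPolicy", function(object) {
  if (object@rotationMaxDeg < 0) return("rotationMaxDeg must be >= 0")
  if (length(object@zoomRange) != 2L || object@zoomRange[1L] <= 0 ||
      object@zoomRange[1L] > object@zoomRange[2L])
    return("zoomRange must be (low, high) with 0 < low <= high")
  if (object@translateMaxFrac < 0 || object@translateMaxFrac > 0.5)
    return("translateMaxFrac must be in [0, 0.5]")
  if (object@shearMax < 0) return("shearMax must be >= 0")
  TRUE
})

#' EvaluationReport: aggregated leave-one-case-out results
#'
#' @slot confusion M x M integer matrix, rows = true class, cols = predicted.
#' @slot perClass data.frame (class, precision, recall, accuracy, auc).
#' @slot macro named numeric: precision, recall, f1.
#' @slot maeMacro macro-averaged mean absolute error, in [0, M-1].
#' @slot mcc multiclass Matthews correlation coefficient, in [-1, 1].
#' @slot folds data.frame (case_id, true, pred, tie) with one row per
#'   evaluated case; zero rows allowed for reports built from a bare matrix.
#' @slot scores numeric matrix, one row per evaluated case, one column per
#'   class: the per-class max-similarity scores used for AUC.
#' @export
setClass("EvaluationReport",
  representation(confusion = "matrix", perClass = "data.frame",
                 macro = "numeric", maeMacro = "numeric", mcc = "numeric",
                 folds = "data.frame", scores = "matrix"))

setValidity("EvaluationReport", function(object) {
  cm <- object@confusion
  if (!length(cm)) return("confusion matrix must be non-empty")
  if (nrow(cm) != ncol(cm)) return("confusion matrix must be square")
  if (any(cm < 0)) return("confusion entries must be non-negative")
  if (!all(c("precision", "recall", "f1") %in% names(object@macro)))
    return("macro must contain precision, recall, f1")
  TRUE
})

## ---- accessors ----

#' @describeIn StrokeCase-class case identifier
#' @param object a StrokeCase / StrokeDataset / PreparedSample
#' @export
setGeneric("caseId", function(object) standardGeneric("caseId"))
#' @export
setMethod("caseId", "StrokeCase", function(object) object@caseId)
#' @export
setMethod("caseId", "PreparedSample", function(object) object@caseId)

#' mRS label accessor
#' @param object object carrying an mRS label
#' @export
setGeneric("mrs", function(object) standardGeneric("mrs"))
#' @export
setMethod("mrs", "StrokeCase", function(object) object@mrs)
#' @export
setMethod("mrs", "PreparedSample", function(object) object@mrs)

#' Volumes accessor
#' @param object a StrokeCase
#' @export
setGeneric("volumes", function(object) standardGeneric("volumes"))
#' @export
setMethod("volumes", "StrokeCase", function(object) object@volumes)

#' Slabs accessor
#' @param object a PreparedSample
#' @export
setGeneric("slabs", function(object) standardGeneric("slabs"))
#' @export
setMethod("slabs", "PreparedSample", function(object) object@slabs)

#' Provenance accessor ("original" / "augmented")
#' @param object a PreparedSample
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))
#' @export
setMethod("provenance", "PreparedSample", function(object) object@provenance)

#' Cases accessor
#' @param object a StrokeDataset
#' @export
setGeneric("cases", function(object) standardGeneric("cases"))
#' @export
setMethod("cases", "StrokeDataset", function(object) object@cases)

#' Per-class case counts
#'
#' Counts of cases per mRS label 0..4 (named integer vector; a sufficient
#' statistic of the label distribution, invariant to case order).
#'
#' @param object a StrokeDataset or a list of PreparedSample
#' @export
setGeneric("classCounts", function(object) standardGeneric("classCounts"))
#' @export
setMethod("classCounts", "StrokeDataset", function(object) {
  labs <- vapply(object@cases, function(x) x@mrs, 0L)
  tabulateLabels(labs)
})

# shared helper: counts over the fixed label set 0..4
tabulateLabels <- function(labs) {
  out <- integer(length(mrsLabels()))
  names(out) <- as.character(mrsLabels())
  if (length(labs)) {
    t <- table(factor(labs, levels = mrsLabels()))
    out[] <- as.integer(t)
  }
  out
}

#' Number of cases
#' @param x a StrokeDataset
#' @export
setMethod("length", "StrokeDataset", function(x) length(x@cases))

setMethod("show", "StrokeCase", function(object) {
  d <- dim(object@volumes[[1L]])
  cat(sprintf("StrokeCase '%s': 6 maps of %s, mRS = %d\n",
              object@caseId, paste(d, collapse = "x"), object@mrs))
})

setMethod("show", "StrokeDataset", function(object) {
  cc <- classCounts(object)
  cat(sprintf("StrokeDataset: %d cases; per-mRS counts: %s\n",
              length(object@cases),
              paste(sprintf("%s:%d", names(cc), cc), collapse = " ")))
})

setMethod("show", "PreparedSample", function(object) {
  d <- dim(object@slabs[[1L]])
  cat(sprintf("PreparedSample '%s' (%s): 6 slabs %s, mRS = %d\n",
              object@caseId, object@provenance,
              paste(d, collapse = "x"), object@mrs))
})

setMethod("show", "PairSet", function(object) {
  cat(sprintf("PairSet: %d pairs (%d same-class, %d dissimilar) over %d samples\n",
              nrow(object@pairs), sum(object@pairs$label == 1L),
              sum(object@pairs$label == 0L), length(object@samples)))
})

setMethod("show", "EvaluationReport", function(object) {
  cat("EvaluationReport\n")
  cat(sprintf("  cases: %d   MAE^M: %.3f   MCC: %.3f\n",
              sum(object@confusion), object@maeMacro, object@mcc))
  cat(sprintf("  macro P/R/F1: %.3f / %.3f / %.3f\n",
              object@macro["precision"], object@macro["recall"],
              object@macro["f1"]))
})
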