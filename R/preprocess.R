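## Preprocessing: resize to the working grid, take the three middle axial
## slices as channels, and mean-center per evaluation fold.

# Interpolation weight matrix for 1D linear resampling from `s` to `t` points
# with endpoint-preserving (align-corners) spacing: output i (0-based) samples
# source coordinate i*(s-1)/(t-1). For t == 1 the source midpoint is used.
linearWeights <- function(s, t) {
  W <- matrix(0, nrow = t, ncol = s)
  if (s == 1L) { W[, 1L] <- 1; return(W) }
  x <- if (t == 1L) (s - 1) / 2 else (seq_len(t) - 1) * (s - 1) / (t - 1)
  lo <- pmin(floor(x), s - 2)
  w <- x - lo
  idx <- cbind(seq_len(t), lo + 1L)
  W[idx] <- W[idx] + (1 - w)
  idx2 <- cbind(seq_len(t), lo + 2L)
  W[idx2] <- W[idx2] + w
  W
}

applyAlongAxis1 <- function(arr, W) {
  d <- dim(arr)
  out <- W %*% matrix(arr, nrow = d[1L])
  array(out, dim = c(nrow(W), d[2L], d[3L]))
}

#' Resize a 3D volume by separable linear interpolation
#'
#' Resamples each axis in turn with endpoint-preserving linear interpolation
#' (the first and last samples of every axis map exactly onto the first and
#' last samples of the output). The working resolution of the method is
#' 150 x 150 x 21.
#'
#' @param volume a 3D numeric array.
#' @param target integer vector of 3 output dimensions
#'   (default `c(150, 150, 21)`).
#' @return A 3D array of dimension `target`.
#' @export
resizeVolume <- function(volume, target = c(150L, 150L, 21L)) {
  d <- dim(volume)
  if (length(d) != 3L) stop("volume must be a 3D array")
  if (any(d < 1L) || any(target < 1L)) stop("dimensions must be >= 1")
  # axis 1
  out <- applyAlongAxis1(volume, linearWeights(d[1L], target[1L]))
  # axis 2: bring to front, resample, restore
  out <- aperm(applyAlongAxis1(aperm(out, c(2L, 1L, 3L)),
                               linearWeights(d[2L], target[2L])),
               c(2L, 1L, 3L))
  # axis 3
  aperm(applyAlongAxis1(aperm(out, c(3L, 2L, 1L)),
                        linearWeights(d[3L], target[3L])),
        c(3L, 2L, 1L))
}

#' Extract the three middle axial slices as channels
#'
#' For depth D the slice indices are floor(D/2)-1, floor(D/2), floor(D/2)+1
#' (0-based) — the unique symmetric center triple for odd D; for D = 21 these
#' are slices 9, 10, 11. Channels are stacked in ascending depth order.
#'
#' @param volume a 3D array with depth >= 3.
#' @return An H x W x 3 array.
#' @export
extractMiddleSlices <- function(volume) {
  d <- dim(volume)
  if (length(d) != 3L) stop("volume must be a 3D array")
  if (d[3L] < 3L) stop("depth must be >= 3 to extract three middle slices")
  mid <- floor(d[3L] / 2)            # 0-based center
  idx <- (mid - 1L):(mid + 1L) + 1L  # back to 1-based
  volume[, , idx, drop = FALSE]
}

#' Prepare a case for the network
#'
#' Resizes each of the six volumes to the working grid and extracts the three
#' middle axial slices, yielding six H x W x 3 slabs with identical spatial
#' registration. A pure function of the input volumes.
#'
#' @param case a [StrokeCase-class].
#' @param target working grid, default `c(150, 150, 21)`.
#' @return A [PreparedSample-class] with provenance "original".
#' @export
prepareCase <- function(case, target = c(150L, 150L, 21L)) {
  sl <- lapply(volumes(case), function(v)
    extractMiddleSlices(resizeVolume(v, target)))
  new("PreparedSample", caseId = case@caseId, slabs = sl, mrs = case@mrs,
      provenance = "original", sourceCaseId = case@caseId,
      transform = list())
}

#' Fold-wise mean centering
#'
#' Subtracts the voxelwise per-modality mean slab of the training samples
#' (originals and augmented alike — they are all training data in the fold)
#' from every training slab and from the test slab(s). After centering, the
#' per-modality voxelwise mean over the training set is zero.
#'
#' @param train non-empty list of [PreparedSample-class] (the fold's training
#'   set).
#' @param test a single [PreparedSample-class] or a list of them (the held-out
#'   data); may be `NULL`.
#' @return `list(train = ..., test = ..., mean = <named list of mean slabs>)`;
#'   `test` has the same shape as the input (single sample or list).
#' @export
foldMeanCenter <- function(train, test = NULL) {
  if (!length(train)) stop("training set must be non-empty")
  mods <- pmfesnModalities()
  meanSlab <- lapply(mods, function(m) {
    acc <- slabs(train[[1L]])[[m]] * 0
    for (s in train) acc <- acc + slabs(s)[[m]]
    acc / length(train)
  })
  names(meanSlab) <- mods
  center <- function(s) {
    s@slabs <- lapply(mods, function(m) s@slabs[[m]] - meanSlab[[m]])
    names(s@slabs) <- mods
    s
  }
  ctrain <- lapply(train, center)
  ctest <- if (is.null(test)) NULL
           else if (is(test, "PreparedSample")) center(test)
           else lapply(test, center)
  list(train = ctrain, test = ctest, mean = meanSlab)
}
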