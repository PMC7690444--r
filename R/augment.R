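## Stage-1 balancing: bring every class up to the size of the largest class
## by geometric augmentation. One transform per new sample, applied
## identically to all six modality slabs.

#' Construct an augmentation policy
#'
#' Bounds for the random geometric transforms (zoom, rotation, translation,
#' shear, horizontal/vertical flip). Magnitude defaults are package choices:
#' rotation within ±10°, zoom 0.9–1.1, translation within ±10% of the slab,
#' shear within ±0.1, both flips allowed.
#'
#' @param rotation_max_deg,zoom_range,translate_max_frac,shear_max,hflip,vflip
#'   see [AugmentationPolicy-class].
#' @return An [AugmentationPolicy-class].
#' @export
augmentationPolicy <- function(rotation_max_deg = 10, zoom_range = c(0.9, 1.1),
                               translate_max_frac = 0.1, shear_max = 0.1,
                               hflip = TRUE, vflip = TRUE) {
  new("AugmentationPolicy", rotationMaxDeg = rotation_max_deg,
      zoomRange = as.numeric(zoom_range),
      translateMaxFrac = translate_max_frac, shearMax = shear_max,
      hflip = hflip, vflip = vflip)
}

#' Largest class and per-class deficits
#'
#' Identifies I, the largest per-class count, and the number of samples
#' `I - n_m` each class must gain to balance the training set.
#'
#' @param counts named (or plain) non-negative integer vector of per-class
#'   counts; at least one must be positive.
#' @return `list(I = <max count>, deficits = <I - counts>)`.
#' @export
largestClass <- function(counts) {
  counts <- as.integer(counts)
  if (!length(counts) || all(counts == 0L))
    stop("need at least one class with a positive count")
  I <- max(counts)
  list(I = I, deficits = I - counts)
}

#' Draw one random geometric transform within a policy's bounds
#'
#' Continuous parameters are uniform within their bounds; flips are
#' Bernoulli(0.5) where allowed. Uses (and advances) R's RNG stream, so a
#' seeded caller gets a reproducible sequence.
#'
#' @param policy an [AugmentationPolicy-class].
#' @return A `GeometricTransform` (classed list with fields rotation_deg,
#'   zoom, tx_frac, ty_frac, shear, hflip, vflip).
#' @export
sampleTransform <- function(policy) {
  validObject(policy)
  tf <- list(
    rotation_deg = stats::runif(1, -policy@rotationMaxDeg, policy@rotationMaxDeg),
    zoom = stats::runif(1, policy@zoomRange[1L], policy@zoomRange[2L]),
    tx_frac = stats::runif(1, -policy@translateMaxFrac, policy@translateMaxFrac),
    ty_frac = stats::runif(1, -policy@translateMaxFrac, policy@translateMaxFrac),
    shear = stats::runif(1, -policy@shearMax, policy@shearMax),
    hflip = if (policy@hflip) stats::runif(1) < 0.5 else FALSE,
    vflip = if (policy@vflip) stats::runif(1) < 0.5 else FALSE)
  structure(tf, class = c("GeometricTransform", "list"))
}

#' Apply a geometric transform to a slab
#'
#' Warps an H x W x C array in-plane (the same 2D transform for every
#' channel) by inverse-mapped bilinear interpolation about the slab center.
#' Out-of-border samples are filled with 0, consistent with skull-stripped
#' background. The composition order is zoom/shear, then rotation, then flip,
#' then translation; pure flips land exactly on the mirrored grid
#' (column x maps to W - 1 - x in 0-based indexing) and are therefore
#' bit-exact.
#'
#' @param slab an H x W x C numeric array (C arbitrary, typically 3).
#' @param transform a `GeometricTransform` from [sampleTransform()].
#' @return The warped array, same dimensions.
#' @export
applyTransform <- function(slab, transform) {
  d <- dim(slab)
  if (length(d) != 3L) stop("slab must be an H x W x C array")
  H <- d[1L]; W <- d[2L]
  th <- transform$rotation_deg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2L, 2L)
  Sh <- matrix(c(1, 0, transform$shear, 1), 2L, 2L)
  Fm <- diag(c(if (transform$hflip) -1 else 1,
               if (transform$vflip) -1 else 1))
  A <- Fm %*% R %*% Sh * transform$zoom
  Ainv <- solve(A)
  cx <- (W + 1) / 2; cy <- (H + 1) / 2
  tx <- transform$tx_frac * W; ty <- transform$ty_frac * H
  # output grid in (x = column, y = row) coordinates
  xo <- rep(seq_len(W), each = H) - cx - tx
  yo <- rep(seq_len(H), times = W) - cy - ty
  xi <- Ainv[1L, 1L] * xo + Ainv[1L, 2L] * yo + cx
  yi <- Ainv[2L, 1L] * xo + Ainv[2L, 2L] * yo + cy
  x0 <- floor(xi); y0 <- floor(yi)
  wx <- xi - x0; wy <- yi - y0
  out <- array(0, dim = d)
  gather <- function(ch, yy, xx) {
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    v <- numeric(length(yy))
    v[ok] <- ch[yy[ok] + H * (xx[ok] - 1L)]
    v
  }
  for (c in seq_len(d[3L])) {
    ch <- slab[, , c]
    v <- (1 - wx) * (1 - wy) * gather(ch, y0, x0) +
         (1 - wx) * wy       * gather(ch, y0 + 1, x0) +
         wx       * (1 - wy) * gather(ch, y0, x0 + 1) +
         wx       * wy       * gather(ch, y0 + 1, x0 + 1)
    out[, , c] <- v
  }
  out
}

# apply one transform identically to all six modality slabs of a sample
transformSample <- function(sample, transform, new_id) {
  sl <- lapply(slabs(sample), applyTransform, transform = transform)
  new("PreparedSample", caseId = new_id, slabs = sl, mrs = sample@mrs,
      provenance = "augmented", sourceCaseId = sample@sourceCaseId,
      transform = unclass(transform))
}

#' Stage-1 balancing by augmentation
#'
#' Augments every minority class with `I - n_m` new samples (I = largest
#' class count) so that all classes are equally sized before pair creation.
#' Each new sample applies one freshly drawn [sampleTransform()] identically
#' to all six modality slabs; source originals are cycled round-robin in a
#' seeded random order. Only training data may pass through here — the
#' held-out sample of an evaluation fold never does.
#'
#' @param train list of [PreparedSample-class], all with provenance
#'   "original".
#' @param policy an [AugmentationPolicy-class].
#' @param seed integer seed for the transform draws and round-robin order;
#'   `NULL` uses the current RNG state.
#' @param labels optional label set to balance over; any requested label with
#'   no sample is an error (an empty class cannot be augmented). Defaults to
#'   the labels present in `train`.
#' @return List of samples: all originals followed by the augmented samples.
#' @export
augmentToBalance <- function(train, policy = augmentationPolicy(),
                             seed = NULL, labels = NULL) {
  if (!length(train)) stop("training set must be non-empty")
  prov <- vapply(train, provenance, "")
  if (any(prov != "original"))
    stop("augmentToBalance expects original samples only")
  labs <- vapply(train, mrs, 0L)
  if (is.null(labels)) labels <- sort(unique(labs))
  counts <- vapply(labels, function(l) sum(labs == l), 0L)
  lc <- largestClass(counts)
  if (any(counts == 0L & lc$deficits > 0L))
    stop("cannot augment empty class(es): ",
         paste(labels[counts == 0L], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  out <- train
  for (k in seq_along(labels)) {
    def <- lc$deficits[k]
    if (def == 0L) next
    members <- which(labs == labels[k])
    order <- members[sample.int(length(members))]  # seeded round-robin order
    for (j in seq_len(def)) {
      src <- train[[order[(j - 1L) %% length(order) + 1L]]]
      tf <- sampleTransform(policy)
      out[[length(out) + 1L]] <-
        transformSample(src, tf, sprintf("%s_aug%d", src@caseId, j))
    }
  }
  out
}
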