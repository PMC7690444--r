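## Synthetic multi-parametric datasets: imbalanced, ordinal, lesion-like
## signal, controllable separability. The generator exists so the whole
## pipeline (I/O, balancing, pairing, training, evaluation) is exercisable
## without any restricted clinical data.

# Fixed per-modality structure. Lesions reduce diffusion (ADC) and perfusion
# (CBV, CBF) and lengthen the timing maps (MTT, TTP, Tmax); baselines give
# each map its own intensity scale.
.modalityContrast <- c(ADC = -1.0, MTT = 1.2, TTP = 1.0,
                       Tmax = 1.5, CBV = -0.8, CBF = -1.1)
.modalityBaseline <- c(ADC = 10, MTT = 5, TTP = 4, Tmax = 3, CBV = 4, CBF = 6)

#' Configuration for the synthetic data generator
#'
#' @param class_counts integer vector of 5 non-negative per-class case counts
#'   for labels 0..4. The default emulates a heavily imbalanced cohort with a
#'   3-case minority class.
#' @param volume_shape integer triple; kept small by default so tests stay
#'   fast (preprocessing resizes to the working grid anyway).
#' @param effect_size non-negative amplitude scale of the class-dependent
#'   lesion signal; 0 removes all class information.
#' @param noise_sd standard deviation of the i.i.d. Gaussian background noise.
#' @param seed integer RNG seed; equal configs give bit-identical datasets.
#' @return A validated list of class "SyntheticConfig".
#' @export
syntheticConfig <- function(class_counts = c(4L, 18L, 11L, 7L, 3L),
                            volume_shape = c(64L, 64L, 21L),
                            effect_size = 2, noise_sd = 1, seed = 1L) {
  stopifnot(length(class_counts) == 5L, all(class_counts >= 0L),
            sum(class_counts) > 0L,
            length(volume_shape) == 3L, all(volume_shape >= 3L),
            effect_size >= 0, noise_sd >= 0)
  structure(list(class_counts = as.integer(class_counts),
                 volume_shape = as.integer(volume_shape),
                 effect_size = as.numeric(effect_size),
                 noise_sd = as.numeric(noise_sd),
                 seed = as.integer(seed)),
            class = "SyntheticConfig")
}

# One lesion geometry per case, shared by all six maps (the synthetic analogue
# of co-registration): an ellipsoid with random center and semi-axes whose
# amplitude AND extent grow with the ordinal label, so nearby labels look more
# alike than distant ones.
lesionMask <- function(shape, label) {
  ctr <- shape * stats::runif(3L, 0.35, 0.65)
  rad <- pmax(shape * 0.15 * (1 + 0.12 * label) * stats::runif(3L, 0.8, 1.2), 1)
  gx <- (seq_len(shape[1L]) - ctr[1L]) / rad[1L]
  gy <- (seq_len(shape[2L]) - ctr[2L]) / rad[2L]
  gz <- (seq_len(shape[3L]) - ctr[3L]) / rad[3L]
  d2 <- outer(outer(gx^2, gy^2, `+`), gz^2, `+`)
  # smooth falloff toward the rim keeps the signal from being a hard box
  m <- pmax(1 - d2, 0)
  m
}

#' Generate a synthetic imbalanced multi-parametric dataset
#'
#' Each case consists of six aligned volumes: a per-modality baseline plus
#' Gaussian noise plus a lesion-like ellipsoid whose amplitude
#' (`effect_size * (1 + label)`) and extent grow with the class label, scaled
#' per modality by a fixed contrast factor (negative for ADC/CBV/CBF,
#' positive for the timing maps). The same lesion geometry is used for all
#' six maps of a case.
#'
#' @param config a [syntheticConfig()].
#' @return A [StrokeDataset-class] with cases ordered by label then index.
#' @export
generateDataset <- function(config = syntheticConfig()) {
  stopifnot(inherits(config, "SyntheticConfig"))
  if (sum(config$class_counts) == 0L)
    stop("all class counts are zero: empty dataset requested")
  set.seed(config$seed)
  mods <- pmfesnModalities()
  shape <- config$volume_shape
  cs <- list()
  for (label in mrsLabels()) {
    n <- config$class_counts[label + 1L]
    if (n == 0L) next
    for (k in seq_len(n)) {
      mask <- lesionMask(shape, label)
      amp <- config$effect_size * (1 + label)
      vols <- lapply(mods, function(m) {
        .modalityBaseline[[m]] +
          .modalityContrast[[m]] * amp * mask +
          array(stats::rnorm(prod(shape), 0, config$noise_sd), dim = shape)
      })
      names(vols) <- mods
      cs[[length(cs) + 1L]] <-
        strokeCase(sprintf("syn_m%d_%02d", label, k), vols, label)
    }
  }
  strokeDataset(cs)
}

#' Quick separability check of a dataset
#'
#' Leave-one-out accuracy of a nearest-centroid classifier on the 6-vector of
#' per-modality mean intensities. Used as an independent sanity oracle for
#' the generator: accuracy sits near chance at `effect_size = 0` and
#' approaches 1 as the class signal dwarfs the noise.
#'
#' @param dataset a [StrokeDataset-class] with at least two classes present.
#' @return Accuracy in \[0, 1\].
#' @export
separabilityCheck <- function(dataset) {
  labs <- vapply(cases(dataset), mrs, 0L)
  if (length(unique(labs)) < 2L)
    stop("separability check needs at least two classes")
  feats <- t(vapply(cases(dataset), function(cs)
    vapply(volumes(cs), mean, 0), numeric(6L)))
  correct <- 0L
  for (i in seq_along(labs)) {
    tr <- setdiff(seq_along(labs), i)
    cls <- sort(unique(labs[tr]))
    cent <- t(vapply(cls, function(m)
      colMeans(feats[tr[labs[tr] == m], , drop = FALSE]), numeric(6L)))
    d2 <- rowSums((cent - matrix(feats[i, ], nrow(cent), 6L, byrow = TRUE))^2)
    if (cls[which.min(d2)] == labs[i]) correct <- correct + 1L
  }
  correct / length(labs)
}
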