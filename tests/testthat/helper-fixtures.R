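# Shared in-code fixtures. Everything is generated programmatically; nothing
# is read from disk except through tempdir() round-trips.

# a StrokeCase with deterministic contents (value ramp + label offset)
makeCase <- function(id, mrs, shape = c(10L, 10L, 5L), offset = 0) {
  vols <- lapply(seq_along(pmfesnModalities()), function(k) {
    array(offset + k + seq_len(prod(shape)) / prod(shape), dim = shape)
  })
  names(vols) <- pmfesnModalities()
  strokeCase(id, vols, mrs)
}

# a PreparedSample with random slabs whose mean tracks the class label, so
# classes are separable by construction
makeSample <- function(id, mrs, hw = 8L, sd = 0.5) {
  sl <- lapply(pmfesnModalities(), function(m)
    array(stats::rnorm(hw * hw * 3, mean = mrs, sd = sd), dim = c(hw, hw, 3L)))
  names(sl) <- pmfesnModalities()
  new("PreparedSample", caseId = id, slabs = sl, mrs = as.integer(mrs),
      provenance = "original", sourceCaseId = id, transform = list())
}

# n_per_class samples per label (labels = which entries are > 0)
makeSamples <- function(counts, hw = 8L, sd = 0.5) {
  out <- list()
  for (m in mrsLabels()) {
    n <- counts[m + 1L]
    if (n == 0L) next
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- makeSample(sprintf("c%d_%d", m, k), m, hw, sd)
  }
  out
}

# identity geometric transform
identityTransform <- function() {
  structure(list(rotation_deg = 0, zoom = 1, tx_frac = 0, ty_frac = 0,
                 shear = 0, hflip = FALSE, vflip = FALSE),
            class = c("GeometricTransform", "list"))
}

# transform with only the named fields changed
tweakTransform <- function(...) {
  tf <- identityTransform()
  mods <- list(...)
  for (nm in names(mods)) tf[[nm]] <- mods[[nm]]
  tf
}

# the frozen desk-scale study conditions used by the LOCO property checks
deskConfig <- function(seed) {
  syntheticConfig(class_counts = c(4L, 18L, 11L, 7L, 3L),
                  volume_shape = c(16L, 16L, 9L),
                  effect_size = 5, noise_sd = 1, seed = seed)
}
deskLoco <- function(ds, seed, ...) {
  locoEvaluate(ds, backbone = "toy", prep_target = c(8L, 8L, 9L),
               toy_filters = c(6L, 12L), seed = seed, ...)
}
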