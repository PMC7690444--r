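test_that("predictCase picks the class of the most similar original", {
  set.seed(40)
  m <- buildSiamese("toy", input_shape = c(6L, 6L, 3L),
                    toy_filters = c(4L), seed = 41)
  test <- makeSample("t", 1, hw = 6L)
  # a single original forces its class regardless of weights
  one <- list(makeSample("o", 3, hw = 6L))
  fr <- predictCase(m, test, one)
  expect_identical(fr$pred, 3L)
  expect_false(fr$tie)
  expect_true(all(fr$scores[!is.na(fr$scores)] >= 0 &
                    fr$scores[!is.na(fr$scores)] <= 1))
  expect_true(all(is.na(fr$scores[c("0", "1", "2", "4")])))
  # a test sample identical to an original self-matches (similarity 1)
  twin <- makeSample("o2", 2, hw = 6L)
  twin_copy <- new("PreparedSample", caseId = "t2", slabs = slabs(twin),
                   mrs = 2L, provenance = "original", sourceCaseId = "t2",
                   transform = list())
  refs <- list(makeSample("r1", 0, hw = 6L), twin,
               makeSample("r3", 4, hw = 6L))
  fr2 <- predictCase(m, twin_copy, refs)
  expect_identical(fr2$pred, 2L)
  expect_equal(max(fr2$similarities), 1, tolerance = 1e-4)
  expect_error(predictCase(m, test, list()), "empty")
})

test_that("exact ties are flagged and broken uniformly at random", {
  set.seed(42)
  m <- buildSiamese("toy", input_shape = c(6L, 6L, 3L),
                    toy_filters = c(4L), seed = 43)
  test <- makeSample("t", 1, hw = 6L)
  ref <- makeSample("r", 0, hw = 6L)
  # two originals with identical slabs but different classes: engineered
  # exactly equal similarity
  ref2 <- new("PreparedSample", caseId = "r2", slabs = slabs(ref), mrs = 4L,
              provenance = "original", sourceCaseId = "r2",
              transform = list())
  picks <- vapply(1:1000, function(i) {
    fr <- predictCase(m, test, list(ref, ref2))
    expect_true(fr$tie)
    fr$pred
  }, 0L)
  frac0 <- mean(picks == 0L)
  expect_true(frac0 > 0.45 && frac0 < 0.55)
})

test_that("augmented samples are rejected from the reference set", {
  set.seed(44)
  m <- buildSiamese("toy", input_shape = c(6L, 6L, 3L),
                    toy_filters = c(4L), seed = 45)
  test <- makeSample("t", 1, hw = 6L)
  src <- makeSample("s", 0, hw = 6L)
  aug <- new("PreparedSample", caseId = "s_aug1", slabs = slabs(src),
             mrs = 0L, provenance = "augmented", sourceCaseId = "s",
             transform = identityTransform() |> unclass())
  expect_error(predictCase(m, test, list(src, aug)), "augmented")
})

test_that("leave-one-case-out accounts for every case exactly once", {
  cfg <- syntheticConfig(class_counts = c(2L, 3L, 3L, 0L, 2L),
                         volume_shape = c(12L, 12L, 7L),
                         effect_size = 4, noise_sd = 1, seed = 46)
  ds <- generateDataset(cfg)
  rep <- locoEvaluate(ds, backbone = "toy", prep_target = c(6L, 6L, 7L),
                      toy_filters = c(4L), seed = 47,
                      keep_fold_details = TRUE)
  n <- length(ds)
  expect_identical(sum(rep@confusion), n)
  expect_identical(nrow(rep@folds), n)
  expect_identical(sort(rep@folds$case_id),
                   sort(vapply(cases(ds), caseId, "")))
  # confusion row sums equal the true per-class counts
  expect_identical(as.integer(rowSums(rep@confusion)),
                   unname(classCounts(ds)))
  # no leakage: the held-out case contributes nothing to its fold
  det <- attr(rep, "fold_details")
  for (d in det) {
    expect_false(d$held_out %in% d$train_ids)
    expect_false(d$held_out %in% d$train_sources)
    expect_true(all(d$reference_provenance == "original"))
  }
})

test_that("identical seeds reproduce the leave-one-out report bit-exactly", {
  cfg <- syntheticConfig(class_counts = c(2L, 2L, 2L, 0L, 0L),
                         volume_shape = c(10L, 10L, 5L),
                         effect_size = 4, noise_sd = 1, seed = 48)
  ds <- generateDataset(cfg)
  r1 <- locoEvaluate(ds, backbone = "toy", prep_target = c(6L, 6L, 5L),
                     toy_filters = c(4L), seed = 49)
  r2 <- locoEvaluate(ds, backbone = "toy", prep_target = c(6L, 6L, 5L),
                     toy_filters = c(4L), seed = 49)
  expect_identical(r1@confusion, r2@confusion)
  expect_identical(r1@folds, r2@folds)
  expect_identical(r1@scores, r2@scores)
  expect_identical(r1@maeMacro, r2@maeMacro)
  expect_identical(r1@mcc, r2@mcc)
})

test_that("a fold whose class vanishes from training still runs", {
  # class 4 has a single case: its fold must proceed and miss structurally
  cfg <- syntheticConfig(class_counts = c(2L, 3L, 0L, 0L, 1L),
                         volume_shape = c(10L, 10L, 5L),
                         effect_size = 4, noise_sd = 1, seed = 50)
  ds <- generateDataset(cfg)
  rep <- locoEvaluate(ds, backbone = "toy", prep_target = c(6L, 6L, 5L),
                      toy_filters = c(4L), seed = 51,
                      keep_fold_details = TRUE)
  det <- attr(rep, "fold_details")
  solo <- which(vapply(cases(ds), mrs, 0L) == 4L)
  expect_true(det[[solo]]$structural_miss)
  expect_false(rep@folds$pred[solo] == 4L)
  expect_identical(sum(rep@confusion), 6L)
})
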