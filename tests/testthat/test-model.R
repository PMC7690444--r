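# closed-form parameter counts, computed independently of branchSpec
convParams <- function(cin, cout) 3 * 3 * cin * cout + cout
denseParams <- function(nin, nout) nin * nout + nout

test_that("toy branch parameter counts match closed-form algebra", {
  sp <- branchSpec("toy", input_shape = c(64L, 64L, 3L),
                   toy_filters = c(8L, 16L))
  # 64 -> pool 32 -> pool 16; flatten 16*16*16 = 4096
  flat <- 16 * 16 * 16
  want_total <- convParams(3, 8) + convParams(8, 16) + 4 * flat +
    denseParams(flat, 20) + denseParams(20, 10)
  want_trainable <- convParams(8, 16) + 2 * flat +
    denseParams(flat, 20) + denseParams(20, 10)
  got <- countParameters(sp)
  expect_identical(got$total, want_total)
  expect_identical(got$trainable, want_trainable)
  expect_identical(got$total, got$trainable + got$non_trainable)
  expect_error(branchSpec("resnet"), "arg")
})

test_that("countParameters sums six branches for the full model", {
  m <- buildSiamese("toy", input_shape = c(8L, 8L, 3L),
                    toy_filters = c(4L, 6L), seed = 1)
  per <- countParameters(branchSpec("toy", c(8L, 8L, 3L), c(4L, 6L)))
  tot <- countParameters(m)
  expect_identical(tot$trainable, 6 * per$trainable)
  expect_identical(tot$total, 6 * per$total)
})

test_that("normalizedCosine maps onto [0, 1] with the fixed conventions", {
  u <- c(1, 2, -3, 0.5)
  expect_equal(normalizedCosine(u, u), 1, tolerance = 1e-7)
  expect_equal(normalizedCosine(u, -u), 0, tolerance = 1e-7)
  expect_equal(normalizedCosine(c(1, 0), c(0, 1)), 0.5, tolerance = 1e-12)
  expect_identical(normalizedCosine(c(0, 0), c(1, 1)), 0.5)
  # symmetry is bit-exact
  set.seed(4)
  v <- rnorm(10); w <- rnorm(10)
  expect_identical(normalizedCosine(v, w), normalizedCosine(w, v))
})

test_that("the similarity-head gradient matches finite differences", {
  ns <- asNamespace("pmfesn")
  set.seed(14)
  U <- matrix(rnorm(3 * 8), 3, 8)
  V <- matrix(rnorm(3 * 8), 3, 8)
  y <- c(1, 0, 1)
  h <- ns$pairHead(U, V, y)
  eps <- 1e-6
  for (k in sample(length(U), 12)) {
    Up <- U; Up[k] <- U[k] + eps
    Um <- U; Um[k] <- U[k] - eps
    num <- (ns$pairHead(Up, V, y, grad = FALSE)$loss -
            ns$pairHead(Um, V, y, grad = FALSE)$loss) / (2 * eps)
    expect_equal(h$dU[k], num, tolerance = 1e-4)
  }
  for (k in sample(length(V), 6)) {
    Vp <- V; Vp[k] <- V[k] + eps
    Vm <- V; Vm[k] <- V[k] - eps
    num <- (ns$pairHead(U, Vp, y, grad = FALSE)$loss -
            ns$pairHead(U, Vm, y, grad = FALSE)$loss) / (2 * eps)
    expect_equal(h$dV[k], num, tolerance = 1e-4)
  }
})

test_that("branch backward matches finite differences through every layer", {
  ns <- asNamespace("pmfesn")
  set.seed(42)
  spec <- branchSpec("toy", input_shape = c(8L, 8L, 3L),
                     toy_filters = c(4L, 6L))
  layers <- ns$instantiateLayers(spec, 0.05, 0.1)
  x <- array(rnorm(8 * 8 * 3 * 4), dim = c(8, 8, 3, 4))
  y <- c(1, 0); pa <- c(1, 3); pb <- c(2, 4)
  lossOf <- function(ls) {
    E <- ns$branchForward(ls, x, train = TRUE)$out
    ns$pairHead(E[pa, , drop = FALSE], E[pb, , drop = FALSE], y,
                grad = FALSE)$loss
  }
  fw <- ns$branchForward(layers, x, train = TRUE)
  h <- ns$pairHead(fw$out[pa, , drop = FALSE], fw$out[pb, , drop = FALSE], y)
  dE <- matrix(0, 4, 10)
  for (k in 1:2) {
    dE[pa[k], ] <- dE[pa[k], ] + h$dU[k, ]
    dE[pb[k], ] <- dE[pb[k], ] + h$dV[k, ]
  }
  grads <- ns$branchBackward(layers, fw$cache, dE)
  eps <- 1e-4
  for (i in seq_along(layers)) {
    gr <- grads[[i]]
    if (is.null(gr)) next
    for (nm in names(gr)) {
      p <- layers[[i]][[nm]]
      for (k in sample(length(p), min(4, length(p)))) {
        lp <- layers; lp[[i]][[nm]][k] <- p[k] + eps
        lm <- layers; lm[[i]][[nm]][k] <- p[k] - eps
        num <- (lossOf(lp) - lossOf(lm)) / (2 * eps)
        ana <- gr[[nm]][k]
        expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 5e-3)
      }
    }
  }
})

test_that("forwardPair is symmetric, bounded, and 1 on identical inputs", {
  set.seed(15)
  m <- buildSiamese("toy", input_shape = c(6L, 6L, 3L),
                    toy_filters = c(4L), seed = 2)
  a <- makeSample("a", 1, hw = 6L)
  b <- makeSample("b", 3, hw = 6L)
  expect_equal(forwardPair(m, a, a), 1, tolerance = 1e-4)
  expect_identical(forwardPair(m, a, b), forwardPair(m, b, a))
  s <- forwardPair(m, a, b)
  expect_true(s >= 0 && s <= 1)
  # shape guard
  bad <- makeSample("c", 1, hw = 8L)
  expect_error(forwardPair(m, a, bad), "shape")
})

test_that("training with lr = 0 leaves all trainable weights untouched", {
  set.seed(16)
  samples <- makeSamples(c(0L, 3L, 3L, 0L, 0L), hw = 6L)
  ps <- buildPairs(samples, seed = 1)
  sp <- splitTrainVal(ps, seed = 2)
  m0 <- buildSiamese("toy", input_shape = c(6L, 6L, 3L),
                     toy_filters = c(4L, 6L), seed = 3)
  cfg <- trainConfig(lr = 0, max_epochs = 2, seed = 4)
  m1 <- trainSiamese(m0, ps@samples, sp$train, sp$val, cfg)
  for (mod in pmfesnModalities()) {
    for (i in seq_along(m0@branches[[mod]])) {
      ly0 <- m0@branches[[mod]][[i]]
      ly1 <- m1@branches[[mod]][[i]]
      for (nm in intersect(names(ly0), c("w", "b", "W", "gamma", "beta")))
        expect_identical(ly1[[nm]], ly0[[nm]])
    }
  }
})

test_that("frozen convolution blocks never move during real training", {
  set.seed(17)
  samples <- makeSamples(c(0L, 3L, 0L, 3L, 0L), hw = 6L)
  ps <- buildPairs(samples, seed = 5)
  sp <- splitTrainVal(ps, seed = 6)
  m0 <- buildSiamese("toy", input_shape = c(6L, 6L, 3L),
                     toy_filters = c(4L, 6L), seed = 7)
  m1 <- trainSiamese(m0, ps@samples, sp$train, sp$val,
                     trainConfig(lr = 1e-2, max_epochs = 3, seed = 8))
  for (mod in pmfesnModalities()) {
    frozen0 <- m0@branches[[mod]][[1]]   # block1 conv (frozen)
    frozen1 <- m1@branches[[mod]][[1]]
    expect_identical(frozen1$w, frozen0$w)
    expect_identical(frozen1$b, frozen0$b)
    # while the trainable block did move
    expect_false(identical(m1@branches[[mod]][[3]]$w,
                           m0@branches[[mod]][[3]]$w))
  }
})

test_that("the early-stop rule halts one epoch after a sub-delta improvement", {
  # improvement at epoch 3 is 5e-5 <= 1e-4, so training halts at epoch 4
  losses <- c(0.70, 0.60, 0.59995, 0.59, 0.58, 0.57)
  expect_identical(earlyStopEpoch(losses, 1e-4, 1L), 4L)
  # monotone fast improvement never stops early
  expect_identical(earlyStopEpoch(c(0.7, 0.6, 0.5, 0.4), 1e-4, 1L), 4L)
  # patience 0 halts immediately at the flat epoch
  expect_identical(earlyStopEpoch(losses, 1e-4, 0L), 3L)
  expect_identical(earlyStopEpoch(0.5, 1e-4, 1L), 1L)
})

test_that("trainSiamese stops within the epoch budget and records history", {
  set.seed(18)
  samples <- makeSamples(c(0L, 3L, 3L, 0L, 0L), hw = 6L)
  ps <- buildPairs(samples, seed = 9)
  sp <- splitTrainVal(ps, seed = 10)
  m <- buildSiamese("toy", input_shape = c(6L, 6L, 3L),
                    toy_filters = c(4L), seed = 11)
  cfg <- trainConfig(max_epochs = 6, seed = 12)
  mt <- trainSiamese(m, ps@samples, sp$train, sp$val, cfg)
  expect_true(nrow(mt@history) <= 6)
  expect_true(all(is.finite(mt@history$train_loss)))
  expect_true(all(is.finite(mt@history$val_loss)))
  expect_identical(
    nrow(mt@history),
    as.integer(earlyStopEpoch(mt@history$train_loss, 1e-4, 1L)))
  # a single-label pair set is rejected
  only_same <- ps@pairs[ps@pairs$label == 1L, ]
  expect_error(trainSiamese(m, ps@samples, only_same, NULL, cfg), "label")
})

test_that("training separates held-out same-class from dissimilar pairs", {
  # small but separable problem; embeddings should rank same-class pairs
  # above dissimilar ones in most runs
  wins <- 0L
  for (s in 1:3) {
    set.seed(100 + s)
    samples <- makeSamples(c(0L, 5L, 5L, 0L, 0L), hw = 6L, sd = 0.3)
    ps <- buildPairs(samples, seed = s)
    sp <- splitTrainVal(ps, seed = s)
    m <- buildSiamese("toy", input_shape = c(6L, 6L, 3L),
                      toy_filters = c(4L, 6L), seed = s)
    mt <- trainSiamese(m, ps@samples, sp$train, sp$val,
                       trainConfig(seed = s))
    E <- embedSamples(mt, ps@samples)
    v <- sp$val
    sims <- vapply(seq_len(nrow(v)), function(k)
      normalizedCosine(E[v$a[k], ], E[v$b[k], ]), 0)
    if (mean(sims[v$label == 1L]) > mean(sims[v$label == 0L]))
      wins <- wins + 1L
  }
  expect_gte(wins, 2L)
})

test_that("a saved model reloads to bit-identical predictions", {
  set.seed(19)
  m <- buildSiamese("toy", input_shape = c(6L, 6L, 3L),
                    toy_filters = c(4L), seed = 20)
  a <- makeSample("a", 1, hw = 6L)
  b <- makeSample("b", 2, hw = 6L)
  p <- file.path(withr::local_tempdir(), "model.rds")
  saveModel(m, p)
  m2 <- loadModel(p)
  expect_identical(forwardPair(m2, a, b), forwardPair(m, a, b))
})
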