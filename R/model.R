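## The parallel multi-parametric feature-embedded siamese network.
##
## Six per-modality branch CNNs (weights NOT shared across modalities) embed
## each sample; the two samples of a pair pass through the SAME branches
## (twin weight sharing), their 6 x 10 branch outputs are concatenated to a
## 60-d vector each, and the pair score is the normalized cosine similarity
## (1 + cos)/2 in [0, 1]. Training minimizes binary cross-entropy on pair
## labels with SGD + momentum.
##
## Two backbones: "vgg16" (the fidelity architecture: 5 conv blocks, blocks
## 1-4 frozen, block 5 fine-tuned) and "toy" (a small configurable conv net
## with the same head and freeze policy, for desk-scale training).

## ---- architecture specs ----

vggBlocks <- list(c(64L, 64L), c(128L, 128L), c(256L, 256L, 256L),
                  c(512L, 512L, 512L), c(512L, 512L, 512L))

#' Describe one branch architecture
#'
#' Builds the layer-by-layer description (output shapes, per-layer trainable
#' and frozen parameter counts) of a single modality branch: a convolutional
#' backbone followed by flatten, batch normalization, dense(20, ReLU) and
#' dense(10, ReLU). All conv layers are 3x3, stride 1, "same" padding, each
#' block ending in 2x2 max pooling. Convolutional blocks before the last one
#' are frozen; the last block is fine-tuned, as are all head layers (batch
#' normalization moving statistics are non-trainable bookkeeping).
#'
#' @param backbone "vgg16" (13 conv layers in 5 blocks) or "toy" (one 3x3
#'   conv per block, filter counts from `toy_filters`).
#' @param input_shape integer triple H, W, C of the branch input
#'   (default 150 x 150 x 3; configurable for the toy backbone).
#' @param toy_filters integer vector of per-block filter counts for the toy
#'   backbone (default c(8, 16)).
#' @return A list with elements `backbone`, `input_shape`, and `layers`
#'   (data.frame: name, type, out_h, out_w, out_c, params_trainable,
#'   params_frozen, trainable).
#' @export
branchSpec <- function(backbone = c("vgg16", "toy"),
                       input_shape = c(150L, 150L, 3L),
                       toy_filters = c(8L, 16L)) {
  backbone <- match.arg(backbone)
  blocks <- if (backbone == "vgg16") vggBlocks
            else lapply(as.integer(toy_filters), identity)
  if (!length(blocks)) stop("backbone needs at least one conv block")
  h <- input_shape[1L]; w <- input_shape[2L]; cin <- input_shape[3L]
  rows <- list(data.frame(name = "input", type = "input", out_h = h,
                          out_w = w, out_c = cin, params_trainable = 0,
                          params_frozen = 0, trainable = FALSE))
  nb <- length(blocks)
  for (b in seq_len(nb)) {
    trainable <- (b == nb)          # fine-tune only the last conv block
    for (k in seq_along(blocks[[b]])) {
      f <- blocks[[b]][k]
      np <- 9L * cin * f + f
      rows[[length(rows) + 1L]] <- data.frame(
        name = sprintf("block%d_conv%d", b, k), type = "conv",
        out_h = h, out_w = w, out_c = f,
        params_trainable = if (trainable) np else 0,
        params_frozen = if (trainable) 0 else np, trainable = trainable)
      cin <- f
    }
    h <- h %/% 2L; w <- w %/% 2L
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("block%d_pool", b), type = "pool", out_h = h,
      out_w = w, out_c = cin, params_trainable = 0, params_frozen = 0,
      trainable = FALSE)
  }
  flat <- h * w * cin
  rows[[length(rows) + 1L]] <- data.frame(
    name = "flatten", type = "flatten", out_h = 1L, out_w = 1L, out_c = flat,
    params_trainable = 0, params_frozen = 0, trainable = FALSE)
  # batch normalization: scale/shift trainable, moving statistics not
  rows[[length(rows) + 1L]] <- data.frame(
    name = "batch_normalization", type = "bn", out_h = 1L, out_w = 1L,
    out_c = flat, params_trainable = 2 * flat, params_frozen = 2 * flat,
    trainable = TRUE)
  rows[[length(rows) + 1L]] <- data.frame(
    name = "dense_1", type = "dense", out_h = 1L, out_w = 1L, out_c = 20L,
    params_trainable = flat * 20 + 20, params_frozen = 0, trainable = TRUE)
  rows[[length(rows) + 1L]] <- data.frame(
    name = "dense_2", type = "dense", out_h = 1L, out_w = 1L, out_c = 10L,
    params_trainable = 20 * 10 + 10, params_frozen = 0, trainable = TRUE)
  list(backbone = backbone, input_shape = as.integer(input_shape),
       layers = do.call(rbind, rows))
}

#' Count parameters of a branch spec, branch, or full siamese model
#'
#' Sums per-layer parameter counts: total, trainable, and non-trainable
#' (frozen convolutions plus batch-normalization moving statistics). For a
#' full model the six modality branches are summed (twin sharing across the
#' two inputs of a pair means the twins add nothing).
#'
#' @param x a [branchSpec()] result, a [buildBranch()] result, or a
#'   [SiameseModel-class].
#' @return `list(total = , trainable = , non_trainable = )`.
#' @export
countParameters <- function(x) {
  if (is(x, "SiameseModel")) {
    per <- countParameters(x@spec$branch)
    return(list(total = 6 * per$total, trainable = 6 * per$trainable,
                non_trainable = 6 * per$non_trainable))
  }
  if (is.list(x) && !is.null(x$spec)) x <- x$spec
  if (is.null(x$layers)) stop("not a branch spec, branch, or model")
  tr <- sum(x$layers$params_trainable)
  fz <- sum(x$layers$params_frozen)
  list(total = tr + fz, trainable = tr, non_trainable = fz)
}

## ---- weight instantiation ----

# One layer object per spec row, with weights where applicable. Non-conv
# weights ~ N(0, init_sd) (the method's stated initialization); conv weights
# (pretrained in the fidelity setting) fall back to N(0, conv_sd) for
# offline/random initialization; batch-norm scale starts at 1, shift at 0.
instantiateLayers <- function(spec, init_sd = 0.01, conv_sd = 0.05) {
  layers <- list()
  cin <- spec$input_shape[3L]
  for (i in seq_len(nrow(spec$layers))) {
    row <- spec$layers[i, ]
    ly <- switch(as.character(row$type),
      input = NULL,
      conv = {
        l <- list(type = "conv", name = row$name,
                  w = matrix(stats::rnorm(9L * cin * row$out_c, 0, conv_sd),
                             9L * cin, row$out_c),
                  b = numeric(row$out_c), trainable = row$trainable)
        cin <- row$out_c
        l
      },
      pool = list(type = "pool", name = row$name),
      flatten = list(type = "flatten", name = row$name),
      bn = list(type = "bn", name = row$name,
                gamma = rep(1, row$out_c), beta = numeric(row$out_c),
                mmean = numeric(row$out_c), mvar = rep(1, row$out_c),
                trainable = TRUE),
      dense = {
        nin <- spec$layers$out_c[i - 1L]
        list(type = "dense", name = row$name,
             W = matrix(stats::rnorm(nin * row$out_c, 0, init_sd),
                        nin, row$out_c),
             b = stats::rnorm(row$out_c, 0, init_sd), trainable = TRUE)
      },
      stop("unknown layer type: ", row$type))
    if (!is.null(ly)) layers[[length(layers) + 1L]] <- ly
  }
  layers
}

#' Build one branch network
#'
#' Instantiates the weights of a single modality branch according to its
#' [branchSpec()]. No pretrained weights are required: convolutions are
#' randomly initialized (the fidelity setting would transplant pretrained
#' filters into the same structure).
#'
#' @inheritParams branchSpec
#' @param init_sd standard deviation for non-convolutional weights
#'   (default 0.01, the method's stated initialization).
#' @param conv_sd standard deviation for random convolutional weights.
#' @return `list(spec = , layers = )` — the symbolic spec plus weight layers.
#' @export
buildBranch <- function(backbone = c("vgg16", "toy"),
                        input_shape = c(150L, 150L, 3L),
                        toy_filters = c(8L, 16L),
                        init_sd = 0.01, conv_sd = 0.05) {
  spec <- branchSpec(backbone, input_shape, toy_filters)
  list(spec = spec, layers = instantiateLayers(spec, init_sd, conv_sd))
}

#' SiameseModel: six modality branches plus training bookkeeping
#'
#' @slot spec list: the shared branch spec plus modality order.
#' @slot branches named list (one weight-layer list per modality). Branch
#'   weights are shared between the two inputs of a pair (twin sharing) but
#'   not across modalities.
#' @slot config the training configuration used (list).
#' @slot history data.frame of per-epoch train/validation loss.
#' @export
setClass("SiameseModel",
  representation(spec = "list", branches = "list", config = "list",
                 history = "data.frame"))

setMethod("show", "SiameseModel", function(object) {
  p <- countParameters(object)
  cat(sprintf("SiameseModel (%s backbone, input %s): 6 branches, 60-d embedding\n",
              object@spec$branch$backbone,
              paste(object@spec$branch$input_shape, collapse = "x")))
  cat(sprintf("  params: %s total, %s trainable, %s non-trainable\n",
              format(p$total, big.mark = ","),
              format(p$trainable, big.mark = ","),
              format(p$non_trainable, big.mark = ",")))
  if (nrow(object@history))
    cat(sprintf("  trained %d epoch(s), final train loss %.5f\n",
                nrow(object@history),
                object@history$train_loss[nrow(object@history)]))
})

#' Build the full six-branch siamese model
#'
#' @inheritParams buildBranch
#' @param seed integer seed for weight initialization; `NULL` uses the
#'   current RNG state.
#' @param instantiate create the weight arrays (default). `FALSE` builds the
#'   architecture only — enough for parameter counting and inspection, and
#'   cheap even for the 89-million-parameter vgg16 configuration.
#' @return An untrained [SiameseModel-class].
#' @export
buildSiamese <- function(backbone = c("vgg16", "toy"),
                         input_shape = c(150L, 150L, 3L),
                         toy_filters = c(8L, 16L), init_sd = 0.01,
                         conv_sd = 0.05, seed = NULL, instantiate = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  spec <- branchSpec(backbone, input_shape, toy_filters)
  branches <- if (instantiate) {
    lapply(pmfesnModalities(), function(m)
      instantiateLayers(spec, init_sd, conv_sd))
  } else {
    lapply(pmfesnModalities(), function(m) list())
  }
  names(branches) <- pmfesnModalities()
  new("SiameseModel", spec = list(branch = spec),
      branches = branches, config = list(),
      history = data.frame(epoch = integer(0), train_loss = numeric(0),
                           val_loss = numeric(0)))
}

## ---- layer engine (forward / backward) ----

# row-broadcast helpers (x is n x f, v length f); faster than sweep()
rowBroadcast <- function(x, v, op) op(x, rep(v, each = nrow(x)))

branchForward <- function(layers, x, train = FALSE, keep_cache = train) {
  cache <- if (keep_cache) vector("list", length(layers)) else NULL
  bn_updates <- list()
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    if (ly$type == "conv") {
      d <- dim(x)
      # ReLU fused into the kernel; patches kept only when the weight
      # gradient will be needed
      keep_p <- keep_cache && ly$trainable
      fw <- cpp_conv2d_fwd(x, as.integer(d), ly$w, ly$b, TRUE, keep_p)
      if (keep_cache)
        cache[[i]] <- list(x = x, dims = d, act = fw$out,
                           patches = if (keep_p) fw$patches
                                     else matrix(0, 0L, 0L))
      x <- fw$out
    } else if (ly$type == "pool") {
      d <- dim(x)
      p <- cpp_maxpool2_fwd(x, as.integer(d))
      if (keep_cache) cache[[i]] <- list(dims = d, argmax = p$argmax)
      x <- p$out
    } else if (ly$type == "flatten") {
      d <- dim(x)
      if (keep_cache) cache[[i]] <- list(dims = d)
      x <- t(matrix(x, ncol = d[4L]))          # N x flat
    } else if (ly$type == "bn") {
      eps <- 1e-3
      if (train) {
        mu <- colMeans(x)
        xc <- rowBroadcast(x, mu, `-`)
        v <- colMeans(xc * xc)                 # biased batch variance
        inv <- 1 / sqrt(v + eps)
        xhat <- rowBroadcast(xc, inv, `*`)
        bn_updates[[length(bn_updates) + 1L]] <-
          list(i = i, mu = mu, v = v)
        if (keep_cache) cache[[i]] <- list(xhat = xhat, inv = inv)
        x <- rowBroadcast(rowBroadcast(xhat, ly$gamma, `*`), ly$beta, `+`)
      } else {
        inv <- 1 / sqrt(ly$mvar + eps)
        xhat <- rowBroadcast(rowBroadcast(x, ly$mmean, `-`), inv, `*`)
        x <- rowBroadcast(rowBroadcast(xhat, ly$gamma, `*`), ly$beta, `+`)
      }
    } else if (ly$type == "dense") {
      y <- rowBroadcast(x %*% ly$W, ly$b, `+`)
      a <- y * (y > 0)             # ReLU
      if (keep_cache) cache[[i]] <- list(x = x, mask = y > 0)
      x <- a
    }
  }
  list(out = x, cache = cache, bn_updates = bn_updates)
}

branchBackward <- function(layers, cache, dout) {
  grads <- vector("list", length(layers))
  g <- dout
  for (i in rev(seq_along(layers))) {
    ly <- layers[[i]]
    if (ly$type == "dense") {
      cc <- cache[[i]]
      g <- g * cc$mask
      grads[[i]] <- list(W = crossprod(cc$x, g), b = colSums(g))
      g <- tcrossprod(g, ly$W)     # g %*% t(W)
    } else if (ly$type == "bn") {
      cc <- cache[[i]]
      dgamma <- colSums(g * cc$xhat)
      dbeta <- colSums(g)
      dxhat <- rowBroadcast(g, ly$gamma, `*`)
      # dx under batch statistics (biased variance)
      t1 <- rowBroadcast(dxhat, colMeans(dxhat), `-`)
      t2 <- rowBroadcast(cc$xhat, colMeans(dxhat * cc$xhat), `*`)
      g <- rowBroadcast(t1 - t2, cc$inv, `*`)
      grads[[i]] <- list(gamma = dgamma, beta = dbeta)
    } else if (ly$type == "flatten") {
      g <- array(t(g), dim = cache[[i]]$dims)
    } else if (ly$type == "pool") {
      g <- cpp_maxpool2_bwd(g, cache[[i]]$argmax,
                            as.integer(cache[[i]]$dims))
    } else if (ly$type == "conv") {
      cc <- cache[[i]]
      first <- !any(vapply(layers[seq_len(i - 1L)],
                           function(l) l$type == "conv", TRUE))
      need_dx <- !first
      bw <- cpp_conv2d_bwd(cc$x, as.integer(cc$dims), ly$w, cc$act, g,
                           cc$patches, need_dx, ly$trainable)
      if (ly$trainable) grads[[i]] <- list(w = bw$dw, b = bw$db)
      if (!need_dx) break
      g <- bw$dx
    }
  }
  grads
}

# SGD with momentum; frozen layers are never touched. Returns updated layers
# and velocities.
sgdStep <- function(layers, grads, vel, lr, momentum) {
  for (i in seq_along(layers)) {
    ly <- layers[[i]]
    gr <- grads[[i]]
    if (is.null(gr)) next
    if (ly$type == "conv" && !ly$trainable) next
    for (nm in names(gr)) {
      key <- paste0(i, ".", nm)
      v <- if (is.null(vel[[key]])) gr[[nm]] * 0 else vel[[key]]
      v <- momentum * v - lr * gr[[nm]]
      vel[[key]] <- v
      layers[[i]][[nm]] <- ly[[nm]] + v
    }
  }
  list(layers = layers, vel = vel)
}

## ---- similarity head ----

#' Normalized cosine similarity
#'
#' `sim(u, v) = (1 + cos(u, v)) / 2` with
#' `cos = u.v / (|u||v| + 1e-8)`, mapping the cosine into \[0, 1\] so it can
#' serve directly as the model's pair score under binary cross-entropy.
#' Symmetric in its arguments (bit-exactly). A zero-norm input yields cosine
#' 0, hence similarity 0.5.
#'
#' @param u,v numeric vectors of equal length.
#' @return Similarity in \[0, 1\].
#' @export
normalizedCosine <- function(u, v) {
  stopifnot(length(u) == length(v))
  (1 + sum(u * v) / (sqrt(sum(u * u)) * sqrt(sum(v * v)) + 1e-8)) / 2
}

# Vectorized pair head on embedding rows. Returns similarity, loss, and the
# gradients of the mean BCE loss w.r.t. U and V.
pairHead <- function(U, V, y, grad = TRUE) {
  eps <- 1e-8
  dot <- rowSums(U * V)
  nu <- sqrt(rowSums(U * U))
  nv <- sqrt(rowSums(V * V))
  denom <- nu * nv + eps
  cosv <- dot / denom
  sim <- (1 + cosv) / 2
  s <- pmin(pmax(sim, 1e-7), 1 - 1e-7)
  loss <- mean(-(y * log(s) + (1 - y) * log(1 - s)))
  if (!grad) return(list(sim = sim, loss = loss))
  n <- length(y)
  dsim <- (s - y) / (s * (1 - s)) / n     # d(mean BCE)/d sim
  dcos <- dsim / 2
  safe_u <- pmax(nu, 1e-12)
  safe_v <- pmax(nv, 1e-12)
  dU <- V * (dcos / denom) - U * (dcos * dot * nv / (safe_u * denom^2))
  dV <- U * (dcos / denom) - V * (dcos * dot * nu / (safe_v * denom^2))
  dU[nu == 0, ] <- 0
  dV[nv == 0, ] <- 0
  list(sim = sim, loss = loss, dU = dU, dV = dV)
}

## ---- sample stacking and embedding ----

# samples -> per-modality arrays (H, W, 3, N), in canonical modality order
stackSlabs <- function(samples) {
  mods <- pmfesnModalities()
  d <- dim(slabs(samples[[1L]])[[1L]])
  for (s in samples)
    if (!identical(dim(slabs(s)[[1L]]), d))
      stop("slab shape differs across samples: ",
           paste(d, collapse = "x"), " vs ",
           paste(dim(slabs(s)[[1L]]), collapse = "x"))
  out <- lapply(mods, function(m) {
    x <- array(0, dim = c(d, length(samples)))
    for (i in seq_along(samples)) x[, , , i] <- slabs(samples[[i]])[[m]]
    x
  })
  names(out) <- mods
  out
}

#' Embed prepared samples into the 60-d space
#'
#' Runs each sample's six modality slabs through the corresponding branches
#' (inference mode) and concatenates the six 10-d outputs in canonical
#' modality order.
#'
#' @param model a [SiameseModel-class].
#' @param samples list of [PreparedSample-class] whose slab shape matches the
#'   model input.
#' @return Numeric matrix, one row per sample, 60 columns.
#' @export
embedSamples <- function(model, samples) {
  stacks <- stackSlabs(samples)
  checkInputShape(model, dim(stacks[[1L]])[1:3])
  E <- matrix(0, length(samples), 0L)
  for (m in pmfesnModalities()) {
    fw <- branchForward(model@branches[[m]], stacks[[m]], train = FALSE,
                        keep_cache = FALSE)
    E <- cbind(E, fw$out)
  }
  E
}

checkInputShape <- function(model, shape) {
  want <- model@spec$branch$input_shape
  if (!identical(as.integer(shape), as.integer(want)))
    stop("slab shape ", paste(shape, collapse = "x"),
         " does not match model input ", paste(want, collapse = "x"))
}

#' Similarity of one sample pair under the model
#'
#' Embeds both samples through the shared branch weights and returns the
#' normalized cosine similarity. Twin weight sharing makes the score exactly
#' symmetric in the order of the two samples.
#'
#' @param model a [SiameseModel-class].
#' @param a,b [PreparedSample-class] objects.
#' @return Similarity in \[0, 1\].
#' @export
forwardPair <- function(model, a, b) {
  E <- embedSamples(model, list(a, b))
  normalizedCosine(E[1L, ], E[2L, ])
}

## ---- training ----

#' Training configuration
#'
#' Defaults are the method's stated hyperparameters: SGD with learning rate
#' 1e-4 and momentum 0.9, batch size 32 pairs, at most 20 epochs with an
#' early stop once the decrease in training loss is <= 1e-4 (patience 1),
#' non-convolutional weights initialized N(0, 0.01).
#'
#' @param lr,momentum,batch_size,max_epochs,early_stop_min_delta,patience,init_sd
#'   see above.
#' @param conv_sd s.d. of random convolutional initialization.
#' @param seed integer or `NULL` (use current RNG state).
#' @return A classed list ("TrainConfig").
#' @export
trainConfig <- function(lr = 1e-4, momentum = 0.9, batch_size = 32L,
                        max_epochs = 20L, early_stop_min_delta = 1e-4,
                        patience = 1L, init_sd = 0.01, conv_sd = 0.05,
                        seed = NULL) {
  stopifnot(lr >= 0, momentum >= 0, batch_size >= 1, max_epochs >= 1,
            early_stop_min_delta >= 0, patience >= 0)
  structure(list(lr = lr, momentum = momentum,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stop_min_delta = early_stop_min_delta,
                 patience = as.integer(patience), init_sd = init_sd,
                 conv_sd = conv_sd, seed = seed),
            class = c("TrainConfig", "list"))
}

#' Epoch at which training halts under the early-stopping rule
#'
#' Training runs for at most `max_epochs`; the first epoch whose improvement
#' over the previous epoch's training loss is `<= min_delta` arms the stop,
#' and training halts after `patience` further epochs. (An improvement of
#' 5e-5 at epoch 3 with patience 1 therefore halts training at epoch 4.)
#'
#' @param losses numeric vector of per-epoch training losses.
#' @param min_delta,patience early-stopping parameters.
#' @return The index of the last epoch trained.
#' @export
earlyStopEpoch <- function(losses, min_delta = 1e-4, patience = 1L) {
  n <- length(losses)
  if (n < 2L) return(n)
  for (e in 2:n) {
    if (losses[e - 1L] - losses[e] <= min_delta)
      return(min(e + patience, n))
  }
  n
}

#' Train the siamese network on a pair set
#'
#' Minimizes binary cross-entropy between pair labels and normalized cosine
#' similarities by SGD with momentum. Pairs are reshuffled before every
#' epoch; within each mini-batch the unique samples are embedded once per
#' modality and the loss gradient is accumulated back through the shared
#' branch weights (twin sharing). Frozen convolution blocks are never
#' updated. Validation loss is monitored (inference mode) but does not drive
#' the early stop, which watches the training loss.
#'
#' @param model an untrained [SiameseModel-class] (see [buildSiamese()]).
#' @param samples list of [PreparedSample-class] referenced by the pair
#'   tables.
#' @param train_pairs,val_pairs data.frames with columns a, b, label (from
#'   [splitTrainVal()]); `val_pairs` may have zero rows.
#' @param config a [trainConfig()].
#' @return The trained model with `@history` filled in.
#' @export
trainSiamese <- function(model, samples, train_pairs, val_pairs = NULL,
                         config = trainConfig()) {
  if (!nrow(train_pairs)) stop("no training pairs")
  if (length(unique(train_pairs$label)) < 2L)
    stop("training pairs must contain both labels (same and dissimilar)")
  if (!is.null(config$seed)) set.seed(config$seed)
  mods <- pmfesnModalities()
  stacks <- stackSlabs(samples)
  checkInputShape(model, dim(stacks[[1L]])[1:3])
  branches <- model@branches
  vels <- lapply(mods, function(m) list())
  names(vels) <- mods
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  stop_at <- Inf
  bn_momentum <- 0.9
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(nrow(train_pairs))
    ep_loss <- 0; ep_n <- 0L
    for (start in seq(1L, nrow(train_pairs), by = config$batch_size)) {
      bidx <- ord[start:min(start + config$batch_size - 1L, nrow(train_pairs))]
      bp <- train_pairs[bidx, , drop = FALSE]
      uidx <- sort(unique(c(bp$a, bp$b)))
      ia <- match(bp$a, uidx)
      ib <- match(bp$b, uidx)
      # forward all unique samples through each branch (training mode)
      fws <- vector("list", length(mods)); names(fws) <- mods
      E <- matrix(0, length(uidx), 0L)
      for (m in mods) {
        fw <- branchForward(branches[[m]], stacks[[m]][, , , uidx, drop = FALSE],
                            train = TRUE)
        fws[[m]] <- fw
        E <- cbind(E, fw$out)
      }
      head <- pairHead(E[ia, , drop = FALSE], E[ib, , drop = FALSE],
                       bp$label)
      # accumulate embedding gradient per unique sample
      dE <- matrix(0, length(uidx), ncol(E))
      for (k in seq_along(ia)) {
        dE[ia[k], ] <- dE[ia[k], ] + head$dU[k, ]
        dE[ib[k], ] <- dE[ib[k], ] + head$dV[k, ]
      }
      for (mi in seq_along(mods)) {
        m <- mods[mi]
        cols <- (mi - 1L) * 10L + 1:10
        grads <- branchBackward(branches[[m]], fws[[m]]$cache,
                                dE[, cols, drop = FALSE])
        upd <- sgdStep(branches[[m]], grads, vels[[m]],
                       config$lr, config$momentum)
        branches[[m]] <- upd$layers
        vels[[m]] <- upd$vel
        # batch-norm moving statistics (non-trainable bookkeeping)
        for (u in fws[[m]]$bn_updates) {
          ly <- branches[[m]][[u$i]]
          ly$mmean <- bn_momentum * ly$mmean + (1 - bn_momentum) * u$mu
          ly$mvar <- bn_momentum * ly$mvar + (1 - bn_momentum) * u$v
          branches[[m]][[u$i]] <- ly
        }
      }
      ep_loss <- ep_loss + head$loss * length(bidx)
      ep_n <- ep_n + length(bidx)
    }
    train_loss <- ep_loss / ep_n
    val_loss <- NA_real_
    if (!is.null(val_pairs) && nrow(val_pairs)) {
      vu <- sort(unique(c(val_pairs$a, val_pairs$b)))
      vE <- matrix(0, length(vu), 0L)
      for (m in mods) {
        fw <- branchForward(branches[[m]],
                            stacks[[m]][, , , vu, drop = FALSE],
                            train = FALSE, keep_cache = FALSE)
        vE <- cbind(vE, fw$out)
      }
      hv <- pairHead(vE[match(val_pairs$a, vu), , drop = FALSE],
                     vE[match(val_pairs$b, vu), , drop = FALSE],
                     val_pairs$label, grad = FALSE)
      val_loss <- hv$loss
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss))
    if (epoch >= stop_at) break
    if (is.finite(stop_at) == FALSE && epoch >= 2L) {
      improvement <- history$train_loss[epoch - 1L] - train_loss
      if (improvement <= config$early_stop_min_delta)
        stop_at <- epoch + config$patience
      if (epoch >= stop_at) break
    }
  }
  model@branches <- branches
  model@config <- unclass(config)
  model@history <- history
  model
}

#' Save / load a trained model
#'
#' Serialized with R's native RDS format; reloading reproduces predictions
#' bit-identically.
#'
#' @param model a [SiameseModel-class].
#' @param path file path.
#' @return `loadModel` returns the model; `saveModel` its path, invisibly.
#' @export
saveModel <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) readRDS(path)
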