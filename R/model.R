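#' Construct a ModelConfig
#'
#' @param nInputChannels input channels (2 + number of organ channels).
#' @param nClasses number of output classes; must be 4.
#' @param encoderDepth number of 2x pooling steps (default 2).
#' @param baseFilters filters at full resolution (default 8).
#' @param dropoutRate rate at the two dropout sites (default 0.25).
#' @param l2Weight L2 regularisation weight on convolution weights
#'   (default 0.001).
#' @return a [ModelConfig-class].
#' @export
ModelConfig <- function(nInputChannels, nClasses = 4, encoderDepth = 2,
                        baseFilters = 8, dropoutRate = 0.25,
                        l2Weight = 0.001) {
  new("ModelConfig", nInputChannels = as.integer(nInputChannels),
      nClasses = as.integer(nClasses), encoderDepth = as.integer(encoderDepth),
      baseFilters = as.integer(baseFilters), dropoutRate = dropoutRate,
      l2Weight = l2Weight)
}

#' Construct a TrainConfig
#'
#' @param fgLossWeight foreground loss weight (default 2.5).
#' @param initialLr initial learning rate (default 0.001).
#' @param lrHalvingPatienceEpochs epochs without validation improvement
#'   before the learning rate is halved (default 5).
#' @param samplesPerEpochTrain,samplesPerEpochVal patches per epoch
#'   (defaults 20000 / 10000).
#' @param epochsPerRound epochs per refresh round (default 10).
#' @param nRounds number of rounds, each followed by a sample-mask refresh
#'   (default 5).
#' @param refreshFraction fraction of training studies refreshed per round
#'   (default 0.5).
#' @param batchSize patches per optimiser step (default 8).
#' @param patchSize integer(3) patch shape (default 64 x 64 x 32).
#' @param seed integer master seed for the whole training run.
#' @return a [TrainConfig-class].
#' @export
TrainConfig <- function(fgLossWeight = 2.5, initialLr = 0.001,
                        lrHalvingPatienceEpochs = 5,
                        samplesPerEpochTrain = 20000,
                        samplesPerEpochVal = 10000, epochsPerRound = 10,
                        nRounds = 5, refreshFraction = 0.5, batchSize = 8,
                        patchSize = c(64, 64, 32), seed = 1) {
  new("TrainConfig", fgLossWeight = fgLossWeight, initialLr = initialLr,
      lrHalvingPatienceEpochs = as.integer(lrHalvingPatienceEpochs),
      samplesPerEpochTrain = as.integer(samplesPerEpochTrain),
      samplesPerEpochVal = as.integer(samplesPerEpochVal),
      epochsPerRound = as.integer(epochsPerRound),
      nRounds = as.integer(nRounds), refreshFraction = refreshFraction,
      batchSize = as.integer(batchSize), patchSize = as.integer(patchSize),
      seed = as.integer(seed))
}

#' Construct an AugmentationSpec
#'
#' @param scaleRange fractional scaling interval (default ±10%).
#' @param rotationRangeRad in-plane rotation interval (default ±0.15 rad).
#' @param petShiftSuv PET intensity shift interval in SUV (default ±0.5).
#' @param ctShiftHu CT intensity shift interval in HU (default ±100).
#' @return an [AugmentationSpec-class].
#' @export
AugmentationSpec <- function(scaleRange = c(-0.1, 0.1),
                             rotationRangeRad = c(-0.15, 0.15),
                             petShiftSuv = c(-0.5, 0.5),
                             ctShiftHu = c(-100, 100)) {
  new("AugmentationSpec", scaleRange = as.numeric(scaleRange),
      rotationRangeRad = as.numeric(rotationRangeRad),
      petShiftSuv = as.numeric(petShiftSuv), ctShiftHu = as.numeric(ctShiftHu))
}

# filters per encoder level and bottleneck
levelFilters <- function(cfg) cfg@baseFilters * 2L^(seq_len(cfg@encoderDepth) - 1L)

#' Build a voxel-wise 3D classifier
#'
#' A compact 3D U-Net: `encoderDepth` encoder levels of 3x3x3 convolution +
#' ReLU + 2x2x2 max pooling, a bottleneck convolution, nearest-neighbour
#' upsampling with skip concatenation and 3x3x3 decoder convolutions, and a
#' final 1x1x1 convolution with softmax over the 4 classes. The two dropout
#' sites sit at the deepest encoder/decoder junctions (after the bottleneck
#' and after the deepest decoder convolution). Weight initialisation is He
#' normal and deterministic given `seed`.
#'
#' @param cfg a [ModelConfig-class].
#' @param seed integer initialisation seed.
#' @return a [VoxelClassifier-class].
#' @export
buildModel <- function(cfg, seed = 1) {
  validObject(cfg)
  withSeed(seed, {
    params <- list()
    he <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)),
                                     nin, nout)
    filters <- levelFilters(cfg)
    cin <- cfg@nInputChannels
    for (l in seq_len(cfg@encoderDepth)) {
      params[[paste0("Wenc", l)]] <- he(27L * cin, filters[l])
      params[[paste0("benc", l)]] <- numeric(filters[l])
      cin <- filters[l]
    }
    cb <- cfg@baseFilters * 2L^cfg@encoderDepth
    params$Wbott <- he(27L * cin, cb)
    params$bbott <- numeric(cb)
    up <- cb
    for (l in rev(seq_len(cfg@encoderDepth))) {
      params[[paste0("Wdec", l)]] <- he(27L * (up + filters[l]), filters[l])
      params[[paste0("bdec", l)]] <- numeric(filters[l])
      up <- filters[l]
    }
    params$Wout <- he(cfg@baseFilters, cfg@nClasses)
    params$bout <- numeric(cfg@nClasses)
    new("VoxelClassifier", config = cfg, params = params,
        seed = as.integer(seed))
  })
}

upsample2 <- function(a) {
  d <- dim(a)
  a[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2),
    rep(seq_len(d[3]), each = 2), , drop = FALSE]
}

downsampleSum <- function(g) {
  d <- dim(g)
  o <- array(0, c(d[1:3] %/% 2L, d[4]))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1)
    o <- o + g[seq(1L + dx, d[1], 2L), seq(1L + dy, d[2], 2L),
               seq(1L + dz, d[3], 2L), , drop = FALSE]
  o
}

concat4 <- function(a, b) {
  d <- dim(a)
  out <- array(0, c(d[1:3], d[4] + dim(b)[4]))
  out[, , , seq_len(d[4])] <- a
  out[, , , d[4] + seq_len(dim(b)[4])] <- b
  out
}

# forward pass; training=TRUE activates dropout (draws from the ambient RNG)
forwardPass <- function(model, x, training = FALSE, keepCache = FALSE) {
  cfg <- model@config
  p <- model@params
  d <- dim(x)[1:3]
  if (any(d %% 2L^cfg@encoderDepth != 0L))
    stop(sprintf(
      "configuration error: patch size %s not divisible by 2^%d",
      paste(d, collapse = "x"), cfg@encoderDepth))
  D <- cfg@encoderDepth
  cache <- list(x = x, enc = vector("list", D), pool = vector("list", D))
  h <- x
  for (l in seq_len(D)) {
    z <- .conv3d_fw(h, p[[paste0("Wenc", l)]], p[[paste0("benc", l)]])
    a <- z * (z > 0)
    pl <- .maxpool3d_fw(a)
    if (keepCache) cache$enc[[l]] <- list(input = h, act = a, idx = pl$idx)
    else cache$enc[[l]] <- list(act = a)
    h <- pl$y
    cache$pool[[l]] <- dim(a)
  }
  zb <- .conv3d_fw(h, p$Wbott, p$bbott)
  ab <- zb * (zb > 0)
  if (training && cfg@dropoutRate > 0) {
    m1 <- array((runif(length(ab)) >= cfg@dropoutRate) /
                  (1 - cfg@dropoutRate), dim(ab))
    ab <- ab * m1
  } else m1 <- NULL
  if (keepCache) cache$bott <- list(input = h, act = ab, mask = m1)
  u <- ab
  cache$dec <- vector("list", D)
  for (l in rev(seq_len(D))) {
    up <- upsample2(u)
    cc <- concat4(up, cache$enc[[l]]$act)
    z <- .conv3d_fw(cc, p[[paste0("Wdec", l)]], p[[paste0("bdec", l)]])
    dl <- z * (z > 0)
    m2 <- NULL
    if (l == D && training && cfg@dropoutRate > 0) {
      m2 <- array((runif(length(dl)) >= cfg@dropoutRate) /
                    (1 - cfg@dropoutRate), dim(dl))
      dl <- dl * m2
    }
    if (keepCache)
      cache$dec[[l]] <- list(input = cc, act = dl, mask = m2,
                             nUp = dim(up)[4])
    u <- dl
  }
  n <- prod(d)
  uMat <- matrix(u, n, dim(u)[4])
  logits <- sweep(uMat %*% p$Wout, 2, p$bout, `+`)
  logits <- logits - apply(logits, 1, max)
  e <- exp(logits)
  probs <- e / rowSums(e)
  if (keepCache) cache$uMat <- uMat
  list(probs = probs, cache = if (keepCache) cache else NULL, dims = d)
}

# backward pass; dLogits is n x nClasses (d loss / d logits)
backwardPass <- function(model, fw, dLogits) {
  cfg <- model@config
  p <- model@params
  cache <- fw$cache
  D <- cfg@encoderDepth
  g <- list()
  g$Wout <- t(cache$uMat) %*% dLogits
  g$bout <- colSums(dLogits)
  du <- dLogits %*% t(p$Wout)
  dU <- array(du, c(fw$dims, ncol(du)))
  dskip <- vector("list", D)
  for (l in seq_len(D)) {
    dc <- cache$dec[[l]]
    dl <- dU
    if (!is.null(dc$mask)) dl <- dl * dc$mask
    dz <- dl * (dc$act != 0)  # relu (and dropout) pass-through mask
    bw <- .conv3d_bw(dc$input, p[[paste0("Wdec", l)]], dz)
    g[[paste0("Wdec", l)]] <- bw$dW
    g[[paste0("bdec", l)]] <- as.numeric(bw$db)
    dcc <- bw$dx
    nUp <- dc$nUp
    dup <- dcc[, , , seq_len(nUp), drop = FALSE]
    dskip[[l]] <- dcc[, , , nUp + seq_len(dim(dcc)[4] - nUp), drop = FALSE]
    dU <- downsampleSum(dup)
  }
  # bottleneck
  db <- dU
  if (!is.null(cache$bott$mask)) db <- db * cache$bott$mask
  dzb <- db * (cache$bott$act != 0)
  bwb <- .conv3d_bw(cache$bott$input, p$Wbott, dzb)
  g$Wbott <- bwb$dW
  g$bbott <- as.numeric(bwb$db)
  dp <- bwb$dx
  for (l in rev(seq_len(D))) {
    da <- dskip[[l]] +
      .maxpool3d_bw(cache$enc[[l]]$idx, dp, as.integer(dim(cache$enc[[l]]$act)))
    dz <- da * (cache$enc[[l]]$act > 0)
    bw <- .conv3d_bw(cache$enc[[l]]$input, p[[paste0("Wenc", l)]], dz)
    g[[paste0("Wenc", l)]] <- bw$dW
    g[[paste0("benc", l)]] <- as.numeric(bw$db)
    dp <- bw$dx
  }
  g
}

#' Per-voxel class probabilities for one patch
#'
#' Dropout is disabled unless `training = TRUE`, so inference is
#' deterministic.
#'
#' @param model a [VoxelClassifier-class].
#' @param channels 4D input array (x, y, z, channel); spatial dims must be
#'   divisible by `2^encoderDepth`.
#' @param training logical; activate dropout.
#' @return 4D array (x, y, z, class) of probabilities summing to 1 per voxel.
#' @export
predictPatch <- function(model, channels, training = FALSE) {
  fw <- forwardPass(model, channels, training = training)
  array(fw$probs, c(fw$dims, model@config@nClasses))
}

#' Weighted categorical cross-entropy
#'
#' Per-voxel loss is `-w_c log p(true class)` with `w_c = fgWeight` for the
#' three foreground classes and 1 for background, favouring sensitivity over
#' precision. The scalar loss is the mean over voxels; the per-voxel map is
#' returned for the adaptive sampler. Probabilities below 1e-7 are clamped
#' before the log.
#'
#' @param probs 4D probability array (x, y, z, 4) (or n x 4 matrix).
#' @param target integer label array with codes 0-3 (matching spatial shape).
#' @param fgWeight weight of foreground classes (default 2.5).
#' @return list with `loss` (scalar mean) and `perVoxel` (array shaped like
#'   `target`).
#' @export
weightedCce <- function(probs, target, fgWeight = 2.5) {
  n <- length(target)
  pm <- if (is.matrix(probs)) probs else matrix(probs, n, 4L)
  tv <- as.integer(target) + 1L
  pTrue <- pm[cbind(seq_len(n), tv)]
  nClamped <- sum(pTrue < 1e-7, na.rm = TRUE)
  if (nClamped > 0) {
    pTrue <- pmax(pTrue, 1e-7)
    message(sprintf("weightedCce: clamped %d zero probabilities", nClamped))
  }
  w <- ifelse(tv > 1L, fgWeight, 1)
  per <- -w * log(pTrue)
  dim(per) <- dim(target)
  list(loss = mean(per), perVoxel = per)
}

# gradient of the mean weighted CCE w.r.t. logits: w * (p - onehot) / n
cceGrad <- function(probs, target, fgWeight) {
  n <- length(target)
  tv <- as.integer(target) + 1L
  w <- ifelse(tv > 1L, fgWeight, 1)
  g <- probs
  g[cbind(seq_len(n), tv)] <- g[cbind(seq_len(n), tv)] - 1
  g * (w / n)
}

#' Randomly augment a training patch
#'
#' One isotropic scaling, one in-plane rotation and per-modality intensity
#' shifts are drawn uniformly from the spec ranges. CT and PET channels are
#' resampled trilinearly, organ channels and the label target by nearest
#' neighbour (no new class codes can appear). Intensity shifts are drawn in
#' raw units (SUV / HU) and applied as the equivalent shift on the
#' normalised channels, then clamped back to \[0, 1\]. With all ranges
#' collapsed to zero the patch is returned unchanged. Deterministic given
#' `seed`.
#'
#' @param p a [Patch-class] with normalised channels (CT, PET, organs...).
#' @param spec an [AugmentationSpec-class].
#' @param seed integer.
#' @param cfg the [PreprocessConfig-class] defining the normalisation
#'   windows (used to convert raw-unit shifts).
#' @return the augmented [Patch-class].
#' @export
augmentPatch <- function(p, spec, seed = 1, cfg = PreprocessConfig()) {
  withSeed(seed, {
    s <- 1 + runif(1, spec@scaleRange[1], spec@scaleRange[2])
    th <- runif(1, spec@rotationRangeRad[1], spec@rotationRangeRad[2])
    petShift <- runif(1, spec@petShiftSuv[1], spec@petShiftSuv[2]) /
      diff(cfg@petClamp)
    ctShift <- runif(1, spec@ctShiftHu[1], spec@ctShiftHu[2]) /
      diff(cfg@ctClamp)
    ch <- p@channels
    tg <- p@target
    if (s != 1 || th != 0) {
      d <- dim(ch)[1:3]
      # output index -> input index: rotate by -th, scale by 1/s, about centre
      R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
                  3, 3, byrow = TRUE) / s
      c0 <- (d - 1) / 2
      A <- cbind(R, c0 - R %*% c0)
      nc <- dim(ch)[4]
      out <- array(0, dim(ch))
      for (k in seq_len(nc)) {
        sub <- array(ch[, , , k], d)
        out[, , , k] <- .resample_affine(sub, A, d, k > 2L)
      }
      ch <- out
      tg <- array(.resample_affine(array(as.double(tg), d), A, d, TRUE), d)
    }
    ch[, , , 1L] <- pmin(pmax(ch[, , , 1L] + ctShift, 0), 1)
    ch[, , , 2L] <- pmin(pmax(ch[, , , 2L] + petShift, 0), 1)
    new("Patch", channels = ch, target = tg, centre = p@centre,
        size = p@size)
  })
}

# Nadam (Nesterov-accelerated Adam) update, applied in place on a parameter
# list; state holds first/second moments and the step counter.
nadamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

nadamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    upd <- lr * (beta1 * mhat + (1 - beta1) * g / bc1) / (sqrt(vhat) + eps)
    params[[nm]] <- params[[nm]] - upd
  }
  list(params = params, state = state)
}

# learning-rate scheduler: halve when the validation loss has not decreased
# for `patience` epochs. Pure so it is unit-testable: feed validation losses
# one at a time.
lrScheduleStep <- function(state, valLoss, patience) {
  if (is.null(state$best) || valLoss < state$best) {
    state$best <- valLoss
    state$stale <- 0L
  } else {
    state$stale <- state$stale + 1L
    if (state$stale >= patience) {
      state$lr <- state$lr / 2
      state$stale <- 0L
    }
  }
  state
}
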