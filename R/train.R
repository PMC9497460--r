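# internal: patch extraction from a pre-stacked channel array (avoids
# re-stacking the study for every patch)
extractFromStacked <- function(x, labels, centre, size) {
  d <- dim(x)[1:3]
  idx <- lapply(1:3, function(a) {
    start <- centre[a] - as.integer(ceiling(size[a] / 2)) + 1L
    reflectIndex(start:(start + size[a] - 1L), d[a])
  })
  list(channels = x[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE],
       target = array(labels[idx[[1]], idx[[2]], idx[[3]]], size))
}

# whole-volume per-voxel weighted loss of the current model on one study
studyLossMap <- function(model, study, fgWeight, tiling) {
  probs <- predictVolumeProbs(model, study, tiling)
  per <- weightedCce(probs, study@labels@data, fgWeight)$perVoxel
  LossMap(per, study@studyId)
}

#' Train the voxel classifier with loss-adaptive patch sampling
#'
#' Runs `nRounds` rounds of `epochsPerRound` epochs. Each epoch draws
#' `samplesPerEpochTrain` augmented training patches (study chosen uniformly,
#' centre drawn from that study's sample mask) and `samplesPerEpochVal`
#' validation patches from masks frozen at initialisation, optimising the
#' weighted categorical cross-entropy with Nadam (Nesterov-accelerated
#' Adam). The learning rate is halved when the validation loss has not
#' decreased for `lrHalvingPatienceEpochs` epochs. After each round the
#' sample masks of a random `refreshFraction` of the training studies are
#' updated toward high-loss voxels. The whole run is deterministic given
#' `cfg@seed`. A non-finite loss aborts with a diagnostic error carrying the
#' epoch state.
#'
#' @param studies list of preprocessed, labelled [PetCtStudy-class] objects.
#' @param split named list with integer vectors `train` and `validation`.
#' @param model a [VoxelClassifier-class] (see [buildModel()]).
#' @param cfg a [TrainConfig-class].
#' @param augSpec an [AugmentationSpec-class]; NULL disables augmentation.
#' @param tiling [TilingConfig-class] used for whole-volume loss maps during
#'   mask refresh.
#' @param verbose print one line per epoch.
#' @return list with `model` (trained), `history` (data.frame: round, epoch,
#'   train_loss, val_loss, lr) and `masks` (final training sample masks).
#' @export
trainModel <- function(studies, split, model, cfg,
                       augSpec = AugmentationSpec(),
                       tiling = TilingConfig(), verbose = FALSE) {
  validObject(cfg)
  trIdx <- split$train
  vaIdx <- split$validation
  if (length(trIdx) < 1L || length(vaIdx) < 1L)
    stop("need at least one training and one validation study")
  size <- cfg@patchSize
  stacked <- lapply(studies, stackInputChannels)
  labs <- lapply(studies, function(s) s@labels@data)
  trMasks <- lapply(trIdx, function(i)
    initSampleMask(studies[[i]]@labels, studies[[i]]@studyId))
  vaMasks <- lapply(vaIdx, function(i)
    initSampleMask(studies[[i]]@labels, studies[[i]]@studyId))
  params <- model@params
  opt <- nadamInit(params)
  lrState <- list(lr = cfg@initialLr, best = NULL, stale = 0L)
  history <- list()

  epochPatches <- function(idxSet, masks, n, augment) {
    pick <- sample.int(length(idxSet), n, replace = TRUE)
    centres <- vector("list", length(idxSet))
    for (j in unique(pick)) {
      k <- sum(pick == j)
      centres[[j]] <- drawPatchCentres(masks[[j]], k,
                                       seed = sample.int(2147483646L, 1L))
    }
    used <- integer(length(idxSet))
    lapply(seq_len(n), function(s) {
      j <- pick[s]
      used[j] <<- used[j] + 1L
      ct <- centres[[j]][used[j], ]
      gi <- idxSet[j]
      p <- extractFromStacked(stacked[[gi]], labs[[gi]], ct, size)
      if (augment && !is.null(augSpec)) {
        pp <- new("Patch", channels = p$channels, target = p$target,
                  centre = as.integer(ct), size = size)
        pp <- augmentPatch(pp, augSpec, seed = sample.int(2147483646L, 1L))
        p <- list(channels = pp@channels, target = pp@target)
      }
      p
    })
  }

  runEpoch <- function(patches, train) {
    tot <- 0
    nb <- 0L
    i <- 1L
    while (i <= length(patches)) {
      batch <- patches[seq.int(i, min(i + cfg@batchSize - 1L,
                                      length(patches)))]
      i <- i + length(batch)
      if (train) {
        gAcc <- NULL
        for (p in batch) {
          mdl <- model; mdl@params <- params
          fw <- forwardPass(mdl, p$channels, training = TRUE,
                            keepCache = TRUE)
          l <- weightedCce(fw$probs, p$target, cfg@fgLossWeight)$loss
          tot <- tot + l
          dL <- cceGrad(fw$probs, p$target, cfg@fgLossWeight)
          g <- backwardPass(mdl, fw, dL)
          gAcc <- if (is.null(gAcc)) g else
            Map(`+`, gAcc, g)
        }
        gAcc <- lapply(gAcc, function(x) x / length(batch))
        l2 <- model@config@l2Weight
        if (l2 > 0)
          for (nm in grep("^W", names(gAcc), value = TRUE))
            gAcc[[nm]] <- gAcc[[nm]] + 2 * l2 * params[[nm]]
        st <- nadamStep(params, gAcc, opt, lrState$lr)
        params <<- st$params
        opt <<- st$state
      } else {
        for (p in batch) {
          mdl <- model; mdl@params <- params
          fw <- forwardPass(mdl, p$channels, training = FALSE)
          tot <- tot + weightedCce(fw$probs, p$target, cfg@fgLossWeight)$loss
        }
      }
      nb <- nb + length(batch)
    }
    tot / nb
  }

  withSeed(cfg@seed, {
    epoch <- 0L
    for (round in seq_len(cfg@nRounds)) {
      for (e in seq_len(cfg@epochsPerRound)) {
        epoch <- epoch + 1L
        trainLoss <- runEpoch(
          epochPatches(trIdx, trMasks, cfg@samplesPerEpochTrain, TRUE), TRUE)
        valLoss <- runEpoch(
          epochPatches(vaIdx, vaMasks, cfg@samplesPerEpochVal, FALSE), FALSE)
        if (!is.finite(trainLoss) || !is.finite(valLoss)) {
          diag <- list(round = round, epoch = epoch, trainLoss = trainLoss,
                       valLoss = valLoss, lr = lrState$lr)
          stop(structure(class = c("petsegDivergence", "error", "condition"),
                         list(message = sprintf(
                           "training diverged at round %d epoch %d (loss %g)",
                           round, epoch, trainLoss),
                           call = sys.call(-1), state = diag)))
        }
        lrBefore <- lrState$lr
        lrState <- lrScheduleStep(lrState, valLoss,
                                  cfg@lrHalvingPatienceEpochs)
        history[[epoch]] <- data.frame(round = round, epoch = epoch,
                                       train_loss = trainLoss,
                                       val_loss = valLoss, lr = lrBefore)
        if (verbose)
          message(sprintf(
            "round %d epoch %d: train %.4f val %.4f lr %.2g", round, epoch,
            trainLoss, valLoss, lrBefore))
      }
      if (cfg@refreshFraction > 0) {
        mdl <- model; mdl@params <- params
        rf <- refreshMasks(trMasks, function(j)
          studyLossMap(mdl, studies[[trIdx[j]]], cfg@fgLossWeight, tiling),
          fraction = cfg@refreshFraction,
          seed = sample.int(2147483646L, 1L))
        trMasks <- rf$masks
      }
    }
  })
  model@params <- params
  list(model = model, history = do.call(rbind, history), masks = trMasks)
}
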