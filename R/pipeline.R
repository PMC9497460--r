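# stable hash of an R object (for config fingerprints in manifests)
configHash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Default run configuration
#'
#' A complete nested configuration for [runPipeline()], at a small smoke
#' scale (override any entry via YAML). Sections: `n_studies`, `phantom`,
#' `preprocess`, `train`, `tiling`, `reader` (simulated second reading).
#'
#' @return a named list.
#' @export
defaultRunConfig <- function() {
  list(
    n_studies = 8,
    phantom = list(grid_shape = c(32, 32, 32),
                   voxel_spacing_mm = c(1.37, 1.37, 2.79),
                   background_suv_mean = 1.0, background_suv_sd = 0.15,
                   lesions_per_class = c(1, 1, 1),
                   lesion_radius_range_mm = c(4, 7),
                   lesion_suv_range = c(4, 10),
                   n_unspecific_bone_foci = 1),
    preprocess = list(ct_clamp = c(-800, 800), pet_clamp = c(0, 25),
                      target_spacing_mm = c(1.37, 1.37, 2.79)),
    model = list(encoder_depth = 2, base_filters = 4, dropout_rate = 0.25,
                 l2_weight = 0.001),
    train = list(fg_loss_weight = 2.5, initial_lr = 0.001,
                 lr_halving_patience_epochs = 5,
                 samples_per_epoch_train = 40, samples_per_epoch_val = 20,
                 epochs_per_round = 2, n_rounds = 1, refresh_fraction = 0.5,
                 batch_size = 4, patch_size = c(16, 16, 8)),
    tiling = list(tile_size = c(32, 32, 16), overlap_voxels = c(8, 8, 4)),
    reader = list(p_drop_lesion = 0.2, p_add_spurious = 0.3,
                  boundary_jitter_voxels = 1))
}

#' Read a run configuration from YAML
#'
#' Unknown keys raise an error naming the offending key; missing keys fall
#' back to [defaultRunConfig()].
#'
#' @param path YAML file.
#' @return a named list.
#' @export
readRunConfig <- function(path) {
  usr <- yaml::read_yaml(path)
  def <- defaultRunConfig()
  merge <- function(d, u, prefix = "") {
    for (k in names(u)) {
      if (!k %in% names(d))
        stop(sprintf("unknown config key '%s%s'", prefix, k))
      d[[k]] <- if (is.list(d[[k]]) && is.list(u[[k]]))
        merge(d[[k]], u[[k]], paste0(prefix, k, ".")) else u[[k]]
    }
    d
  }
  merge(def, usr)
}

phantomSpecFromConfig <- function(cf, seed) {
  PhantomSpec(gridShape = unlist(cf$grid_shape),
              voxelSpacingMm = unlist(cf$voxel_spacing_mm),
              backgroundSuvMean = cf$background_suv_mean,
              backgroundSuvSd = cf$background_suv_sd,
              lesionsPerClass = unlist(cf$lesions_per_class),
              lesionRadiusRangeMm = unlist(cf$lesion_radius_range_mm),
              lesionSuvRange = unlist(cf$lesion_suv_range),
              nUnspecificBoneFoci = cf$n_unspecific_bone_foci,
              seed = seed)
}

#' Run the whole pipeline end to end
#'
#' Generates a phantom cohort, preprocesses it, trains the classifier with
#' adaptive sampling, predicts the test studies, evaluates the model and a
#' simulated second reading lesion-wise against the phantom truth, and
#' quantifies tumour burden. All stage seeds derive from `seed`. Writes
#' `history.csv`, `report_class<k>.csv`, `burden.csv` and `manifest.json`
#' into `outDir`.
#'
#' @param config nested configuration list (see [defaultRunConfig()]) or a
#'   YAML path.
#' @param outDir output directory.
#' @param seed global seed.
#' @param verbose print progress.
#' @return invisibly, a list with the trained model, history, reports and
#'   burden table.
#' @export
runPipeline <- function(config = defaultRunConfig(), outDir = tempfile(),
                        seed = 1, verbose = FALSE) {
  if (is.character(config)) config <- readRunConfig(config)
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  spec <- phantomSpecFromConfig(config$phantom, deriveSeed(seed, "phantom"))
  cohort <- generateCohort(config$n_studies, spec)
  pcfg <- PreprocessConfig(unlist(config$preprocess$ct_clamp),
                           unlist(config$preprocess$pet_clamp),
                           unlist(config$preprocess$target_spacing_mm))
  studies <- lapply(cohort$studies, preprocessStudy, cfg = pcfg)
  mcfg <- ModelConfig(nInputChannels = 2L + dim(studies[[1]]@organs)[4],
                      encoderDepth = config$model$encoder_depth,
                      baseFilters = config$model$base_filters,
                      dropoutRate = config$model$dropout_rate,
                      l2Weight = config$model$l2_weight)
  model <- buildModel(mcfg, seed = deriveSeed(seed, "init"))
  tr <- config$train
  tcfg <- TrainConfig(fgLossWeight = tr$fg_loss_weight,
                      initialLr = tr$initial_lr,
                      lrHalvingPatienceEpochs = tr$lr_halving_patience_epochs,
                      samplesPerEpochTrain = tr$samples_per_epoch_train,
                      samplesPerEpochVal = tr$samples_per_epoch_val,
                      epochsPerRound = tr$epochs_per_round,
                      nRounds = tr$n_rounds,
                      refreshFraction = tr$refresh_fraction,
                      batchSize = tr$batch_size,
                      patchSize = unlist(tr$patch_size),
                      seed = deriveSeed(seed, "train"))
  tiling <- TilingConfig(unlist(config$tiling$tile_size),
                         unlist(config$tiling$overlap_voxels))
  fit <- trainModel(studies, cohort$split, model, tcfg, tiling = tiling,
                    verbose = verbose)
  testIdx <- cohort$split$test
  preds <- predictCohort(fit$model, studies[testIdx], tiling)
  sets <- list(truth = list(), AI = list(), readingB = list())
  burdens <- list()
  for (j in seq_along(testIdx)) {
    s <- studies[[testIdx[j]]]
    pert <- ReaderPerturbation(config$reader$p_drop_lesion,
                               config$reader$p_add_spurious,
                               config$reader$boundary_jitter_voxels,
                               seed = deriveSeed(seed, paste0("reader", j)))
    sets$truth[[j]] <- extractLesions(s@labels, s@pet, "truth", s@studyId)
    sets$AI[[j]] <- extractLesions(preds[[j]], s@pet, "AI", s@studyId)
    sets$readingB[[j]] <- extractLesions(perturbReading(s@labels, pert),
                                         s@pet, "readingB", s@studyId)
    burdens <- c(burdens, lapply(sets, function(x) studyBurden(x[[j]])))
  }
  reports <- lapply(FOREGROUND_CODES, function(k)
    pairwiseReport(sets, k))
  history <- fit$history
  utils::write.csv(history, file.path(outDir, "history.csv"),
                   row.names = FALSE)
  for (k in FOREGROUND_CODES)
    utils::write.csv(reports[[k]],
                     file.path(outDir, sprintf("report_class%d.csv", k)),
                     row.names = FALSE)
  burdenTab <- cohortBurdenTable(burdens)
  utils::write.csv(burdenTab, file.path(outDir, "burden.csv"),
                   row.names = FALSE)
  manifest <- list(seed = seed, config_hash = configHash(config),
                   config = config,
                   package_version = as.character(utils::packageVersion("petseg")),
                   r_version = R.version.string,
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(model = fit$model, history = history, reports = reports,
                 burden = burdenTab, outDir = outDir))
}

#' Command-line entry point
#'
#' Dispatches the subcommands `phantom`, `preprocess`, `train`, `predict`,
#' `evaluate`, `burden` and `pipeline`; see `inst/cli/petseg` for the
#' executable wrapper. Returns the exit code (0 on success, 2 on usage or
#' configuration errors).
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit code.
#' @export
cliMain <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: petseg <command> [options]",
    "commands:",
    "  phantom    --n N --out DIR [--config FILE] [--seed S]",
    "  preprocess --in DIR --out DIR [--config FILE]",
    "  train      --out DIR [--config FILE] [--seed S]",
    "  predict    --model FILE --in DIR --out FILE [--config FILE]",
    "  evaluate   --pred DIR --ref DIR --out FILE",
    "  burden     --in DIR --out FILE",
    "  pipeline   --out DIR [--config FILE] [--seed S]", sep = "\n")
  opt <- function(flag, default = NULL) {
    i <- which(argv == flag)
    if (length(i) == 1L && i < length(argv)) argv[i + 1L] else default
  }
  if (length(argv) < 1L) { message(usage); return(2L) }
  cmd <- argv[1]
  res <- tryCatch({
    cfg <- if (!is.null(opt("--config"))) readRunConfig(opt("--config"))
           else defaultRunConfig()
    seed <- as.integer(opt("--seed", "1"))
    switch(cmd,
      phantom = {
        n <- as.integer(opt("--n", cfg$n_studies))
        out <- opt("--out"); stopifnot(!is.null(out))
        spec <- phantomSpecFromConfig(cfg$phantom, deriveSeed(seed, "phantom"))
        cohort <- generateCohort(n, spec)
        for (i in seq_len(n))
          writeStudy(cohort$studies[[i]],
                     file.path(out, sprintf("study-%03d", i)))
        jsonlite::write_json(cohort$split, file.path(out, "split.json"),
                             digits = NA)
        0L
      },
      preprocess = {
        src <- opt("--in"); out <- opt("--out")
        stopifnot(!is.null(src), !is.null(out))
        pcfg <- PreprocessConfig(unlist(cfg$preprocess$ct_clamp),
                                 unlist(cfg$preprocess$pet_clamp),
                                 unlist(cfg$preprocess$target_spacing_mm))
        for (d in list.dirs(src, recursive = FALSE))
          writeStudy(preprocessStudy(readStudy(d), pcfg),
                     file.path(out, basename(d)))
        0L
      },
      train = ,
      pipeline = {
        out <- opt("--out"); stopifnot(!is.null(out))
        res <- runPipeline(cfg, out, seed)
        saveRDS(res$model, file.path(out, "model.rds"))
        0L
      },
      predict = {
        model <- readRDS(opt("--model"))
        study <- readStudy(opt("--in"))
        if (!study@preprocessed) study <- preprocessStudy(study)
        tiling <- TilingConfig(unlist(cfg$tiling$tile_size),
                               unlist(cfg$tiling$overlap_voxels))
        writeLabelMap(predictVolume(model, study, tiling), opt("--out"))
        0L
      },
      evaluate = {
        pred <- readStudy(opt("--pred")); ref <- readStudy(opt("--ref"))
        sets <- list(
          AI = list(extractLesions(pred@labels, pred@pet, "AI")),
          reference = list(extractLesions(ref@labels, ref@pet, "reference")))
        rep <- do.call(rbind, lapply(FOREGROUND_CODES, function(k)
          cbind(class_code = k, pairwiseReport(sets, k))))
        utils::write.csv(rep, opt("--out"), row.names = FALSE)
        0L
      },
      burden = {
        s <- readStudy(opt("--in"))
        if (is.null(s@labels)) stop("study has no label map")
        b <- studyBurden(extractLesions(s@labels, s@pet, "labels",
                                        s@studyId))
        utils::write.csv(cbind(study_id = s@studyId, burdenTable(b)),
                         opt("--out"), row.names = FALSE)
        0L
      },
      { message("unknown command '", cmd, "'\n", usage); 2L })
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    2L
  })
  res
}
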