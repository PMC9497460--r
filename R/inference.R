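#' Construct a TilingConfig
#'
#' @param tileSize integer(3) sliding-window tile shape; every axis must be
#'   divisible by `2^encoderDepth` of the model it is used with.
#' @param overlapVoxels integer(3) overlap between neighbouring tiles.
#' @return a [TilingConfig-class].
#' @export
TilingConfig <- function(tileSize = c(32, 32, 16), overlapVoxels = c(8, 8, 4)) {
  new("TilingConfig", tileSize = as.integer(tileSize),
      overlapVoxels = as.integer(overlapVoxels))
}

tileStarts <- function(n, tile, overlap) {
  if (n <= tile) return(1L)
  step <- tile - overlap
  s <- seq.int(1L, n - tile + 1L, by = step)
  if (s[length(s)] != n - tile + 1L) s <- c(s, n - tile + 1L)
  unique(s)
}

#' Whole-volume class probabilities by sliding-window inference
#'
#' The volume is covered with overlapping tiles; per-voxel probabilities of
#' overlapping tiles are averaged. Volumes smaller than the tile are
#' mirror-padded to tile size and cropped back. Dropout is off, so the
#' result is deterministic.
#'
#' @param model a [VoxelClassifier-class].
#' @param study a preprocessed [PetCtStudy-class].
#' @param cfg a [TilingConfig-class].
#' @return a 4D array (x, y, z, class) of averaged probabilities.
#' @export
predictVolumeProbs <- function(model, study, cfg = TilingConfig()) {
  x <- stackInputChannels(study)
  d <- dim(x)[1:3]
  tile <- cfg@tileSize
  if (any(tile %% 2L^model@config@encoderDepth != 0L))
    stop("configuration error: tile size not divisible by 2^encoderDepth")
  if (any(d < tile)) {
    # single padded-tile path: mirror-pad up to tile size, predict, crop
    idx <- lapply(1:3, function(a) reflectIndex(seq_len(max(d[a], tile[a])),
                                                d[a]))
    xp <- x[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
    sp <- study
    sp@pet@data <- array(xp[, , , 2L], dim(xp)[1:3])
    sp@ct@data <- array(xp[, , , 1L], dim(xp)[1:3])
    sp@organs <- xp[, , , -(1:2), drop = FALSE]
    probs <- predictVolumeProbs(model, sp, cfg)
    return(probs[seq_len(d[1]), seq_len(d[2]), seq_len(d[3]), , drop = FALSE])
  }
  nc <- model@config@nClasses
  acc <- array(0, c(d, nc))
  cnt <- array(0, d)
  for (zs in tileStarts(d[3], tile[3], cfg@overlapVoxels[3]))
    for (ys in tileStarts(d[2], tile[2], cfg@overlapVoxels[2]))
      for (xs in tileStarts(d[1], tile[1], cfg@overlapVoxels[1])) {
        xe <- xs + tile[1] - 1L; ye <- ys + tile[2] - 1L
        ze <- zs + tile[3] - 1L
        sub <- x[xs:xe, ys:ye, zs:ze, , drop = FALSE]
        pr <- predictPatch(model, sub)
        acc[xs:xe, ys:ye, zs:ze, ] <- acc[xs:xe, ys:ye, zs:ze, ] + pr
        cnt[xs:xe, ys:ye, zs:ze] <- cnt[xs:xe, ys:ye, zs:ze] + 1
      }
  acc / as.vector(cnt)
}

#' Predict a whole-volume label map
#'
#' Argmax of the averaged sliding-window probabilities; ties are broken
#' toward the lower class code, so repeated calls give identical output.
#'
#' @inheritParams predictVolumeProbs
#' @return a [LabelMap-class] on the study grid.
#' @export
predictVolume <- function(model, study, cfg = TilingConfig()) {
  probs <- predictVolumeProbs(model, study, cfg)
  d <- dim(probs)[1:3]
  lab <- argmaxRows(matrix(probs, prod(d), dim(probs)[4])) - 1L
  LabelMap(array(as.double(lab), d), study@pet@spacing, study@pet@origin)
}

#' Predict label maps for a collection of studies
#'
#' Maps [predictVolume()] over the studies; per-study wall time and
#' voxel-class counts are collected in the `log` attribute of the result.
#' Studies that fail validation are recorded as NULL, skipped, and reported
#' in a warning at the end.
#'
#' @param model a [VoxelClassifier-class].
#' @param studies list of preprocessed [PetCtStudy-class] objects.
#' @param cfg a [TilingConfig-class].
#' @return a list of [LabelMap-class] (NULL for failed studies), with a
#'   data.frame attribute `log`.
#' @export
predictCohort <- function(model, studies, cfg = TilingConfig()) {
  out <- vector("list", length(studies))
  logRows <- list()
  failed <- character()
  for (i in seq_along(studies)) {
    sid <- studies[[i]]@studyId
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(predictVolume(model, studies[[i]], cfg),
                    error = function(e) e)
    if (inherits(res, "error")) {
      failed <- c(failed, sprintf("%s (%s)", sid, conditionMessage(res)))
      next
    }
    out[[i]] <- res
    counts <- vapply(0:3, function(k) sum(res@data == k), numeric(1))
    logRows[[length(logRows) + 1L]] <- data.frame(
      study_id = sid, seconds = proc.time()[["elapsed"]] - t0,
      background = counts[1], prostate = counts[2], node = counts[3],
      bone = counts[4])
  }
  attr(out, "log") <- if (length(logRows)) do.call(rbind, logRows) else
    data.frame()
  if (length(failed))
    warning("prediction skipped for: ", paste(failed, collapse = "; "))
  out
}
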