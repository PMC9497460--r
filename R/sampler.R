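#' Construct a SampleMask from raw weights
#'
#' Weights are normalised to sum 1 on construction.
#'
#' @param weights 3D non-negative array with at least one positive entry.
#' @param studyId identifier of the study the mask aligns to.
#' @return a [SampleMask-class].
#' @export
SampleMask <- function(weights, studyId = "study") {
  tot <- sum(weights)
  if (!is.finite(tot) || tot <= 0)
    stop("sample mask needs at least one positive weight")
  new("SampleMask", weights = weights / tot, studyId = studyId)
}

#' Construct a LossMap
#'
#' @param values 3D non-negative finite array of per-voxel losses.
#' @param studyId identifier.
#' @return a [LossMap-class].
#' @export
LossMap <- function(values, studyId = "study") {
  new("LossMap", values = values, studyId = studyId)
}

#' Initialise the patch-sampling mask from a label map
#'
#' The initial mask makes 50% of patch centres background and 50%
#' foreground, with each foreground class *present in the map* equally
#' likely and voxels uniform within each class. Maps without any foreground
#' fall back to a uniform mask so every study stays usable.
#'
#' @param labels a [LabelMap-class].
#' @param studyId identifier stored on the mask.
#' @return a [SampleMask-class] (weights sum to 1).
#' @export
initSampleMask <- function(labels, studyId = "study") {
  lab <- labels@data
  if (length(lab) == 0L) stop("empty label grid")
  fgPresent <- FOREGROUND_CODES[vapply(FOREGROUND_CODES,
                                       function(k) any(lab == k), logical(1))]
  w <- array(0, dim(lab))
  if (length(fgPresent) == 0L) {
    w[] <- 1
  } else {
    nBg <- sum(lab == 0)
    if (nBg > 0) w[lab == 0] <- 0.5 / nBg
    shareBg <- if (nBg > 0) 0.5 else 0
    for (k in fgPresent) {
      nK <- sum(lab == k)
      w[lab == k] <- (1 - shareBg) / length(fgPresent) / nK
    }
  }
  SampleMask(w, studyId)
}

#' Draw patch centres from a sample mask
#'
#' `n` independent draws from the categorical distribution over voxels given
#' by the mask weights. Deterministic given `seed`.
#'
#' @param mask a [SampleMask-class].
#' @param n number of centres (>= 1).
#' @param seed integer.
#' @return an n x 3 integer matrix of voxel indices.
#' @export
drawPatchCentres <- function(mask, n, seed = 1) {
  n <- asCount(n, "n")
  if (n < 1L) stop("n must be >= 1")
  w <- mask@weights
  idx <- withSeed(seed,
    sample.int(length(w), n, replace = TRUE, prob = as.vector(w)))
  arrayInd(idx, dim(w))
}

#' Extract a training patch around a centre voxel
#'
#' Regions outside the volume are mirror-padded (reflection without edge
#' repeat), so corner-centred patches stay free of constant-value
#' artefacts. The patch covers indices
#' `centre - ceiling(size/2) + 1 ... centre + floor(size/2)` per axis.
#'
#' @param study a preprocessed [PetCtStudy-class] with labels.
#' @param centre integer(3) voxel index.
#' @param size integer(3) patch size; must not exceed twice the volume
#'   extent (mirror padding is single-reflection).
#' @return a [Patch-class].
#' @export
extractPatch <- function(study, centre, size) {
  size <- as.integer(size)
  d <- dim(study@pet@data)
  if (any(size > 2L * d - 2L) || any(size < 1L))
    stop("patch size must be between 1 and twice the volume extent")
  centre <- as.integer(centre)
  idx <- lapply(1:3, function(a) {
    start <- centre[a] - as.integer(ceiling(size[a] / 2)) + 1L
    reflectIndex(start:(start + size[a] - 1L), d[a])
  })
  x <- stackInputChannels(study)
  channels <- x[idx[[1]], idx[[2]], idx[[3]], , drop = FALSE]
  target <- study@labels@data[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  new("Patch", channels = channels, target = array(target, size),
      centre = centre, size = size)
}

# the adaptive update on raw (unnormalised) weights:
# w' = 0.5 w + 0.5 (max w / max l) l.
# Covariant under uniform rescaling of w, so the sampling distribution is
# unaffected by whether stored weights are normalised.
adaptWeights <- function(w, l) {
  0.5 * w + 0.5 * (max(w) / max(l)) * l
}

#' Adapt a sample mask toward high-loss voxels
#'
#' Applies the hard-example update: the new weight of voxel p is the mean of
#' its old weight and the per-voxel loss rescaled so that the highest-loss
#' voxel receives a contribution equal to the current maximum weight. The
#' result is re-normalised to sum 1. The update is covariant under uniform
#' scaling of the weights, so applying it to the stored normalised weights
#' yields the same sampling distribution as applying it to any raw multiple
#' of them. An all-zero loss map returns the mask unchanged (zero loss means
#' no hard examples).
#'
#' @param mask a [SampleMask-class].
#' @param loss a [LossMap-class] on the same grid.
#' @return the updated, re-normalised [SampleMask-class].
#' @export
updateSampleMask <- function(mask, loss) {
  if (!identical(dim(mask@weights), dim(loss@values)))
    stop("alignment error: mask and loss grids differ")
  if (max(loss@values) == 0) return(mask)
  SampleMask(adaptWeights(mask@weights, loss@values), mask@studyId)
}

#' Refresh the sample masks of a random half of the training studies
#'
#' Selects `round(fraction * n)` studies uniformly at random, computes their
#' per-voxel loss maps with `lossFun` and updates only the selected masks
#' via [updateSampleMask()]. Deterministic given `seed`.
#'
#' @param masks list of [SampleMask-class], one per training study.
#' @param lossFun function(index) returning the [LossMap-class] for training
#'   study `index` (typically whole-volume model loss).
#' @param fraction fraction of studies to refresh (default 0.5).
#' @param seed integer.
#' @return list with `masks` (updated list) and `selected` (indices).
#' @export
refreshMasks <- function(masks, lossFun, fraction = 0.5, seed = 1) {
  n <- length(masks)
  if (n == 0L) stop("empty study list")
  k <- as.integer(roundHalfUp(fraction * n))
  selected <- if (k > 0L) withSeed(seed, sort(sample.int(n, k))) else integer()
  for (i in selected)
    masks[[i]] <- updateSampleMask(masks[[i]], lossFun(i))
  list(masks = masks, selected = selected)
}

#' Persist a sample mask as NIfTI
#'
#' @param mask a [SampleMask-class].
#' @param path output file (.nii/.nii.gz).
#' @param spacingMm voxel spacing recorded in the header.
#' @return `path` invisibly; `readSampleMask` returns the mask.
#' @export
writeSampleMask <- function(mask, path, spacingMm = c(1, 1, 1)) {
  im <- RNifti::asNifti(mask@weights)
  RNifti::pixdim(im) <- spacingMm
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname writeSampleMask
#' @param studyId identifier for the restored mask.
#' @export
readSampleMask <- function(path, studyId = "study") {
  im <- RNifti::readNifti(path)
  SampleMask(array(as.numeric(im), dim = dim(im)), studyId)
}
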