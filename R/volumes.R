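#' Construct a Volume
#'
#' @param data 3D numeric array (x, y, z).
#' @param spacing numeric(3) voxel extent in mm.
#' @param origin numeric(3) world coordinate of the first voxel in mm.
#' @return a [Volume-class] object.
#' @export
Volume <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  new("Volume", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a LabelMap
#'
#' @inheritParams Volume
#' @return a [LabelMap-class] object.
#' @export
LabelMap <- function(data, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  storage.mode(data) <- "double"
  new("LabelMap", data = data, spacing = as.numeric(spacing),
      origin = as.numeric(origin))
}

#' Construct a PetCtStudy
#'
#' @param pet,ct [Volume-class] objects on the same grid.
#' @param organs 4D binary array (x, y, z, organ channel).
#' @param organNames names of the organ channels.
#' @param labels optional [LabelMap-class].
#' @param studyId identifier.
#' @param preprocessed TRUE once the study is clamped/normalised.
#' @return a [PetCtStudy-class] object.
#' @export
PetCtStudy <- function(pet, ct, organs,
                       organNames = paste0("organ", seq_len(dim(organs)[4])),
                       labels = NULL, studyId = "study",
                       preprocessed = FALSE) {
  new("PetCtStudy", pet = pet, ct = ct, organs = organs,
      organNames = organNames, labels = labels, studyId = studyId,
      preprocessed = preprocessed)
}

#' Construct a PreprocessConfig
#'
#' @param ctClamp HU clamp window (default c(-800, 800)).
#' @param petClamp SUV clamp window (default c(0, 25)).
#' @param targetSpacingMm target voxel grid (default c(1.37, 1.37, 2.79) mm).
#' @return a [PreprocessConfig-class] object.
#' @export
PreprocessConfig <- function(ctClamp = c(-800, 800), petClamp = c(0, 25),
                             targetSpacingMm = c(1.37, 1.37, 2.79)) {
  new("PreprocessConfig", ctClamp = as.numeric(ctClamp),
      petClamp = as.numeric(petClamp),
      targetSpacingMm = as.numeric(targetSpacingMm))
}

clampUnit <- function(x, lo, hi) {
  x[is.na(x)] <- lo
  (pmin(pmax(x, lo), hi) - lo) / (hi - lo)
}

#' Clamp and normalise a CT volume
#'
#' HU values are clamped to the configured window (default \[-800, 800\] HU)
#' and mapped affinely to \[0, 1\]. Missing values are treated as air (the
#' lower bound). Idempotent: a volume already in \[0, 1\] with a \[0, 1\]
#' clamp window is unchanged, and re-applying the same config to its own
#' output is a no-op because the output window is inside the clamp window
#' only after rescaling — idempotence here means
#' `clampNormaliseCt(clampNormaliseCt(v, cfg), PreprocessConfig(ctClamp =
#' c(0, 1)))` equals the single application.
#'
#' @param v a [Volume-class] in HU.
#' @param cfg a [PreprocessConfig-class].
#' @return a [Volume-class] with values in \[0, 1\].
#' @export
clampNormaliseCt <- function(v, cfg = PreprocessConfig()) {
  Volume(clampUnit(v@data, cfg@ctClamp[1], cfg@ctClamp[2]), v@spacing,
         v@origin)
}

#' Clamp and normalise a PET volume
#'
#' SUV values are clamped to the configured window (default \[0, 25\]) and
#' divided by the upper bound, so SUV s maps to min(s, 25)/25. Negative
#' values clamp to 0.
#'
#' @inheritParams clampNormaliseCt
#' @param v a [Volume-class] in SUV.
#' @return a [Volume-class] with values in \[0, 1\].
#' @export
clampNormalisePet <- function(v, cfg = PreprocessConfig()) {
  Volume(clampUnit(v@data, cfg@petClamp[1], cfg@petClamp[2]), v@spacing,
         v@origin)
}

# output shape when resampling: physical extent / target spacing, half-up
resampledShape <- function(shape, spacing, target) {
  pmax(1L, as.integer(roundHalfUp(shape * spacing / target)))
}

resampleArray <- function(arr, spacing, target, nearest) {
  d <- dim(arr)[1:3]
  outd <- resampledShape(d, spacing, target)
  if (identical(outd, as.integer(d)) &&
      isTRUE(all.equal(as.numeric(spacing), as.numeric(target))))
    return(arr)
  # map 0-based output index -> 0-based input index through world coordinates
  A <- matrix(0, 3, 4)
  diag(A[, 1:3]) <- target / spacing
  .resample_affine(arr, A, as.integer(outd), nearest)
}

#' Resample a study to the target voxel grid
#'
#' All members are rescaled to the target spacing (default
#' 1.37 x 1.37 x 2.79 mm per voxel). PET and CT are interpolated
#' trilinearly; organ masks and label maps use nearest-neighbour so no new
#' class codes can appear. The output shape per axis is the physical extent
#' divided by the target spacing, rounded half-up.
#'
#' @param s a [PetCtStudy-class].
#' @param cfg a [PreprocessConfig-class].
#' @return a [PetCtStudy-class] on the target grid.
#' @export
resampleStudy <- function(s, cfg = PreprocessConfig()) {
  sp <- s@pet@spacing
  tg <- cfg@targetSpacingMm
  if (any(tg <= 0)) stop("target spacing must be positive")
  pet <- Volume(resampleArray(s@pet@data, sp, tg, FALSE), tg, s@pet@origin)
  ct <- Volume(resampleArray(s@ct@data, sp, tg, FALSE), tg, s@ct@origin)
  organs <- resampleArray(s@organs, sp, tg, TRUE)
  if (length(dim(organs)) == 3L) dim(organs) <- c(dim(organs), 1L)
  labels <- NULL
  if (!is.null(s@labels))
    labels <- LabelMap(resampleArray(s@labels@data, sp, tg, TRUE), tg,
                       s@labels@origin)
  PetCtStudy(pet, ct, organs, s@organNames, labels, s@studyId,
             preprocessed = s@preprocessed)
}

#' Preprocess a study into the network input representation
#'
#' Convenience wrapper: clamp/normalise CT and PET, then resample everything
#' to the target grid and mark the study preprocessed.
#'
#' @inheritParams resampleStudy
#' @return a preprocessed [PetCtStudy-class].
#' @export
preprocessStudy <- function(s, cfg = PreprocessConfig()) {
  s@ct <- clampNormaliseCt(s@ct, cfg)
  s@pet <- clampNormalisePet(s@pet, cfg)
  s@preprocessed <- TRUE
  resampleStudy(s, cfg)
}

#' Stack a preprocessed study into the multi-channel network input
#'
#' Channel order is fixed: channel 1 = CT, channel 2 = PET, then the organ
#' channels in stored order. All values must already be in \[0, 1\].
#'
#' @param s a preprocessed [PetCtStudy-class].
#' @return a 4D array (x, y, z, 2 + n organ channels).
#' @export
stackInputChannels <- function(s) {
  rng <- range(s@ct@data, s@pet@data)
  if (rng[1] < 0 || rng[2] > 1)
    stop("study is not preprocessed: CT/PET values outside [0,1]")
  d <- dim(s@pet@data)
  nOrg <- dim(s@organs)[4]
  out <- array(0, c(d, 2L + nOrg))
  out[, , , 1L] <- s@ct@data
  out[, , , 2L] <- s@pet@data
  out[, , , 2L + seq_len(nOrg)] <- s@organs
  out
}

#' Write a study to NIfTI files
#'
#' Writes pet.nii.gz, ct.nii.gz, organs.nii.gz (4D), labels.nii.gz (when
#' present) and a study.json sidecar with identifiers, spacing and organ
#' channel names into `dir`.
#'
#' @param s a [PetCtStudy-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeStudy <- function(s, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wv <- function(arr, spacing, file) {
    im <- RNifti::asNifti(arr)
    RNifti::pixdim(im) <- if (length(dim(arr)) == 4L) c(spacing, 1) else spacing
    RNifti::writeNifti(im, file.path(dir, file))
  }
  wv(s@pet@data, s@pet@spacing, "pet.nii.gz")
  wv(s@ct@data, s@ct@spacing, "ct.nii.gz")
  wv(s@organs, s@pet@spacing, "organs.nii.gz")
  if (!is.null(s@labels)) wv(s@labels@data, s@labels@spacing, "labels.nii.gz")
  meta <- list(study_id = s@studyId, organ_names = s@organNames,
               spacing_mm = s@pet@spacing, origin_mm = s@pet@origin,
               preprocessed = s@preprocessed)
  jsonlite::write_json(meta, file.path(dir, "study.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a study from NIfTI files
#'
#' Expects the layout written by [writeStudy()]. All grids must agree;
#' mismatched shapes raise an alignment error and label maps are validated
#' against the legal class codes.
#'
#' @param dir directory containing pet.nii.gz, ct.nii.gz, organs.nii.gz and
#'   optionally labels.nii.gz plus study.json.
#' @return a [PetCtStudy-class].
#' @export
readStudy <- function(dir) {
  need <- c("pet.nii.gz", "ct.nii.gz", "organs.nii.gz")
  for (f in need)
    if (!file.exists(file.path(dir, f)))
      stop(sprintf("missing required volume '%s' in %s", f, dir))
  rd <- function(f) {
    im <- RNifti::readNifti(file.path(dir, f))
    list(data = array(as.numeric(im), dim = dim(im)),
         spacing = RNifti::pixdim(im))
  }
  pet <- rd("pet.nii.gz"); ct <- rd("ct.nii.gz"); org <- rd("organs.nii.gz")
  if (!identical(dim(pet$data), dim(ct$data)))
    stop("alignment error: PET and CT grids differ")
  meta <- list(study_id = basename(dir), preprocessed = FALSE)
  mf <- file.path(dir, "study.json")
  if (file.exists(mf)) meta <- utils::modifyList(meta, jsonlite::read_json(mf))
  organs <- org$data
  if (length(dim(organs)) == 3L) dim(organs) <- c(dim(organs), 1L)
  labels <- NULL
  lf <- file.path(dir, "labels.nii.gz")
  if (file.exists(lf)) {
    l <- rd("labels.nii.gz")
    if (!identical(dim(l$data)[1:3], dim(pet$data)))
      stop("alignment error: label grid differs from PET")
    ldat <- round(l$data)
    if (!all(ldat %in% 0:3))
      stop("validation error: unknown label codes ",
           paste(setdiff(unique(c(ldat)), 0:3), collapse = ", "))
    labels <- LabelMap(ldat, pet$spacing[1:3])
  }
  organNames <- if (!is.null(meta$organ_names)) unlist(meta$organ_names)
                else paste0("organ", seq_len(dim(organs)[4]))
  PetCtStudy(Volume(pet$data, pet$spacing[1:3]),
             Volume(ct$data, ct$spacing[1:3]),
             round(organs), organNames, labels,
             studyId = as.character(meta$study_id),
             preprocessed = isTRUE(meta$preprocessed))
}

#' Write / read a label map as NIfTI
#'
#' Round-trips are lossless for the integer class codes.
#'
#' @param l a [LabelMap-class].
#' @param path output file (.nii or .nii.gz).
#' @return `path`, invisibly.
#' @export
writeLabelMap <- function(l, path) {
  im <- RNifti::asNifti(l@data)
  RNifti::pixdim(im) <- l@spacing
  RNifti::writeNifti(im, path)
  invisible(path)
}

#' @rdname writeLabelMap
#' @export
readLabelMap <- function(path) {
  im <- RNifti::readNifti(path)
  dat <- round(array(as.numeric(im), dim = dim(im)))
  if (!all(dat %in% 0:3))
    stop("validation error: unknown label codes in ", path)
  LabelMap(dat, RNifti::pixdim(im)[1:3])
}
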