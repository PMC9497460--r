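#' Total lesion volume of one lesion
#'
#' Voxel count times voxel volume, reported in millilitres.
#'
#' @param lesion a [Lesion-class].
#' @param spacingMm numeric(3) voxel spacing in mm.
#' @return volume in mL.
#' @export
lesionTlv <- function(lesion, spacingMm) {
  if (any(spacingMm <= 0)) stop("spacing must be positive")
  nrow(lesion@voxelIndices) * prod(spacingMm) / 1000
}

#' Total lesion uptake of one lesion
#'
#' TLU = SUVmean x TLV per lesion (the standard total-lesion-uptake
#' construction, analogous to total lesion glycolysis); study-level TLU is
#' the sum of lesion TLUs.
#'
#' @param lesion a [Lesion-class] (with `suvMean` computed over its PET
#'   voxels and `volumeMl` set).
#' @return TLU in SUV·mL.
#' @export
lesionTlu <- function(lesion) {
  lesion@suvMean * lesion@volumeMl
}

#' Per-class tumour burden of one study
#'
#' Sums TLV and TLU per lesion class; classes without lesions report 0.
#'
#' @param lesionSet a [LesionSet-class] covering the whole study.
#' @param spacingMm voxel spacing; defaults to the spacing stored on the
#'   set.
#' @return a [BurdenSummary-class] whose table has one row per class with
#'   columns class_code, class_name, tlv_ml, tlu.
#' @export
studyBurden <- function(lesionSet, spacingMm = lesionSet@spacingMm) {
  tab <- data.frame(class_code = FOREGROUND_CODES,
                    class_name = CLASS_NAMES[FOREGROUND_CODES + 1L],
                    tlv_ml = 0, tlu = 0)
  for (l in lesionSet@lesions) {
    r <- match(l@classCode, tab$class_code)
    tlv <- lesionTlv(l, spacingMm)
    tab$tlv_ml[r] <- tab$tlv_ml[r] + tlv
    tab$tlu[r] <- tab$tlu[r] + l@suvMean * tlv
  }
  new("BurdenSummary", table = tab, studyId = lesionSet@studyId,
      sourceId = lesionSet@sourceId)
}

#' Long-format burden table for a cohort
#'
#' One row per study, source and class with TLV (mL) and TLU (SUV·mL);
#' convenient for CSV export and histogram binning.
#'
#' @param burdens list of [BurdenSummary-class].
#' @return a data.frame (study_id, source, class_code, class_name, tlv_ml,
#'   tlu).
#' @export
cohortBurdenTable <- function(burdens) {
  do.call(rbind, lapply(burdens, function(b) {
    cbind(data.frame(study_id = b@studyId, source = b@sourceId),
          b@table)
  }))
}
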