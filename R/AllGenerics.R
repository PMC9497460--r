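#' @rdname Volume-class
#' @param object,x an object
#' @export
setGeneric("volData", function(x) standardGeneric("volData"))

#' @rdname Volume-class
#' @export
setGeneric("volSpacing", function(x) standardGeneric("volSpacing"))

#' @rdname PetCtStudy-class
#' @export
setGeneric("petVol", function(x) standardGeneric("petVol"))

#' @rdname PetCtStudy-class
#' @export
setGeneric("ctVol", function(x) standardGeneric("ctVol"))

#' @rdname PetCtStudy-class
#' @export
setGeneric("organMask", function(x) standardGeneric("organMask"))

#' @rdname PetCtStudy-class
#' @export
setGeneric("labelMap", function(x) standardGeneric("labelMap"))

#' @rdname PetCtStudy-class
#' @export
setGeneric("studyId", function(x) standardGeneric("studyId"))

#' @rdname SampleMask-class
#' @export
setGeneric("maskWeights", function(x) standardGeneric("maskWeights"))

#' @rdname LesionSet-class
#' @export
setGeneric("lesions", function(x) standardGeneric("lesions"))

#' @rdname MatchResult-class
#' @export
setGeneric("sensitivity", function(x) standardGeneric("sensitivity"))

#' @rdname MatchResult-class
#' @export
setGeneric("ppv", function(x) standardGeneric("ppv"))

#' @rdname BurdenSummary-class
#' @export
setGeneric("burdenTable", function(x) standardGeneric("burdenTable"))

setMethod("volData", "Volume", function(x) x@data)
setMethod("volSpacing", "Volume", function(x) x@spacing)
setMethod("petVol", "PetCtStudy", function(x) x@pet)
setMethod("ctVol", "PetCtStudy", function(x) x@ct)
setMethod("organMask", "PetCtStudy", function(x) x@organs)
setMethod("labelMap", "PetCtStudy", function(x) x@labels)
setMethod("studyId", "PetCtStudy", function(x) x@studyId)
setMethod("maskWeights", "SampleMask", function(x) x@weights)
setMethod("lesions", "LesionSet", function(x) x@lesions)
setMethod("sensitivity", "MatchResult", function(x) x@sensitivity)
setMethod("ppv", "MatchResult", function(x) x@ppv)
setMethod("burdenTable", "BurdenSummary", function(x) x@table)

setMethod("show", "Volume", function(object) {
  d <- dim(object@data)
  cat(sprintf("%s: %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm\n",
              class(object), d[1], d[2], d[3], object@spacing[1],
              object@spacing[2], object@spacing[3]))
  cat(sprintf("  value range [%.3g, %.3g]\n", min(object@data),
              max(object@data)))
})

setMethod("show", "LabelMap", function(object) {
  d <- dim(object@data)
  cat(sprintf("LabelMap: %d x %d x %d voxels, spacing %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], object@spacing[1], object@spacing[2],
              object@spacing[3]))
  tab <- table(factor(object@data, levels = 0:3, labels = CLASS_NAMES))
  cat("  voxels per class:",
      paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
      "\n")
})

setMethod("show", "PetCtStudy", function(object) {
  d <- dim(object@pet@data)
  cat(sprintf("PetCtStudy '%s': %d x %d x %d voxels, %d organ channels%s\n",
              object@studyId, d[1], d[2], d[3], dim(object@organs)[4],
              if (object@preprocessed) " (preprocessed)" else ""))
  if (!is.null(object@labels)) {
    nFg <- sum(object@labels@data > 0)
    cat(sprintf("  labels present: %d foreground voxels\n", nFg))
  }
})

setMethod("show", "SampleMask", function(object) {
  cat(sprintf("SampleMask for '%s': %s grid, max weight %.3g, %d nonzero\n",
              object@studyId, paste(dim(object@weights), collapse = " x "),
              max(object@weights), sum(object@weights > 0)))
})

setMethod("show", "VoxelClassifier", function(object) {
  np <- sum(vapply(object@params, length, integer(1)))
  cat(sprintf(
    "VoxelClassifier: 3D U-Net, depth %d, %d input channels, %d parameters\n",
    object@config@encoderDepth, object@config@nInputChannels, np))
})

setMethod("show", "LesionSet", function(object) {
  cc <- vapply(object@lesions, function(l) l@classCode, integer(1))
  cat(sprintf("LesionSet '%s' / study '%s': %d lesions", object@sourceId,
              object@studyId, length(object@lesions)))
  if (length(cc))
    cat(" (", paste(sprintf("%s=%d", CLASS_NAMES[2:4],
                            tabulate(cc, 3)), collapse = ", "), ")", sep = "")
  cat("\n")
})

setMethod("show", "MatchResult", function(object) {
  cat(sprintf(
    "MatchResult [%s vs %s, class %s]: TP=%d FP=%d FN=%d sens=%.3f ppv=%.3f\n",
    object@candidateId, object@referenceId, CLASS_NAMES[object@classCode + 1L],
    object@tp, object@fp, object@fn, object@sensitivity, object@ppv))
})

setMethod("show", "BurdenSummary", function(object) {
  cat(sprintf("BurdenSummary '%s' / study '%s':\n", object@sourceId,
              object@studyId))
  print(object@table, row.names = FALSE)
})
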