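#' @import methods
#' @importFrom stats rnorm runif rpois setNames cor.test sd
#' @importFrom utils head
#' @useDynLib petseg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

setClassUnion("LabelMapOrNULL", "NULL")

#' Volume: a 3D scalar grid with voxel spacing
#'
#' The elementary container for one co-registered image: a 3D numeric array
#' in (x, y, z) order plus the physical per-voxel extent in millimetres and a
#' world-space origin. Voxel indices are 1-based in R; world coordinates are
#' `origin + (index - 1) * spacing`.
#'
#' @slot data 3D numeric array.
#' @slot spacing numeric(3), per-voxel extent in mm (all > 0).
#' @slot origin numeric(3), world coordinate of the first voxel, in mm.
#' @export
setClass("Volume",
  representation(data = "array", spacing = "numeric", origin = "numeric"),
  prototype(data = array(0, c(1, 1, 1)), spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("Volume", function(object) {
  if (length(dim(object@data)) != 3L) return("data must be a 3D array")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0)) return("spacing must be 3 positive finite values")
  if (length(object@origin) != 3L || any(!is.finite(object@origin)))
    return("origin must be 3 finite values")
  TRUE
})

#' LabelMap: a voxel-wise class-code grid
#'
#' A [Volume] whose values are the integer class codes 0 = background,
#' 1 = prostate tumour/recurrence, 2 = lymph-node metastasis,
#' 3 = bone metastasis.
#'
#' @export
setClass("LabelMap", contains = "Volume")

setValidity("LabelMap", function(object) {
  v <- object@data
  if (!all(v %in% 0:3)) return("label codes must be in {0,1,2,3}")
  TRUE
})

setIs("LabelMap", "LabelMapOrNULL")

#' PetCtStudy: an aligned PET/CT/organ-mask/label bundle
#'
#' All members share one voxel grid: a PET volume in SUV, a CT volume in HU
#' (or both in normalised units after preprocessing), a multi-channel binary
#' organ mask, and optionally a ground-truth/reading [LabelMap].
#'
#' @slot pet [Volume] in SUV (normalised units after preprocessing).
#' @slot ct [Volume] in HU (normalised units after preprocessing).
#' @slot organs 4D binary array (x, y, z, channel).
#' @slot organNames character, one name per organ channel.
#' @slot labels [LabelMap] or NULL.
#' @slot studyId character scalar.
#' @slot preprocessed logical; TRUE once clamped/normalised to [0,1].
#' @export
setClass("PetCtStudy",
  representation(pet = "Volume", ct = "Volume", organs = "array",
                 organNames = "character", labels = "LabelMapOrNULL",
                 studyId = "character", preprocessed = "logical"),
  prototype(preprocessed = FALSE, studyId = "study"))

setValidity("PetCtStudy", function(object) {
  d <- dim(object@pet@data)
  if (!identical(dim(object@ct@data), d))
    return("PET and CT grids differ in shape")
  od <- dim(object@organs)
  if (length(od) != 4L || !identical(od[1:3], d))
    return("organ mask must be 4D and share the PET grid")
  if (length(object@organNames) != od[4])
    return("organNames length must equal the number of organ channels")
  if (!all(object@organs %in% c(0, 1)))
    return("organ mask channels must be binary")
  if (!is.null(object@labels) && !identical(dim(object@labels@data), d))
    return("label map must share the PET grid")
  if (!isTRUE(all.equal(object@pet@spacing, object@ct@spacing)))
    return("PET and CT spacing differ")
  TRUE
})

#' PhantomSpec: parameters of the synthetic PET-CT phantom
#'
#' Defines one synthetic study: grid geometry, PET background statistics,
#' lesion counts per class, lesion size/uptake ranges, the number of
#' unspecific (benign-mimicking) bone uptake foci, CT tissue levels and the
#' seed from which all randomness flows.
#'
#' @slot gridShape integer(3) voxels per axis.
#' @slot voxelSpacingMm numeric(3) mm.
#' @slot backgroundSuvMean,backgroundSuvSd PET background SUV statistics.
#' @slot lesionsPerClass integer(3): counts for (prostate, node, bone).
#' @slot lesionRadiusRangeMm numeric(2) lesion radius interval, mm.
#' @slot lesionSuvRange numeric(2) lesion peak SUV interval; its minimum must
#'   exceed the background mean.
#' @slot nUnspecificBoneFoci integer: benign bone uptakes labelled background.
#' @slot ctTissueHu named numeric: HU levels for air, soft tissue and bone.
#' @slot seed integer.
#' @export
setClass("PhantomSpec",
  representation(gridShape = "integer", voxelSpacingMm = "numeric",
                 backgroundSuvMean = "numeric", backgroundSuvSd = "numeric",
                 lesionsPerClass = "integer", lesionRadiusRangeMm = "numeric",
                 lesionSuvRange = "numeric", nUnspecificBoneFoci = "integer",
                 ctTissueHu = "numeric", seed = "integer"))

setValidity("PhantomSpec", function(object) {
  if (length(object@gridShape) != 3L || any(object@gridShape < 8L))
    return("gridShape must be 3 values >= 8")
  if (any(object@voxelSpacingMm <= 0)) return("voxel spacing must be positive")
  if (length(object@lesionsPerClass) != 3L || any(object@lesionsPerClass < 0L))
    return("lesionsPerClass must be 3 non-negative counts")
  if (any(object@lesionRadiusRangeMm <= 0) ||
      diff(object@lesionRadiusRangeMm) < 0)
    return("lesion radii must be a positive non-decreasing interval")
  if (object@lesionSuvRange[1] <= object@backgroundSuvMean)
    return("lesion SUV minimum must exceed the background mean")
  if (object@nUnspecificBoneFoci < 0L) return("focus count must be >= 0")
  if (!all(c("air", "soft", "bone") %in% names(object@ctTissueHu)))
    return("ctTissueHu needs named levels air, soft, bone")
  TRUE
})

#' ReaderPerturbation: parameters of a simulated alternative reading
#'
#' @slot pDropLesion probability a true lesion is omitted.
#' @slot pAddSpurious expected number of spurious lesions per study.
#' @slot boundaryJitterVoxels max dilation/erosion radius, voxels.
#' @slot seed integer.
#' @export
setClass("ReaderPerturbation",
  representation(pDropLesion = "numeric", pAddSpurious = "numeric",
                 boundaryJitterVoxels = "integer", seed = "integer"))

setValidity("ReaderPerturbation", function(object) {
  if (object@pDropLesion < 0 || object@pDropLesion > 1)
    return("pDropLesion must be in [0,1]")
  if (object@pAddSpurious < 0) return("pAddSpurious must be >= 0")
  if (object@boundaryJitterVoxels < 0L) return("jitter must be >= 0")
  TRUE
})

#' PreprocessConfig: clamping and resampling parameters
#'
#' @slot ctClamp numeric(2), HU window mapped to [0,1] (default [-800, 800]).
#' @slot petClamp numeric(2), SUV window mapped to [0,1] (default [0, 25]).
#' @slot targetSpacingMm numeric(3), the common voxel grid
#'   (default 1.37 x 1.37 x 2.79 mm).
#' @export
setClass("PreprocessConfig",
  representation(ctClamp = "numeric", petClamp = "numeric",
                 targetSpacingMm = "numeric"),
  prototype(ctClamp = c(-800, 800), petClamp = c(0, 25),
            targetSpacingMm = c(1.37, 1.37, 2.79)))

setValidity("PreprocessConfig", function(object) {
  if (diff(object@ctClamp) <= 0 || diff(object@petClamp) <= 0)
    return("clamp intervals must be non-degenerate")
  if (any(object@targetSpacingMm <= 0)) return("target spacing must be positive")
  TRUE
})

#' SampleMask: per-voxel patch-centre sampling weights
#'
#' One non-negative weight per voxel of a study, stored normalised to sum 1;
#' the categorical distribution from which training patch centres are drawn.
#'
#' @slot weights 3D non-negative array summing to 1.
#' @slot studyId character.
#' @export
setClass("SampleMask",
  representation(weights = "array", studyId = "character"))

setValidity("SampleMask", function(object) {
  w <- object@weights
  if (length(dim(w)) != 3L) return("weights must be a 3D array")
  if (any(w < 0) || any(!is.finite(w))) return("weights must be finite and >= 0")
  if (abs(sum(w) - 1) > 1e-8) return("weights must sum to 1")
  TRUE
})

#' LossMap: per-voxel training loss over a study
#'
#' @slot values 3D non-negative finite array.
#' @slot studyId character.
#' @export
setClass("LossMap",
  representation(values = "array", studyId = "character"))

setValidity("LossMap", function(object) {
  v <- object@values
  if (length(dim(v)) != 3L) return("values must be a 3D array")
  if (any(!is.finite(v)) || any(v < 0)) return("loss must be finite and >= 0")
  TRUE
})

#' Patch: a multi-channel training example
#'
#' @slot channels 4D array (x, y, z, channel) of network inputs.
#' @slot target 3D integer label sub-grid (same spatial shape).
#' @slot centre integer(3) voxel index in the source volume.
#' @slot size integer(3).
#' @export
setClass("Patch",
  representation(channels = "array", target = "array", centre = "integer",
                 size = "integer"))

setValidity("Patch", function(object) {
  sd1 <- dim(object@channels)[1:3]
  if (!identical(as.integer(sd1), as.integer(object@size)))
    return("channel spatial shape must equal size")
  if (!identical(as.integer(dim(object@target)), as.integer(object@size)))
    return("target shape must equal size")
  TRUE
})

#' ModelConfig: architecture parameters of the voxel classifier
#'
#' A compact 3D U-Net: `encoderDepth` resolution levels with 3x3x3
#' convolutions, 2x2x2 max pooling, nearest-neighbour upsampling with skip
#' concatenation, two dropout sites at the deepest encoder/decoder junctions,
#' and L2 weight regularisation on all convolution weights.
#'
#' @slot nInputChannels count of input channels (CT + PET + organ channels).
#' @slot nClasses always 4.
#' @slot encoderDepth number of pooling steps.
#' @slot baseFilters filters at full resolution.
#' @slot dropoutRate dropout rate at the two dropout sites (default 0.25).
#' @slot l2Weight L2 regularisation weight (default 0.001).
#' @export
setClass("ModelConfig",
  representation(nInputChannels = "integer", nClasses = "integer",
                 encoderDepth = "integer", baseFilters = "integer",
                 dropoutRate = "numeric", l2Weight = "numeric"),
  prototype(nClasses = 4L, encoderDepth = 2L, baseFilters = 8L,
            dropoutRate = 0.25, l2Weight = 0.001))

setValidity("ModelConfig", function(object) {
  if (object@nClasses != 4L) return("nClasses must be 4")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    return("dropoutRate must be in [0,1)")
  if (object@l2Weight < 0) return("l2Weight must be >= 0")
  if (object@nInputChannels < 1L || object@baseFilters < 1L ||
      object@encoderDepth < 1L) return("counts must be positive")
  TRUE
})

#' VoxelClassifier: a trainable voxel-wise 3D classifier
#'
#' Holds the [ModelConfig] and the parameter list (convolution weight
#' matrices and biases). Use [predictPatch()] for per-voxel class
#' probabilities and [trainModel()] to fit it.
#'
#' @slot config [ModelConfig].
#' @slot params named list of weight matrices / bias vectors.
#' @slot seed integer used for weight initialisation.
#' @export
setClass("VoxelClassifier",
  representation(config = "ModelConfig", params = "list", seed = "integer"))

#' TrainConfig: the training regime
#'
#' Defaults follow the full-scale regime: foreground loss weight 2.5,
#' initial learning rate 0.001 halved after 5 epochs without validation
#' improvement, 20,000 training and 10,000 validation samples per epoch,
#' 5 rounds of 10 epochs with a sample-mask refresh of half the training
#' studies after each round. Tests and examples use scaled-down values.
#'
#' @export
setClass("TrainConfig",
  representation(fgLossWeight = "numeric", initialLr = "numeric",
                 lrHalvingPatienceEpochs = "integer",
                 samplesPerEpochTrain = "integer",
                 samplesPerEpochVal = "integer", epochsPerRound = "integer",
                 nRounds = "integer", refreshFraction = "numeric",
                 batchSize = "integer", patchSize = "integer",
                 seed = "integer"),
  prototype(fgLossWeight = 2.5, initialLr = 0.001,
            lrHalvingPatienceEpochs = 5L, samplesPerEpochTrain = 20000L,
            samplesPerEpochVal = 10000L, epochsPerRound = 10L, nRounds = 5L,
            refreshFraction = 0.5, batchSize = 8L,
            patchSize = c(64L, 64L, 32L), seed = 1L))

setValidity("TrainConfig", function(object) {
  if (object@fgLossWeight <= 0) return("fgLossWeight must be > 0")
  if (any(c(object@samplesPerEpochTrain, object@samplesPerEpochVal,
            object@epochsPerRound, object@nRounds, object@batchSize) < 1L))
    return("all counts must be positive")
  if (object@refreshFraction < 0 || object@refreshFraction > 1)
    return("refreshFraction must be in [0,1]")
  if (length(object@patchSize) != 3L || any(object@patchSize < 4L))
    return("patchSize must be 3 values >= 4")
  TRUE
})

#' AugmentationSpec: random patch augmentation ranges
#'
#' One random isotropic scaling, one in-plane rotation, and per-modality
#' intensity shifts are drawn uniformly from symmetric ranges and applied to
#' each training patch. Intensity shift ranges are given in raw image units
#' (SUV for PET, HU for CT) and applied as the equivalent shift on the
#' normalised channels.
#'
#' @slot scaleRange fractional scaling interval (default c(-0.1, 0.1)).
#' @slot rotationRangeRad rotation interval in radians (default ±0.15).
#' @slot petShiftSuv PET shift interval in SUV (default ±0.5).
#' @slot ctShiftHu CT shift interval in HU (default ±100).
#' @export
setClass("AugmentationSpec",
  representation(scaleRange = "numeric", rotationRangeRad = "numeric",
                 petShiftSuv = "numeric", ctShiftHu = "numeric"),
  prototype(scaleRange = c(-0.1, 0.1), rotationRangeRad = c(-0.15, 0.15),
            petShiftSuv = c(-0.5, 0.5), ctShiftHu = c(-100, 100)))

setValidity("AugmentationSpec", function(object) {
  symm <- function(r) length(r) == 2L && isTRUE(all.equal(r[1], -r[2]))
  if (!symm(object@scaleRange) || !symm(object@rotationRangeRad) ||
      !symm(object@petShiftSuv) || !symm(object@ctShiftHu))
    return("all augmentation ranges must be symmetric about 0")
  TRUE
})

#' TilingConfig: sliding-window whole-volume inference
#'
#' @slot tileSize integer(3); each axis must be divisible by 2^encoderDepth.
#' @slot overlapVoxels integer(3), strictly less than the tile size.
#' @export
setClass("TilingConfig",
  representation(tileSize = "integer", overlapVoxels = "integer"),
  prototype(tileSize = c(32L, 32L, 16L), overlapVoxels = c(8L, 8L, 4L)))

setValidity("TilingConfig", function(object) {
  if (any(object@overlapVoxels >= object@tileSize))
    return("overlap must be smaller than the tile size")
  if (any(object@overlapVoxels < 0L)) return("overlap must be >= 0")
  TRUE
})

#' Lesion: one connected lesion component
#'
#' @slot classCode 1, 2 or 3.
#' @slot voxelIndices n x 3 integer matrix of member voxels.
#' @slot volumeMl volume in millilitres.
#' @slot suvMean mean PET value over the lesion voxels.
#' @slot lesionId character.
#' @export
setClass("Lesion",
  representation(classCode = "integer", voxelIndices = "matrix",
                 volumeMl = "numeric", suvMean = "numeric",
                 lesionId = "character"))

setValidity("Lesion", function(object) {
  if (!object@classCode %in% 1:3) return("classCode must be 1, 2 or 3")
  if (nrow(object@voxelIndices) < 1L) return("a lesion must have >= 1 voxel")
  if (object@volumeMl <= 0) return("volume must be positive")
  TRUE
})

#' LesionSet: all lesions of one reading of one study
#'
#' @slot lesions list of [Lesion].
#' @slot sourceId reading/model identifier.
#' @slot studyId character.
#' @slot gridShape integer(3) of the source grid.
#' @slot spacingMm numeric(3).
#' @export
setClass("LesionSet",
  representation(lesions = "list", sourceId = "character",
                 studyId = "character", gridShape = "integer",
                 spacingMm = "numeric"))

#' MatchResult: lesion-level comparison of two readings
#'
#' Candidate lesions with at least one voxel of segmentation overlap with a
#' same-class reference lesion are true positives; candidates with none are
#' false positives. Reference lesions with overlap are "detected", those
#' without are false negatives. Sensitivity = detected / total reference
#' lesions; PPV = TP / (TP + FP). Detected references and TP candidates are
#' tracked separately so one candidate spanning two references does not
#' inflate PPV.
#'
#' @export
setClass("MatchResult",
  representation(tp = "integer", fp = "integer", fn = "integer",
                 detectedRefs = "integer", nRefs = "integer",
                 tpIds = "character", fpIds = "character", fnIds = "character",
                 sensitivity = "numeric", ppv = "numeric",
                 classCode = "integer", candidateId = "character",
                 referenceId = "character"))

#' BurdenSummary: per-class TLV and TLU of one study
#'
#' @slot table data.frame with columns class_code, class_name, tlv_ml, tlu.
#' @slot studyId,sourceId identifiers.
#' @export
setClass("BurdenSummary",
  representation(table = "data.frame", studyId = "character",
                 sourceId = "character"))

CLASS_NAMES <- c("background", "prostate", "node", "bone")
FOREGROUND_CODES <- 1:3
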