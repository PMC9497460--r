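#' Extract lesions from a label map
#'
#' Lesions are maximal 26-connected components computed separately per
#' foreground class (a node lesion touching a bone lesion stays two
#' lesions). Each lesion is annotated with its volume (voxel count times
#' voxel volume, in mL) and mean PET value over its voxels.
#'
#' @param labels a [LabelMap-class].
#' @param pet the aligned PET [Volume-class] (SUV).
#' @param sourceId reading/model identifier stored on the set.
#' @param studyId study identifier.
#' @return a [LesionSet-class].
#' @export
extractLesions <- function(labels, pet, sourceId = "reading",
                           studyId = "study") {
  if (!identical(dim(labels@data), dim(pet@data)))
    stop("alignment error: label and PET grids differ")
  d <- dim(labels@data)
  voxMl <- prod(labels@spacing) / 1000
  out <- list()
  for (cls in FOREGROUND_CODES) {
    mask <- array(as.integer(labels@data == cls), d)
    if (!any(mask > 0)) next
    lab <- .label_components26(mask)
    for (k in seq_len(max(lab))) {
      lin <- which(lab == k)
      out[[length(out) + 1L]] <- new("Lesion", classCode = cls,
        voxelIndices = arrayInd(lin, d), volumeMl = length(lin) * voxMl,
        suvMean = mean(pet@data[lin]),
        lesionId = sprintf("%s-%s-%d", sourceId, CLASS_NAMES[cls + 1L], k))
    }
  }
  new("LesionSet", lesions = out, sourceId = sourceId, studyId = studyId,
      gridShape = as.integer(d), spacingMm = labels@spacing)
}

# paint each lesion of one class into an integer grid (values = lesion index)
lesionIndexGrid <- function(set, classCode) {
  g <- array(0L, set@gridShape)
  sel <- which(vapply(set@lesions, function(l) l@classCode, integer(1)) ==
                 classCode)
  for (j in seq_along(sel)) {
    vi <- set@lesions[[sel[j]]]@voxelIndices
    g[vi] <- j
  }
  list(grid = g, lesionIdx = sel)
}

#' Match candidate lesions against a reference reading
#'
#' A candidate lesion with at least one voxel of same-class segmentation
#' overlap with any reference lesion is a true positive; without overlap it
#' is a false positive. A reference lesion overlapped by any candidate is
#' detected; otherwise it is a false negative. Sensitivity is detected
#' reference lesions over all reference lesions; PPV is TP / (TP + FP).
#' Matching is class-specific and independent of lesion enumeration order.
#'
#' @param candidate,reference [LesionSet-class] objects from the same study.
#' @param classCode 1 (prostate), 2 (node) or 3 (bone).
#' @return a [MatchResult-class].
#' @export
matchLesions <- function(candidate, reference, classCode) {
  classCode <- as.integer(classCode)
  if (!classCode %in% FOREGROUND_CODES)
    stop("classCode must be 1, 2 or 3")
  if (!identical(candidate@gridShape, reference@gridShape))
    stop("alignment error: candidate and reference grids differ")
  cg <- lesionIndexGrid(candidate, classCode)
  rg <- lesionIndexGrid(reference, classCode)
  nC <- length(cg$lesionIdx)
  nR <- length(rg$lesionIdx)
  both <- cg$grid > 0L & rg$grid > 0L
  tpC <- sort(unique(cg$grid[both]))
  detR <- sort(unique(rg$grid[both]))
  fpC <- setdiff(seq_len(nC), tpC)
  fnR <- setdiff(seq_len(nR), detR)
  idOf <- function(set, sel, j) set@lesions[[sel[j]]]@lesionId
  tp <- length(tpC); fp <- length(fpC); fn <- length(fnR)
  new("MatchResult", tp = tp, fp = fp, fn = fn,
      detectedRefs = length(detR), nRefs = nR,
      tpIds = vapply(tpC, function(j) idOf(candidate, cg$lesionIdx, j),
                     character(1)),
      fpIds = vapply(fpC, function(j) idOf(candidate, cg$lesionIdx, j),
                     character(1)),
      fnIds = vapply(fnR, function(j) idOf(reference, rg$lesionIdx, j),
                     character(1)),
      sensitivity = if (nR > 0) length(detR) / nR else NA_real_,
      ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
      classCode = classCode, candidateId = candidate@sourceId,
      referenceId = reference@sourceId)
}

#' Pairwise lesion-detection report across readings
#'
#' Each source (a reading or the model) is alternately compared against each
#' other source used as reference. Per ordered pair, TP/FP/FN are pooled
#' over the shared studies; sensitivity is pooled detected reference lesions
#' over pooled reference lesions (studies without reference lesions
#' contribute only FP counts), PPV is pooled TP/(TP+FP), and per-patient
#' values divide by the number of shared studies. Summary rows per
#' candidate report the mean over its references (average of per-reference
#' pooled values) and the range.
#'
#' @param setsBySource named list; each element is a list of
#'   [LesionSet-class] objects (one per study, aligned across sources).
#' @param classCode 1, 2 or 3.
#' @return a data.frame with one row per ordered (candidate, reference)
#'   pair plus one summary row per candidate (`row_type == "summary"`,
#'   reference `"(mean)"`, with `sens_lo/hi` and `ppv_lo/hi` ranges).
#' @export
pairwiseReport <- function(setsBySource, classCode) {
  src <- names(setsBySource)
  if (length(src) < 2L) stop("need at least two sources")
  nStudies <- unique(vapply(setsBySource, length, integer(1)))
  if (length(nStudies) != 1L || nStudies == 0L)
    stop("sources must share the same study list")
  rows <- list()
  for (cand in src) for (ref in setdiff(src, cand)) {
    tp <- fp <- fn <- det <- nref <- 0L
    for (i in seq_len(nStudies)) {
      m <- matchLesions(setsBySource[[cand]][[i]], setsBySource[[ref]][[i]],
                        classCode)
      tp <- tp + m@tp; fp <- fp + m@fp; fn <- fn + m@fn
      det <- det + m@detectedRefs; nref <- nref + m@nRefs
    }
    rows[[length(rows) + 1L]] <- data.frame(
      row_type = "pair", candidate = cand, reference = ref,
      n_studies = nStudies, tp_total = tp, fp_total = fp, fn_total = fn,
      tp_per_patient = tp / nStudies, fp_per_patient = fp / nStudies,
      fn_per_patient = fn / nStudies,
      sensitivity_pct = if (nref > 0) 100 * det / nref else NA_real_,
      ppv_pct = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
      sens_lo = NA_real_, sens_hi = NA_real_, ppv_lo = NA_real_,
      ppv_hi = NA_real_)
  }
  df <- do.call(rbind, rows)
  summ <- lapply(src, function(cand) {
    sub <- df[df$candidate == cand, ]
    data.frame(row_type = "summary", candidate = cand, reference = "(mean)",
               n_studies = nStudies, tp_total = mean(sub$tp_total),
               fp_total = mean(sub$fp_total), fn_total = mean(sub$fn_total),
               tp_per_patient = mean(sub$tp_per_patient),
               fp_per_patient = mean(sub$fp_per_patient),
               fn_per_patient = mean(sub$fn_per_patient),
               sensitivity_pct = mean(sub$sensitivity_pct),
               ppv_pct = mean(sub$ppv_pct),
               sens_lo = min(sub$sensitivity_pct),
               sens_hi = max(sub$sensitivity_pct),
               ppv_lo = min(sub$ppv_pct), ppv_hi = max(sub$ppv_pct))
  })
  rbind(df, do.call(rbind, summ))
}

#' Spearman rank correlation between two per-study burden vectors
#'
#' Ties are handled by average ranks; the p-value is two-sided.
#'
#' @param burdenA,burdenB paired numeric vectors of length >= 3.
#' @return list with `rho` and `p_value`.
#' @export
spearmanBurden <- function(burdenA, burdenB) {
  if (length(burdenA) != length(burdenB)) stop("vectors must be paired")
  if (length(burdenA) < 3L) stop("need at least 3 paired values")
  if (sd(burdenA) == 0 || sd(burdenB) == 0) {
    warning("zero variance in a burden vector; correlation undefined")
    return(list(rho = NA_real_, p_value = NA_real_))
  }
  ct <- suppressWarnings(cor.test(burdenA, burdenB, method = "spearman",
                                  exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}
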