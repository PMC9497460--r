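#' Construct a PhantomSpec
#'
#' Defaults describe a small pelvis-like phantom on the 1.37 x 1.37 x 2.79 mm
#' grid: soft-tissue background with mean SUV 1.0 (sd 0.15), smooth-edged
#' spherical lesions of 4-8 mm radius and peak SUV 4-10, one prostate
#' lesion, two nodal and two bone lesions, plus two unspecific bone foci
#' with lesion-like uptake but background label.
#'
#' @param gridShape voxels per axis.
#' @param voxelSpacingMm per-voxel extent in mm.
#' @param backgroundSuvMean,backgroundSuvSd PET background statistics (SUV).
#' @param lesionsPerClass counts for (prostate, node, bone).
#' @param lesionRadiusRangeMm lesion radius interval in mm.
#' @param lesionSuvRange lesion peak SUV interval; min must exceed the
#'   background mean.
#' @param nUnspecificBoneFoci benign-mimicking bone uptakes labelled
#'   background.
#' @param ctTissueHu named HU levels for air, soft tissue and bone.
#' @param seed integer; all phantom randomness flows from it.
#' @return a [PhantomSpec-class] object.
#' @export
PhantomSpec <- function(gridShape = c(48, 48, 48),
                        voxelSpacingMm = c(1.37, 1.37, 2.79),
                        backgroundSuvMean = 1.0, backgroundSuvSd = 0.15,
                        lesionsPerClass = c(1, 2, 2),
                        lesionRadiusRangeMm = c(4, 8),
                        lesionSuvRange = c(4, 10),
                        nUnspecificBoneFoci = 2,
                        ctTissueHu = c(air = -800, soft = 40, bone = 700),
                        seed = 1) {
  new("PhantomSpec", gridShape = as.integer(gridShape),
      voxelSpacingMm = as.numeric(voxelSpacingMm),
      backgroundSuvMean = backgroundSuvMean,
      backgroundSuvSd = backgroundSuvSd,
      lesionsPerClass = as.integer(lesionsPerClass),
      lesionRadiusRangeMm = as.numeric(lesionRadiusRangeMm),
      lesionSuvRange = as.numeric(lesionSuvRange),
      nUnspecificBoneFoci = as.integer(nUnspecificBoneFoci),
      ctTissueHu = ctTissueHu, seed = as.integer(seed))
}

#' Construct a ReaderPerturbation
#'
#' @param pDropLesion probability each true lesion is omitted.
#' @param pAddSpurious expected number of spurious lesions per study.
#' @param boundaryJitterVoxels maximum dilation/erosion radius in voxels.
#' @param seed integer.
#' @return a [ReaderPerturbation-class] object.
#' @export
ReaderPerturbation <- function(pDropLesion = 0, pAddSpurious = 0,
                               boundaryJitterVoxels = 0, seed = 1) {
  new("ReaderPerturbation", pDropLesion = pDropLesion,
      pAddSpurious = pAddSpurious,
      boundaryJitterVoxels = as.integer(boundaryJitterVoxels),
      seed = as.integer(seed))
}

# evaluate expr with a temporary RNG seed, restoring global RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# squared ellipsoidal mm distance field from a centre over index grids
distMmSq <- function(ix, iy, iz, centre, spacing) {
  dx <- (ix - centre[1]) * spacing[1]
  dy <- (iy - centre[2]) * spacing[2]
  dz <- (iz - centre[3]) * spacing[3]
  outer(outer(dx^2, dy^2, `+`), dz^2, `+`)
}

# deterministic compartment geometry in voxel units, scaled to the grid
phantomCompartments <- function(d) {
  ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
  rel <- function(p) p * d
  sphereMask <- function(centre, radii) {
    dx <- ((ix - centre[1]) / radii[1])^2
    dy <- ((iy - centre[2]) / radii[2])^2
    dz <- ((iz - centre[3]) / radii[3])^2
    outer(outer(dx, dy, `+`), dz, `+`) <= 1
  }
  body <- sphereMask(rel(c(0.5, 0.5, 0.5)), 0.47 * d)
  cylinder <- function(cxy, r) {
    dx <- ((ix - cxy[1] * d[1]) / r)^2
    dy <- ((iy - cxy[2] * d[2]) / r)^2
    inPlane <- outer(dx, dy, `+`) <= 1
    array(rep(inPlane, d[3]), dim = d) & body
  }
  skeleton <- cylinder(c(0.5, 0.7), max(3, 0.1 * d[1])) |
    cylinder(c(0.2, 0.5), max(2.5, 0.07 * d[1])) |
    cylinder(c(0.8, 0.5), max(2.5, 0.07 * d[1]))
  prostate <- sphereMask(rel(c(0.5, 0.38, 0.3)), pmax(3, 0.12 * d)) & body &
    !skeleton
  nodes <- (sphereMask(rel(c(0.33, 0.45, 0.6)), pmax(3, 0.11 * d)) |
            sphereMask(rel(c(0.67, 0.45, 0.6)), pmax(3, 0.11 * d))) & body &
    !skeleton & !prostate
  list(body = body, skeleton = skeleton, prostate = prostate, nodes = nodes)
}

# place one smooth-edged spherical lesion; returns NULL when no admissible
# centre is found within the retry budget
placeLesion <- function(occupied, compartment, rMm, spacing, clipMask = NULL,
                        maxTries = 200L) {
  d <- dim(occupied)
  cand <- which(compartment & !occupied)
  if (!length(cand)) return(NULL)
  ix <- seq_len(d[1]); iy <- seq_len(d[2]); iz <- seq_len(d[3])
  for (i in seq_len(maxTries)) {
    centre <- arrayInd(cand[sample.int(length(cand), 1L)], d)[1, ]
    rVox <- rMm / spacing
    lo <- centre - ceiling(rVox) - 1L
    hi <- centre + ceiling(rVox) + 1L
    if (any(lo < 1L) || any(hi > d)) next
    dmm <- sqrt(distMmSq(ix, iy, iz, centre, spacing))
    support <- dmm <= rMm
    if (!is.null(clipMask)) support <- support & clipMask
    if (!any(support)) next
    # keep a 1-voxel moat so same-class lesions can never merge
    halo <- dilate26(support)
    if (any(halo & occupied)) next
    return(list(centre = centre, dmm = dmm, support = support))
  }
  NULL
}

# 26-neighbourhood binary dilation / erosion via array shifts
shift3 <- function(a, s) {
  d <- dim(a)
  out <- array(FALSE, d)
  src <- lapply(1:3, function(i) {
    r <- seq_len(d[i]) + s[i]
    r[r >= 1 & r <= d[i]]
  })
  dst <- lapply(1:3, function(i) {
    r <- seq_len(d[i])
    r[r + s[i] >= 1 & r + s[i] <= d[i]]
  })
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

dilate26 <- function(a) {
  out <- a
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1)
    if (sx || sy || sz) out <- out | shift3(a, c(sx, sy, sz))
  out
}

erode26 <- function(a) {
  out <- a
  for (sx in -1:1) for (sy in -1:1) for (sz in -1:1)
    if (sx || sy || sz) out <- out & shift3(a, c(sx, sy, sz))
  out
}

#' Generate one synthetic PET-CT study
#'
#' Builds aligned PET, CT, organ-mask and ground-truth label volumes on one
#' grid. The phantom contains four organ compartments (prostate bed, pelvic
#' nodes region, skeleton, soft tissue); lesions are smooth-edged spheres
#' (a cumulative-normal radial profile approximating PET partial-volume
#' blur) whose labelled voxels always stay above the background mean plus
#' one standard deviation; unspecific bone foci carry lesion-like uptake but
#' keep the background label, mimicking benign bone uptake of
#' \[18F\]PSMA-1007. Deterministic given `spec@seed`.
#'
#' @param spec a [PhantomSpec-class].
#' @return a [PetCtStudy-class] with ground-truth labels and a
#'   `lesionManifest` data.frame (centre, radius, peak SUV, class) attached
#'   as metadata via `attr(study, "lesionManifest")`.
#' @export
generateStudy <- function(spec) {
  validObject(spec)
  withSeed(spec@seed, {
    d <- spec@gridShape
    sp <- spec@voxelSpacingMm
    comp <- phantomCompartments(d)
    pet <- array(0, d)
    nBody <- sum(comp$body)
    pet[comp$body] <- rnorm(nBody, spec@backgroundSuvMean,
                            spec@backgroundSuvSd)
    pet[!comp$body] <- abs(rnorm(sum(!comp$body), 0, 0.02))
    ct <- array(spec@ctTissueHu[["air"]], d)
    ct[comp$body] <- spec@ctTissueHu[["soft"]]
    ct[comp$skeleton] <- spec@ctTissueHu[["bone"]]
    ct <- ct + array(rnorm(prod(d), 0, 20), d)
    labels <- array(0, d)
    occupied <- array(FALSE, d)
    sigmaMm <- 1.2  # edge blur width

    manifest <- list()
    compOf <- list(comp$prostate, comp$nodes, comp$skeleton)
    classes <- rep(1:3, times = spec@lesionsPerClass)
    kinds <- rep("lesion", length(classes))
    classes <- c(classes, rep(3L, spec@nUnspecificBoneFoci))
    kinds <- c(kinds, rep("unspecific_focus",
                          spec@nUnspecificBoneFoci))
    for (i in seq_along(classes)) {
      cls <- classes[i]
      rMm <- runif(1, spec@lesionRadiusRangeMm[1], spec@lesionRadiusRangeMm[2])
      suv <- runif(1, spec@lesionSuvRange[1], spec@lesionSuvRange[2])
      clip <- if (cls == 3L) comp$skeleton else comp$body
      pl <- placeLesion(occupied, compOf[[cls]], rMm, sp, clip)
      if (is.null(pl))
        stop("placement error: could not place ", kinds[i], " of class ", cls,
             " after bounded retries")
      profile <- stats::pnorm((rMm - pl$dmm) / sigmaMm)
      blur <- pl$dmm <= rMm + 2 * sigmaMm
      blur <- blur & (if (cls == 3L) comp$skeleton else comp$body)
      pet[blur] <- pet[blur] +
        (suv - spec@backgroundSuvMean) * profile[blur]
      if (kinds[i] == "lesion") labels[pl$support] <- cls
      occupied <- occupied | pl$support
      manifest[[i]] <- data.frame(kind = kinds[i], class_code = cls,
                                  cx = pl$centre[1], cy = pl$centre[2],
                                  cz = pl$centre[3], radius_mm = rMm,
                                  peak_suv = suv)
    }
    # invariant: labelled lesion voxels exceed background mean + 1 sd
    if (any(labels > 0)) {
      floorSuv <- spec@backgroundSuvMean + spec@backgroundSuvSd
      if (min(pet[labels > 0]) <= floorSuv)
        stop("phantom invariant violated: lesion uptake not above background",
             " mean + 1 sd; increase lesion SUV or reduce background sd")
    }
    organs <- array(0, c(d, 4L))
    organs[, , , 1] <- comp$prostate
    organs[, , , 2] <- comp$nodes
    organs[, , , 3] <- comp$skeleton
    organs[, , , 4] <- comp$body & !comp$skeleton
    study <- PetCtStudy(Volume(pet, sp), Volume(ct, sp), organs,
                        c("prostate_bed", "pelvic_nodes", "skeleton",
                          "soft_tissue"),
                        LabelMap(labels, sp),
                        studyId = sprintf("phantom-%d", spec@seed))
    attr(study, "lesionManifest") <-
      if (length(manifest)) do.call(rbind, manifest) else
        data.frame(kind = character(), class_code = integer(),
                   cx = integer(), cy = integer(), cz = integer(),
                   radius_mm = numeric(), peak_suv = numeric())
    study
  })
}

# largest-remainder apportionment; ties go to the earlier group
splitSizes <- function(n, proportions = c(420, 120, 120) / 660) {
  p <- proportions / sum(proportions)
  raw <- p * n
  base <- floor(raw)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(-(raw - base), seq_along(raw))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  setNames(as.integer(base), c("train", "validation", "test"))
}

#' Generate a cohort of phantom studies with a train/validation/test split
#'
#' Per-study seeds are derived from `spec@seed`, so the cohort is bitwise
#' reproducible. Split proportions default to 420/120/120 out of 660; sizes
#' are apportioned by largest remainder with ties resolved toward the
#' earlier group (train first).
#'
#' @param n number of studies (>= 1).
#' @param spec a [PhantomSpec-class] used as the template for every study.
#' @param proportions length-3 split proportions (train, validation, test).
#' @return list with `studies` (list of [PetCtStudy-class]) and `split`
#'   (named list of index vectors).
#' @export
generateCohort <- function(n, spec = PhantomSpec(),
                           proportions = c(420, 120, 120) / 660) {
  n <- asCount(n, "n")
  if (n < 1L) stop("n must be >= 1")
  studies <- vector("list", n)
  for (i in seq_len(n)) {
    s <- spec
    s@seed <- deriveSeed(spec@seed, paste0("study", i))
    studies[[i]] <- generateStudy(s)
    studies[[i]]@studyId <- sprintf("phantom-%03d", i)
  }
  sizes <- splitSizes(n, proportions)
  idx <- seq_len(n)
  split <- list(train = idx[seq_len(sizes[1])],
                validation = idx[sizes[1] + seq_len(sizes[2])],
                test = idx[sizes[1] + sizes[2] + seq_len(sizes[3])])
  list(studies = studies, split = split)
}

#' Simulate an alternative human reading of a ground-truth label map
#'
#' Emulates inter-reader variability: each true lesion (26-connected
#' component, per class) is independently dropped with `pDropLesion`;
#' surviving lesions are dilated or eroded by up to `boundaryJitterVoxels`
#' (erosion stops before a lesion would vanish); spurious small lesions are
#' added with Poisson expectation `pAddSpurious`. With all parameters zero
#' the output is voxel-identical to the input. Deterministic given
#' `pert@seed`.
#'
#' @param truth a [LabelMap-class] ground truth.
#' @param pert a [ReaderPerturbation-class].
#' @return a perturbed [LabelMap-class].
#' @export
perturbReading <- function(truth, pert) {
  validObject(pert)
  if (pert@pDropLesion == 0 && pert@pAddSpurious == 0 &&
      pert@boundaryJitterVoxels == 0L)
    return(truth)
  withSeed(pert@seed, {
    d <- dim(truth@data)
    out <- array(0, d)
    for (cls in FOREGROUND_CODES) {
      mask <- array(as.integer(truth@data == cls), d)
      if (!any(mask > 0)) next
      lab <- .label_components26(mask)
      for (k in seq_len(max(lab))) {
        if (runif(1) < pert@pDropLesion) next
        les <- lab == k
        if (pert@boundaryJitterVoxels > 0L) {
          j <- sample(seq(-pert@boundaryJitterVoxels,
                          pert@boundaryJitterVoxels), 1L)
          if (j > 0) for (s in seq_len(j)) les <- dilate26(les)
          if (j < 0) for (s in seq_len(-j)) {
            nxt <- erode26(les)
            if (!any(nxt)) break  # never erode to extinction
            les <- nxt
          }
        }
        out[les & out == 0] <- cls
      }
    }
    nSpur <- rpois(1, pert@pAddSpurious)
    for (s in seq_len(nSpur)) {
      cls <- sample(FOREGROUND_CODES, 1L)
      r <- sample(1:2, 1L)
      for (try in 1:50) {
        centre <- vapply(d, function(n) sample.int(n, 1L), integer(1))
        lo <- pmax(centre - r, 1L); hi <- pmin(centre + r, d)
        box <- out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
        if (all(box == 0)) {
          out[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- cls
          break
        }
      }
    }
    LabelMap(out, truth@spacing, truth@origin)
  })
}
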