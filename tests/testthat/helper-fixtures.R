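# Shared fixtures and independent oracles, all built in code at test time.

# small fast phantom spec on an isotropic 2 mm grid
tinySpec <- function(seed = 1, ...) {
  args <- list(gridShape = c(24, 24, 24), voxelSpacingMm = c(2, 2, 2),
               lesionsPerClass = c(1, 1, 1), lesionRadiusRangeMm = c(4, 6),
               nUnspecificBoneFoci = 0, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(PhantomSpec, args)
}

# a preprocessed tiny study (target grid = native grid so no resampling)
tinyStudy <- function(seed = 1, ...) {
  preprocessStudy(generateStudy(tinySpec(seed, ...)),
                  PreprocessConfig(targetSpacingMm = c(2, 2, 2)))
}

# label map literal from an array
lm <- function(arr, spacing = c(1, 1, 1)) LabelMap(arr, spacing)

# independent pure-R 26-connectivity components (BFS), used as the oracle
# against the compiled labelling and the lesion matcher
ccOracle <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nb <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  nxt <- 0L
  for (s in which(mask != 0)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue)) {
      v <- arrayInd(queue[1], d)
      queue <- queue[-1]
      for (r in seq_len(nrow(nb))) {
        p <- v + nb[r, ]
        if (any(p < 1) || any(p > d)) next
        if (mask[p[1], p[2], p[3]] != 0 && lab[p[1], p[2], p[3]] == 0L) {
          lab[p[1], p[2], p[3]] <- nxt
          queue <- c(queue, (p[3] - 1) * d[1] * d[2] + (p[2] - 1) * d[1] + p[1])
        }
      }
    }
  }
  lab
}

# brute-force lesion matching oracle: enumerates voxel overlap directly on
# two label grids for one class, using ccOracle components
matchOracle <- function(candArr, refArr, cls) {
  cl <- ccOracle(array(as.integer(candArr == cls), dim(candArr)))
  rl <- ccOracle(array(as.integer(refArr == cls), dim(refArr)))
  nC <- max(cl); nR <- max(rl)
  tp <- 0L
  for (k in seq_len(nC))
    if (any(rl[cl == k] > 0)) tp <- tp + 1L
  det <- 0L
  for (k in seq_len(nR))
    if (any(cl[rl == k] > 0)) det <- det + 1L
  list(tp = tp, fp = nC - tp, fn = nR - det, det = det, nRefs = nR,
       sens = if (nR > 0) det / nR else NA_real_,
       ppv = if (nC > 0) tp / nC else NA_real_)
}

# random sparse label map for matcher fuzzing
randomLabelArr <- function(d = c(8, 8, 8), pFg = 0.08) {
  arr <- array(0, d)
  n <- prod(d)
  fg <- which(runif(n) < pFg)
  arr[fg] <- sample(1:3, length(fg), replace = TRUE)
  arr
}

# tiny trained-shape model (random weights) for inference tests
tinyModel <- function(seed = 1, nIn = 6, depth = 2, filters = 4) {
  buildModel(ModelConfig(nInputChannels = nIn, encoderDepth = depth,
                         baseFilters = filters, dropoutRate = 0.25),
             seed = seed)
}
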