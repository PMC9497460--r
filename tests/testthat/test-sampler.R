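test_that("initial mask is 50% background, foreground split over present classes", {
  # 100 background, 10 prostate, 5 bone, no node: weights 0.005/0.025/0.05
  arr <- array(0, c(115, 1, 1))
  arr[101:110, 1, 1] <- 1
  arr[111:115, 1, 1] <- 3
  m <- initSampleMask(lm(arr))
  w <- maskWeights(m)
  expect_equal(sum(w), 1)
  expect_equal(unique(w[arr == 0]), 0.005)
  expect_equal(unique(w[arr == 1]), 0.025)
  expect_equal(unique(w[arr == 3]), 0.05)

  # all three classes present: each class's weights sum to 1/6
  arr3 <- array(0, c(60, 1, 1))
  arr3[1:6, 1, 1] <- 1; arr3[7:18, 1, 1] <- 2; arr3[19:21, 1, 1] <- 3
  w3 <- maskWeights(initSampleMask(lm(arr3)))
  for (k in 1:3) expect_equal(sum(w3[arr3 == k]), 1 / 6)
  expect_equal(sum(w3[arr3 == 0]), 0.5)

  # no foreground: uniform fallback
  wu <- maskWeights(initSampleMask(lm(array(0, c(4, 4, 4)))))
  expect_true(all(abs(wu - 1 / 64) < 1e-12))
})

test_that("patch centres follow the mask distribution", {
  # degenerate mask: every centre is the single weighted voxel
  w <- array(0, c(5, 5, 5)); w[2, 3, 4] <- 1
  ctr <- drawPatchCentres(SampleMask(w), 20, seed = 1)
  expect_true(all(ctr[, 1] == 2 & ctr[, 2] == 3 & ctr[, 3] == 4))

  # uniform over 2 voxels: frequencies within the 99% binomial interval
  w2 <- array(0, c(2, 1, 1)); w2[] <- 1
  ctr2 <- drawPatchCentres(SampleMask(w2), 10000, seed = 2)
  f <- mean(ctr2[, 1] == 1)
  expect_gt(f, 0.48); expect_lt(f, 0.52)

  expect_error(drawPatchCentres(SampleMask(w2), 0), "n must be")
  # determinism
  expect_identical(drawPatchCentres(SampleMask(w2), 50, seed = 7),
                   drawPatchCentres(SampleMask(w2), 50, seed = 7))
})

test_that("empirical centre frequencies pass a chi-square goodness-of-fit", {
  set.seed(11)
  w <- array(runif(100), c(100, 1, 1))
  m <- SampleMask(w)
  ctr <- drawPatchCentres(m, 50000, seed = 99)
  counts <- tabulate(ctr[, 1], 100)
  p <- suppressWarnings(stats::chisq.test(counts,
                                          p = as.vector(maskWeights(m))))
  expect_gt(p$p.value, 0.01)
})

test_that("half the centres of an initialised phantom mask are background", {
  s <- tinyStudy(seed = 13)
  m <- initSampleMask(labelMap(s))
  ctr <- drawPatchCentres(m, 10000, seed = 3)
  onBg <- mean(volData(labelMap(s))[ctr] == 0)
  expect_gt(onBg, 0.487); expect_lt(onBg, 0.513)
})

test_that("patch extraction slices interiors and mirror-pads corners", {
  s <- tinyStudy(seed = 14)
  x <- stackInputChannels(s)
  p <- extractPatch(s, c(12, 12, 12), c(8, 8, 8))
  expect_identical(p@channels, x[9:16, 9:16, 9:16, , drop = FALSE])
  expect_identical(p@target,
                   array(volData(labelMap(s))[9:16, 9:16, 9:16], c(8, 8, 8)))

  # corner: compare against an explicit hand-mirrored index oracle
  pc <- extractPatch(s, c(1, 1, 1), c(6, 6, 6))
  mirror <- c(3, 2, 1, 2, 3, 4)  # indices -2..3 reflected into 1..24
  expect_identical(pc@channels,
                   x[mirror, mirror, mirror, , drop = FALSE])

  # full-volume patch equals the volume
  pf <- extractPatch(s, c(12, 12, 12), c(24, 24, 24))
  expect_identical(pf@channels, x)
  expect_error(extractPatch(s, c(1, 1, 1), c(64, 8, 8)), "twice")
})

test_that("the adaptive weight update matches its scalar definition", {
  # three voxels, w = (1,1,1), l = (1,2,4): w' = (0.625, 0.75, 1.0)
  expect_equal(petseg:::adaptWeights(c(1, 1, 1), c(1, 2, 4)),
               c(0.625, 0.75, 1.0))
  # spatially constant loss makes any uniform mask a fixed point
  w <- array(1 / 27, c(3, 3, 3))
  l <- array(5, c(3, 3, 3))
  m2 <- updateSampleMask(SampleMask(w), LossMap(l))
  expect_equal(maskWeights(m2), w)
})

test_that("the vectorised update equals a per-voxel oracle and is monotone", {
  set.seed(5)
  for (rep in 1:20) {
    w <- array(runif(8 * 8 * 8), c(8, 8, 8))
    l <- array(runif(8 * 8 * 8), c(8, 8, 8))
    got <- petseg:::adaptWeights(w, l)
    oracle <- array(0, dim(w))
    mw <- max(w); ml <- max(l)
    for (i in seq_along(w))
      oracle[i] <- 0.5 * w[i] + 0.5 * (mw / ml) * l[i]
    expect_equal(got, oracle, tolerance = 1e-12)
  }
  # order preservation: equal old weights, larger loss -> larger new weight
  w <- array(0.3, c(4, 1, 1))
  l <- array(c(0.1, 0.4, 0.2, 0.9), c(4, 1, 1))
  out <- petseg:::adaptWeights(w, l)
  expect_equal(order(out), order(c(l)))
  # covariance under uniform rescaling of w
  out10 <- petseg:::adaptWeights(10 * w, l)
  expect_equal(out10 / sum(out10), out / sum(out), tolerance = 1e-12)
})

test_that("update handles degenerate losses and misaligned grids", {
  m <- SampleMask(array(runif(27), c(3, 3, 3)))
  expect_identical(updateSampleMask(m, LossMap(array(0, c(3, 3, 3)))), m)
  expect_error(updateSampleMask(m, LossMap(array(1, c(2, 2, 2)))),
               "alignment")
})

test_that("mask refresh selects the configured fraction deterministically", {
  masks <- lapply(1:10, function(i)
    SampleMask(array(runif(27), c(3, 3, 3)), paste0("s", i)))
  lossFun <- function(i) LossMap(array(runif(27), c(3, 3, 3)))
  r0 <- refreshMasks(masks, lossFun, fraction = 0, seed = 1)
  expect_identical(r0$masks, masks)
  r1 <- refreshMasks(masks, lossFun, fraction = 1, seed = 1)
  expect_length(r1$selected, 10)
  rh <- refreshMasks(masks, lossFun, fraction = 0.5, seed = 4)
  expect_length(rh$selected, 5)
  expect_identical(rh$selected,
                   refreshMasks(masks, lossFun, 0.5, seed = 4)$selected)
  expect_error(refreshMasks(list(), lossFun), "empty")
})

test_that("sample masks persist to NIfTI and back", {
  m <- SampleMask(array(runif(27), c(3, 3, 3)), "s1")
  f <- withr::local_tempfile(fileext = ".nii.gz")
  writeSampleMask(m, f)
  back <- readSampleMask(f, "s1")
  expect_equal(maskWeights(back), maskWeights(m), tolerance = 1e-6)
})
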