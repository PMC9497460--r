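test_that("CT clamp-normalise maps the HU window onto [0,1]", {
  v <- Volume(array(c(1000, -800, 0, 800, -1000, NA), c(6, 1, 1)))
  out <- volData(clampNormaliseCt(v))
  expect_equal(out[, 1, 1], c(1, 0, 0.5, 1, 0, 0))
  # idempotent: re-normalising an already-normalised volume with a [0,1]
  # window changes nothing
  again <- clampNormaliseCt(clampNormaliseCt(v),
                            PreprocessConfig(ctClamp = c(0, 1)))
  expect_equal(volData(again), out)
})

test_that("PET clamp-normalise divides by the SUV ceiling", {
  v <- Volume(array(c(30, 0, 5, 25, -2), c(5, 1, 1)))
  out <- volData(clampNormalisePet(v))
  expect_equal(out[, 1, 1], c(1, 0, 0.2, 1, 0))
})

test_that("clamp-normalise operators are monotone", {
  x <- sort(runif(50, -1200, 1200))
  outCt <- volData(clampNormaliseCt(Volume(array(x, c(50, 1, 1)))))
  expect_true(all(diff(outCt[, 1, 1]) >= 0))
  outPet <- volData(clampNormalisePet(Volume(array(sort(runif(50, -1, 40)),
                                                   c(50, 1, 1)))))
  expect_true(all(diff(outPet[, 1, 1]) >= 0))
})

test_that("resampling at the target spacing is the identity", {
  s <- tinyStudy(seed = 3)
  r <- resampleStudy(s, PreprocessConfig(targetSpacingMm = c(2, 2, 2)))
  expect_identical(volData(petVol(r)), volData(petVol(s)))
  expect_identical(volData(labelMap(r)), volData(labelMap(s)))
})

test_that("halving the spacing doubles the in-plane grid and keeps codes", {
  spec <- tinySpec(seed = 5)
  spec@voxelSpacingMm <- c(2.74, 2.74, 2.79)
  s <- generateStudy(spec)
  r <- resampleStudy(s, PreprocessConfig())  # target 1.37 x 1.37 x 2.79
  expect_equal(dim(volData(petVol(r)))[1:2], 2 * dim(volData(petVol(s)))[1:2])
  expect_equal(dim(volData(petVol(r)))[3], dim(volData(petVol(s)))[3])
  expect_true(all(unique(c(volData(labelMap(r)))) %in%
                    unique(c(volData(labelMap(s))))))
})

test_that("resampling preserves the volume of a large sphere within 5%", {
  d <- c(40, 40, 40)
  ctr <- c(20, 20, 20)
  ix <- seq_len(d[1])
  dist2 <- outer(outer((ix - ctr[1])^2, (ix - ctr[2])^2, `+`),
                 (ix - ctr[3])^2, `+`)
  sphere <- array(as.double(dist2 <= 6^2), d)  # radius 6 voxels
  lmap <- LabelMap(sphere, spacing = c(2, 2, 2))
  pet <- Volume(sphere + 1, c(2, 2, 2))
  study <- PetCtStudy(pet, Volume(sphere, c(2, 2, 2)),
                      array(0, c(d, 1)), labels = lmap)
  r <- resampleStudy(study, PreprocessConfig(targetSpacingMm = c(1.37, 1.37,
                                                                 2.79)))
  volIn <- sum(sphere) * prod(c(2, 2, 2))
  volOut <- sum(volData(labelMap(r))) * prod(c(1.37, 1.37, 2.79))
  expect_lt(abs(volOut - volIn) / volIn, 0.05)
})

test_that("study NIfTI round-trips are lossless for codes and shapes", {
  s <- generateStudy(tinySpec(seed = 8))
  dir <- withr::local_tempdir()
  writeStudy(s, dir)
  back <- readStudy(dir)
  expect_identical(volData(labelMap(back)), volData(labelMap(s)))
  expect_identical(organMask(back), organMask(s))
  expect_equal(volData(petVol(back)), volData(petVol(s)), tolerance = 1e-6)
  expect_equal(volSpacing(petVol(back)), volSpacing(petVol(s)))

  f <- file.path(dir, "lab.nii.gz")
  writeLabelMap(labelMap(s), f)
  expect_identical(volData(readLabelMap(f)), volData(labelMap(s)))
})

test_that("misaligned or incomplete study directories are rejected", {
  s <- generateStudy(tinySpec(seed = 8))
  dir <- withr::local_tempdir()
  writeStudy(s, dir)
  file.remove(file.path(dir, "organs.nii.gz"))
  expect_error(readStudy(dir), "organs.nii.gz")
  # mismatched grids
  dir2 <- withr::local_tempdir()
  writeStudy(s, dir2)
  small <- Volume(volData(petVol(s))[1:10, 1:10, 1:10], c(2, 2, 2))
  im <- RNifti::asNifti(volData(small))
  RNifti::writeNifti(im, file.path(dir2, "ct.nii.gz"))
  expect_error(readStudy(dir2), "alignment error")
})

test_that("input channel stacking fixes order and validates its domain", {
  s <- tinyStudy(seed = 6)
  x <- stackInputChannels(s)
  expect_equal(dim(x)[4], 2 + dim(organMask(s))[4])
  expect_identical(x[, , , 1], volData(ctVol(s)))
  expect_identical(x[, , , 2], volData(petVol(s)))
  # an all-zero organ mask is legal
  s0 <- s
  s0@organs <- array(0, dim(organMask(s)))
  expect_silent(stackInputChannels(s0))
  # out-of-range CT is a validation error
  bad <- s
  bad@ct@data[1, 1, 1] <- 1.2
  expect_error(stackInputChannels(bad), "preprocessed")
})
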