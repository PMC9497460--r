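test_that("a spec without lesions yields an all-background label map", {
  s <- generateStudy(tinySpec(seed = 4, lesionsPerClass = c(0, 0, 0)))
  expect_true(all(volData(labelMap(s)) == 0))
  expect_equal(sort(unique(c(organMask(s)))), c(0, 1))
})

test_that("connected-component counts per class equal the requested counts", {
  spec <- PhantomSpec(gridShape = c(40, 40, 40), voxelSpacingMm = c(2, 2, 2),
                      lesionsPerClass = c(1, 3, 2),
                      lesionRadiusRangeMm = c(4.5, 6),
                      nUnspecificBoneFoci = 0, seed = 7)
  s <- generateStudy(spec)
  set <- extractLesions(labelMap(s), petVol(s))
  counts <- tabulate(vapply(lesions(set), function(l) l@classCode,
                            integer(1)), 3)
  expect_equal(counts, c(1, 3, 2))
  # cross-check one class against the independent BFS component oracle
  boneOracle <- ccOracle(array(as.integer(volData(labelMap(s)) == 3),
                               dim(volData(labelMap(s)))))
  expect_equal(max(boneOracle), 2)
})

test_that("generation is voxel-identical under a repeated seed", {
  a <- generateStudy(tinySpec(seed = 9))
  b <- generateStudy(tinySpec(seed = 9))
  expect_identical(volData(petVol(a)), volData(petVol(b)))
  expect_identical(volData(ctVol(a)), volData(ctVol(b)))
  expect_identical(volData(labelMap(a)), volData(labelMap(b)))
  c <- generateStudy(tinySpec(seed = 10))
  expect_false(identical(volData(petVol(a)), volData(petVol(c))))
})

test_that("lesion voxels exceed background mean + 1 sd and bone stays in the skeleton", {
  spec <- tinySpec(seed = 12, nUnspecificBoneFoci = 2)
  s <- generateStudy(spec)
  lab <- volData(labelMap(s))
  pet <- volData(petVol(s))
  expect_gt(min(pet[lab > 0]),
            spec@backgroundSuvMean + spec@backgroundSuvSd)
  skeleton <- organMask(s)[, , , 3]
  expect_true(all(skeleton[lab == 3] == 1))
  expect_true(all(lab %in% 0:3))
})

test_that("cohort split sizes follow largest-remainder apportionment", {
  expect_equal(unname(petseg:::splitSizes(660)), c(420L, 120L, 120L))
  expect_equal(unname(petseg:::splitSizes(10, c(7, 1.5, 1.5) / 10)),
               c(7L, 2L, 1L))
  expect_equal(sum(petseg:::splitSizes(121)), 121L)
  co1 <- generateCohort(4, tinySpec(seed = 2), proportions = c(2, 1, 1) / 4)
  co2 <- generateCohort(4, tinySpec(seed = 2), proportions = c(2, 1, 1) / 4)
  expect_identical(co1$split, co2$split)
  expect_identical(volData(petVol(co1$studies[[3]])),
                   volData(petVol(co2$studies[[3]])))
  expect_error(generateCohort(0, tinySpec()), "n must be")
})

test_that("perturbReading honours its identity and total-drop limits", {
  s <- generateStudy(tinySpec(seed = 21))
  truth <- labelMap(s)
  ident <- perturbReading(truth, ReaderPerturbation(0, 0, 0, seed = 1))
  expect_identical(volData(ident), volData(truth))
  gone <- perturbReading(truth, ReaderPerturbation(1, 0, 0, seed = 1))
  expect_true(all(volData(gone) == 0))
})

test_that("boundary jitter never erodes a lesion to extinction", {
  s <- generateStudy(tinySpec(seed = 30))
  truth <- labelMap(s)
  nTruth <- max(ccOracle(array(as.integer(volData(truth) > 0),
                               dim(volData(truth)))))
  for (seed in 1:5) {
    pert <- perturbReading(truth, ReaderPerturbation(0, 0, 2, seed = seed))
    for (cls in 1:3) {
      if (!any(volData(truth) == cls)) next
      expect_true(any(volData(pert) == cls),
                  info = sprintf("class %d seed %d", cls, seed))
    }
  }
})

test_that("spurious additions appear with the configured expectation", {
  s <- generateStudy(tinySpec(seed = 33, lesionsPerClass = c(0, 0, 0)))
  truth <- labelMap(s)
  nSpur <- vapply(1:20, function(seed) {
    p <- perturbReading(truth, ReaderPerturbation(0, 3, 0, seed = seed))
    max(ccOracle(array(as.integer(volData(p) > 0), dim(volData(p)))))
  }, numeric(1))
  expect_gt(mean(nSpur), 1)  # Poisson(3) mean over 20 draws is far above 1
  expect_true(all(volData(perturbReading(truth,
    ReaderPerturbation(0, 0, 0, seed = 1))) == 0))
})

test_that("invalid phantom specs are rejected", {
  expect_error(PhantomSpec(lesionSuvRange = c(0.5, 2)), "exceed")
  expect_error(PhantomSpec(lesionsPerClass = c(-1, 0, 0)), "non-negative")
  expect_error(ReaderPerturbation(pDropLesion = 1.5), "0,1")
})
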