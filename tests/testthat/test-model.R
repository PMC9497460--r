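test_that("the classifier is a dense, normalised, reproducible map", {
  m <- tinyModel(seed = 3, nIn = 3)
  x <- array(runif(8 * 8 * 4 * 3), c(8, 8, 4, 3))
  pr <- predictPatch(m, x)
  expect_equal(dim(pr), c(8, 8, 4, 4))
  sums <- apply(pr, 1:3, sum)
  expect_true(all(abs(sums - 1) < 1e-6))
  m2 <- tinyModel(seed = 3, nIn = 3)
  expect_identical(m@params, m2@params)
  m3 <- tinyModel(seed = 4, nIn = 3)
  expect_false(identical(m@params, m3@params))
  # patch size must divide by 2^depth
  expect_error(predictPatch(m, array(0, c(6, 8, 4, 3))),
               "configuration error")
})

test_that("foreground voxels carry exactly 2.5x the background loss", {
  probs <- matrix(0.5, 2, 4)
  target <- array(c(0, 3), c(2, 1, 1))  # background and bone, same p_true
  per <- weightedCce(probs, target, fgWeight = 2.5)$perVoxel
  expect_equal(per[2, 1, 1] / per[1, 1, 1], 2.5)
})

test_that("weighted cross-entropy matches hand arithmetic and its oracle", {
  # perfect prediction: zero loss
  pPerfect <- matrix(c(1, 0, 0, 0), 1, 4)
  expect_equal(weightedCce(pPerfect, array(0, c(1, 1, 1)))$loss, 0)

  # bg voxel p_true 0.5, node voxel p_true 0.25 -> (ln2 + 2.5 ln4)/2
  probs <- rbind(c(0.5, 0.2, 0.2, 0.1), c(0.25, 0.25, 0.25, 0.25))
  target <- array(c(0, 2), c(2, 1, 1))
  expect_equal(weightedCce(probs, target, 2.5)$loss,
               (log(2) + 2.5 * log(4)) / 2)

  # fgWeight = 1 reduces to plain categorical cross-entropy
  set.seed(8)
  pm <- matrix(runif(40 * 4), 40, 4)
  pm <- pm / rowSums(pm)
  tg <- array(sample(0:3, 40, TRUE), c(40, 1, 1))
  plain <- -mean(log(pm[cbind(1:40, c(tg) + 1)]))
  expect_equal(weightedCce(pm, tg, fgWeight = 1)$loss, plain,
               tolerance = 1e-10)

  # zero probability at the true class is clamped and logged
  pz <- matrix(c(0, 1, 0, 0), 1, 4)
  expect_message(res <- weightedCce(pz, array(0, c(1, 1, 1))), "clamped")
  expect_true(is.finite(res$loss))
})

test_that("backpropagation matches finite differences", {
  cfg <- ModelConfig(nInputChannels = 2, encoderDepth = 2, baseFilters = 2,
                     dropoutRate = 0, l2Weight = 0)
  m <- buildModel(cfg, seed = 5)
  set.seed(6)
  x <- array(runif(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  tg <- array(sample(0:3, 8 * 8 * 4, TRUE), c(8, 8, 4))
  fw <- petseg:::forwardPass(m, x, keepCache = TRUE)
  g <- petseg:::backwardPass(m, fw,
                             petseg:::cceGrad(fw$probs, tg, 2.5))
  eps <- 1e-6
  for (nm in c("Wenc1", "Wbott", "Wdec1", "Wout", "bdec2", "bout")) {
    i <- which.max(abs(g[[nm]]))  # check the largest-gradient entry
    mp <- m; mp@params[[nm]][i] <- mp@params[[nm]][i] + eps
    lp <- weightedCce(petseg:::forwardPass(mp, x)$probs, tg, 2.5)$loss
    mm <- m; mm@params[[nm]][i] <- mm@params[[nm]][i] - eps
    lm_ <- weightedCce(petseg:::forwardPass(mm, x)$probs, tg, 2.5)$loss
    num <- (lp - lm_) / (2 * eps)
    expect_equal(g[[nm]][i], num, tolerance = 1e-5,
                 info = paste("param", nm))
  }
})

test_that("augmentation with collapsed ranges is the identity", {
  s <- tinyStudy(seed = 17)
  p <- extractPatch(s, c(12, 12, 12), c(8, 8, 8))
  z <- AugmentationSpec(scaleRange = c(0, 0), rotationRangeRad = c(0, 0),
                        petShiftSuv = c(0, 0), ctShiftHu = c(0, 0))
  a <- augmentPatch(p, z, seed = 1)
  expect_equal(a@channels, p@channels)
  expect_identical(a@target, p@target)
})

test_that("intensity shifts convert between raw units and normalised channels", {
  # a +100 HU shift on 0 HU lands at (100+800)/1600 = 0.5625 after
  # normalisation
  expect_equal(volData(clampNormaliseCt(Volume(array(100, c(1, 1, 1)))))[1],
               0.5625)
  # an extreme positive CT shift on a mid-grey patch raises channel 1 by
  # close to 100/1600 (clamped to [0,1])
  s <- tinyStudy(seed = 17)
  p <- extractPatch(s, c(12, 12, 12), c(8, 8, 8))
  sp <- AugmentationSpec(scaleRange = c(0, 0), rotationRangeRad = c(0, 0),
                         petShiftSuv = c(0, 0), ctShiftHu = c(-100, 100))
  a <- augmentPatch(p, sp, seed = 2)
  shift <- a@channels[, , , 1] - p@channels[, , , 1]
  inRange <- abs(p@channels[, , , 1] - 0.5) < 0.4  # away from the clamp
  expect_lt(diff(range(shift[inRange])), 1e-10)    # one global shift
  expect_lte(max(abs(shift)), 100 / 1600 + 1e-12)
})

test_that("augmentation never invents label codes and stays in [0,1]", {
  s <- tinyStudy(seed = 18)
  p <- extractPatch(s, c(12, 12, 12), c(16, 16, 16))
  for (seed in 1:5) {
    a <- augmentPatch(p, AugmentationSpec(), seed = seed)
    expect_true(all(a@target %in% unique(c(p@target))))
    expect_true(all(a@channels >= 0 & a@channels <= 1))
    expect_true(all(a@channels[, , , 3:6] %in% c(0, 1)))
  }
})

test_that("the learning rate halves after the stated patience", {
  st <- list(lr = 0.001, best = NULL, stale = 0L)
  # strictly decreasing validation loss: LR stays constant
  for (v in c(1, 0.9, 0.8, 0.7, 0.6, 0.5, 0.4))
    st <- petseg:::lrScheduleStep(st, v, 5L)
  expect_equal(st$lr, 0.001)
  # constant validation loss for 5 consecutive epochs: LR becomes 0.0005
  st <- list(lr = 0.001, best = NULL, stale = 0L)
  st <- petseg:::lrScheduleStep(st, 1, 5L)
  for (i in 1:5) st <- petseg:::lrScheduleStep(st, 1, 5L)
  expect_equal(st$lr, 0.0005)
})

test_that("Nadam decreases a convex toy objective", {
  params <- list(w = c(5, -3))
  st <- petseg:::nadamInit(params)
  for (i in 1:200) {
    g <- list(w = 2 * params$w)
    out <- petseg:::nadamStep(params, g, st, lr = 0.05)
    params <- out$params; st <- out$state
  }
  expect_lt(sum(params$w^2), 1e-2)
})
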