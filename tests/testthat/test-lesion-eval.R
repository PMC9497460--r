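test_that("lesion extraction follows per-class 26-connectivity", {
  sp <- c(1, 1, 1)
  expect_length(lesions(extractLesions(lm(array(0, c(4, 4, 4))),
                                       Volume(array(1, c(4, 4, 4))))), 0)
  # two same-class voxels sharing only a corner form one lesion
  arr <- array(0, c(4, 4, 4))
  arr[1, 1, 1] <- 2; arr[2, 2, 2] <- 2
  set <- extractLesions(lm(arr), Volume(array(1, c(4, 4, 4))))
  expect_length(lesions(set), 1)
  # a node lesion touching a bone lesion stays two lesions
  arr2 <- array(0, c(4, 4, 4))
  arr2[1:2, 1, 1] <- 2; arr2[3:4, 1, 1] <- 3
  set2 <- extractLesions(lm(arr2), Volume(array(1, c(4, 4, 4))))
  expect_length(lesions(set2), 2)
  expect_setequal(vapply(lesions(set2), function(l) l@classCode, integer(1)),
                  c(2L, 3L))
  # annotations: volume and SUV mean
  pet <- Volume(array(seq_len(64) / 10, c(4, 4, 4)))
  arr3 <- array(0, c(4, 4, 4)); arr3[1:3, 1, 1] <- 1
  l3 <- lesions(extractLesions(lm(arr3, c(2, 2, 2)), pet))[[1]]
  expect_equal(l3@volumeMl, 3 * 8 / 1000)
  expect_equal(l3@suvMean, mean(c(0.1, 0.2, 0.3)))
  expect_error(extractLesions(lm(array(0, c(3, 3, 3))),
                              Volume(array(0, c(4, 4, 4)))), "alignment")
})

test_that("matching handles identical, disjoint and shared-overlap readings", {
  pet <- Volume(array(1, c(5, 5, 1)))
  mk <- function(arr) extractLesions(lm(arr), pet)
  a <- array(0, c(5, 5, 1)); a[2:3, 2, 1] <- 1
  same <- matchLesions(mk(a), mk(a), 1)
  expect_equal(sensitivity(same), 1); expect_equal(ppv(same), 1)
  expect_equal(same@fp, 0L); expect_equal(same@fn, 0L)

  b <- array(0, c(5, 5, 1)); b[5, 5, 1] <- 1
  disj <- matchLesions(mk(a), mk(b), 1)
  expect_equal(sensitivity(disj), 0); expect_equal(ppv(disj), 0)

  # one candidate spanning two reference lesions, plus one unmatched
  # candidate: detected refs = 2, TP = 1, FP = 1, FN = 0
  cand <- array(0, c(5, 5, 1)); cand[1:4, 1, 1] <- 1; cand[1, 5, 1] <- 1
  ref <- array(0, c(5, 5, 1)); ref[1, 1, 1] <- 1; ref[4, 1, 1] <- 1
  res <- matchLesions(mk(cand), mk(ref), 1)
  expect_equal(res@detectedRefs, 2L)
  expect_equal(res@tp, 1L); expect_equal(res@fp, 1L); expect_equal(res@fn, 0L)
  expect_equal(sensitivity(res), 1)
  expect_equal(ppv(res), 0.5)
  # cross-class overlap never matches
  cls2 <- array(0, c(5, 5, 1)); cls2[1, 1, 1] <- 2
  expect_equal(matchLesions(mk(cls2), mk(ref), 2)@tp, 0L)
})

test_that("matching equals the brute-force overlap oracle with FP/FN duality", {
  pet <- Volume(array(1, c(8, 8, 8)))
  set.seed(77)
  for (i in 1:60) {
    ca <- randomLabelArr(); ra <- randomLabelArr()
    cs <- extractLesions(lm(ca), pet, "X"); rs <- extractLesions(lm(ra), pet, "Y")
    for (cls in 1:3) {
      got <- matchLesions(cs, rs, cls)
      want <- matchOracle(ca, ra, cls)
      expect_equal(got@tp, want$tp); expect_equal(got@fp, want$fp)
      expect_equal(got@fn, want$fn)
      expect_equal(got@detectedRefs, want$det)
      rev <- matchLesions(rs, cs, cls)
      expect_equal(got@fp, rev@fn)  # duality
      expect_equal(rev@fp, got@fn)
    }
  }
})

test_that("matching is invariant to lesion enumeration order", {
  pet <- Volume(array(1, c(6, 6, 6)))
  set.seed(3)
  ca <- randomLabelArr(c(6, 6, 6), 0.1); ra <- randomLabelArr(c(6, 6, 6), 0.1)
  cs <- extractLesions(lm(ca), pet)
  rs <- extractLesions(lm(ra), pet)
  csRev <- cs; csRev@lesions <- rev(cs@lesions)
  for (cls in 1:3) {
    a <- matchLesions(cs, rs, cls); b <- matchLesions(csRev, rs, cls)
    expect_equal(a@tp, b@tp); expect_equal(a@fp, b@fp)
    expect_equal(a@sensitivity, b@sensitivity)
  }
})

test_that("the pairwise report pools studies and averages across references", {
  pet <- Volume(array(1, c(6, 6, 6)))
  set.seed(9)
  arrs <- replicate(4, randomLabelArr(c(6, 6, 6), 0.12), simplify = FALSE)
  mkSets <- function(id, arrs) lapply(arrs, function(a)
    extractLesions(lm(a), pet, id))
  # two identical sources agree perfectly in every cell
  sets <- list(A = mkSets("A", arrs), B = mkSets("B", arrs))
  rep1 <- pairwiseReport(sets, 2)
  pairRows <- rep1[rep1$row_type == "pair", ]
  expect_true(all(pairRows$sensitivity_pct == 100))
  expect_true(all(pairRows$ppv_pct == 100))
  expect_true(all(pairRows$fp_total == 0) && all(pairRows$fn_total == 0))
  # FP total of X-vs-Y equals FN total of Y-vs-X for independent sources
  arrs2 <- replicate(4, randomLabelArr(c(6, 6, 6), 0.12), simplify = FALSE)
  sets2 <- list(X = mkSets("X", arrs), Y = mkSets("Y", arrs2))
  rep2 <- pairwiseReport(sets2, 3)
  xy <- rep2[rep2$row_type == "pair" & rep2$candidate == "X", ]
  yx <- rep2[rep2$row_type == "pair" & rep2$candidate == "Y", ]
  expect_equal(xy$fp_total, yx$fn_total)
  expect_equal(yx$fp_total, xy$fn_total)
  # summary rows carry means and ranges
  sm <- rep2[rep2$row_type == "summary" & rep2$candidate == "X", ]
  expect_equal(sm$sensitivity_pct, xy$sensitivity_pct)
  expect_error(pairwiseReport(list(A = mkSets("A", arrs)), 1), "two sources")
})

test_that("Spearman burden correlation matches rank arithmetic", {
  a <- c(3, 7, 11, 20, 40)
  expect_equal(spearmanBurden(a, a)$rho, 1)
  expect_equal(spearmanBurden(a, rev(a))$rho, -1)
  # hand computation: d = (-1, 1, -1, 1, 0), sum d^2 = 4,
  # rho = 1 - 6*4 / (5 * 24) = 0.8
  r <- spearmanBurden(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 0.8)
  expect_true(r$p_value > 0 && r$p_value < 1)
  expect_error(spearmanBurden(1:2, 2:3), "at least 3")
  expect_error(spearmanBurden(1:3, 1:4), "paired")
  expect_warning(z <- spearmanBurden(c(1, 1, 1), c(1, 2, 3)), "variance")
  expect_true(is.na(z$rho))
})
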