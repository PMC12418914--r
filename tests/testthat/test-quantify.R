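test_that("double-angle method inverts the flip-angle ratio", {
  one <- function(x) array(x, c(1, 1, 1))
  expect_equal(doubleAngleB1(one(1), one(1))$flipDeg[1], 60)
  expect_equal(doubleAngleB1(one(1), one(2 * cos(pi / 4)))$flipDeg[1], 45)
  # out-of-range ratio and zero signal are invalid, not errors
  bad <- doubleAngleB1(one(0), one(1))
  expect_false(bad$valid[1])
  expect_true(is.na(bad$flipDeg[1]))
  expect_false(doubleAngleB1(one(1), one(2.5))$valid[1])
})

test_that("a simulated 43-degree flip field is recovered to within a degree", {
  # forward double-angle signal model S_a = sin(a), S_2a = sin(2a)
  true <- array(runif(200, 40, 46), c(10, 10, 2))
  a <- sin(true * pi / 180)
  a2 <- sin(2 * true * pi / 180)
  est <- doubleAngleB1(a, a2)
  expect_true(all(est$valid))
  expect_lt(max(abs(est$flipDeg - true)), 1)
  expect_lt(abs(mean(est$flipDeg) - mean(true)), 1)
})

test_that("saturation factor obeys the Ernst steady state", {
  expect_equal(saturationFactor(3350, 335, 90), 1, tolerance = 1e-4)
  expect_equal(saturationFactor(290, 335, 90), 1 - exp(-290 / 335))
  # arg-max over flip angle equals the Ernst angle
  alphas <- seq(1, 179, by = 0.001)
  f <- saturationFactor(290, 70, alphas)
  expect_equal(alphas[which.max(f)], ernstAngle(290, 70), tolerance = 0.01)
  expect_equal(ernstAngle(290, 70), acos(exp(-290 / 70)) * 180 / pi)
  expect_equal(ernstAngle(290, 70), 89.1, tolerance = 0.01)
})

test_that("T2 delay correction is exponential and monotone", {
  expect_equal(t2Correction(0, 36), 1)
  expect_equal(t2Correction(2, 36), exp(-2 / 36))
  expect_equal(t2Correction(2, 36), 0.946, tolerance = 0.001)
  d <- t2Correction(seq(0, 10, by = 1), 36)
  expect_true(all(diff(d) < 0))
  expect_error(t2Correction(2, -1), "positive")
})

test_that("concentration estimation applies reference, labels and corrections", {
  relax <- relaxationAssumptions()
  acq <- acqParams()
  hdo <- naturalAbundanceHdo(relax)
  expect_equal(estimateConcentration(0, 5, relax, acq), 0)
  # identical relaxation factors, 2 vs 1 labels -> C_HDO / 2
  relEq <- relaxationAssumptions(t1Glc = 335, t2Glc = 36)
  expect_equal(estimateConcentration(5, 5, relEq, acq), hdo / 2)
  # receiver-scale invariance
  c1 <- estimateConcentration(3, 7, relax, acq)
  c2 <- estimateConcentration(3 * 1234, 7 * 1234, relax, acq)
  expect_equal(c1, c2)
  # correction switches isolate each factor
  cSat <- estimateConcentration(1, 1, relax, acq, correctT2 = FALSE)
  expect_equal(cSat, saturationFactor(290, 335, 90) /
                 saturationFactor(290, 70, 90) / 2 * hdo)
  cT2 <- estimateConcentration(1, 1, relax, acq, correctSaturation = FALSE)
  expect_equal(cT2, 1 / 2 * hdo)  # T2 water = T2 glc -> factor 1
  # non-positive reference flagged as NA
  expect_true(is.na(estimateConcentration(1, 0, relax, acq)))
})

test_that("exclusion filters use strict thresholds and exact counts", {
  set.seed(1)
  dims <- c(14, 14, 8)
  mask <- array(FALSE, dims)
  mask[2:13, 2:13, 2:7] <- TRUE     # 864 voxels, trimmed to 857 below
  idx <- which(mask)
  mask[idx[seq.int(858, length(idx))]] <- FALSE
  expect_equal(sum(mask), 857)
  vals <- array(2, dims)
  hot <- sample(which(mask), 20)
  vals[hot] <- 6                    # 20 of 857 voxels above 5 mM
  cm <- concentrationMap(vals, mask)
  crlb <- array(10, dims)
  ex <- applyExclusions(cm, crlb)
  expect_equal(ex$counts$concExcluded, 20)
  expect_equal(ex$counts$crlbExcluded, 0)
  expect_equal(round(100 * ex$counts$concExcluded / ex$counts$maskVoxels), 2)
  expect_equal(ex$counts$survivingPercent, 100 * (857 - 20) / 857)
  # ties at exactly CRLB 50 are retained
  crlb50 <- array(50, dims)
  ex50 <- applyExclusions(cm, crlb50, crlbMax = 50)
  expect_equal(ex50$counts$crlbExcluded, 0)
  crlb51 <- array(50 + 1e-9, dims)
  expect_equal(applyExclusions(cm, crlb51)$counts$crlbExcluded, sum(mask))
  # empty mask: zero counts, no error
  cmEmpty <- concentrationMap(vals, array(FALSE, dims))
  exE <- applyExclusions(cmEmpty, crlb)
  expect_equal(exE$counts$maskVoxels, 0)
  # exact integer determinism on repeated runs
  ex2 <- applyExclusions(cm, crlb)
  expect_identical(ex$counts, ex2$counts)
})

test_that("mM to mg/dL conversion uses the glucose molar mass", {
  expect_equal(mMToMgPerDl(5), 90.08)
  expect_equal(mMToMgPerDl(0), 0)
  expect_equal(mMToMgPerDl(1, molarMass = 180.16), 18.016)
  expect_error(mMToMgPerDl(-1), "non-negative")
})

test_that("concentration bias stays bounded across tracer levels (full pipeline)", {
  # denoised: median relative error over the 0.5-4 mM ensemble <= 10%
  relerr <- c()
  run2 <- endToEndRun()
  relerr["2"] <- mean(run2$glucoseCourse$value) / 2 - 1
  for (cc in c(0.5, 4)) {
    spec <- defaultPhantomSpec(glcKind = "constant", glcPeak = cc, seed = 11L)
    run <- runDynamicStudy(spec,
                           frameTimesMin = seq(8.5 / 2, by = 8.5, length.out = 4))
    relerr[as.character(cc)] <- mean(run$glucoseCourse$value) / cc - 1
  }
  expect_lte(median(abs(relerr)), 0.10)
  # raw (no denoising): median relative error <= 20%
  relerrRaw <- c()
  for (cc in c(0.5, 2, 4)) {
    spec <- defaultPhantomSpec(glcKind = "constant", glcPeak = cc, seed = 12L)
    run <- runDynamicStudy(spec, frameTimesMin = c(4.25, 12.75),
                           denoise = FALSE)
    relerrRaw[as.character(cc)] <- mean(run$glucoseCourse$value) / cc - 1
  }
  expect_lte(median(abs(relerrRaw)), 0.20)
})
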