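test_that("mask aggregation respects mode and exclusions", {
  m <- array(3, c(4, 4, 2))
  mask <- array(FALSE, c(4, 4, 2)); mask[1:2, 1:2, 1] <- TRUE
  expect_equal(maskAggregate(m, mask, "mean"), 3)
  expect_equal(maskAggregate(m, mask, "sd"), 0)
  expect_equal(maskAggregate(m, mask, "sum"), 12)
  # sum is invariant to voxel-count-preserving mask relabeling
  mask2 <- array(FALSE, c(4, 4, 2)); mask2[3:4, 3:4, 2] <- TRUE
  expect_equal(maskAggregate(m, mask2, "sum"), maskAggregate(m, mask, "sum"))
  # excluded voxels are dropped
  ex <- array(FALSE, c(4, 4, 2)); ex[1, 1, 1] <- TRUE
  expect_equal(maskAggregate(m, mask, "sum", excluded = ex), 9)
  expect_error(maskAggregate(m, array(FALSE, c(4, 4, 2)), "mean"), "empty mask")
})

test_that("kidney signal sums agree across the two spatial resolutions", {
  # same smooth phantom simulated at 1.8 and 0.9 mL protocols: the mask sum
  # of reconstructed (volume-proportional) amplitudes approximates the
  # volume integral, so the two sums agree within 5%
  relax <- relaxationAssumptions()
  sums <- vapply(list(c(22, 22, 21), c(28, 28, 27)), function(mx) {
    acq <- acqParams(matrixSize = mx, nSpectralPoints = 24)
    traj <- makeCrtTrajectory(acq)
    spec <- defaultPhantomSpec(noiseSd = 0)
    lm <- buildLabelMap(spec, acq)
    mask <- compartmentMask(lm, c("kidney_left", "kidney_right"))
    ksp <- simulateFidImage(lm, crtDMI:::referenceSpec(spec), acq, relax, traj)
    img <- adjointNudft(ksp, traj, acq)
    cov <- estimateNoiseCov(crtDMI:::noiseCovOrIdentity(ksp))
    cmb <- combineCoils(img, cov)
    maskAggregate(Mod(imageData(cmb)[, , , 1]), mask, "sum")
  }, numeric(1))
  expect_equal(sums[2] / sums[1], 1, tolerance = 0.05)
})

test_that("fold change and COV follow their definitions", {
  expect_equal(foldChange(c(5, 50)), c(1, 10))
  expect_equal(foldChange(c(4, 2, 8), baselineIndex = 2), c(2, 1, 4))
  expect_error(foldChange(c(0, 1)), "positive")
  expect_equal(covPercent(c(9, 10, 11)), 10)
  expect_equal(covPercent(rep(4, 5)), 0)
  expect_equal(covPercent(3 * c(9, 10, 11)), covPercent(c(9, 10, 11)))
  expect_error(covPercent(5), "at least 2")
  expect_error(covPercent(c(-2, 2)), "mean must be positive")
})

test_that("a programmed saturating uptake round-trips to its plateau fold change", {
  # phantom water programmed with dC/C0 = 1.8 -> plateau fold change 2.8
  relax <- relaxationAssumptions()
  hdo <- naturalAbundanceHdo(relax)
  acq <- smallAcq(matrixSize = c(12, 12, 10), nSpectralPoints = 48,
                  nRings = 8, fov = c(180, 180, 150))
  traj <- makeCrtTrajectory(acq)
  spec <- phantomSpec(list(
    list(name = "body", center = c(0, 0, 0), semiAxes = c(80, 80, 70),
         linewidthHz = 14,
         metabolites = list(
           water = list(kind = "saturating", c0 = hdo, dc = 1.8 * hdo, tau = 12),
           glc = list(kind = "constant", c0 = 0)))
  ), nCoils = 1L, coilCenters = matrix(c(0, 0, 200), 1), coilSigma = 300,
     noiseSd = 0, seed = 3L)
  lm <- buildLabelMap(spec, acq)
  mask <- compartmentMask(lm, "body")
  times <- c(0.01, 120)   # baseline and deep plateau (t = 10 tau)
  vals <- vapply(seq_along(times), function(i) {
    ksp <- simulateFidImage(lm, spec, acq, relax, traj, timeMin = times[i],
                            timeIndex = i)
    img <- adjointNudft(ksp, traj, acq)
    cmb <- combineCoils(img, estimateNoiseCov(crtDMI:::noiseCovOrIdentity(ksp)))
    ft <- fitImage(fidToSpectrum(cmb), basisSet2H(), mask)
    maskAggregate(ft$amplitude[, , , "water"], mask, "sum")
  }, numeric(1))
  expect_equal(foldChange(vals)[2], 2.8, tolerance = 0.1)
})

test_that("Friedman comparison matches the repeated-measures chi-square", {
  # identical conditions: statistic 0, p = 1
  m <- matrix(rep(c(3, 1, 4, 1, 5), 3), ncol = 3)
  f0 <- friedmanCompare(m)
  expect_equal(f0$statistic, 0)
  expect_equal(f0$p.value, 1)
  # permuting block order leaves the statistic unchanged
  set.seed(9)
  g <- matrix(rnorm(60), 20, 3)
  expect_equal(friedmanCompare(g)$statistic,
               friedmanCompare(g[sample(20), ])$statistic)
  # textbook worked example: 3 treatments x 4 blocks with clean ranks
  tb <- rbind(c(1, 2, 3), c(1.5, 2.5, 3.5), c(0.5, 2.2, 3.1), c(1.1, 1.9, 3.4))
  ft <- friedmanCompare(tb)
  # all blocks rank the columns 1 < 2 < 3: chi2 = 12*4*(1+0+1)/(3*4) = 8
  expect_equal(ft$statistic, 8, tolerance = 1e-10)
  expect_equal(ft$df, 2)
  expect_equal(ft$p.value, pchisq(8, 2, lower.tail = FALSE), tolerance = 1e-10)
  # a 3-sigma shifted condition is detected in >= 95% of seeded trials
  hits <- vapply(1:40, function(s) {
    set.seed(s)
    gg <- matrix(rnorm(60), 20, 3)
    gg[, 3] <- gg[, 3] + 3
    friedmanCompare(gg)$p.value < 0.01
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  expect_error(friedmanCompare(cbind(1:3)), "2 conditions")
})

test_that("paired t-test matches the textbook statistic", {
  x <- c(12.1, 11.4, 13.2, 10.9, 12.8)
  y <- c(11.2, 11.0, 12.1, 10.4, 12.2)
  d <- x - y
  pt <- pairedCompare(x, y)
  expect_equal(pt$statistic, mean(d) / (sd(d) / sqrt(5)), tolerance = 1e-10)
  expect_equal(pt$df, 4)
  expect_equal(pt$p.value,
               2 * pt(-abs(pt$statistic), 4), tolerance = 1e-10)
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(bhAdjust(0.03), 0.03)
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  # hand-worked step-up: p * n / i with monotonicity from the largest down
  p <- c(0.005, 0.04, 0.03, 0.8)
  expect_equal(bhAdjust(p), c(0.02, 0.0533333333, 0.0533333333, 0.8),
               tolerance = 1e-9)
  sorted <- sort(runif(20))
  expect_true(!is.unsorted(bhAdjust(sorted)))
  expect_true(all(bhAdjust(sorted) <= 1))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("time courses assemble aggregates with fold changes", {
  maps <- list(array(2, c(2, 2, 2)), array(6, c(2, 2, 2)))
  mask <- array(TRUE, c(2, 2, 2))
  tc <- timeCourse(maps, c(5, 10), mask)
  expect_equal(tc$value, c(2, 6))
  expect_equal(tc$foldChange, c(1, 3))
  expect_error(timeCourse(maps, c(10, 5), mask), "increasing")
  expect_error(timeCourse(maps, c(1, 2, 3), mask), "one map per time point")
})
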