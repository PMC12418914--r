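test_that("label maps voxelize compartments deterministically", {
  acq <- acqParams()
  spec <- defaultPhantomSpec()
  lm <- buildLabelMap(spec, acq)
  # two kidneys present as disjoint non-background regions
  expect_setequal(unique(as.vector(labelArray(lm))), 0:3)
  expect_gt(sum(labelArray(lm) == 2), 0)
  expect_gt(sum(labelArray(lm) == 3), 0)
  # kidneys are disjoint in x by construction
  left <- which(labelArray(lm) == 2, arr.ind = TRUE)
  right <- which(labelArray(lm) == 3, arr.ind = TRUE)
  expect_lt(max(left[, 1]), min(right[, 1]))
  # empty compartment list -> all background
  empty <- phantomSpec(list(), noiseSd = 0)
  expect_true(all(labelArray(buildLabelMap(empty, acq)) == 0))
  # fully outside geometry errors, naming the compartment
  bad <- phantomSpec(list(
    list(name = "lost", center = c(500, 0, 0), semiAxes = c(5, 5, 5),
         metabolites = list())
  ), noiseSd = 0)
  expect_error(buildLabelMap(bad, acq), "lost")
})

test_that("voxelized ellipsoid volume matches the analytic volume within 5%", {
  acq <- acqParams(fov = c(120, 120, 120), matrixSize = c(40, 40, 40),
                   nRings = 20)  # 3 mm grid
  spec <- phantomSpec(list(
    list(name = "ell", center = c(0, 0, 0), semiAxes = c(30, 15, 15),
         metabolites = list())
  ), noiseSd = 0)
  lm <- buildLabelMap(spec, acq)
  analytic <- 4 / 3 * pi * 30 * 15 * 15 / 27
  expect_equal(sum(labelArray(lm) > 0), analytic, tolerance = 0.05)
})

test_that("uptake curves satisfy their closed forms", {
  expect_equal(uptakeCurve("saturating", list(c0 = 2, dc = 8, tau = 5), 0), 2)
  expect_equal(uptakeCurve("saturating", list(c0 = 2, dc = 8, tau = 5), 50),
               10, tolerance = 0.01)  # t = 10 tau -> within 1% of plateau
  expect_equal(uptakeCurve("constant", list(c0 = 3), c(0, 10)), c(3, 3))
  # gamma-variate peaks at tp with value c0 + a (numeric argmax oracle)
  tt <- seq(0, 120, by = 0.01)
  cv <- uptakeCurve("gamma_variate", list(c0 = 1, a = 2, tp = 37, alpha = 2), tt)
  expect_equal(tt[which.max(cv)], 37, tolerance = 0.02)
  expect_equal(max(cv), 3, tolerance = 1e-6)
  expect_error(uptakeCurve("bogus", list(c0 = 1), 0), "unknown")
  expect_error(uptakeCurve("saturating", list(c0 = -1, dc = 1, tau = 1), 0),
               "non-negative")
  expect_error(uptakeCurve("constant", list(c0 = 1), c(3, 2)), "increasing")
})

test_that("simulated k-space is linear in concentration and seed-reproducible", {
  acq <- smallAcq()
  traj <- makeCrtTrajectory(acq)
  relax <- relaxationAssumptions()
  spec <- blobSpec(water = 8, glc = 1.5)
  lm <- buildLabelMap(spec, acq)
  k1 <- simulateFidImage(lm, spec, acq, relax, traj)
  spec2 <- spec
  spec2@compartments[[1]]$metabolites$water$c0 <- 16
  spec2@compartments[[1]]$metabolites$glc$c0 <- 3
  k2 <- simulateFidImage(lm, spec2, acq, relax, traj)
  expect_equal(k2@data, 2 * k1@data, tolerance = 1e-14)

  specN <- blobSpec(water = 8, noiseSd = 0.5, nCoils = 2L)
  lmN <- buildLabelMap(specN, acq)
  ka <- simulateFidImage(lmN, specN, acq, relax, traj, timeIndex = 3L)
  kb <- simulateFidImage(lmN, specN, acq, relax, traj, timeIndex = 3L)
  expect_identical(ka@data, kb@data)
  kc <- simulateFidImage(lmN, specN, acq, relax, traj, timeIndex = 4L)
  expect_false(identical(ka@data, kc@data))
})

test_that("zero-concentration phantom yields pure noise at the stated SD", {
  acq <- smallAcq(nSpectralPoints = 16)
  traj <- makeCrtTrajectory(acq)
  relax <- relaxationAssumptions()
  spec <- blobSpec(water = 0, glc = 0, noiseSd = 0.7, nCoils = 2L)
  lm <- buildLabelMap(spec, acq)
  ksp <- simulateFidImage(lm, spec, acq, relax, traj)
  samp <- c(Re(ksp@data[, , , 1]), Im(ksp@data[, , , 1]))
  expect_gt(length(samp), 1e4)
  expect_equal(sd(samp), 0.7, tolerance = 0.05)
  # inter-channel correlation close to the requested value
  x <- Re(ksp@data[, , , 1]); y <- Re(ksp@data[, , , 2])
  expect_equal(cor(as.vector(x), as.vector(y)), 0.2, tolerance = 0.05)
})

test_that("a point source has constant k-space modulus at fixed FID time", {
  acq <- smallAcq()
  traj <- makeCrtTrajectory(acq)
  relax <- relaxationAssumptions()
  spec <- phantomSpec(list(
    list(name = "pt", center = c(10, -10, 10), semiAxes = c(4, 4, 4),
         linewidthHz = 1e-9,
         metabolites = list(water = list(kind = "constant", c0 = 10),
                            glc = list(kind = "constant", c0 = 0)))
  ), nCoils = 1L, coilCenters = matrix(0, 1, 3), coilSigma = 1e6,
     noiseSd = 0, seed = 1L)
  lm <- buildLabelMap(spec, acq)
  ksp <- simulateFidImage(lm, spec, acq, relax, traj)
  for (t in c(1, 16, 32)) {
    m <- Mod(ksp@data[, , t, 1])
    expect_lt(max(m) / min(m) - 1, 1e-10)
  }
})

test_that("the two simulated resonances are separated by gamma*B0*0.9 Hz", {
  acq <- smallAcq(nSpectralPoints = 64)
  traj <- makeCrtTrajectory(acq)
  relax <- relaxationAssumptions()
  specW <- blobSpec(water = 10, glc = 0)
  specG <- blobSpec(water = 0, glc = 10)
  lm <- buildLabelMap(specW, acq)
  fW <- fidToSpectrum(adjointNudft(simulateFidImage(lm, specW, acq, relax, traj),
                                   traj, acq), zerofillFactor = 8)
  fG <- fidToSpectrum(adjointNudft(simulateFidImage(lm, specG, acq, relax, traj),
                                   traj, acq), zerofillFactor = 8)
  vW <- Mod(imageData(fW)[6, 6, 4, , 1])
  vG <- Mod(imageData(fG)[6, 6, 4, , 1])
  sep <- freqAxis(fW)[which.max(vW)] - freqAxis(fG)[which.max(vG)]
  expect_equal(sep, 0.9 * 6.536 * 7, tolerance = 0.03)
  # and the glucose peak sits at 3.9 ppm on the ppm axis
  expect_equal(ppmAxis(fG)[which.max(vG)], 3.9, tolerance = 0.01)
})
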