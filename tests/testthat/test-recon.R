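test_that("adjoint NUDFT on the degenerate Cartesian trajectory matches the FFT inverse", {
  acq <- smallAcq(matrixSize = c(8, 8, 4), nSpectralPoints = 16, nRings = 4,
                  fov = c(80, 80, 40))
  traj <- makeCrtTrajectory(acq, degenerateCartesian = TRUE)
  set.seed(42)
  dims <- c(8L, 8L, 4L)
  nT <- 16
  kdata <- array(complex(real = rnorm(64 * 4 * nT), imaginary = rnorm(64 * 4 * nT)),
                 dim = c(64, 4, nT, 1))
  ksp <- new("KSpaceData", data = kdata, noise = matrix(0 + 0i, 1, 1),
             acq = acq, meta = list())
  img <- adjointNudft(ksp, traj, acq)
  for (t in c(1, 7, 16)) {
    # in-plane samples are already the Cartesian grid (kx fastest); kz is
    # the third dimension
    kcube <- array(kdata[, , t, 1], dim = dims)
    oracle <- ifftOracle3d(kcube, dims)
    err <- max(Mod(imageData(img)[, , , t, 1] - oracle)) / max(Mod(oracle))
    expect_lt(err, 1e-10)
  }
})

test_that("adjoint NUDFT is linear and maps zero to zero", {
  acq <- smallAcq(matrixSize = c(6, 6, 4), nSpectralPoints = 4, nRings = 3,
                  fov = c(60, 60, 40))
  traj <- makeCrtTrajectory(acq)
  n <- sampleCount(traj)
  mk <- function(seed) {
    set.seed(seed)
    array(complex(real = rnorm(n * 4 * 4), imaginary = rnorm(n * 4 * 4)),
          dim = c(n, 4, 4, 1))
  }
  z <- new("KSpaceData", data = array(0 + 0i, c(n, 4, 4, 1)),
           noise = matrix(0 + 0i, 1, 1), acq = acq, meta = list())
  expect_true(all(imageData(adjointNudft(z, traj, acq)) == 0))
  a <- mk(1); b <- mk(2)
  ra <- adjointNudft(new("KSpaceData", data = a, noise = z@noise, acq = acq,
                         meta = list()), traj, acq)
  rb <- adjointNudft(new("KSpaceData", data = b, noise = z@noise, acq = acq,
                         meta = list()), traj, acq)
  rab <- adjointNudft(new("KSpaceData", data = a + b, noise = z@noise,
                          acq = acq, meta = list()), traj, acq)
  expect_equal(imageData(rab), imageData(ra) + imageData(rb), tolerance = 1e-12)
})

test_that("k-space dimension mismatch is rejected", {
  acq <- smallAcq(matrixSize = c(6, 6, 4), nSpectralPoints = 4, nRings = 3,
                  fov = c(60, 60, 40))
  traj <- makeCrtTrajectory(acq)
  bad <- new("KSpaceData", data = array(0 + 0i, c(10, 4, 4, 1)),
             noise = matrix(0 + 0i, 1, 1), acq = acq, meta = list())
  expect_error(adjointNudft(bad, traj, acq), "match the trajectory")
})

test_that("density-weighted adjoint approximately inverts the forward model", {
  # smooth Gaussian amplitude map at the full 1.8 mL protocol
  acq <- acqParams(nSpectralPoints = 2)
  traj <- makeCrtTrajectory(acq)
  x <- crtDMI:::coordVec(22, 270); y <- x; z <- crtDMI:::coordVec(21, 260)
  g <- exp(-outer(outer(x^2, y^2, "+"), z^2, "+") / (2 * 45^2))
  K <- forwardNudft(g, traj, acq)
  ksp <- new("KSpaceData", data = array(K, dim = c(dim(K), 1, 1)),
             noise = matrix(0 + 0i, 1, 1), acq = acq, meta = list())
  est <- Mod(imageData(adjointNudft(ksp, traj, acq))[, , , 1, 1]) / voxelVolume(acq)
  nrmse <- sqrt(mean((est - g)^2)) / sqrt(mean(g^2))
  expect_lt(nrmse, 0.15)
})

test_that("FID to spectrum is unitary and phases resonances correctly", {
  s <- syntheticSpectrum(Aw = 5, Ag = 0, lw = 10, phi = 0)
  # Parseval: spectrum energy equals FID energy
  t <- s$delay + (0:95) / 380
  fid <- 5 * exp((2i * pi * 0 - pi * 10) * t)
  expect_equal(sum(Mod(s$spectrum)^2), sum(Mod(fid)^2), tolerance = 1e-12)
  # the delay-corrected water peak is real and positive at its maximum
  pk <- which.max(Mod(s$spectrum))
  expect_equal(abs(s$freq[pk]), 0, tolerance = 380 / 96)
  expect_lt(abs(Arg(s$spectrum[pk])), 0.15)
  # frequency-domain input is rejected
  img <- new("SpectralImage", data = array(fid, c(1, 1, 1, 96)),
             domain = "fid", dwell = 1 / 380, acqDelay = s$delay,
             freqAxis = numeric(0), referencePpm = 4.8, hzPerPpm = 45.752,
             voxelSize = c(10, 10, 10), nTimeMeasured = 96L, perCoil = FALSE)
  sp <- fidToSpectrum(img)
  expect_error(fidToSpectrum(sp), "already")
})

test_that("a mono-exponential FID gives a Lorentzian of the expected width", {
  # T2* = 1/(pi * lw): absorption-mode FWHM = lw within 2% (zerofill x4).
  # A wide bandwidth keeps the wrapped tails of the discrete spectrum from
  # broadening the line (at 380 Hz the wrap alone adds ~6%).
  bw <- 2000
  for (lw in c(8.8, 14)) {
    n <- 1024  # long acquisition so truncation does not broaden the line
    t <- (0:(n - 1)) / bw
    fid <- exp(-pi * lw * t)
    img <- new("SpectralImage", data = array(fid + 0i, c(1, 1, 1, n)),
               domain = "fid", dwell = 1 / bw, acqDelay = 0,
               freqAxis = numeric(0), referencePpm = 4.8, hzPerPpm = 45.752,
               voxelSize = c(10, 10, 10), nTimeMeasured = as.integer(n),
               perCoil = FALSE)
    sp <- fidToSpectrum(img, zerofillFactor = 4)
    v <- Re(imageData(sp)[1, 1, 1, ])
    f <- freqAxis(sp)
    half <- max(v) / 2
    above <- range(which(v >= half))
    # sub-bin interpolation at both half-maximum crossings
    interp <- function(i1, i2) {
      f[i1] + (half - v[i1]) * (f[i2] - f[i1]) / (v[i2] - v[i1])
    }
    fwhm <- interp(above[2], above[2] + 1) - interp(above[1], above[1] - 1)
    expect_equal(fwhm, lw, tolerance = 0.02)
  }
})

test_that("a pure glucose tone lands at 3.9 ppm on the ppm axis", {
  s <- syntheticSpectrum(Aw = 0, Ag = 7, lw = 10)
  pk <- which.max(Mod(s$spectrum))
  expect_equal(s$freq[pk], -0.9 * 45.752, tolerance = 380 / 96)
  ppm <- 4.8 + s$freq / 45.752
  expect_equal(ppm[pk], 3.9, tolerance = 0.1)
})
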