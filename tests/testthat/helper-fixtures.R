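# shared fixtures: small geometries, synthetic spectra, and a cache for
# heavy pipeline runs reused across test files

smallAcq <- function(matrixSize = c(12, 12, 8), nSpectralPoints = 32,
                     nRings = 8, fov = c(120, 120, 80), ...) {
  acqParams(matrixSize = matrixSize, nSpectralPoints = nSpectralPoints,
            nRings = nRings, fov = fov, ...)
}

# single-compartment phantom on the small grid
blobSpec <- function(water = 10, glc = 0, linewidth = 14, noiseSd = 0,
                     nCoils = 1L, seed = 7L, semiAxes = c(30, 30, 25)) {
  phantomSpec(list(
    list(name = "blob", center = c(0, 0, 0), semiAxes = semiAxes,
         linewidthHz = linewidth,
         metabolites = list(water = list(kind = "constant", c0 = water),
                            glc = list(kind = "constant", c0 = glc)))
  ), nCoils = nCoils,
     coilCenters = matrix(rep(c(0, 0, 0), nCoils), nCoils, 3, byrow = TRUE),
     coilSigma = 1e6, noiseSd = noiseSd, seed = seed)
}

# two-resonance synthetic voxel spectrum generated through the package's
# own FID -> spectrum path (exact within floating point)
syntheticSpectrum <- function(Aw = 10, Ag = 3, lw = 14, phi = 0.3,
                              noiseSd = 0, seed = 1, n = 96, bw = 380,
                              delay = 0.002) {
  t <- delay + (0:(n - 1)) / bw
  fg <- (3.9 - 4.8) * 45.752
  fid <- Aw * exp((2i * pi * 0 - pi * lw) * t) +
    Ag * exp((2i * pi * fg - pi * lw) * t)
  fid <- fid * exp(1i * phi)
  if (noiseSd > 0) {
    set.seed(seed)
    fid <- fid + complex(real = rnorm(n, sd = noiseSd),
                         imaginary = rnorm(n, sd = noiseSd))
  }
  img <- new("SpectralImage", data = array(fid, dim = c(1, 1, 1, n)),
             domain = "fid", dwell = 1 / bw, acqDelay = delay,
             freqAxis = numeric(0), referencePpm = 4.8, hzPerPpm = 45.752,
             voxelSize = c(10, 10, 10), nTimeMeasured = as.integer(n),
             perCoil = FALSE)
  sp <- fidToSpectrum(img)
  list(spectrum = imageData(sp)[1, 1, 1, ], freq = freqAxis(sp),
       dwell = 1 / bw, delay = delay)
}

fitSynthetic <- function(...) {
  s <- syntheticSpectrum(...)
  fitVoxel(s$spectrum, s$freq, basisSet2H(), dwell = s$dwell,
           acqDelay = s$delay)
}

# correlated complex noise (test-side copy of the generator's model)
testNoise <- function(n, nCoils, sd, rho = 0) {
  R <- matrix(rho, nCoils, nCoils); diag(R) <- 1
  L <- chol(R)
  (matrix(rnorm(n * nCoils, sd = sd), n, nCoils) +
     1i * matrix(rnorm(n * nCoils, sd = sd), n, nCoils)) %*% L
}

# lazily computed heavy pipeline runs, shared across test files
.pipelineCache <- new.env(parent = emptyenv())

cachedRun <- function(key, expr) {
  if (!exists(key, envir = .pipelineCache)) {
    assign(key, force(expr), envir = .pipelineCache)
  }
  get(key, envir = .pipelineCache)
}

# the end-to-end 2.0 mM study at the 1.8 mL protocol (paper's 6-frame
# dynamic glucose protocol), reused by the acceptance and quantify tests
endToEndRun <- function() {
  cachedRun("e2e2mM", {
    spec <- defaultPhantomSpec(glcKind = "constant", glcPeak = 2, seed = 1L)
    runDynamicStudy(spec, frameTimesMin = seq(8.5 / 2, by = 8.5, length.out = 6))
  })
}

# inverse-FFT oracle for the centered-grid conventions: voxel j at
# (j - N/2) FOV/N, Cartesian sample m at m/FOV, so
# rho_j = sum_m d_m e^{i 2 pi m (j - N/2)/N} = N * ifft(d * (-1)^m) in
# stored (wrapped) order
ifftOracle3d <- function(kcube, dims) {
  sgn <- function(n) (-1)^(((seq_len(n) - 1L) - n / 2))
  s <- outer(outer(sgn(dims[1]), sgn(dims[2])), sgn(dims[3]))
  wrap <- function(n) {
    m <- ((seq_len(n) - 1L) - n / 2)
    (m %% n) + 1L
  }
  K <- array(0 + 0i, dims)
  K[wrap(dims[1]), wrap(dims[2]), wrap(dims[3])] <- kcube * s
  fft(K, inverse = TRUE) / prod(dims)
}
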