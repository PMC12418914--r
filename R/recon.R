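# in-plane encoding matrix exp(-i 2 pi (kx x + ky y)), (nSamp x nx*ny)
inplaneEncoding <- function(traj, acq) {
  x <- coordVec(acq@matrixSize[1], acq@fov[1])
  y <- coordVec(acq@matrixSize[2], acq@fov[2])
  g <- expand.grid(x = x, y = y)          # x fastest, matches array layout
  exp(-2i * pi * (outer(traj@kx, g$x) + outer(traj@ky, g$y)))
}

# kz encoding matrix exp(-i 2 pi kz z), (nz x nKz)
kzEncoding <- function(traj, acq) {
  z <- coordVec(acq@matrixSize[3], acq@fov[3])
  exp(-2i * pi * outer(z, traj@kzOffsets))
}

#' Forward non-uniform DFT of a voxel map
#'
#' Evaluates k(s, p) = sum_r m(r) exp(-i 2 pi k_s.r) exp(-i 2 pi kz_p z) dV
#' on the trajectory's in-plane samples and kz partitions, with dV the
#' voxel volume in mL. This is the spatial-encoding operator of the phantom
#' forward model; it is exposed so that reconstruction accuracy can be
#' assessed on arbitrary (e.g. smooth) amplitude maps.
#'
#' @param map numeric or complex 3-D array on the acquisition grid.
#' @param traj \linkS4class{Trajectory}.
#' @param acq \linkS4class{AcquisitionParams}.
#' @return complex matrix (in-plane sample x kz partition).
#' @export
forwardNudft <- function(map, traj, acq) {
  dims <- acq@matrixSize
  if (!identical(dim(map), as.integer(dims))) {
    stopf("map dimensions do not match the acquisition matrix")
  }
  E <- inplaneEncoding(traj, acq)
  Ez <- kzEncoding(traj, acq)
  m <- matrix(map, prod(dims[1:2]), dims[3])
  (E %*% (m %*% Ez)) * voxelVolume(acq)
}

#' Adjoint non-uniform DFT reconstruction
#'
#' Reconstructs per-coil spatial-spectral images from CRT k-space:
#' rho(r, t) = sum_s w_s d_s(t) exp(+i 2 pi k_s.r), evaluated on the
#' acquisition voxel grid for every FID time point, with the kz direction
#' handled as a standard inverse DFT over the Cartesian partitions. On the
#' degenerate Cartesian trajectory with uniform weights this is exactly the
#' inverse discrete Fourier transform.
#'
#' @param ksp \linkS4class{KSpaceData}.
#' @param traj the \linkS4class{Trajectory} the data were sampled on.
#' @param acq \linkS4class{AcquisitionParams}.
#' @return A per-coil FID-domain \linkS4class{SpectralImage}
#'   (x, y, z, time, coil).
#' @export
adjointNudft <- function(ksp, traj, acq) {
  dims <- acq@matrixSize
  d <- dim(ksp@data)
  nSamp <- d[1]; nKz <- d[2]; nT <- d[3]; nCoils <- d[4]
  if (nSamp != sampleCount(traj) || nKz != length(traj@kzOffsets)) {
    stopf("k-space dimensions do not match the trajectory (%d x %d vs %d x %d)",
          nSamp, nKz, sampleCount(traj), length(traj@kzOffsets))
  }
  Eadj <- Conj(t(inplaneEncoding(traj, acq)))   # (nx*ny) x nSamp
  EzAdj <- Conj(kzEncoding(traj, acq)) / nKz    # nz x nKz
  # density-compensation area calibration: the weighted sum discretizes the
  # continuous inverse transform over the covered k-area (pi kmax^2 for the
  # ring disk); exactly 1 on the degenerate Cartesian grid
  alpha <- if (traj@degenerateCartesian) {
    1
  } else {
    pi * traj@kmax^2 * acq@fov[1] * acq@fov[2] / (dims[1] * dims[2])
  }
  nXY <- prod(dims[1:2])
  out <- array(0 + 0i, dim = c(dims, nT, nCoils))
  for (c in seq_len(nCoils)) {
    D <- matrix(ksp@data[, , , c], nSamp, nKz * nT) * (alpha * traj@weights)
    I1 <- Eadj %*% D                             # nXY x (nKz*nT)
    dim(I1) <- c(nXY, nKz, nT)
    I1 <- aperm(I1, c(1, 3, 2))                  # nXY x nT x nKz
    dim(I1) <- c(nXY * nT, nKz)
    I2 <- I1 %*% t(EzAdj)                        # (nXY*nT) x nz
    dim(I2) <- c(nXY, nT, dims[3])
    out[, , , , c] <- aperm(I2, c(1, 3, 2))
  }
  new("SpectralImage",
    data = out, domain = "fid", dwell = dwellTime(acq),
    acqDelay = acq@acqDelay / 1000, freqAxis = numeric(0),
    referencePpm = acq@referencePpm, hzPerPpm = hzPerPpm(acq),
    voxelSize = acq@fov / dims, nTimeMeasured = as.integer(nT),
    perCoil = TRUE
  )
}

#' Transform FIDs to spectra
#'
#' Per-voxel DFT of the time axis with optional exponential apodization and
#' zero-filling, normalized by 1/sqrt(N) so the transform conserves energy
#' (Parseval). The acquisition delay is compensated by the first-order
#' spectral phase ramp exp(-i 2 pi f t_delay), which leaves every resonance
#' phase-pure at its own frequency. The frequency axis is centered on the
#' carrier; \code{\link{ppmAxis}} maps it to ppm via
#' ppm = referencePpm + f / (gamma B0).
#'
#' @param img FID-domain \linkS4class{SpectralImage} (combined or
#'   per-coil).
#' @param zerofillFactor zero-filling factor (1 = none; fitting operates on
#'   unfilled spectra).
#' @param apodizationHz exponential line broadening in Hz (0 = none).
#' @return A spectrum-domain \linkS4class{SpectralImage}.
#' @export
fidToSpectrum <- function(img, zerofillFactor = 1, apodizationHz = 0) {
  if (img@domain != "fid") stopf("image is already in the frequency domain")
  d <- dim(img@data)
  n <- d[4]
  nf <- as.integer(round(zerofillFactor * n))
  bw <- 1 / img@dwell
  tRel <- (seq_len(n) - 1L) * img@dwell
  apod <- if (apodizationHz > 0) exp(-pi * apodizationHz * tRel) else rep(1, n)

  nOther <- prod(d[-4])
  perm <- c(4, seq_along(d)[-4])
  M <- matrix(aperm(img@data, perm), n, nOther)
  M <- M * apod
  if (nf > n) M <- rbind(M, matrix(0 + 0i, nf - n, nOther))
  S <- stats::mvfft(M) / sqrt(nf)
  ord <- shiftOrder(nf)
  S <- S[ord, , drop = FALSE]
  freq <- kIndexVec(nf) * (bw / nf)
  S <- S * exp(-2i * pi * freq * img@acqDelay)

  outDims <- d; outDims[4] <- nf
  S <- array(S, dim = c(nf, d[-4]))
  S <- aperm(S, order(perm))
  new("SpectralImage",
    data = S, domain = "spectrum", dwell = img@dwell,
    acqDelay = img@acqDelay, freqAxis = freq,
    referencePpm = img@referencePpm, hzPerPpm = img@hzPerPpm,
    voxelSize = img@voxelSize, nTimeMeasured = img@nTimeMeasured,
    perCoil = img@perCoil
  )
}
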