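#' Construct a phantom specification
#'
#' @param compartments list of compartment descriptors (see
#'   \linkS4class{PhantomSpec}).
#' @param nCoils number of receive channels.
#' @param coilCenters nCoils x 3 matrix of coil positions in mm.
#' @param coilSigma Gaussian falloff scale of the coil sensitivities, mm.
#' @param noiseSd SD of the real/imaginary parts of the per-channel complex
#'   k-space noise.
#' @param noiseCorr inter-channel noise correlation.
#' @param seed integer seed.
#' @return A \linkS4class{PhantomSpec}.
#' @export
phantomSpec <- function(compartments, nCoils = 2L,
                        coilCenters = rbind(c(-70, 150, 0), c(70, 150, 0)),
                        coilSigma = 160, noiseSd = 0, noiseCorr = 0.2,
                        seed = 42L) {
  new("PhantomSpec",
    compartments = compartments, nCoils = as.integer(nCoils),
    coilCenters = coilCenters, coilSigma = coilSigma,
    noiseSd = noiseSd, noiseCorr = noiseCorr, seed = as.integer(seed)
  )
}

#' Default digital kidney phantom
#'
#' A supine abdomen: a large ellipsoidal body compartment carrying the
#' natural-abundance HDO signal, two ellipsoidal kidneys whose 2H-glucose
#' follows a gamma-variate uptake curve peaking at \code{glcPeak} mM around
#' \code{glcPeakTime} minutes, and optionally an anterior "stomach"
#' contaminant with a high constant glucose level. Linewidths default to
#' 14 Hz, the in vivo regime. The default noise SD is calibrated so that
#' the raw (pre-denoise) kidney water SNR of the full default pipeline is
#' about 7.
#'
#' @param relax \linkS4class{RelaxationAssumptions} supplying the
#'   natural-abundance water level.
#' @param glcPeak peak kidney 2H-glucose concentration, mM.
#' @param glcPeakTime time-to-peak of the kidney glucose curve, minutes.
#' @param glcKind kidney glucose curve family, "gamma_variate",
#'   "saturating" or "constant".
#' @param withStomach add the anterior contaminant compartment.
#' @param stomachGlc its constant glucose concentration, mM.
#' @param linewidthHz Lorentzian linewidth of all compartments, Hz.
#' @param noiseSd,noiseCorr,seed noise model, see \code{\link{phantomSpec}}.
#' @return A \linkS4class{PhantomSpec}.
#' @export
defaultPhantomSpec <- function(relax = relaxationAssumptions(),
                               glcPeak = 2.0, glcPeakTime = 37,
                               glcKind = "gamma_variate",
                               withStomach = FALSE, stomachGlc = 12,
                               linewidthHz = 14,
                               noiseSd = 357, noiseCorr = 0.2,
                               seed = 42L) {
  hdo <- naturalAbundanceHdo(relax)
  glcCurve <- switch(glcKind,
    gamma_variate = list(kind = "gamma_variate", c0 = 0, a = glcPeak,
                         tp = glcPeakTime, alpha = 2),
    saturating = list(kind = "saturating", c0 = 0, dc = glcPeak,
                      tau = glcPeakTime / 3),
    constant = list(kind = "constant", c0 = glcPeak),
    stopf("unknown glucose curve kind '%s'", glcKind)
  )
  comps <- list(
    list(name = "body", center = c(0, 10, 0), semiAxes = c(115, 80, 105),
         linewidthHz = linewidthHz,
         metabolites = list(water = list(kind = "constant", c0 = hdo),
                            glc = list(kind = "constant", c0 = 0))),
    list(name = "kidney_left", center = c(-60, 25, 0), semiAxes = c(22, 28, 60),
         linewidthHz = linewidthHz,
         metabolites = list(water = list(kind = "constant", c0 = hdo),
                            glc = glcCurve)),
    list(name = "kidney_right", center = c(60, 25, 0), semiAxes = c(22, 28, 60),
         linewidthHz = linewidthHz,
         metabolites = list(water = list(kind = "constant", c0 = hdo),
                            glc = glcCurve))
  )
  if (withStomach) {
    comps <- c(comps, list(
      list(name = "stomach", center = c(0, -50, 40), semiAxes = c(40, 28, 40),
           linewidthHz = linewidthHz,
           metabolites = list(water = list(kind = "constant", c0 = hdo),
                              glc = list(kind = "constant", c0 = stomachGlc)))
    ))
  }
  phantomSpec(comps, noiseSd = noiseSd, noiseCorr = noiseCorr, seed = seed)
}

#' Voxelize the phantom compartments into a label map
#'
#' Deterministic voxel-center-in-ellipsoid test on the acquisition grid.
#' Later-listed compartments override earlier ones where ellipsoids
#' overlap. A compartment whose ellipsoid covers no voxel center raises an
#' error naming it.
#'
#' @param spec a \linkS4class{PhantomSpec}.
#' @param acq an \linkS4class{AcquisitionParams} defining grid and FOV.
#' @return A \linkS4class{LabelMap}; label i corresponds to compartment i.
#' @examples
#' lm <- buildLabelMap(defaultPhantomSpec(), acqParams())
#' table(labelArray(lm))
#' @export
buildLabelMap <- function(spec, acq) {
  dims <- acq@matrixSize
  x <- coordVec(dims[1], acq@fov[1])
  y <- coordVec(dims[2], acq@fov[2])
  z <- coordVec(dims[3], acq@fov[3])
  labels <- array(0L, dim = dims)
  for (i in seq_along(spec@compartments)) {
    comp <- spec@compartments[[i]]
    dx2 <- ((x - comp$center[1]) / comp$semiAxes[1])^2
    dy2 <- ((y - comp$center[2]) / comp$semiAxes[2])^2
    dz2 <- ((z - comp$center[3]) / comp$semiAxes[3])^2
    inside <- outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
    if (!any(inside)) {
      stopf("compartment '%s' lies entirely outside the grid extent", comp$name)
    }
    labels[inside] <- i
  }
  new("LabelMap",
    labels = labels,
    legend = vapply(spec@compartments, `[[`, character(1), "name"),
    voxelSize = acq@fov / dims
  )
}

#' Logical mask of one or more compartments
#'
#' @param labels a \linkS4class{LabelMap}.
#' @param names compartment names to include.
#' @return logical 3-D array.
#' @export
compartmentMask <- function(labels, names) {
  idx <- match(names, labels@legend)
  if (anyNA(idx)) stopf("unknown compartment(s): %s",
                        paste(names[is.na(idx)], collapse = ", "))
  array(labels@labels %in% idx, dim = dim(labels@labels))
}

#' Tracer uptake curves
#'
#' Closed-form concentration time courses used by the phantom:
#' \describe{
#'   \item{saturating}{C(t) = c0 + dc (1 - exp(-t/tau))}
#'   \item{gamma_variate}{C(t) = c0 + a (t/tp)^alpha exp(alpha (1 - t/tp)),
#'     peaking at t = tp with value c0 + a}
#'   \item{constant}{C(t) = c0}
#' }
#'
#' @param kind curve family name.
#' @param params named list of curve parameters (all non-negative; time
#'   scales strictly positive).
#' @param times minutes, non-negative and increasing.
#' @return concentrations in mM, one per time point.
#' @examples
#' uptakeCurve("saturating", list(c0 = 1, dc = 9, tau = 10), c(0, 30, 100))
#' @export
uptakeCurve <- function(kind, params, times) {
  if (any(times < 0)) stopf("times must be non-negative")
  if (is.unsorted(times, strictly = FALSE)) stopf("times must be increasing")
  nums <- unlist(params[vapply(params, is.numeric, logical(1))])
  if (any(nums < 0)) stopf("uptake-curve parameters must be non-negative")
  switch(kind,
    constant = rep(params$c0, length(times)),
    saturating = {
      if (params$tau <= 0) stopf("tau must be positive")
      params$c0 + params$dc * (1 - exp(-times / params$tau))
    },
    gamma_variate = {
      if (params$tp <= 0 || params$alpha <= 0) stopf("tp and alpha must be positive")
      params$c0 + params$a * (times / params$tp)^params$alpha *
        exp(params$alpha * (1 - times / params$tp))
    },
    stopf("unknown uptake-curve kind '%s'", kind)
  )
}

# complex Gaussian coil sensitivity maps: (nx*ny*nz) x nCoils
coilSensitivities <- function(spec, acq) {
  dims <- acq@matrixSize
  x <- coordVec(dims[1], acq@fov[1])
  y <- coordVec(dims[2], acq@fov[2])
  z <- coordVec(dims[3], acq@fov[3])
  grid <- as.matrix(expand.grid(x = x, y = y, z = z))
  phases <- withSeed(spec@seed, stats::runif(spec@nCoils, -pi, pi))
  sens <- matrix(0 + 0i, nrow(grid), spec@nCoils)
  for (c in seq_len(spec@nCoils)) {
    d2 <- rowSums(sweep(grid, 2, spec@coilCenters[c, ])^2)
    sens[, c] <- exp(-d2 / (2 * spec@coilSigma^2)) * exp(1i * phases[c])
  }
  sens
}

#' Simulate one CRT k-space acquisition of the phantom
#'
#' Forward model: each voxel's FID is a sum over resonances,
#' rho(r, t) = sum_m A_m(r) exp(i 2 pi f_m t) exp(-pi lw t), evaluated at
#' t = delay + n dwell, with f_m = (ppm_m - referencePpm) gamma B0 (plus an
#' optional per-compartment B0 offset) and amplitude A_m proportional to
#' concentration x number of 2H labels x the steady-state saturation
#' factor \code{\link{saturationFactor}}. The k-space sample for coil c is
#' sum_r s_c(r) rho(r, t) exp(-i 2 pi k.r) dV (dV in mL, making per-voxel
#' reconstructed amplitudes proportional to voxel volume as in real MRSI,
#' so kidney signal sums are comparable across resolutions). Correlated
#' complex Gaussian noise is added per channel, and a noise-only block with
#' identical statistics is attached.
#'
#' @param labels \linkS4class{LabelMap} from \code{\link{buildLabelMap}}.
#' @param spec \linkS4class{PhantomSpec}.
#' @param acq \linkS4class{AcquisitionParams}.
#' @param relax \linkS4class{RelaxationAssumptions} (T1 values set the
#'   saturation factors).
#' @param traj \linkS4class{Trajectory} consistent with \code{acq}.
#' @param timeMin acquisition time in minutes (fed to the uptake curves).
#' @param timeIndex integer frame index; noise is seeded per frame so every
#'   (seed, frame) pair is reproducible.
#' @param noiseDraws size of the noise-only reference block per channel.
#' @return A \linkS4class{KSpaceData}.
#' @export
simulateFidImage <- function(labels, spec, acq, relax, traj,
                             timeMin = 0, timeIndex = 0L,
                             noiseDraws = 4096L) {
  if (!identical(traj@matrixSize, acq@matrixSize) ||
      max(abs(traj@fov - acq@fov)) > 1e-9) {
    stopf("trajectory geometry does not match the acquisition parameters")
  }
  dims <- acq@matrixSize
  nT <- acq@nSpectralPoints
  nSamp <- sampleCount(traj)
  nKz <- length(traj@kzOffsets)
  dwell <- dwellTime(acq)
  tAbs <- acq@acqDelay / 1000 + (seq_len(nT) - 1L) * dwell  # seconds

  metInfo <- list(
    water = list(ppm = 4.8, nLabels = relax@nLabelsWater, t1 = relax@t1Water),
    glc = list(ppm = 3.9, nLabels = relax@nLabelsGlc, t1 = relax@t1Glc)
  )

  sens <- coilSensitivities(spec, acq)
  kdata <- array(0 + 0i, dim = c(nSamp, nKz, nT, spec@nCoils))

  for (ci in seq_along(spec@compartments)) {
    comp <- spec@compartments[[ci]]
    mask <- labels@labels == ci
    if (!any(mask)) next
    lw <- if (is.null(comp$linewidthHz)) 14 else comp$linewidthHz
    b0 <- if (is.null(comp$b0OffsetHz)) 0 else comp$b0OffsetHz
    # spatial encoding of this compartment, per coil (metabolite-independent)
    kBase <- vector("list", spec@nCoils)
    for (c in seq_len(spec@nCoils)) {
      m <- array(as.numeric(mask), dim = dims) *
        array(sens[, c], dim = dims)
      kBase[[c]] <- forwardNudft(m, traj, acq)
    }
    for (met in names(comp$metabolites)) {
      info <- metInfo[[met]]
      conc <- uptakeCurve(comp$metabolites[[met]]$kind,
                          comp$metabolites[[met]], timeMin)
      amp <- conc * info$nLabels *
        saturationFactor(acq@tr, info$t1, acq@flipAngle)
      if (amp == 0) next
      f <- ppmToHz(info$ppm, acq) + b0
      g <- exp((1i * 2 * pi * f - pi * lw) * tAbs)
      for (c in seq_len(spec@nCoils)) {
        contrib <- outer(as.vector(kBase[[c]]), g) * amp
        dim(contrib) <- c(nSamp, nKz, nT)
        kdata[, , , c] <- kdata[, , , c] + contrib
      }
    }
  }

  noiseBlock <- matrix(0 + 0i, spec@nCoils, noiseDraws)
  if (spec@noiseSd > 0) {
    nEntries <- nSamp * nKz * nT
    noise <- withSeed(spec@seed + 7919L * (as.integer(timeIndex) + 1L), {
      list(
        data = complexNoise(nEntries, spec@nCoils, spec@noiseSd, spec@noiseCorr),
        block = complexNoise(noiseDraws, spec@nCoils, spec@noiseSd, spec@noiseCorr)
      )
    })
    for (c in seq_len(spec@nCoils)) {
      kdata[, , , c] <- kdata[, , , c] + array(noise$data[, c], dim = c(nSamp, nKz, nT))
    }
    noiseBlock <- t(noise$block)
  }

  new("KSpaceData",
    data = kdata, noise = noiseBlock, acq = acq,
    meta = list(timeMin = timeMin, timeIndex = as.integer(timeIndex),
                seed = spec@seed)
  )
}
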