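#' @import methods
NULL

#' Acquisition parameters for a 2H-MRSI concentric-ring protocol
#'
#' Holds the timing, geometry and field constants of a deuterium MRSI
#' acquisition: field strength, gyromagnetic ratio of 2H, repetition time,
#' flip angle, acquisition delay, spectral bandwidth and number of spectral
#' points, field of view, matrix size, number of concentric rings and the
#' carrier position in ppm.
#'
#' @slot fieldStrength static field strength in tesla.
#' @slot gamma2H gyromagnetic ratio of deuterium in MHz per tesla. The
#'   product \code{gamma2H * fieldStrength} is the carrier frequency in MHz
#'   and, numerically, the Hz width of one ppm.
#' @slot tr repetition time in ms.
#' @slot flipAngle excitation flip angle in degrees.
#' @slot acqDelay delay between excitation and the first FID sample, ms.
#' @slot spectralBandwidth readout (spectral) bandwidth in Hz; the FID dwell
#'   time is its reciprocal.
#' @slot nSpectralPoints number of FID time points.
#' @slot fov field of view in mm, length 3.
#' @slot matrixSize reconstruction matrix, length 3.
#' @slot nRings number of concentric rings of the readout trajectory.
#' @slot referencePpm chemical shift of the carrier (water, 4.8 ppm).
#' @export
setClass("AcquisitionParams",
  representation(
    fieldStrength = "numeric",
    gamma2H = "numeric",
    tr = "numeric",
    flipAngle = "numeric",
    acqDelay = "numeric",
    spectralBandwidth = "numeric",
    nSpectralPoints = "integer",
    fov = "numeric",
    matrixSize = "integer",
    nRings = "integer",
    referencePpm = "numeric"
  )
)

setValidity("AcquisitionParams", function(object) {
  msg <- character(0)
  pos <- c(
    fieldStrength = object@fieldStrength, gamma2H = object@gamma2H,
    tr = object@tr, flipAngle = object@flipAngle,
    spectralBandwidth = object@spectralBandwidth
  )
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    msg <- c(msg, "field strength, gamma, TR, flip angle and bandwidth must be positive")
  }
  if (object@acqDelay < 0) msg <- c(msg, "acquisition delay must be non-negative")
  if (object@nSpectralPoints < 2L) msg <- c(msg, "need at least 2 spectral points")
  if (length(object@fov) != 3L || any(object@fov <= 0)) {
    msg <- c(msg, "fov must be 3 positive lengths (mm)")
  }
  if (length(object@matrixSize) != 3L || any(object@matrixSize < 2L)) {
    msg <- c(msg, "matrix must have 3 entries, each >= 2")
  }
  if (object@nRings < 1L) msg <- c(msg, "nRings must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Assumed relaxation constants and labelling factors for quantification
#'
#' T1/T2 of the 2H water and glucose resonances, tissue water content, the
#' number of 2H labels per molecule and the natural-abundance deuterium
#' fraction used to compute the internal HDO reference concentration.
#'
#' @slot t1Water,t1Glc longitudinal relaxation times, ms.
#' @slot t2Water,t2Glc transverse relaxation times, ms.
#' @slot waterContent tissue water content fraction (0, 1].
#' @slot nLabelsWater,nLabelsGlc 2H atoms per molecule (HDO: 1; [6,6']-2H
#'   glucose: 2).
#' @slot naturalAbundance fraction of hydrogen that is deuterium.
#' @export
setClass("RelaxationAssumptions",
  representation(
    t1Water = "numeric", t1Glc = "numeric",
    t2Water = "numeric", t2Glc = "numeric",
    waterContent = "numeric",
    nLabelsWater = "integer", nLabelsGlc = "integer",
    naturalAbundance = "numeric"
  )
)

setValidity("RelaxationAssumptions", function(object) {
  msg <- character(0)
  if (any(c(object@t1Water, object@t1Glc, object@t2Water, object@t2Glc) <= 0)) {
    msg <- c(msg, "relaxation times must be positive")
  }
  if (object@waterContent <= 0 || object@waterContent > 1) {
    msg <- c(msg, "water content must be in (0, 1]")
  }
  if (object@nLabelsWater < 1L || object@nLabelsGlc < 1L) {
    msg <- c(msg, "label counts must be >= 1")
  }
  if (object@naturalAbundance <= 0 || object@naturalAbundance >= 1) {
    msg <- c(msg, "natural abundance must be a small positive fraction")
  }
  if (length(msg)) msg else TRUE
})

#' Digital phantom specification
#'
#' Describes the synthetic abdomen: ellipsoidal compartments with per-
#' metabolite baseline concentrations and uptake curves, a Lorentzian
#' linewidth per compartment, smooth Gaussian coil-sensitivity profiles for
#' the receive channels, and the correlated complex noise model.
#'
#' Each compartment is a list with elements \code{name}, \code{center} (mm),
#' \code{semiAxes} (mm), \code{linewidthHz}, optional \code{b0OffsetHz}, and
#' \code{metabolites}: a named list (names \code{"water"}, \code{"glc"}) of
#' uptake descriptors \code{list(kind=, ...params)} understood by
#' \code{\link{uptakeCurve}}.
#'
#' @slot compartments list of compartment descriptors; later entries
#'   override earlier ones where ellipsoids overlap.
#' @slot nCoils number of receive channels.
#' @slot coilCenters nCoils x 3 matrix of coil positions, mm.
#' @slot coilSigma Gaussian falloff scale of the sensitivities, mm.
#' @slot noiseSd standard deviation of the real and imaginary parts of the
#'   per-channel complex noise, in k-space signal units.
#' @slot noiseCorr correlation coefficient between channels.
#' @slot seed integer seed making the simulation reproducible.
#' @export
setClass("PhantomSpec",
  representation(
    compartments = "list",
    nCoils = "integer",
    coilCenters = "matrix",
    coilSigma = "numeric",
    noiseSd = "numeric",
    noiseCorr = "numeric",
    seed = "integer"
  )
)

setValidity("PhantomSpec", function(object) {
  msg <- character(0)
  if (object@nCoils < 1L) msg <- c(msg, "need at least one coil")
  if (nrow(object@coilCenters) != object@nCoils || ncol(object@coilCenters) != 3L) {
    msg <- c(msg, "coilCenters must be nCoils x 3")
  }
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be >= 0")
  if (abs(object@noiseCorr) >= 1) msg <- c(msg, "noise correlation must lie in (-1, 1)")
  for (comp in object@compartments) {
    if (is.null(comp$name) || is.null(comp$center) || is.null(comp$semiAxes)) {
      msg <- c(msg, "each compartment needs name, center and semiAxes")
      break
    }
    if (any(comp$semiAxes <= 0)) msg <- c(msg, sprintf("compartment '%s': semi-axes must be positive", comp$name))
    if (!is.null(comp$linewidthHz) && comp$linewidthHz <= 0) {
      msg <- c(msg, sprintf("compartment '%s': linewidth must be positive", comp$name))
    }
  }
  if (length(msg)) msg else TRUE
})

#' Integer label map of the phantom voxel grid
#'
#' @slot labels 3-D integer array; 0 is background, positive values index
#'   the legend.
#' @slot legend character vector of compartment names, one per label value.
#' @slot voxelSize voxel edge lengths in mm.
#' @export
setClass("LabelMap",
  representation(
    labels = "array",
    legend = "character",
    voxelSize = "numeric"
  )
)

setValidity("LabelMap", function(object) {
  msg <- character(0)
  if (length(dim(object@labels)) != 3L) msg <- c(msg, "labels must be a 3-D array")
  if (any(object@labels < 0)) msg <- c(msg, "labels must be non-negative")
  if (max(object@labels) > length(object@legend)) {
    msg <- c(msg, "label values exceed legend length")
  }
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0)) {
    msg <- c(msg, "voxelSize must be 3 positive lengths")
  }
  if (length(msg)) msg else TRUE
})

#' Concentric-ring k-space trajectory
#'
#' In-plane ring coordinates with per-sample density-compensation weights
#' and the Cartesian kz partition offsets. A degenerate mode holds exactly
#' the Cartesian grid points of the target matrix, used as an FFT oracle
#' hook.
#'
#' @slot radii ring radii, 1/mm (empty in degenerate Cartesian mode).
#' @slot angularCounts number of angular samples per ring.
#' @slot kx,ky in-plane sample coordinates, 1/mm, flattened over rings.
#' @slot ringIndex ring membership of each sample.
#' @slot kzOffsets Cartesian kz phase-encode offsets, 1/mm.
#' @slot weights per-sample density weights, positive, summing to 1.
#' @slot degenerateCartesian TRUE when the samples are the Cartesian grid.
#' @slot kmax in-plane Nyquist radius matrix/(2 FOV), 1/mm.
#' @slot fov,matrixSize geometry the trajectory was built for.
#' @export
setClass("Trajectory",
  representation(
    radii = "numeric",
    angularCounts = "integer",
    kx = "numeric",
    ky = "numeric",
    ringIndex = "integer",
    kzOffsets = "numeric",
    weights = "numeric",
    degenerateCartesian = "logical",
    kmax = "numeric",
    fov = "numeric",
    matrixSize = "integer"
  )
)

setValidity("Trajectory", function(object) {
  msg <- character(0)
  n <- length(object@kx)
  if (length(object@ky) != n || length(object@weights) != n) {
    msg <- c(msg, "kx, ky and weights must have equal length")
  }
  if (any(object@weights <= 0)) msg <- c(msg, "weights must be strictly positive")
  if (abs(sum(object@weights) - 1) > 1e-8) msg <- c(msg, "weights must sum to 1")
  if (!object@degenerateCartesian) {
    kr <- sqrt(object@kx^2 + object@ky^2)
    if (any(kr > object@kmax * (1 + 1e-12))) {
      msg <- c(msg, "samples exceed the Nyquist radius")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Multi-coil k-space data from one simulated acquisition
#'
#' @slot data complex array with dimensions (sample, kz partition, FID time
#'   point, coil).
#' @slot noise complex noise-only reference block, coils x draws, with the
#'   same inter-channel covariance as the data noise.
#' @slot acq the \linkS4class{AcquisitionParams} used.
#' @slot meta list of bookkeeping values (seed, acquisition time, ...).
#' @export
setClass("KSpaceData",
  representation(
    data = "array",
    noise = "matrix",
    acq = "AcquisitionParams",
    meta = "list"
  )
)

setValidity("KSpaceData", function(object) {
  msg <- character(0)
  if (length(dim(object@data)) != 4L) {
    msg <- c(msg, "data must be (sample, kz, time, coil)")
  }
  if (!is.complex(object@data)) msg <- c(msg, "data must be complex")
  if (length(msg)) msg else TRUE
})

#' Spatial-spectral image
#'
#' The container passed between reconstruction, coil combination, denoising
#' and fitting: a complex voxel grid by FID-time (or frequency) array with
#' its axis metadata.
#'
#' @slot data complex array (x, y, z, time/frequency) or with a trailing
#'   coil dimension when \code{perCoil} is TRUE.
#' @slot domain "fid" or "spectrum".
#' @slot dwell FID dwell time in seconds (1 / spectral bandwidth).
#' @slot acqDelay acquisition delay in seconds.
#' @slot freqAxis frequency axis in Hz relative to the carrier (spectrum
#'   domain only, ascending).
#' @slot referencePpm carrier position in ppm.
#' @slot hzPerPpm carrier frequency in MHz = Hz per ppm.
#' @slot voxelSize voxel edge lengths, mm.
#' @slot nTimeMeasured number of measured FID points (before zero-filling).
#' @slot perCoil TRUE while the coil dimension is still present.
#' @export
setClass("SpectralImage",
  representation(
    data = "array",
    domain = "character",
    dwell = "numeric",
    acqDelay = "numeric",
    freqAxis = "numeric",
    referencePpm = "numeric",
    hzPerPpm = "numeric",
    voxelSize = "numeric",
    nTimeMeasured = "integer",
    perCoil = "logical"
  )
)

setValidity("SpectralImage", function(object) {
  msg <- character(0)
  nd <- length(dim(object@data))
  if (object@perCoil && nd != 5L) msg <- c(msg, "per-coil data must be 5-D (x,y,z,t,coil)")
  if (!object@perCoil && nd != 4L) msg <- c(msg, "combined data must be 4-D (x,y,z,t)")
  if (!object@domain %in% c("fid", "spectrum")) msg <- c(msg, "domain must be 'fid' or 'spectrum'")
  if (object@domain == "spectrum") {
    if (length(object@freqAxis) != dim(object@data)[4]) {
      msg <- c(msg, "frequency axis must match the spectral dimension")
    }
    if (length(object@freqAxis) > 1 && any(diff(object@freqAxis) <= 0)) {
      msg <- c(msg, "frequency (and hence ppm) axis must be strictly monotonic")
    }
  }
  if (object@dwell <= 0) msg <- c(msg, "dwell must be positive")
  if (length(msg)) msg else TRUE
})

#' Coil noise covariance
#'
#' @slot cov complex Hermitian coil-by-coil covariance matrix.
#' @slot nSamples number of noise draws used for the estimate.
#' @slot illConditioned TRUE when the condition number exceeds 1e6
#'   (e.g. duplicated channels).
#' @export
setClass("NoiseCovariance",
  representation(
    cov = "matrix",
    nSamples = "integer",
    illConditioned = "logical"
  )
)

setValidity("NoiseCovariance", function(object) {
  msg <- character(0)
  C <- object@cov
  if (nrow(C) != ncol(C)) msg <- c(msg, "covariance must be square")
  if (max(Mod(C - Conj(t(C)))) > 1e-8 * max(Mod(C), 1e-300)) {
    msg <- c(msg, "covariance must be Hermitian")
  }
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(Re(ev)) < -1e-8 * max(abs(Re(ev)), 1e-300)) {
    msg <- c(msg, "covariance must be positive semi-definite")
  }
  if (length(msg)) msg else TRUE
})

#' Spectral basis set
#'
#' Analytic singlet basis for the linear-combination fit: the 2H water
#' (4.8 ppm) and glucose (3.9 ppm) resonances with their label counts.
#'
#' @slot resonances data.frame with columns name, ppm, nLabels.
#' @slot lineshape "lorentzian" or "voigt".
#' @export
setClass("BasisSet",
  representation(
    resonances = "data.frame",
    lineshape = "character"
  )
)

setValidity("BasisSet", function(object) {
  msg <- character(0)
  r <- object@resonances
  if (nrow(r) < 1L) msg <- c(msg, "need at least one resonance")
  if (!all(c("name", "ppm", "nLabels") %in% names(r))) {
    msg <- c(msg, "resonances need columns name, ppm, nLabels")
  } else if (anyDuplicated(r$ppm)) {
    msg <- c(msg, "resonance ppm values must be distinct")
  }
  if (!object@lineshape %in% c("lorentzian", "voigt")) {
    msg <- c(msg, "lineshape must be 'lorentzian' or 'voigt'")
  }
  if (length(msg)) msg else TRUE
})

#' Per-voxel spectral fit result
#'
#' @slot table data.frame, one row per resonance: amplitude (a.u.),
#'   frequency offset from the nominal position (Hz), FWHM (Hz), CRLB as
#'   percent of the amplitude, and spectral peak height (a.u.).
#' @slot phase0 shared zero-order phase, rad.
#' @slot baseline fitted constant complex baseline.
#' @slot snr water peak height over the off-resonant noise SD.
#' @slot sigma noise SD of the spectrum's real part.
#' @slot residRms root-mean-square of the complex fit residual.
#' @slot converged TRUE when the optimizer reported convergence.
#' @export
setClass("FitResult",
  representation(
    table = "data.frame",
    phase0 = "numeric",
    baseline = "complex",
    snr = "numeric",
    sigma = "numeric",
    residRms = "numeric",
    converged = "logical"
  )
)

setValidity("FitResult", function(object) {
  msg <- character(0)
  tb <- object@table
  if (any(tb$fwhmHz <= 0, na.rm = TRUE)) msg <- c(msg, "linewidths must be positive")
  if (any(tb$crlbPercent < 0, na.rm = TRUE)) msg <- c(msg, "CRLB must be >= 0")
  if (length(object@snr) && !is.na(object@snr) && object@snr < 0) msg <- c(msg, "SNR must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Voxel-wise concentration map with exclusion flags
#'
#' @slot values mM per voxel, array (x, y, z) or (x, y, z, time).
#' @slot crlbExcluded logical array: fit CRLB above the exclusion threshold.
#' @slot concExcluded logical array: concentration above the physiological
#'   ceiling (contamination filter).
#' @slot unfit logical array: voxel never fitted / invalid reference.
#' @slot mask logical 3-D kidney mask the aggregates refer to.
#' @slot metabolite metabolite name.
#' @export
setClass("ConcentrationMap",
  representation(
    values = "array",
    crlbExcluded = "array",
    concExcluded = "array",
    unfit = "array",
    mask = "array",
    metabolite = "character"
  )
)

setValidity("ConcentrationMap", function(object) {
  msg <- character(0)
  if (!identical(dim(object@values), dim(object@crlbExcluded)) ||
      !identical(dim(object@values), dim(object@concExcluded)) ||
      !identical(dim(object@values), dim(object@unfit))) {
    msg <- c(msg, "flag arrays must match the value array")
  }
  ok <- !(object@crlbExcluded | object@concExcluded | object@unfit)
  if (any(object@values[ok] < 0, na.rm = TRUE)) {
    msg <- c(msg, "retained concentrations must be non-negative")
  }
  if (length(msg)) msg else TRUE
})
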