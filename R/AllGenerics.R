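#' Accessor generics
#'
#' Small accessor family used instead of direct slot access: dwell time in
#' seconds, matrix size, voxel size/volume, frequency and ppm axes, and the
#' underlying data array.
#'
#' @param object an object of one of the package's classes.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dwellTime", function(object) standardGeneric("dwellTime"))

#' @rdname accessors
#' @export
setGeneric("matrixSize", function(object) standardGeneric("matrixSize"))

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(object) standardGeneric("voxelSize"))

#' @rdname accessors
#' @export
setGeneric("voxelVolume", function(object) standardGeneric("voxelVolume"))

#' @rdname accessors
#' @export
setGeneric("freqAxis", function(object) standardGeneric("freqAxis"))

#' @rdname accessors
#' @export
setGeneric("ppmAxis", function(object) standardGeneric("ppmAxis"))

#' @rdname accessors
#' @export
setGeneric("imageData", function(object) standardGeneric("imageData"))

#' @rdname accessors
#' @export
setGeneric("labelArray", function(object) standardGeneric("labelArray"))

#' @rdname accessors
#' @export
setGeneric("sampleCount", function(object) standardGeneric("sampleCount"))

#' @rdname accessors
#' @export
setMethod("dwellTime", "AcquisitionParams", function(object) 1 / object@spectralBandwidth)

#' @rdname accessors
#' @export
setMethod("dwellTime", "SpectralImage", function(object) object@dwell)

#' @rdname accessors
#' @export
setMethod("matrixSize", "AcquisitionParams", function(object) object@matrixSize)

#' @rdname accessors
#' @export
setMethod("matrixSize", "Trajectory", function(object) object@matrixSize)

#' @rdname accessors
#' @export
setMethod("voxelSize", "AcquisitionParams", function(object) object@fov / object@matrixSize)

#' @rdname accessors
#' @export
setMethod("voxelSize", "SpectralImage", function(object) object@voxelSize)

#' @rdname accessors
#' @export
setMethod("voxelSize", "LabelMap", function(object) object@voxelSize)

#' @rdname accessors
#' @export
setMethod("voxelVolume", "AcquisitionParams", function(object) {
  prod(object@fov / object@matrixSize) / 1000  # mL
})

#' @rdname accessors
#' @export
setMethod("voxelVolume", "SpectralImage", function(object) prod(object@voxelSize) / 1000)

#' @rdname accessors
#' @export
setMethod("freqAxis", "SpectralImage", function(object) {
  if (object@domain != "spectrum") stopf("image is in FID domain; no frequency axis")
  object@freqAxis
})

#' @rdname accessors
#' @export
setMethod("ppmAxis", "SpectralImage", function(object) {
  object@referencePpm + freqAxis(object) / object@hzPerPpm
})

#' @rdname accessors
#' @export
setMethod("imageData", "SpectralImage", function(object) object@data)

#' @rdname accessors
#' @export
setMethod("labelArray", "LabelMap", function(object) object@labels)

#' @rdname accessors
#' @export
setMethod("sampleCount", "Trajectory", function(object) length(object@kx))

setMethod("show", "AcquisitionParams", function(object) {
  cat(sprintf(
    "AcquisitionParams: %.1f T 2H-MRSI | TR %g ms, flip %g deg, delay %g ms\n",
    object@fieldStrength, object@tr, object@flipAngle, object@acqDelay
  ))
  cat(sprintf(
    "  FOV %s mm, matrix %s, %d rings | %g Hz bandwidth, %d points\n",
    paste(object@fov, collapse = "x"),
    paste(object@matrixSize, collapse = "x"),
    object@nRings, object@spectralBandwidth, object@nSpectralPoints
  ))
  cat(sprintf("  nominal voxel volume %.3f mL\n", voxelVolume(object)))
})

setMethod("show", "Trajectory", function(object) {
  if (object@degenerateCartesian) {
    cat(sprintf(
      "Trajectory (degenerate Cartesian): %d in-plane points, %d kz partitions\n",
      sampleCount(object), length(object@kzOffsets)
    ))
  } else {
    cat(sprintf(
      "Trajectory: %d rings, %d in-plane samples, %d kz partitions, kmax %.4f /mm\n",
      length(object@radii), sampleCount(object), length(object@kzOffsets), object@kmax
    ))
  }
})

setMethod("show", "SpectralImage", function(object) {
  d <- dim(object@data)
  cat(sprintf(
    "SpectralImage [%s]: %s grid x %d %s points%s\n",
    object@domain, paste(d[1:3], collapse = "x"), d[4],
    if (object@domain == "fid") "time" else "frequency",
    if (object@perCoil) sprintf(" x %d coils", d[5]) else ""
  ))
})

setMethod("show", "LabelMap", function(object) {
  counts <- tabulate(object@labels + 1L, nbins = length(object@legend) + 1L)
  cat(sprintf("LabelMap %s, voxel %s mm\n",
              paste(dim(object@labels), collapse = "x"),
              paste(signif(object@voxelSize, 3), collapse = "x")))
  cat(sprintf("  background: %d voxels\n", counts[1]))
  for (i in seq_along(object@legend)) {
    cat(sprintf("  %s: %d voxels\n", object@legend[i], counts[i + 1L]))
  }
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (converged: %s, SNR %.2f, phase %.2f rad)\n",
              object@converged, object@snr, object@phase0))
  print(object@table, digits = 4)
})

setMethod("show", "ConcentrationMap", function(object) {
  nEx <- sum(object@crlbExcluded | object@concExcluded | object@unfit)
  cat(sprintf("ConcentrationMap [%s]: %s, %d voxels flagged for exclusion\n",
              object@metabolite, paste(dim(object@values), collapse = "x"), nEx))
})
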