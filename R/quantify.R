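#' Flip-angle map by the double-angle method
#'
#' From two magnitude images acquired at nominal flip angles alpha and
#' 2 alpha (long TR), the achieved flip angle per voxel is
#' alpha = arccos(S_2a / (2 S_a)). Voxels with non-positive signal or a
#' ratio outside (0, 2) are marked invalid.
#'
#' @param imgAlpha,img2Alpha numeric arrays of equal dimensions.
#' @return list with \code{flipDeg} (degrees, NA where invalid) and
#'   \code{valid} (logical array).
#' @examples
#' doubleAngleB1(array(1, c(1, 1, 1)), array(1, c(1, 1, 1)))$flipDeg  # 60
#' @export
doubleAngleB1 <- function(imgAlpha, img2Alpha) {
  if (!identical(dim(imgAlpha), dim(img2Alpha))) {
    stopf("the two images must have identical dimensions")
  }
  ratio <- img2Alpha / imgAlpha
  valid <- is.finite(ratio) & imgAlpha > 0 & ratio > 0 & ratio < 2
  flip <- array(NA_real_, dim = dim(imgAlpha))
  flip[valid] <- acos(ratio[valid] / 2) * 180 / pi
  list(flipDeg = flip, valid = valid)
}

#' Steady-state saturation factor
#'
#' Ernst steady-state signal fraction for repeated excitation:
#' f = sin(a) (1 - E1) / (1 - E1 cos(a)), E1 = exp(-TR/T1). Used both in
#' the phantom forward model and (inverted) in concentration estimation.
#'
#' @param tr repetition time, ms.
#' @param t1 longitudinal relaxation time, ms.
#' @param flipDeg flip angle, degrees.
#' @return unitless factor in (0, 1].
#' @examples
#' saturationFactor(290, 335, 90)   # 1 - exp(-290/335)
#' ernstAngle(290, 70)              # ~89.1 deg
#' @export
saturationFactor <- function(tr, t1, flipDeg) {
  if (any(tr <= 0) || any(t1 <= 0)) stopf("TR and T1 must be positive")
  a <- flipDeg * pi / 180
  e1 <- exp(-tr / t1)
  sin(a) * (1 - e1) / (1 - e1 * cos(a))
}

#' Ernst angle
#'
#' The flip angle maximizing the steady-state signal for given TR and T1:
#' arccos(exp(-TR/T1)), in degrees.
#'
#' @inheritParams saturationFactor
#' @export
ernstAngle <- function(tr, t1) acos(exp(-tr / t1)) * 180 / pi

#' Transverse decay correction for the acquisition delay
#'
#' @param delay acquisition delay, ms.
#' @param t2 transverse relaxation time, ms.
#' @return exp(-delay/T2).
#' @export
t2Correction <- function(delay, t2) {
  if (any(t2 <= 0)) stopf("T2 must be positive")
  exp(-delay / t2)
}

#' Metabolite concentration by internal water referencing
#'
#' Converts fitted metabolite amplitudes to mM via the natural-abundance
#' HDO signal of a voxel-matched pre-tracer reference scan:
#' C = (A_met / A_water_ref) x (f_sat,w f_T2,w) / (f_sat,m f_T2,m)
#'     x (n_water / n_met) x C_HDO,
#' with the Ernst saturation factors, the delay T2-decay factors, the 2H
#' label counts and the natural-abundance HDO concentration (~13.9 mM).
#' Each correction factor can be switched off independently. The estimate
#' is invariant to any receiver scale common to both scans.
#'
#' @param ampMet metabolite amplitude (scalar or array).
#' @param ampWaterRef water amplitude of the reference scan, same shape.
#' @param relax \linkS4class{RelaxationAssumptions}.
#' @param acq \linkS4class{AcquisitionParams} (TR, flip, delay).
#' @param metabolite "glc" or "water".
#' @param correctSaturation,correctT2 apply the respective factor.
#' @return concentration in mM; NA where the reference is non-positive.
#' @export
estimateConcentration <- function(ampMet, ampWaterRef,
                                  relax = relaxationAssumptions(),
                                  acq = acqParams(),
                                  metabolite = c("glc", "water"),
                                  correctSaturation = TRUE,
                                  correctT2 = TRUE) {
  metabolite <- match.arg(metabolite)
  t1m <- if (metabolite == "glc") relax@t1Glc else relax@t1Water
  t2m <- if (metabolite == "glc") relax@t2Glc else relax@t2Water
  nm <- if (metabolite == "glc") relax@nLabelsGlc else relax@nLabelsWater
  corr <- 1
  if (correctSaturation) {
    corr <- corr * saturationFactor(acq@tr, relax@t1Water, acq@flipAngle) /
      saturationFactor(acq@tr, t1m, acq@flipAngle)
  }
  if (correctT2) {
    corr <- corr * t2Correction(acq@acqDelay, relax@t2Water) /
      t2Correction(acq@acqDelay, t2m)
  }
  conc <- ampMet / ampWaterRef * corr *
    (relax@nLabelsWater / nm) * naturalAbundanceHdo(relax)
  conc[!is.finite(conc) | ampWaterRef <= 0] <- NA_real_
  conc
}

#' Build a concentration map with exclusion flags
#'
#' @param values mM array (x, y, z) or (x, y, z, time).
#' @param mask logical 3-D kidney mask.
#' @param metabolite name.
#' @return A \linkS4class{ConcentrationMap} with all flags FALSE except
#'   \code{unfit} where values are NA.
#' @export
concentrationMap <- function(values, mask, metabolite = "glc") {
  dims <- dim(values)
  f <- array(FALSE, dim = dims)
  unfit <- array(!is.finite(values), dim = dims)
  vals <- values
  vals[unfit] <- 0
  new("ConcentrationMap",
    values = vals, crlbExcluded = f, concExcluded = f, unfit = unfit,
    mask = mask, metabolite = metabolite
  )
}

#' Apply the CRLB and concentration exclusion filters
#'
#' Flags voxels whose fit CRLB exceeds \code{crlbMax} percent (strictly
#' greater; ties are retained) and voxels whose concentration exceeds
#' \code{concMax} mM (the stomach-contamination ceiling, 5 mM = ~90 mg/dL
#' increase). Counts refer to voxels inside the map's kidney mask.
#'
#' @param conc a \linkS4class{ConcentrationMap}.
#' @param crlbMap CRLB percent array matching the value array (or NULL to
#'   skip the CRLB filter).
#' @param crlbMax CRLB threshold, percent.
#' @param concMax concentration ceiling, mM.
#' @return list with the updated \code{map} and \code{counts}: number of
#'   mask voxels flagged by each filter, total mask voxels and the
#'   surviving percentage.
#' @export
applyExclusions <- function(conc, crlbMap = NULL, crlbMax = 50, concMax = 5) {
  vals <- conc@values
  dims <- dim(vals)
  maskFull <- conc@mask
  if (length(dims) == 4L) maskFull <- array(maskFull, dim = dims)
  crlbEx <- array(FALSE, dim = dims)
  if (!is.null(crlbMap)) crlbEx <- is.finite(crlbMap) & crlbMap > crlbMax
  concEx <- vals > concMax & !conc@unfit
  conc@crlbExcluded <- crlbEx
  conc@concExcluded <- array(concEx, dim = dims)
  inMask <- maskFull & !conc@unfit
  nMask <- sum(maskFull)
  nCrlb <- sum(crlbEx & maskFull)
  nConc <- sum(concEx & maskFull)
  nAny <- sum((crlbEx | concEx | conc@unfit) & maskFull)
  list(
    map = conc,
    counts = list(
      maskVoxels = nMask,
      crlbExcluded = nCrlb,
      concExcluded = nConc,
      excluded = nAny,
      survivingPercent = if (nMask > 0) 100 * (nMask - nAny) / nMask else NA_real_
    )
  )
}

#' Convert mM to mg/dL
#'
#' @param c concentration, mM.
#' @param molarMass g/mol (glucose: 180.16).
#' @return mg/dL (= mM x molar mass / 10).
#' @examples
#' mMToMgPerDl(5)   # ~90 mg/dL
#' @export
mMToMgPerDl <- function(c, molarMass = 180.16) {
  if (any(c < 0, na.rm = TRUE)) stopf("concentrations must be non-negative")
  c * molarMass / 10
}
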