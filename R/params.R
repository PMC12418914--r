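#' Construct acquisition parameters
#'
#' Defaults reproduce the 7 T renal 2H-MRSI protocol: TR 290 ms, flip 90
#' degrees, 2.0 ms acquisition delay, 380 Hz spectral bandwidth with 96
#' points, FOV 270 x 270 x 260 mm and 47 concentric rings. The two
#' protocols of interest differ only in matrix size: 22 x 22 x 21 (about
#' 1.8 mL nominal voxel volume) and 28 x 28 x 27 (about 0.9 mL).
#'
#' @param fieldStrength tesla.
#' @param gamma2H deuterium gyromagnetic ratio, MHz/T.
#' @param tr repetition time, ms.
#' @param flipAngle degrees.
#' @param acqDelay acquisition delay, ms.
#' @param spectralBandwidth Hz.
#' @param nSpectralPoints FID points.
#' @param fov field of view, mm (length 3).
#' @param matrixSize length-3 integer matrix size.
#' @param nRings number of concentric rings.
#' @param referencePpm carrier chemical shift (water).
#' @return An \linkS4class{AcquisitionParams} object.
#' @examples
#' acq <- acqParams()
#' voxelVolume(acq)                      # ~1.84 mL
#' voxelVolume(acqParams(matrixSize = c(28, 28, 27)))  # ~0.9 mL
#' @export
acqParams <- function(fieldStrength = 7.0, gamma2H = 6.536, tr = 290,
                      flipAngle = 90, acqDelay = 2.0,
                      spectralBandwidth = 380, nSpectralPoints = 96,
                      fov = c(270, 270, 260), matrixSize = c(22, 22, 21),
                      nRings = 47, referencePpm = 4.8) {
  new("AcquisitionParams",
    fieldStrength = fieldStrength, gamma2H = gamma2H, tr = tr,
    flipAngle = flipAngle, acqDelay = acqDelay,
    spectralBandwidth = spectralBandwidth,
    nSpectralPoints = as.integer(nSpectralPoints),
    fov = as.numeric(fov), matrixSize = as.integer(matrixSize),
    nRings = as.integer(nRings), referencePpm = referencePpm
  )
}

#' Construct relaxation and labelling assumptions
#'
#' Defaults are the brain-literature values adopted for the kidney at 7 T:
#' T1 335/70 ms and T2 36/36 ms for water/glucose, 80 percent tissue water
#' content, one 2H label on HDO and two on [6,6']-2H glucose, and a
#' natural-abundance deuterium fraction of 1.56e-4.
#'
#' @param t1Water,t1Glc,t2Water,t2Glc ms.
#' @param waterContent fraction in (0, 1].
#' @param nLabelsWater,nLabelsGlc 2H atoms per molecule.
#' @param naturalAbundance deuterium fraction of hydrogen.
#' @return A \linkS4class{RelaxationAssumptions} object.
#' @export
relaxationAssumptions <- function(t1Water = 335, t1Glc = 70,
                                  t2Water = 36, t2Glc = 36,
                                  waterContent = 0.80,
                                  nLabelsWater = 1L, nLabelsGlc = 2L,
                                  naturalAbundance = 1.56e-4) {
  new("RelaxationAssumptions",
    t1Water = t1Water, t1Glc = t1Glc, t2Water = t2Water, t2Glc = t2Glc,
    waterContent = waterContent,
    nLabelsWater = as.integer(nLabelsWater),
    nLabelsGlc = as.integer(nLabelsGlc),
    naturalAbundance = naturalAbundance
  )
}

#' Natural-abundance HDO reference concentration
#'
#' The intrinsic semi-heavy water concentration used as internal reference:
#' 2 x natural abundance x 55510 mM (pure water) x tissue water content,
#' about 13.9 mM at the defaults.
#'
#' @param relax a \linkS4class{RelaxationAssumptions} object.
#' @return concentration in mM.
#' @examples
#' naturalAbundanceHdo(relaxationAssumptions())
#' @export
naturalAbundanceHdo <- function(relax = relaxationAssumptions()) {
  2 * relax@naturalAbundance * 55510 * relax@waterContent
}

# Hz per ppm at this field (numerically the carrier frequency in MHz)
hzPerPpm <- function(acq) acq@gamma2H * acq@fieldStrength

# resonance offset from carrier in Hz
ppmToHz <- function(ppm, acq) (ppm - acq@referencePpm) * hzPerPpm(acq)
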