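---
title: "Methods: simulating and quantifying renal deuterium metabolic imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulating and quantifying renal deuterium metabolic imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crtDMI)
```

## The problem

Deuterium metabolic imaging (DMI) maps the uptake of deuterium-labelled
tracers — heavy water (HDO/D2O) and [6,6']-2H glucose — by acquiring
spatially resolved 2H NMR spectra. In the kidney at 7 T, a density-weighted
concentric-ring-trajectory (CRT) readout makes dynamic 3D mapping at ~1.8
and ~0.9 mL nominal voxel volumes practical, but the data are low-SNR and
require a dedicated processing chain: non-Cartesian reconstruction, coil
combination, spectral denoising, model fitting and internal-reference
quantification. `crtDMI` implements that chain together with a digital
kidney phantom so that every stage can be validated against a known ground
truth — something in vivo data cannot provide.

## The forward model (phantom)

The phantom is a set of ellipsoidal compartments (body, left/right kidney,
optionally an anterior "stomach" contaminant) voxelized on the acquisition
grid by a deterministic center-in-ellipsoid test. Each compartment carries
per-metabolite concentration time courses (constant, saturating
`C0 + dC(1-exp(-t/tau))`, or gamma-variate
`C0 + A (t/tp)^a exp(a(1-t/tp))`), a Lorentzian linewidth and an optional
B0 frequency offset. The voxel FID is

    rho(r, t) = sum_m A_m(r) exp(i 2 pi f_m t - pi lw t),   t = delay + n dwell

with `f_m = (ppm_m - 4.8) * gamma_2H * B0` — so glucose (3.9 ppm) sits
41.2 Hz below water at 7 T — and amplitude

    A_m(r) = C_m(r, t_frame) * n_labels_m * f_sat(TR, T1_m, alpha),

the Ernst steady-state factor `f_sat = sin(a)(1-E1)/(1-E1 cos(a))`,
`E1 = exp(-TR/T1)`. Because the FID clock starts at the 2.0 ms acquisition
delay, T2*-decay over the delay is part of the simulation rather than a
separate factor. A k-space sample for coil `c` is

    d_c(k, t) = sum_r s_c(r) rho(r, t) exp(-i 2 pi k.r) dV

with smooth Gaussian coil-sensitivity profiles `s_c` (two channels behind
the back, seeded random per-coil phases) and `dV` the voxel volume in mL.
The `dV` factor makes reconstructed per-voxel amplitudes *extensive*
(proportional to voxel volume), as in real MRSI; this is what makes the
kidney *signal sum* comparable between the 1.8 and 0.9 mL protocols, and
it cancels voxel-wise in every concentration ratio. Correlated complex
Gaussian noise (per-component SD `noiseSd`, inter-channel correlation 0.2)
is added, and a noise-only block with identical statistics is attached for
covariance estimation.

### Default study conditions

The defaults encode the study regime this package emulates:

* Protocol: 7 T, TR 290 ms, flip 90 deg, 2.0 ms delay, 380 Hz bandwidth,
  96 points, FOV 270 x 270 x 260 mm, 47 rings; matrices 22x22x21 (1.84 mL
  voxels) and 28x28x27 (0.90 mL).
* Relaxation assumptions used for quantification: T1 335/70 ms and
  T2 36/36 ms (water/glucose), 80% tissue water content; natural-abundance
  fraction 1.56e-4 gives an HDO reference of
  `2 * 1.56e-4 * 55510 * 0.8 = 13.86` mM.
* Kidneys: ellipsoids with 22 x 28 x 60 mm semi-axes (~155 mL, a typical
  adult kidney), glucose peaking at 2.0 mM ~37 min after intake
  (gamma-variate), natural-abundance water everywhere; 14 Hz linewidths.
* `noiseSd = 357` (k-space units): calibrated once so that the raw
  (pre-denoise) kidney water SNR of the full default pipeline is about 7,
  the regime reported for dynamic renal DMI before denoising. At these
  settings the pipeline reproduces kidney FWHM ~14 Hz and pre-denoise
  SNR 7-9.

What the phantom does *not* emulate: respiratory/cardiac motion, B0 maps
beyond piecewise-constant offsets, Bloch-simulated excitation profiles,
spatially varying noise, and the spectral complexity of real tissue
(macromolecular background, lipid sidebands). Tests passing on this
phantom therefore validate the *processing chain*, not the biology of real
data; in vivo data are less low-rank than the phantom, so denoising gains
here (SNR can triple or more) overshoot the roughly twofold gains seen in
vivo.

## Trajectory and reconstruction

Ring radii follow the half-offset scheme `r_i = kmax (i + 1/2)/nRings`
(no ring sits at k = 0, whose angular Nyquist count would be undefined),
with `kmax = matrix/(2 FOV)` and per-ring angular counts at or above the
Nyquist number `ceil(2 pi r_i FOV)`. The kz direction uses `matrix_z`
Cartesian phase encodes. Density-compensation weights are annulus-area
weights (proportional to ring radius over angular count) times an optional
radial Hamming window, normalized to sum to one. At least `matrix/2` rings
are required, otherwise the radial spacing would exceed 1/FOV.

Reconstruction is the direct adjoint non-uniform DFT
`rho(r) = alpha sum_k w_k d_k exp(+i 2 pi k.r)` — an O(N_k N_vox) matrix
product, trivial at these matrix sizes and exactly testable. The scale
`alpha = (covered k-area) * FOV_x FOV_y / (N_x N_y)` is the standard
density-compensation area calibration: it equals 1 on the degenerate
Cartesian trajectory (where the adjoint is *exactly* the inverse FFT, the
test-suite oracle) and `pi/4` for the ring disk. On a smooth Gaussian
phantom at the full 1.8 mL protocol the adjoint inverts the forward model
with ~1.5% normalized RMSE (the uniform window is the default; the Hamming
window trades Gibbs ringing against resolution and a global scale).

Spectra are obtained per voxel by an energy-preserving DFT
(`1/sqrt(N)` convention, so Parseval holds), optional exponential
apodization and zero-filling (display only; fitting uses measured points),
and the first-order phase ramp `exp(-i 2 pi f t_delay)` that compensates
the acquisition delay — each resonance then comes out phase-pure at its
own frequency. The ppm axis is `4.8 + f/(gamma B0)`.

## Coil combination (WSVD)

Per voxel, the coil x time matrix is whitened with the inverse square root
of the measured noise covariance (Hermitian-symmetrized sample covariance
of the noise block; a ridge of `1e-6 tr(C)/n` guards against duplicated
channels), and the rank-1 SVD gives the combination. The output is
returned in raw signal units as the matched filter `w^H X / ||w||`, with
the global phase fixed so the first FID point is real-positive — a stable
convention for downstream fitting. For one coil this is the identity up to
that phase. Two equal coils with independent equal noise gain sqrt(2) in
SNR. At near-zero signal the dominant singular vector is noise-determined
and the combination cannot track the signal subspace — a known limitation
of all data-driven combinations at very low SNR.

## Denoising (tensor MP-PCA)

The dynamic stack (x, y, z, FID time, frame) is denoised patch-wise:
5x5x5 spatial patches sliding with stride 2, each unfolded sequentially
along its tensor modes (patch voxels, time, dynamics), hard-truncating
singular values at the Marchenko-Pastur rank, two sweeps, uniform
averaging of overlapping patches, on complex data so phase is preserved.
The rank rule accepts the smallest signal rank `p` whose trailing
eigenvalue spread fits inside the MP bulk width `4 sqrt((M-p)/N) sigma^2`,
with a 5% allowance for finite-size (Tracy-Widom) edge fluctuation — the
empirical 99th percentile of the spread/width ratio is 1.02-1.06 across
the unfolding shapes used here. The estimator's noise SD is reported per
real component and lands within 15% of the generator's value on image-
domain fixtures.

Two behaviours matter for interpretation. First, denoising gains grow with
dynamic redundancy — with eight frames the RMSE to noiseless truth drops
by far more than with one, which is why dynamic DMI should be denoised
jointly. Second, hard truncation slightly *shrinks* weak signal components
whose spatial structure straddles patch boundaries (the glucose rim of the
kidney): with only two frames this costs ~10% of the kidney-mean glucose
amplitude, with four or more frames ~3-4%. The reference scan is denoised
separately from the tracer frames; denoising it jointly would inflate the
water reference relative to glucose and bias concentrations low.

## Spectral fitting, CRLB, SNR

Each voxel spectrum is fitted by nonlinear least squares (Levenberg-
Marquardt with box bounds) against a phased sum of analytic singlets plus
a constant complex baseline:

    S(f) = e^{i phi} sum_m A_m L(f; f_m + delta_m, lw_m) + b

with `|delta| <= 20` Hz and `lw` in 2-50 Hz. The model FID is transformed
with the *same* delay-corrected DFT as the data, so the fit lives in
measured-point space and the Lorentzian width parameter is exact (no
wrapped-lineshape bias at the 380 Hz bandwidth). An analytic basis is
appropriate because 2H singlets at 7 T show no resolvable J-structure at
14 Hz linewidths; a Voigt option adds a Gaussian width per resonance.
There is no first-order phase term (the delay is handled in
reconstruction) and no spline baseline (2H spectra have no macromolecular
background).

CRLBs come from the Fisher information `J = Re(G^H G)/sigma^2` of the
model Jacobian, where `sigma` is the noise SD of the residual's real part
in a window at least 100 Hz from every resonance (subtracting the fitted
tails keeps strong peaks from inflating the noise floor; without this the
CRLB overestimates the empirical scatter by ~50% at high SNR). Parameters
the model is insensitive to — the shift and width of a zero-amplitude
resonance — are dropped from the information matrix before inversion.
Across 200 noise realizations the mean reported amplitude CRLB matches the
empirical SD within a few percent. SNR is the fitted water peak height
over that same noise SD; the raw-peak variant is available as
`snrEstimate()`.

## Quantification

Concentrations use internal referencing to the natural-abundance HDO
signal of the voxel-matched pre-tracer reference scan:

    C_met = (A_met / A_water_ref)
            * (f_sat,w f_T2,w) / (f_sat,m f_T2,m)
            * (n_w / n_m) * C_HDO,

with `C_HDO = 13.86 mM`, label counts 1 (HDO) and 2 ([6,6']-2H-glucose),
Ernst saturation factors and `exp(-delay/T2)` decay factors (each
switchable so tests can verify them independently; with equal water and
glucose T2 of 36 ms the T2 factor cancels). The estimate is invariant to
any receiver scale common to both scans. For D2O experiments, where water
itself is the tracer, maps stay in arbitrary units. B1+ maps from the
double-angle method (`alpha = arccos(S_2a/2S_a)`) are diagnostic only and
not applied voxel-wise, mirroring the protocol's single-reference-voltage
choice. Exclusion filters flag voxels with amplitude CRLB strictly above
50% (ties retained) and glucose above 5 mM (~90 mg/dL increase, the
stomach-contamination ceiling); counts are integer-deterministic.

End-to-end, a phantom with 2.0 mM kidney glucose processed through the
full default chain (6 frames at the 1.8 mL protocol) is recovered at the
kidney-mask mean within 10%. The residual ~7% low bias is partial-volume
physics: the point-spread function spills glucose signal out of edge
voxels while the water reference (present body-wide) stays locally flat.
The same effect — and the same order of magnitude — underlies the
underestimation that internal-reference DMI reports in vivo.

## Dynamics and statistics

Kidney aggregates use the mask mean/SD, or the sum when comparing across
resolutions (the extensive amplitudes make the sum a volume integral).
Fold changes are relative to the first (baseline) frame; the coefficient
of variation is `100 * sd/mean` with the sample SD. Group comparisons wrap
the standard implementations: Friedman's chi-square on within-block ranks
(fully tied blocks return statistic 0, p = 1), the paired t-test, and
Benjamini-Hochberg step-up adjustment. Frame time stamps default to
acquisition midpoints of ~8.5 min frames.

## Problem sizes and reproducibility

Unit and property tests run on reduced geometries (8-16 voxel grids,
24-48 spectral points); the acceptance-style checks exercise the full
22x22x21 / 96-point protocol with 6-8 dynamic frames, which one CPU
processes in a few minutes per stage. All randomness flows from explicit
integer seeds: a phantom (seed, frame index) pair reproduces k-space
bit-identically.
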