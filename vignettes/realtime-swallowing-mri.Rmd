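---
title: "Real-time 3D stack-of-stars MRI of swallowing: models, simulation and reconstruction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Real-time 3D stack-of-stars MRI of swallowing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(starstack)
```

## The problem

Swallowing disorders (dysphagia) are conventionally assessed with X-ray
videofluoroscopy, which projects all anatomy onto a single plane and exposes
the patient to ionising radiation. Real-time MRI is a radiation-free
alternative, but a single 2D slice can miss aspiration occurring outside the
imaged plane. Imaging a thin 3D slab in real time requires aggressive
undersampling: at 2 x 2 x 6 mm resolution with seven sagittal slices, only
six radial spokes per slice can be acquired per frame if the displayed frame
rate is to reach 12 fps after sliding-window doubling.

This package implements that acquisition-and-reconstruction chain at desk
scale: trajectory design, point-spread-function (PSF) analysis, multi-coil
k-space simulation from a dynamic digital swallowing phantom,
compressed-sensing reconstruction, and the quantitative swallowing metrics.
Because no scanner data ships with the package, a synthetic phantom with
exhaustive analytic ground truth stands in for the volunteer, and every
pipeline stage is validated in closed loop against that truth.

## Sampling patterns

A stack-of-stars (SOS) trajectory samples radial spokes in the kx-ky plane
and phase-encodes the slice direction kz on a Cartesian grid. One *star* is
one pass over all kz partitions. Four patterns are implemented:

* **ASOS** (aligned): all kz partitions of a star share one azimuth; the
  azimuth advances by the golden angle between stars.
* **RSOS-psi1** (rotated, golden angle): the azimuth advances by
  `tiny_golden_angle(1)` = 111.25 degrees at *every* readout, continuing
  seamlessly from the inner kz loop into the next star.
* **RSOS-psi9** (rotated, tiny golden angle): the same construction with
  `tiny_golden_angle(N)` = 180/(tau + N - 1) degrees, tau the golden ratio.
  Choosing N equal to the kz count (9 for seven slices with 1.28 slice
  oversampling, psi9 = 18.71 degrees) keeps the spokes evenly distributed
  while making the gradient jumps - and hence eddy-current excitation -
  an order of magnitude smaller.
* **RSOS-GR**: a simulation-only comparator with uniform in-plane spacing
  per partition and a golden-ratio-derived per-partition offset. The
  original scheme's rotation rule is published only qualitatively, so ours
  is a documented convention; because its angles depend on the spoke count
  it is rejected for sliding-window reconstruction.

The kz partitions are visited in linear ascending order inside a star; this
inner-loop order is the simplest convention consistent with "kz fully
sampled for each angle" and is recorded in the schedule, which stores
azimuths modulo 360 degrees (spokes are full diameters, and opposed spokes
must remain distinguishable for gradient-delay estimation).

## PSF incoherence

For compressed sensing, aliasing should look like noise. Mirroring the acquisition
protocol's geometry, `compute_psf()` transforms unit samples on a
trajectory (256 readout samples, 9 kz partitions) with the adjoint gridding
NUFFT and `incoherence()` divides the central-peak magnitude by the standard
deviation of the side-lobe magnitudes. Two conventions that the incoherence definition leaves
open are fixed here and switchable: ramp density compensation (|k| with a
quarter-sample DC weight) is applied so a fully sampled trajectory
approaches a delta PSF, and the side-lobe region excludes a 1-voxel ball
around the peak, with the scalar computed on the full 3D volume using
magnitudes. `sweep_incoherence()` reproduces the qualitative result that all
rotated patterns beat the aligned pattern (at six spokes per slice the
rotated-to-aligned ratio is about 1.7), with the continuous golden-angle
variants marginally ahead below 18 spokes per slice.

## The gridding NUFFT

No NUFFT library exists in this R environment, so the package carries its
own: Kaiser-Bessel gridding on a 2x oversampled grid with a width-8 kernel
(Beatty beta), an FFT-derived deapodization that exactly inverts the
discrete spreading, and a cached fine lookup table for the kernel. Because
kz is Cartesian in a stack-of-stars, the slice direction uses exact centred
FFTs; only the in-plane transform is approximate. The width-8 kernel keeps
the relative error against direct DFT summation below 1e-6 (asserted in the
tests on 32 x 32 x 3 instances), and the forward/adjoint pair are exact
numerical transposes by construction, which the conjugate-gradient and
proximal solvers rely on.

## Forward model and hardware imperfections

`simulate_kspace()` samples the forward transform of (object x coil map)
per scheduled event, using the phantom frame nearest in time (no intra-spoke
motion). Complex Gaussian noise follows a Hermitian positive-definite coil
covariance. Two imperfections are modelled as shifts of the sampling
positions along the readout:

* a global **gradient delay** of a configurable number of samples;
* an **eddy-current** error proportional to the azimuthal jump from the
  previous event.

The eddy model needs a word of justification. A scalar phase per event
proportional to the jump would be a global gauge for the constant-increment
rotated patterns (every jump is 111.25 degrees in RSOS-psi1) and could not
degrade their images at all. The standard first-order picture of
eddy-current errors in radial imaging is a k-space displacement along the
readout - equivalently a linear phase across the spoke - so the per-event
error is implemented as a shift of `eddy_coupling` samples per degree of
jump. With it, ASOS (which only jumps at star boundaries, one event in nine)
is barely affected while RSOS-psi1 shifts every spoke, reproducing the
experimentally observed quality reversal; RSOS-psi9's jumps, 5.9 times
smaller, sit in between. The model is heuristic and off by default.

## Reconstruction

The chain is the standard one for this acquisition regime: noise pre-whitening (eigen-based,
since the covariance is complex Hermitian), gradient-delay correction from
the phase slope of opposed-spoke cross-spectra, coil sensitivities from the
central 15% of k-space normalised by root-sum-of-squares (a deliberate
simplification of ESPIRiT; the interface accepts any `sensitivity_maps`
object, so a full implementation can be plugged in), CG-SENSE on the
density-weighted normal equations for the fully sampled reference, and for
the real-time series `cs_recon()`, which minimises

    0.5 || W^(1/2) (E x - y) ||^2
      + lambda_llr  * sum_patches || Casorati(patch, t) ||_*
      + lambda_tv   * || grad_t x ||_1

with defaults lambda_llr = 0.001 and lambda_tv = 0.005. The choice of
regularisers is standard for real-time radial imaging; the solver and the
data scale are the package's own choices: data are normalised so the peak
magnitude of the (amplitude-fitted) gridded initialisation is 1, the locally
low-rank term acts on 8 x 8 in-plane patches stacked over time with a
seeded random cyclic shift per iteration, the temporal total-variation prox
is solved exactly per voxel (Condat's direct 1D algorithm, applied to real
and imaginary parts), and the solver is proximal-gradient with FISTA
momentum, adaptive restart and step halving, so the logged objective is
non-increasing. Thirty outer iterations with a 1e-4 relative-change
tolerance are the default budget. Regularisation weights are flagged as
scale-dependent: on data normalised differently they would need rescaling.

`sliding_window()` reconstructs the series twice, independently, with the
second run's bins offset by half a frame of events, and interleaves frames
by acquisition midpoint - no blending - doubling 6.2 fps to the reported
12 fps. `flat_field()` divides a volume by its own wide-Gaussian-blurred
copy (sigma 32 mm by default; "wide" is otherwise unspecified) with a
1e-3-of-peak floor guarding the empty background.

## The digital phantom and what it does (not) show

`dynamic_swallow_phantom()` renders a midsagittal slab in which a
hyperintense 20 mL bolus (exactly 833 voxels at 0.024 mL/voxel) travels from
the oral cavity through the pharynx into the oesophagus, a laryngeal marker
rises by exactly 20 mm, and the mandible-hyoid distance shortens by exactly
25% - the plausibility scale of published volunteer measurements. Motion
occupies a 2.2 s window; displacement profiles are raised bumps saturated at
their peak for the central fifth of the swallow, reflecting that laryngeal
elevation is *held* during pharyngeal transit rather than touched for a
single frame. The bolus path is kept clear of the landmark markers so that
centroid tracking on reconstructions is unambiguous; the static phantom's
texture is band-limited to the radially sampled k-space disk (smoothed
speckle, raised-cosine body edge) so that a Nyquist-sampled acquisition can
represent it - a real object imaged by the same scanner is subject to the
same truncation.

What passing the closed-loop tests shows: the trajectory, forward model,
solvers and metrics are mutually consistent and recover programmed motion
through 33-fold per-frame undersampling. What it does not show: performance
on real tissue contrast, through-plane motion, B0 inhomogeneity,
relaxation effects (TE and flip angle are metadata only; the signal model is
proton-density-like) or rater variability - none of which the phantom
emulates.

## Measurement conventions

The swallowing metrics operate on landmark tracks and bolus masks, as the
original measurements were manual; automating segmentation would be
unvalidatable against a single human rater. For closed-loop validation the
package provides `track_blob()` - an intensity-weighted centroid in a moving
search window, refined within each frame by mean-shift re-centring (capped
at half the window radius so the tracker cannot climb onto a brighter
neighbouring structure), with an optional 3-frame running median standing in
for the temporal judgement a human rater applies - and
`estimate_bolus_volume()`, a
partial-volume integral estimator: blurring conserves the intensity
integral, so summing background-subtracted, plateau-normalised intensity
over a region of interest is unbiased under reconstruction smoothing, unlike
a thresholded voxel count. Duration counts frames between the last
pre-swallow stationary state and the first return to stationary; additional
clearing swallows are excluded by construction. "Middle slice" is slice
`floor(n_slices / 2)` of the prescribed slab.

Two conventions in the validation protocol deserve emphasis. Frames are
flat-fielded before tracking, exactly as the in-vivo pipeline flat-fields
its reconstructions: without it, an unlucky coil configuration can starve a
landmark of contrast and let its tracker drift onto an artefact. And the
smoothing policy differs by measure: laryngeal elevation is a *peak*
displacement, which temporal smoothing systematically erodes, so its track
is used raw (the capped mean-shift already suppresses outliers); submental
contraction is an extreme deviation of the *difference* of two tracks, whose
noise is doubled, so both landmark tracks are median-smoothed over three
frames. The bolus volume is integrated on the unfiltered reconstruction,
because the flat-field division is nonlinear and would break the
integral-conservation argument the estimator rests on.

## Numerical and scale choices

Problem sizes in the tests and the acceptance script are the package's
desk-scale defaults: matrix 64 (128 readout samples) for reconstruction
loops, matrix 32 for oracle comparisons, the protocol's 256-sample readout
and 9 kz partitions for the PSF study, 4-8 simulated coils, and a 5 s
dynamic series at the native 6.17 fps. At these sizes the full suite runs in
minutes on one CPU while every qualitative conclusion - incoherence
orderings, the eddy-current quality reversal at 7 slices, the rotated
pattern's advantage at 21 slices, and parameter recovery within one voxel /
3 percentage points - is reproduced. One scale-dependent caveat: at 27 kz
partitions the tiny-golden-angle variant with order equal to the kz count
advances only ~5.3 degrees per kz plane, so its per-plane coverage builds up
over many frames; in short desk-scale runs the golden-angle rotation
(RSOS-psi1) is the variant that demonstrates the clean-hardware advantage
over ASOS at 21 slices.

Printed scanner SSIM values are deliberately not asserted anywhere: they
depend on the authors' raw data. Reconstruction quality comparisons in this
package use a clean (eddy-free, fully sampled, CG-SENSE) reference of the
same simulated object, since in simulation the ground truth is available
and the scientific question is about the undersampled reconstruction, not
the reference.

## Known limitations

* The RSOS-GR comparator is a documented convention, not the published
  scheme, whose rotation rule is unavailable in formula form.
* Sensitivity estimation is a low-resolution rSOS ratio, not ESPIRiT.
* No Toeplitz embedding, GPU path, or slice-parallel reconstruction.
* The eddy-current model is first-order and uncalibrated against hardware.
* The k-space container is R-native serialization (no HDF5 binding is
  available in this toolchain); the layout is versioned and validated, and
  schedules also round-trip through plain CSV.
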