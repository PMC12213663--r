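---
title: "Multi-scale cryo-CLEM registration: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale cryo-CLEM registration: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cryoclem)
```

## Scope and model

`cryoclem` registers cryo-fluorescence images of vitrified specimens onto
cryo-EM montage maps and tomogram z-projections through fiducial markers
at three scales, and evaluates morphometric criteria for calling a
structure a synapse under cryo conditions. It consumes reconstructed
tomograms and already-acquired images; motion correction, tilt-series
alignment, reconstruction, missing-wedge recovery and segmentation are
upstream tools' jobs and are out of scope.

### Coordinate convention

One convention everywhere: 0-based pixel indices, a point `(x, y)` is
`(column, row)`, origin at the **center** of the top-left pixel. Stating
this once and testing against it avoids the classic half-pixel
registration bug when moving between image libraries. Reflections (a grid
imaged mirrored in one modality, which happens routinely between LM and
EM) are permitted in similarity and affine fits and recorded through the
sign of the determinant.

### Transform models

All stages fit planar transforms by weighted least squares:

* `translation` (1+ pairs), `rigid` (2+), `similarity` (2+) via the
  closed-form orthogonal-Procrustes solution with isotropic scale,
* `affine` (3+ non-collinear pairs) via normal equations on centered
  coordinates.

The **default model for both correlation stages is similarity**
(rotation + isotropic scale + translation + optional reflection). The
optical-to-EM relation is dominated by magnification and rotation, and a
similarity needs only two points — relevant when as few as six gold
particles are available. An affine option exists for operators who suspect
anisotropic distortion. The original workflow this reimplements did not
state the transform family its scripts fit, so the model is an explicit
user choice rather than a guess baked in.

The **channel-shift default is affine**: chromatic shift varies across the
field of view, and the calibration bead set (default 20 beads) easily
constrains six parameters.

### Error reporting

Each fit reports the fiducial registration error (FRE, the RMS residual
norm) and leave-one-out target registration error estimates (LOO TRE):
each marker's prediction error under the fit made from all other markers.
LOO TRE is the reported precision proxy because it is assumption-light and
honest about small-N optimism; the full anisotropic TRE theory is out of
scope. For iid Gaussian noise of sd σ in the target frame,
`E[FRE_rms] ≈ σ·√(2(1 − dof/2N))`; the test suite verifies the measured
mean to within 10% at the six-marker fine-stage minimum, and verifies that
mean LOO TRE ≥ mean FRE.

A robust (RANSAC-style) variant guards against a mis-picked marker:
minimal samples, consensus maximization at a residual gate, then a
least-squares refit on the consensus. The seed is a required argument and
the sampler leaves the session RNG untouched — reproducibility is not
optional. Consensus must exceed the model minimum by at least one point;
an exact-interpolation consensus proves nothing.

### Matching

With an initial transform, correspondences are mutual nearest neighbours
under that transform within a gate. Without one, an exhaustive hypothesis
search over source/target point pairs proposes two-point similarity
alignments (both handedness variants) and keeps the hypothesis with the
largest consensus, ties broken by total distance. This is quadratic in
both set sizes and is deliberately capped at 30 points per side — marker
sets in this workflow are 6–15 points, and a cap converts a quadratic
blow-up into an actionable error message. The workflow keeps at most the
30 strongest detections per side before matching: genuine gold outscores
bead-edge responses at the gold scale in the band-pass detector.

## Fiducial detection

Detection is a band-pass (difference-of-Gaussians) blob response tuned to
the expected marker diameter, local-maximum extraction, close-pair
suppression (higher score wins; equal scores keep the smaller (row,
column)), and sub-pixel refinement. Dark EM markers are handled by
negating the response, never by mutating the input, so dark detection on
an image and bright detection on its negation agree to machine precision.

Two refinement options:

* `"gaussian"` (default): least-squares fit of a radial Gaussian with free
  amplitude, background and width. The center of any radially symmetric
  marker — a PSF-limited spot or a soft-edged disc — is recovered without
  bias; the width parameter absorbs the profile shape. On noiseless
  rendered scenes this localizes to better than 0.05 px, which is what
  lets the end-to-end chain close at the sub-tomogram-pixel level.
* `"centroid"`: iterated background-subtracted centroid, cheaper and
  adequate at moderate SNR, but biased when a neighbouring marker's tail
  enters the window.

Two detection gates are applied: a threshold relative to the maximum
response (default 0.25) and a noise floor of 8 robust standard deviations
(MAD) of the band-pass response. The relative threshold alone cannot
separate weak true markers from noise maxima on an image that contains
markers; the absolute floor pins the false-positive rate (the test suite
requires ≤ 1 per 10⁶ pixels at peak SNR ≈ 10 while holding recall ≥ 99%).

A marker whose expected diameter falls below one pixel at the image's
pixel size is refused with a pointer to use a higher magnification — the
same physics that makes 10 nm tracer gold invisible on a montage.

## The synthetic scene generator

The generator emulates the imaging hierarchy so that every stage can be
tested against exact ground truth. Its defaults are the study conditions:

| parameter | default | basis |
|---|---|---|
| FM pixel | 160 nm | 100× objective onto a ~16 µm camera pixel; plausible for the 0.8 NA air objective used on cryo-stages (no pixel size is published for that system — documented assumption) |
| PSF FWHM | 400 nm | ~λ/2NA for a 0.8 NA air objective; 200 nm beads render as PSF-limited spots of size `max(diameter, FWHM)` |
| montage pixel | 4.0 nm | mid-magnification (3600×) montage scale |
| tomogram pixel | 0.5432 nm | the tomographic pixel size of the emulated acquisitions |
| beads | 8–15 | the coarse-stage marker count range |
| 50 nm gold | 6–15 | the fine-stage marker count range |
| bead separation | ≥ 1000 nm | ≥ 2 rendered FM spot diameters, the regime where detection is reliable |
| gold separation | ≥ 150 nm | ≥ 1.5 detection footprints in the tomogram projection |
| tracer clearance | 100 nm from 50 nm gold | markers are ultrasonically dispersed before freezing to prevent clustering; a tracer particle inside a gold's refinement window would bias localization |

Frame sizes default to a 96 px fluorescence frame, 2048 px montage and
2048 px tomogram projection. These are crops of real acquisition formats,
chosen so a full detection-driven pipeline runs in seconds; all sizes are
spec fields, and smaller frames are used in tests that exercise I/O rather
than detection. The 3D tomogram renderer refuses volumes above 5·10⁸
voxels; its role is testing the z-projection, not producing full-size
tomograms.

EM contrast places dark markers on a brighter background, matching
density contrast in cryo-EM. Noise is Poisson shot noise plus Gaussian
read noise of sd `noise_sigma × amplitude` in fluorescence, and Gaussian
plus correlated texture in EM. Peak SNR is defined as
`A / √(A + B + (noise_sigma·A)²)` for amplitude `A` over background `B`.
The generator makes no attempt at TEM image formation physics (CTF, dose,
phase plate); what passing tests show is that the *geometry* pipeline is
correct and noise-stable, not that the detector would perform identically
on real micrographs.

All randomness flows from the single spec seed through a private RNG that
never touches the session's `.Random.seed`.

### Noise convention for the closure study

The statistical closure study perturbs each registration stage's
correspondences with iid Gaussian noise **in that stage's target frame**
(montage pixels for the coarse stage, tomogram pixels for the fine stage).
This is the convention under which the FRE noise law
`σ·√(2(1 − 2/N))` is exact, so one convention serves both studies. Under
it, 0.5 px of measurement noise per stage leaves the mapped probe point
within 50 nm — the scale of the fine marker itself — in well over 95% of
scenes. Source-frame noise would additionally propagate through the
~40× fluorescence-to-montage magnification; users with large
fluorescence-side localization errors should read the reported LOO TRE,
which captures whatever error is actually in their picks.

## Morphometry

All distances are computed in nm, converting from pixels on entry, so
measurements from images of different magnification are directly
comparable.

**Cleft width**: the presynaptic trace is resampled at a fixed arc-length
step (default 2 nm); at each sample the width is the distance along the
local normal to the nearest crossing of the postsynaptic trace, searching
both sides of the line. Tangents are central differences, with
second-order one-sided differences at the ends (a first-order end
difference biases the normal by half a step — visible as a 10⁻⁴ nm error
on analytic phantoms). Samples whose normal misses the other trace are
dropped and counted. Intersecting traces are an error, detected by
grid-binned exact segment tests.

**Vesicle states**: the gap `s` = (signed distance from vesicle center to
the presynaptic trace) − radius partitions into
`docked_or_primed` (s ≤ 2 nm), `tethered_candidate` (2 < s ≤ 10 nm) and
`free`. The 10 nm bound encodes the observation that vesicle–membrane
tether filaments are mostly shorter than 10 nm; the 2 nm contact bound is
a conservative annotation-noise allowance. Both are config-overridable and
flagged in reports as motivated-not-measured. Ω-shaped fusing profiles and
fully collapsed vesicles cannot be derived from a circle-plus-polyline
model, so they are annotation flags honored by the classifier. Presynaptic
traces are digitized with the cytosol to the left of travel; a vesicle
center more than one radius beyond the membrane on the extracellular side
is an inconsistent annotation and errors.

**Identification criteria**: (1) two opposed membranes with strong
vesicle-count asymmetry (defaults: ≥ 5 presynaptic vesicles, post/pre
ratio ≤ 0.25); (2) at least one attached vesicle (tethered, docked/primed
or fusing); (3) mean cleft width within 15–25 nm with coefficient of
variation ≤ 0.25 **and** electron densities present in the cleft. Density
detection from raw tomograms is out of scope, so that last item is an
externally supplied boolean. The width window is centered on the ~20 nm
uniform cleft reported under cryo conditions; all thresholds are
parameters of `morphometry_thresholds()`.

## Numerical choices

* Similarity/rigid fits use the SVD sign convention that permits
  reflections when `allow_reflection = TRUE` (default); rank-deficient or
  coincident configurations raise errors naming the problem.
* Warping is inverse-mapped bilinear interpolation; out-of-source pixels
  take a fill value (default 0) and a validity mask rides along as an
  attribute so overlay normalization never mixes fill with signal. An
  epsilon of 10⁻⁹ px keeps exact-edge samples valid under rounding.
* The eight dihedral orientation variants carry exactly constructed
  integer transforms (not fitted ones), so orientation round-trips are
  bit-exact.
* TIFF float samples are stored scaled into [0, 1] (libtiff leaves values
  outside that range undefined) with the scale recorded in a JSON sidecar;
  MRC files are written mode 2 with the voxel size in the header.
* Minimum-separation placement uses bounded rejection sampling and errors
  when the requested density is infeasible, rather than silently clumping.

## Problem sizes used in validation

The shipped validation suite runs, per check: 1000 random instances for
exact recovery and for closed-form-vs-oracle agreement (the oracle is an
exhaustive rotation grid with per-angle linear solves, refined by 1D
optimization — it shares no code with the Procrustes path); 2000
repetitions per noise level for the FRE law; 500 rendered scenes for
detection performance; 500 trials for robust fitting; one full
image-driven pipeline run plus 500 coordinate-level scenes for closure;
and 30 phantoms per morphometry property. These sizes make the Monte-Carlo
standard errors comfortably smaller than the tolerances being asserted.

## Known limitations

* Correlation is 2D: fluorescence is mapped onto a tomogram z-projection
  or slice, not into the volume. Axial assignment remains the operator's
  judgement, as in the manual workflow.
* The exhaustive matcher assumes the two marker sets overlap
  substantially; with fewer than three true common markers it errors.
* The detector is tuned for roughly isotropic blob-like markers; rod-like
  contaminants can produce paired edge responses (mitigated by the
  strongest-N cap and robust fitting, not eliminated).
* The synthetic EM background is statistically simple; detector thresholds
  transfer to real data only after checking the response histogram.
* Criteria defaults encode one laboratory's observations; they are
  starting points for configuration, not biological constants.
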