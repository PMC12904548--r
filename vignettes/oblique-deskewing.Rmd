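---
title: "Oblique-compensation acquisition and de-skewing: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Oblique-compensation acquisition and de-skewing: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mesodeskew)
```

# The imaging problem

Mesoscale selective-plane illumination microscopes (mesoSPIM-style
instruments) image cleared tissue by sweeping the sample through a static
light sheet along the detection axis. They are built for bulk specimens;
thin vibratome-cut slices are mechanically fragile and laterally extended,
so they are instead sandwiched between refractive-index-matched slides and
mounted at an angle $\theta$ (typically $45^\circ$) between the slice plane
and the detection axis. That mounting creates the problem this package
models: a plain $z$ scan of a tilted slice produces a *sheared* raw volume
in which the in-focus content drifts across the camera by
$z_s \tan\theta / p$ pixels per frame ($z_s$ the stage step, $p$ the pixel
pitch at the sample). De-skewing such a volume computationally requires
padding and a rotation, which inflates file sizes and processing time.

The alternative implemented here is *oblique-compensation acquisition*: a
coupled stage motion that adds a lateral step

$$x_s = n\, z_s \tan\theta$$

to the $n$-th frame's axial step $n z_s$. At $\theta = 45^\circ$ this
simplifies to $x_s = z_s$. The compensation cancels the apparent drift of
the in-focus content, so the slice stays centred on the camera; the raw
stack can then be cropped to its content *before* any resampling, and the
remaining reconstruction is a lossless axis permutation (the 90-degree
reorientation), one scaling along the slab normal and one shear in the
slab plane.

# Coordinate model

Stacks are indexed `(plane, row, column)`, 0-based and voxel-centred:
planes are frames (raw) or $z'$ sections (reconstructed), rows are camera
$y$, columns camera $x$ or $x'$. The laboratory frame is
$(x, y, z)$ with the light sheet at $z = 0$ and $z$ along the detection
axis; the sample frame is $(x', y, z')$ with $x'$ in the slice plane and
$z'$ along the slab normal. Their planar components are related by the
self-inverse orthogonal block

$$\begin{pmatrix} x \\ z \end{pmatrix} =
  \begin{pmatrix} \sin\theta & \cos\theta \\ \cos\theta & -\sin\theta
  \end{pmatrix}
  \begin{pmatrix} x' \\ z' \end{pmatrix},$$

applied after removing the per-frame stage translation. The sign of the
compensating motion (`scan_sign`) is fixed to $+1$, the choice under which
in-focus content recorded in any frame lands at camera
$x = z'/\cos\theta$ — the centring property. A camera whose $x$ axis runs
against the stage corresponds to `scan_sign = -1`. The handedness of $z'$
is a documentation-level convention; all quantitative outputs are
invariant under flipping it.

Two consequences of the model that the tests pin down at $45^\circ$: the
in-plane advance per frame is $\sqrt{2}\, z_s$ along $x'$, and camera $x$
samples $z'$ at a pitch of $p/\sqrt 2$.

A distinction worth stating because it is easy to get backwards: the
centring property concerns *in-focus content*. A blurred point emitter is
physically stationary in camera $x$ under a plain $z$ scan and *moves*
under the compensated scan (the stage displaces it laterally while the PSF
still shows it); what the compensation fixes is where content is when the
sheet actually intersects it. The simulator reproduces both behaviours and
the test suite asserts the in-focus version.

## Reconstruction transforms

`build_affine()` derives, from first principles, the voxel-index affine
transform from raw indices $(n, j, i)$ to an output grid in sample
coordinates, and both reconstruction paths use it:

* standard shear: the linear part contains a rotation block (rotation +
  scaling); nothing can be cropped beforehand, because the sheared
  acquisition leaves wedge-shaped empty regions that only the transform
  untangles;
* oblique compensation: after the axis permutation that sends camera $x$
  to the $z'$ plane axis (folded into the matrix, never resampled), the
  linear part is a scaling plus a single shear term, and content-free
  camera-$x$ margins are cropped first (`crop_to_content()`, bit-exact on
  the retained region, default threshold 0 with a 2-pixel guard — the
  simulated background is exactly zero; real data need a positive
  threshold).

The default output grid uses the native pitches
$(z'\!: p\cos\theta,\; y\!: p,\; x'\!: z_s/\cos\theta)$ — at $45^\circ$,
$(p/\sqrt2, p, \sqrt2 z_s)$ — to avoid unnecessary interpolation; an
isotropic grid is available. The output origin is snapped to integer
multiples of the pitch so reconstructions of one sample under different
scan modes land on a common lattice and can be compared voxel by voxel.
The output shape is the tight bounding box of the eight transformed input
corners; the snap and the bounding box use a $10^{-9}$ relative tolerance
so that exactly representable corners (for example at
$\theta = 90^\circ$) do not fall to the wrong side of a voxel boundary.

Resampling is inverse-mapped trilinear interpolation with zero fill
(implemented in C++), the standard artifact-minimal choice that is
testable against closed forms: identity and integer shifts are exact, a
rotated Gaussian ball keeps its centre and width to within 1%, and
interior flux is conserved to better than 0.5%. Reconstruction keeps
float32-style numeric data internally; 16-bit export states its scaling
in the sidecar metadata. Byte accounting always uses voxel count times
nominal dtype size, because container overhead is format-specific and
would not compare across modes.

The determinant of the index transform equals the ratio of input to
output voxel volumes, which gives a closed-form padding estimate:
`padding_fraction` $= 1 - N_{in}\lvert\det A\rvert / N_{out}$. The
`predict_shapes()` overhead calculus reuses `build_affine()` itself, so
predicted shapes agree bit-exactly with what the resampler produces.

# The synthetic-data generator

No raw microscope data accompany the method, so the package ships a
first-class simulator whose defaults encode the study conditions:
sub-resolution beads of 1 µm FWHM-equivalent diameter, and nuclei whose
per-axis FWHM-equivalent extents are drawn uniformly from 5–15 µm (the
typical cardiomyocyte/fibroblast nuclear size range), placed uniformly in
a slab whose $z'$ extent plays the role of the nominal slice thickness.
The acquisition samples at $z_s = 1$ µm steps and $p = 1.31$ µm pitch at
$45^\circ$ unless configured otherwise, matching the instrument regime the
geometry defaults describe. Bead density and signal-to-noise are not
reported quantities anywhere we could anchor them, so fixtures choose
sparse fields (tens to hundreds of beads) at peak SNR of order 20–50.

Objects are Gaussian blobs with the stated FWHM-equivalent extents rather
than rasterised ellipsoids. The reason is numerical: a Gaussian object
convolved with the Gaussian PSF has an exact closed form, so rendered
stacks carry no rasterisation aliasing, flux is conserved across scan
modes by construction (tested to 0.5%), and the quadrature law
$\mathrm{FWHM}_{meas}^2 = \mathrm{FWHM}_{obj}^2 + \mathrm{FWHM}_{PSF}^2$
holds exactly, giving the nuclei module a sharp oracle. Each frame is
evaluated as a $z$-weight times a separable conditional Gaussian in camera
$x$ and $y$; object tilt (restricted to the $x'$–$z'$ plane) and the
mounting angle introduce an $x$–$z$ covariance handled through the
conditional mean, so obliquely imaged objects show the physically correct
tilted streaks.

The PSF is an anisotropic Gaussian specified in the *laboratory* frame,
with two scalar knobs:

* `astigmatism_delta` multiplies the $x$ width, emulating the lateral
  asymmetry that stressed mounting slides induce;
* `mode_axial_inflation` multiplies the $z$ width in standard-shear
  acquisitions only. It is the single knob emulating the axial-resolution
  penalty of sweeping the tunable-lens focus across the whole field,
  rather than the confined central region the compensated scan allows. No
  sheet-profile model (waist, confocal parameter, sweep waveform) is
  attempted — nothing in the available material constrains one.

Noise is shot noise (Poisson at a configurable photon scale), additive
Gaussian read noise and a constant offset, all driven by one seed; the
whole simulation is bit-reproducible from the configuration seed.

## What the generator does *not* emulate

Stripe and shadowing artifacts, refractive-index aberration fields,
photobleaching, spatially varying PSFs, stitching registration error
(tile offsets are exact by construction), chromatin texture inside
nuclei, and nucleus splitting/touching morphology. Passing tests therefore
demonstrate that the geometry, reconstruction and measurement chain is
self-consistent and detects configured effects at realistic sizes — not
that segmentation or fitting would reach the same accuracy on real tissue,
where background, texture and artifacts dominate the error budget.

# Measurement conventions

**Beads.** Candidates are 26-neighbourhood intensity maxima above a
threshold, non-max-suppressed at a minimum separation (brighter wins,
exact ties to the lower linear index). Each bead is measured in a window
(default six times the expected FWHM per axis) by an intensity-weighted,
background-subtracted centroid refinement followed by three axis-aligned
Gaussian-plus-offset least-squares fits — 1D profiles through the refined
centre, consistent with the PSF-fitting tools this field uses, with a
sum-projection option. A bead is accepted only if all three fits reach
$R^2 \ge 0.95$ and the window was not clipped by the stack boundary.
Because slight focus changes can swap which lateral axis is wider, the
lateral pair is reported sorted as $\mathrm{FWHM}_{min}$ and
$\mathrm{FWHM}_{max}$; the anisotropy ratio
$A = \mathrm{FWHM}_{min}/\mathrm{FWHM}_{max} \in (0, 1]$ is reported both
as the ratio of cohort means (the headline statistic) and as the per-bead
median — the two estimators generally differ on skewed cohorts, so both
are kept. Cohort summaries state mean, SD, median, quartiles and
1.5 × IQR whisker bounds per dimension.

**Axial effect-size detection.** One property test configures
`mode_axial_inflation` to the ratio of the instrument-class axial means
(13.15/8.72 ≈ 1.51) and asks the pipeline to recover it. The measurement
is taken on the *raw* stacks via sum-projection profiles along the frame
axis: frame sums of a bead image are exactly the laboratory-$z$ marginal
of the blurred blob in both scan modes, independent of the lateral drift,
so the estimator isolates precisely the width the knob scales. Profiles
along the reconstructed $z'$ axis would instead mix lateral and axial
widths through the $45^\circ$ rotation (an axis-aligned line profile
through a tilted elongated Gaussian approaches the *harmonic* mean of its
widths), a real geometric effect that would confound the check. The
lateral PSF in that experiment is kept narrow (0.7 µm sigma) so the small
residual mixing stays well inside the 5% tolerance; the expected residual
is computed in closed form, not tuned.

**Nuclei.** Segmentation is the simplest deterministic baseline the
phantoms satisfy: isotropic Gaussian smoothing (default 1.5 µm), a global
Otsu threshold on the smoothed volume (or a numeric threshold), 6-connected
components and a minimum-volume filter (default 20 µm³). Touching nuclei
are *not* split — no splitting rule is anchored anywhere — so recall
fixtures keep centres apart, and dense real tissue would need a
watershed-style extension. Per-nucleus sizes are the same Gaussian profile
fits through the label centroid, reported raw and, when the PSF is known,
quadrature-corrected ($\sqrt{\max(m^2 - \mathrm{PSF}^2, 0)}$), because
whether reported nuclear sizes should be deconvolved is a judgement call
best left to the reader. Resolvability compares each nucleus's axial FWHM
against per-mode axial resolution limits (defaults 13.15 and 8.72 µm) and
reports the fraction at or above each limit, overall and per ROI.

# Tiling and overhead

The standard shear acquisition of a tilted slice must cover the in-plane
$x'$ extent with *coupled* $x$–$z$ tiles, each overlapping 10% by
default; the compensated scan covers the whole $x'$ extent in one sweep
(bounded only by the working distance), so it tiles at most the shared
$y$ axis. `tiling_plan()` returns the minimal covering counts with step
$\mathrm{fov}\cdot(1 - \mathrm{overlap})$; for a 10 mm × 10 mm slice and
a 5.8 mm field this is a 2 × 2 plan against 1 × 2. Known-offset fusion
(`fuse_tiles()`) blends overlaps with a linear ramp; since offsets are
exact in the synthetic setting, any consistent blend is unbiased, and a
constant field fuses to the same constant.

# Problem sizes and determinism

The shipped test suite runs entirely on synthetic data at sizes chosen to
exercise every code path at full numerical fidelity: raw stacks of
roughly $10^5$–$10^7$ voxels, 100 beads across 20 randomised geometries
(both scan modes) for the round-trip suite, 50 seeded repeats at SNR 20
for noisy FWHM recovery, 50 randomised shape predictions, and
25–40-nucleus phantoms for segmentation recall. The whole suite and the
acceptance script each complete in a few minutes on one CPU. Every
stochastic step flows from an explicit seed; identical configurations
produce bit-identical stacks, CSVs and reports.

# Known limitations

* The exact transform matrices used by the original processing pipeline
  were not available for inspection; the matrices here are derived from
  first principles and validated against round-trip, corner-box and
  cross-mode oracles instead.
* Whether analysis volumes should be resampled to isotropic voxels first
  is left as an option (`isotropic = TRUE`); the defaults keep native
  pitches.
* The light-sheet profile is absorbed into a single axial Gaussian width;
  waist, propagation and sweep dynamics are out of scope.
* Absolute byte figures ignore container overhead; only size *factors*
  are meaningful, and wall-clock processing-time comparisons are
  hardware-bound and deliberately not modelled.
* `theta_deg = 90` (perpendicular mounting) is valid for the standard
  path and degenerate for the compensated path, whose lateral step
  diverges with $\tan\theta$.
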