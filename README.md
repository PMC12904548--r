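# mesodeskew

Acquisition geometry, volume reconstruction and quantification for
mesoscale light-sheet (mesoSPIM-style) imaging of **thin tissue slices
mounted at an oblique angle** between the illumination and detection axes.
It is written for microscopists and image analysts who work with
stage-scanned light-sheet data of 45°-mounted vibratome-cut sections and
need to (i) reason about the two possible scan strategies, (ii) de-skew
raw stacks into sample coordinates, (iii) characterise the system PSF from
bead stacks, (iv) measure nuclear sizes against mode-specific resolution
limits, and (v) budget the data-size cost of each strategy — all of it
testable end-to-end on synthetic phantoms, since every step is backed by a
first-class simulator.

## The model

A slice mounted at angle θ to the detection axis and scanned only along
the detection axis *z* yields a sheared raw volume: in-focus content
drifts across the camera by `z_step·tan(θ)/pitch` pixels per frame, and
de-skewing it needs padding plus a rotation+scaling resampling.
**Oblique-compensation acquisition** adds a coupled lateral stage step per
frame *n*

```
x_s = n · z_step · tan(θ)        (at θ = 45°:  x_s = z_step)
```

which cancels the drift: the slice stays centred on the camera, the raw
stack is cropped to content *before* any resampling, and the remaining
reconstruction is a lossless 90° reorientation, one scaling along the slab
normal z′ and one shear along the in-plane axis x′. The package implements
both pipelines over one inverse-mapped trilinear affine resampler, plus:

* Gaussian bead/nuclei phantoms imaged through an anisotropic (optionally
  astigmatic) Gaussian PSF under either scan mode, with seeded shot/read
  noise — the synthetic ground truth every test measures against;
* per-bead, per-axis Gaussian profile fits with an R² ≥ 0.95 acceptance
  gate; lateral widths reported as sorted (FWHM_min, FWHM_max) with the
  anisotropy ratio A = FWHM_min/FWHM_max, where FWHM = 2√(2 ln 2)·σ;
* nuclei segmentation (smooth → Otsu → connected components → volume
  filter) and axial-FWHM resolvability fractions against per-mode limits;
* closed-form shape/byte accounting (`predict_shapes()`, guaranteed to
  match the actual resampler) and minimal 10%-overlap tiling plans —
  the standard mode must tile the in-plane extent as coupled x–z tiles,
  the compensated mode never tiles x′.

## Worked example

Simulate beads in a 220 × 120 × 60 µm slab, acquire under compensation at
θ = 45° (1 µm steps, 1.31 µm pitch, a 400-px-wide camera), reconstruct,
and measure the PSF:

```r
library(mesodeskew)

geom    <- acquisition_geometry(45, z_step_um = 1, pixel_pitch_um = 1.31,
                                scan_mode = "oblique_comp")
phantom <- make_phantom(phantom_spec("beads", 25,
                                     bounds_um = c(220, 120, 60), seed = 1))
psf     <- psf_model(sigma_x_um = 2.07, sigma_y_um = 2.90, sigma_z_um = 3.70)
raw     <- acquire(phantom, psf, geom, camera = list(nx = 400))
rec     <- reconstruct_oblique(raw)
rec
#> reconstruction_result (oblique_comp): 16,027,200 -> 111 x 106 x 261 voxels, size factor 0.383

det  <- detect_beads(rec$volume, min_separation_um = 15,
                     intensity_threshold = 0.25 * max(rec$volume$data))
fits <- measure_beads(rec$volume, det, window_um = c(30, 30, 30))
s    <- summarize_fwhm(fits)
s$per_dimension[, c("dimension", "n_beads", "mean", "sd", "median")]
#>    dimension n_beads mean     sd median
#> 1   fwhm_min      18 6.29 0.1086   6.29
#> 2   fwhm_max      18 6.88 0.0454   6.90
#> 3 fwhm_axial      18 6.22 0.1076   6.19
s$anisotropy
#>   group n_beads anisotropy_mean anisotropy_perbead_median
#> 1   all      18           0.914                     0.912
```

Reading the numbers: the reconstruction is *smaller* than the raw stack
(size factor 0.38) because the centred slice lets content-free camera
columns be cropped before the affine step — the standard-shear pipeline on
the same phantom has a size factor above 2. Of 22 detections, 18 beads
pass the R² gate. `fwhm_max ≈ 6.90 µm` is the pure camera-y width
(√(6.83² + 1²) for the 2.90 µm-σ PSF convolved with the 1 µm bead);
`fwhm_min` and `fwhm_axial` are line profiles along x′ and z′, which at a
45° mount mix the lab-frame lateral and axial widths — the geometric
mixing is real and the measurement reports what an analyst would measure
in sample coordinates.

A scriptable surface over the same functions ships in
`inst/cli/mesodeskew.R` (subcommands `simulate`, `reconstruct`,
`analyze-beads`, `analyze-nuclei`, `predict-overhead`, `demo`), and
`run_pipeline()` drives the whole chain from one YAML/list configuration
with a single seed.

See `vignettes/oblique-deskewing.Rmd` for the coordinate conventions,
the PSF and noise models, measurement conventions and design decisions.

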