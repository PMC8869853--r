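# shgfb

Quantification of fibrillar collagen in paired forward/backward
second-harmonic generation (SHG) microscopy images.

## What this package is for

SHG microscopy images fibrillar collagen label-free: two excitation photons
scatter off the non-centrosymmetric collagen fiber and emerge as one photon
at twice the energy. The **directionality** of that emission — the ratio of
forward-detected to backward-detected SHG intensity, **F/B** — reports on
the fiber's internal structure (fibril diameter, spacing, and packing
disorder), and the **dispersion of fiber orientations** reports on how
aligned the collagen network is. Both are image-based prognostic signatures
in breast cancer, and both are measured on paired tumor sections (e.g.
pre-treatment core needle biopsies vs post-treatment excisions, tumor bulk
vs tumor–stroma interface).

`shgfb` implements the full measurement chain for users analysing such
paired F/B image data, plus a synthetic fiber-phantom generator with
per-pixel ground truth so that every estimator in the chain can be
validated without any tissue data:

* **I/O and preprocessing** — paired multi-page TIFF z-stacks, per-pixel
  maximum-intensity projection (MIP), percentile background subtraction,
  and integer-pixel translation registration of calibration series.
* **Collagen masking** — the *manual* method (one global threshold per
  channel, masks multiplied) and the *adaptive* method: seed mask at
  0.6× the image mean, selection of the smallest window that holds >5%
  foreground around every pixel, then per-pixel thresholding at 0.6× the
  local window mean. Final mask = F-mask × B-mask in both methods.
* **F/B quantification** — masked per-pixel F/B, ROI means, unweighted
  patient aggregates, and hourly session calibration factors
  (reference F/B ÷ current F/B) to remove detector drift.
* **Fiber organization** — a uniform 3×3 grid dictates nine measurement
  points; the local orientation at the collagen pixel nearest each point
  is measured by the structure tensor's principal direction, and the
  sample standard deviation of the nine axial angles (after 0/180°
  branch-cut alignment) quantifies organization: lower SD = more aligned.
* **Cohort statistics** — D'Agostino–Pearson-routed paired/unpaired
  comparisons (t-tests vs Wilcoxon/Mann–Whitney), residual cancer burden
  (RCB) class pooling (0/I vs II/III), subgroup analyses, and logistic
  association of baseline measures with binarized outcome (with a
  Firth-penalized fallback under separation).
* **Phantoms and simulated cohorts** — Gaussian-profile fiber scenes with
  imposed per-pixel F/B and known angles, z-stacks, gain-drift calibration
  series, and bivariate-normal patient cohorts parameterised by group
  means/SDs and a pre/post correlation.

## Worked example

Render a noisy phantom whose every fiber pixel has true F/B = 5, run the
adaptive pipeline, and measure one field:

```r
library(shgfb)

cfg  <- scene_config(shape = c(128, 128), ratio = 5, amplitude_B = 100,
                     background = 5, noise = "poisson", seed = 42)
sc   <- render_scene(cfg)
fs   <- subtract_background(sc$F)$image
bs   <- subtract_background(sc$B)$image
mask <- adaptive_mask(fs, bs)
roi_mean_fb(fb_image(fs, bs, mask))
#>    mean_fb n_pixels n_excluded   method calibrated
#> 1 4.892805     3633          0 adaptive      FALSE
```

The masked mean recovers the imposed ratio within ~2% (photon noise and
the Gaussian fiber profile account for the residual bias; the package's
acceptance checks bound it below 5%).

Fiber organization on a phantom whose nine grid-cell fibers have angles
drawn around 60° with SD 10°:

```r
s2  <- render_scene(grid_fiber_scene(shape = c(128, 128), angle_mean = 60,
                                     angle_sd = 10, seed = 42))
smp <- orientation_sample(s2$B, (s2$truth$label > 0) * 1, window = 15)
orientation_sd(smp$angle[smp$valid])
#> [1] 6.311125
```

A paired comparison at the reference effect size (patient-level bulk F/B
5.25 → 6.24, SD = SEM·√22, pre/post correlation 0.6, n = 22):

```r
set.seed(1)
sdp <- 0.36 * sqrt(22); sdq <- 0.37 * sqrt(22)
sig <- matrix(c(sdp^2, .6 * sdp * sdq, .6 * sdp * sdq, sdq^2), 2)
xy  <- MASS::mvrnorm(22, c(5.25, 6.24), sig)
tidy(compare_paired(xy[, 1], xy[, 2]))
#> # A tibble: 1 × 6
#>   test_name statistic p_value     n route      flags
#>   <chr>         <dbl>   <dbl> <int> <chr>      <chr>
#> 1 paired-t      -3.49 0.00219    22 parametric ""
```

`run_study()` drives the whole chain — from a directory of per-patient
TIFF pairs or a simulation spec to ROI, patient, organization, and
comparison tables — and `run_selfcheck()` prints the invariant battery.

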