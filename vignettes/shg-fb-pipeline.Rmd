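---
title: "Quantifying collagen F/B and fiber organization from paired SHG images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collagen F/B and fiber organization from paired SHG images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement model

Second-harmonic generation (SHG) from a collagen fiber is emitted both
forward (along the excitation axis, collected through a condenser) and
backward (epi-detected through the objective). The ratio of the two
intensities, F/B, is governed by the fiber's internal structure — fibril
diameter, spacing, and packing disorder — which makes it a per-pixel
optical readout of sub-resolution collagen architecture. The quantity this
package estimates is the **masked mean F/B of an imaged field**: the
arithmetic mean of per-pixel ratios of the background-subtracted channels,
restricted to pixels that a collagen mask accepts in *both* channels.

A second, independent readout is **fiber organization**: the spread of
fiber orientations across a field. The package measures orientation at
nine fixed grid points (removing user freedom in choosing measurement
sites) and summarizes a field by the sample standard deviation of the nine
axial angles; a lower SD means a more aligned collagen network.

Both readouts are computed per field (three fields per region in the
reference design), averaged to patient level, and compared across paired
conditions (pre/post treatment, tumor bulk / tumor–stroma interface) with
a normality-routed statistical layer.

## Pipeline stages and their parameters

### Projection and background

Stacks are collapsed by per-pixel maximum-intensity projection — a
pixel-by-pixel autofocus for tissue that is not perfectly parallel to the
image plane. The axial span of a stack is `(n_slices - 1) * step_um`
(three slices at 3 µm steps span 6 µm).

Background is estimated per channel as the 10th intensity percentile
(`background_p = 10`) and subtracted with clipping at zero. The percentile
estimator is scale-covariant — scaling an image scales its offset — which
preserves the ratio invariances the rest of the pipeline relies on. On
sparse fiber images the 10th percentile falls inside the pure-background
population, and on noiseless phantoms it recovers the generator's offset
exactly. The order of operations is fixed as *project → subtract → mask*:
masks are therefore defined on offset-free intensities, and manual
thresholds are interpreted as heights above background.

### Masking

Two mask constructions are provided, differing only in how thresholds are
chosen:

* **Manual** (`manual_mask`): one global threshold per channel
  (`tF`, `tB`), pixels strictly above threshold are kept, and the two
  binary masks are multiplied. In automated runs the per-channel
  thresholds are set by a percentile rule (`manual_percentile = 90`),
  standing in for a blinded observer's choice.
* **Adaptive** (`adaptive_mask`): per channel, a seed mask keeps pixels
  strictly above `alpha = 0.6` times the image mean; the window schedule
  (odd sizes from the largest that fits the image, halving down to 7) is
  scanned for the smallest size whose window, centered on **every** pixel,
  contains more than `fill_frac = 0.05` seed pixels; the channel mask then
  keeps pixels strictly above 0.6 times the mean of that window centered
  on them. The two channel masks are multiplied, mirroring the manual
  method.

Numerical conventions, fixed for determinism: strict inequality at every
threshold (a pixel exactly at threshold is background); windows are
cropped at image borders, never padded (padding would invent intensities);
if no scheduled window satisfies the fill criterion everywhere, the
largest scheduled size is used and flagged. The "centered on any pixel"
fill criterion is read universally (*every* center must qualify): the
existential reading degenerates to the smallest window touching one seed
pixel, which defeats the criterion's purpose of guaranteeing stable local
means. Because every threshold is a fraction of a mean, the adaptive mask
— and hence the F/B estimate — is invariant under multiplying both
channels by any positive constant; this is asserted to 1e-9 relative in
the acceptance checks.

No morphological cleanup (opening, size filters) is applied.

### F/B and calibration

The F/B image is the pixelwise quotient of the background-subtracted
channels on the final mask. Masked pixels with `B = 0` cannot yield a
finite ratio; they are excluded and tallied. Masked pixels with `F = 0`
are retained with ratio 0: they are inside collagen by mask consensus, and
dropping them would bias F/B upward. ROI means are arithmetic means of
retained pixels; patient aggregates weight each ROI equally regardless of
its pixel count.

Detector drift over an imaging session is removed by re-imaging one
calibration field hourly: later frames are registered to the first by
integer-pixel translation (maximizing mean-removed cross-correlation
within `max_shift`), and the calibration factor for hour *t* is the
reference F/B divided by the hour-*t* F/B. Measurements are multiplied by
their session's factor exactly once (double application is an error), with
linear interpolation between hourly factors for intermediate times.

### Orientation and organization

The 3×3 grid places its lines at the quarter positions of the image
(rows/columns `floor(H/4), floor(H/2), floor(3H/4)`), spacing them
uniformly with margins. For each of the nine intersections, the anchor is
the nearest mask pixel within `search_radius = 64` px (Euclidean
distance; ties broken row-major); points with no reachable collagen are
flagged invalid and dropped, and a field needs at least `min_valid = 5`
valid points.

Orientation at an anchor is the principal direction of the local structure
tensor: intensity gradients are accumulated as weighted outer products
over a `window = 21` px Gaussian-weighted neighborhood, and the dominant
fiber direction (the eigenvector of the smaller eigenvalue) is mapped to
degrees in [0, 180) counter-clockwise from the horizontal "3 o'clock"
axis. Two numerical choices matter here. First, the patch is pre-smoothed
with a σ = 1.5 px Gaussian before differencing: central differences on raw
pixels carry a 4-fold angular bias that peaks near 22.5° + k·45° at about
1.6°, and pre-smoothing reduces it to under 0.8°, keeping single-angle
errors and angle-difference errors inside the 2° bound the package
guarantees. Second, the reference procedure this automates was a manual
one — an observer clicking the fiber nearest each grid point; the
structure tensor at the nearest mask pixel is this package's automated
stand-in, and that substitution is the main deliberate deviation from the
reference procedure.

Fiber angles are axial (θ and θ + 180° are the same fiber), so a plain SD
is inflated across the 0/180 wrap. `orientation_sd()` therefore evaluates
the n cyclic branch cuts — equivalently, shifting each of the k smallest
angles by +180 — and reports the sample SD (n − 1 denominator) of the
minimal-spread representation. This keeps the statistic in plain degrees,
comparable with conventionally reported values (e.g. 40.2°), while
removing the wraparound artifact; for spreads below ~45° it agrees with
full circular statistics in rank order. A patient's organization value is
the mean of the per-field SDs of two tumor-bulk fields (pooling all 18
angles into one SD is available as `mode = "pooled"`; whether to average
SDs or pool angles is genuinely underdetermined, and averaging was chosen
as the default because it treats fields symmetrically with the F/B
aggregation).

### Statistical layer

Every comparison first assesses normality with the D'Agostino–Pearson
omnibus test (implemented from the standard transformed-skewness and
transformed-kurtosis Z formulas; no installed R package provides it, and
the implementation is frozen against an independent reference on fixed
samples). Paired designs assess the pairwise *differences* — that is what
the paired t-test assumes normal; unpaired designs assess each sample. If
every relevant normality p-value exceeds 0.05 the parametric route is
taken (paired/Welch t-test), otherwise the rank-based equivalent (Wilcoxon
signed-rank / Mann–Whitney; exact when n ≤ 25 without ties or zero
differences, else the continuity-corrected approximation). The omnibus
test needs n ≥ 8: `route_test()` refuses smaller samples, and the
`compare_*` front-ends route them nonparametrically. All tests are
two-sided and p-values are reported raw, one per comparison, without
multiplicity correction — matching how such cohort comparisons are
conventionally reported.

RCB classes are pooled 0/I vs II/III (similar five-year prognosis), and
baseline association with the pooled outcome uses single-predictor
logistic regression with a two-sided Wald p; complete separation is
detected and rerouted to a Firth-penalized fit with a flag.

The acceptance checks verify the layer empirically: type-I error of both
routed comparisons within [0.03, 0.07] at nominal 0.05 (n = 22, 10,000
replicates), and power ≥ 60% at the reference bulk effect (5.25 → 6.24,
SD = SEM·√22, ρ = 0.6, n = 22, 500 replicates).

## What the phantom generator does and does not emulate

`render_scene()` draws fibers as anti-aliased line segments with Gaussian
cross-sections; overlapping fibers sum intensity, and the label map keeps
the locally brightest fiber. The backward channel receives the profile,
the forward channel receives `ratio` times the profile, and a constant
offset is added to **both** channels (two separate detectors, each with a
dark offset; subtracting it from both recovers `F/B = ratio` exactly in
the noiseless case). Noise — Poisson by default, since photon-counting
detectors are shot-noise limited and no detector noise model was otherwise
specified — is applied independently per channel after image formation.
Contributions are cut to exactly zero beyond 4σ of a fiber's axis so that
far-field pixels carry only the offset (this is what makes the percentile
background estimator exact on noiseless phantoms). Scenes are
byte-reproducible from their config, z-stacks scale a common noiseless
scene by per-slice axial weights with fresh noise per slice, and
calibration series apply per-hour channel gains and (sub-pixel)
translations to a reference pair.

Simulated cohorts draw each patient's paired pre/post values from a
bivariate normal with per-cell means and SDs and correlation ρ. The
default parameter tables carry the reference group statistics (e.g. bulk
F/B 5.25 ± 0.36 SEM pre vs 6.24 ± 0.37 post, manual masking, HER2+
cohort), with SDs reconstructed as SEM·√22 since groups of 22 patients
are reported as mean ± SEM. ρ is not derivable from printed group
statistics; 0.6 is used as a realistic within-patient correlation for a
paired tissue readout and is exposed in the config. RCB classes default to
sampling from the 5/5/6/6 class distribution (a deterministic
`"proportional"` allocation reproducing the exact 10/12 pooled split is
available where subgroup sizes themselves are part of the design).

The generator is deliberately *not* a physical SHG model: there is no
electromagnetic forward model linking fibril architecture to F/B, no Gouy
phase, no depth-dependent scattering, no fixation/staining effects. The
true ratio is imposed, not derived. Passing recovery tests therefore shows
that the *estimators* are unbiased and invariant as claimed on images with
the assumed structure (Gaussian-profile fibers, uniform background,
per-pixel noise) — it cannot show that F/B values from processed tissue
match fresh-tissue values, or that the masks segment real tissue texture
as cleanly as phantoms.

## Problem sizes and runtime choices

The validation suite renders phantoms at 96×96–128×128 rather than full
512×512 acquisition size: every property checked (mask oracle
equivalence, ratio recovery, scale invariance, orientation recovery) is
resolution-independent for the fiber geometry used, and the smaller fields
keep the full suite to a few minutes. Monte-Carlo sizes follow the stated
guarantees: 10,000 replicates for test size, 500 for power, 200 phantom
fields for dispersion recovery. The simulated end-to-end studies use 4–6
patients with 2–3 fields per cell — enough to exercise every bookkeeping
path (both methods, all regions and timepoints, subgroup flagging)
deterministically.

## Known limitations

* Registration is integer-pixel translation only; rotation or scale drift
  across a session is assumed negligible (sub-pixel shifts are recovered
  to within 0.5 px).
* The adaptive window schedule below the image size and its minimum (7 px)
  are conventions; both are configurable.
* The branch-cut SD is a linear statistic on axial data; for spreads
  approaching uniformity (≫45°) it compresses relative to a truly
  circular dispersion measure, and comparisons should then be interpreted
  as ordinal.
* `fiber_spec` ratios are constant along a fiber; spatial F/B gradients
  within single fibers are not modeled.
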