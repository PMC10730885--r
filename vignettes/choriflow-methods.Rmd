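---
title: "Quantifying choriocapillaris flow deficits on synthetic OCTA: models and methods"
author: "choriflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying choriocapillaris flow deficits on synthetic OCTA: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The measurement problem

The choriocapillaris is the dense capillary monolayer beneath Bruch's
membrane that supplies the photoreceptors and the retinal pigment
epithelium (RPE).  On en-face OCT angiography (OCTA), early diabetic
damage appears not as missing vessels but as *flow deficits*: dark
regions ("flow voids") scattered through an otherwise bright slab.  Two
summary statistics capture this:

* **CCFA ratio** — the percentage of the analyzed area classified as
  flow signal after local adaptive binarization.  Lower values mean more
  flow deficit.
* **CV of the CCFA ratio** — the binarized slab is split into an
  18 x 18 grid of equal tiles, the flow fraction of each tile is
  computed, and the coefficient of variation (sample SD / mean) of the
  324 tile values measures how *spatially heterogeneous* the deficits
  are.  Diffuse, uniform signal loss leaves the CV low; patchy, clustered
  voids raise it.

The superficial retinal plexus is summarized by **vessel length density**
(VLD): total perfused centerline length per unit area (mm/mm^2), obtained
by skeletonizing a vessel segmentation.

`choriflow` implements this measurement chain together with a synthetic
image and cohort generator, so that every stage can be validated against
exported ground truth — patient-level OCTA data of this kind are rarely
publicly available, and synthetic scenes with known truth are the only
way to test the chain end to end.

## The measurement chain

### Magnification correction and crop

OCTA scan dimensions assume a fixed axial length; a longer eye magnifies
the retina onto a larger physical field.  `bennett_scale_factor()`
applies the Littmann-Bennett scaling `q = 0.01306 (AL - 1.82)`; in the
ratio between the subject eye and the device-assumed eye the constant
cancels, leaving `(AL - 1.82) / (AL_assumed - 1.82)`.  The assumed axial
length defaults to 24.46 mm and is configurable, since device families
differ and the value matters only through the ratio.

The correction is implemented as a *metadata rescale* — the pixel grid is
never resampled, only the physical pixel size changes — followed by a
centred crop to the common analyzed extent of 2.7 x 2.7 mm.  Area ratios
(like the CCFA ratio) are scale-free, so resampling would only add
interpolation artifacts before binarization.  The crop pixel count floors
to a whole pixel and the exact realized extent is recorded; a shortfall
of less than one pixel is treated as the rounding artifact it is, which
makes the crop idempotent.  Eyes whose corrected extent cannot cover the
crop are excluded with an explicit code, and eyes with a device quality
index of 7 or less are excluded before any measurement (`quality_filter()`,
strict `> 7`).

### Phansalkar binarization

Flow/no-flow classification uses the Phansalkar local threshold,
designed for low-contrast images:

    T = m * (1 + p * exp(-q * m) + k * (s / R - 1))

with `m`, `s` the mean and population SD of the intensities in a square
window around each pixel.  The constants are not universal across the
literature, so they are explicit and overridable; the defaults are the
original method's `p = 2`, `q = 10`, `k = 0.25`, `R = 0.5` with a window
radius of 4 px (about 23 um at the default scale — the order of the
intercapillary distance).  Windows are reflect-padded at the borders to
avoid dark-border threshold bias.  Polarity is fixed: a pixel strictly
brighter than its local threshold is flow.  The implementation uses
integral images and is tested for exact agreement against a brute-force
sliding-window oracle.

### Tile CV conventions

"18 x 18 smaller images" is read as an 18-by-18 *grid* (324 tiles of
~150 um on the 2.7 mm extent), not as 18-pixel tiles: the resulting tile
size brackets the 200-250 um lobule scale that the statistic is meant to
probe.  The mask is centre-trimmed to the largest multiple of 18 (460 ->
450 px at the default geometry; the trim is recorded).  The CV uses the
sample (n-1) SD; with 324 tiles the choice is nearly irrelevant, but a
convention must be fixed to be reproducible.  When the grid divides the
mask evenly, the mean of the tile ratios times 100 equals the global
CCFA ratio exactly, and the suite asserts this identity.

### The impaired-flow rule

`classify_impaired()` flags an eye when CCFA ratio < 65.9 **and**
CV >= 0.140 — the two marginal Youden cutoffs, with the strictness of
each inequality fixed as stated.  Both cutoffs are
configurable, and `build_report()` can re-derive them from a cohort's own
ROC curves.

### Vessel length density

The device software that measures VLD clinically is proprietary, so the
package implements a transparent equivalent: global Otsu threshold on a
background-flattened, lightly denoised image; removal of specks under
3 px; Zhang-Suen thinning to a 1-px skeleton; and length as the sum of
8-connected adjacency steps (1 per orthogonal pair, sqrt(2) per diagonal
pair).  Two details matter for accuracy:

* A diagonal pair whose two pixels share an occupied orthogonal
  neighbour is a staircase shortcut, not an independent step, and is
  excluded.  Counting all pairs naively overestimates a staircase of
  n orthogonal steps as `n + (n-1) * sqrt(2)/2` — a ~15% inflation on
  realistic networks.
* The denoising blur is 0.4 px.  This value minimizes the worst-case
  ground-truth recovery error across the density range of interest
  (about 18-21 mm/mm^2): stronger blurs erode vessel tips and bias the
  length down; no blur leaves speckle pinholes inside vessels that the
  skeleton loops around, biasing it up.

Matching clinical practice for this metric, VLD is computed on the nominal
3 x 3 mm extent without axial-length correction.

## The synthetic scene model

### Choriocapillaris slab

The baseline texture is a jittered hexagonal lattice of lobules (domain
diameter 225 um, within the anatomical 200-250 um range), with intensity
falling gently from lobule centre to boundary.  Flow voids are unions of
random ellipses stamped into the scene until the void area reaches
`void_param` of the frame — so `void_param` *is* the true void coverage,
the recorded `true_flow_fraction` is exact by construction, and the
global coverage is decoupled from where the voids sit.  Void centres are
drawn with acceptance probability proportional to a smooth positive
random field (exponentiated Gaussian-blurred white noise, correlation
scale 300 um, mean 1) whose log-amplitude `heterogeneity_param` controls
spatial clustering: at 0 the voids are uniform; larger values concentrate
them, raising the tile CV without moving the mean.

Void sizes default to the intercapillary scale (minor axis 18-26 um,
aspect up to 1.6, with 1.5% larger confluent voids of 40-80 um).  The
size distribution sets the *floor* of the tile CV — the CV measured with
zero heterogeneity — because coarser voids make 150-um tiles intrinsically
noisier.  With coarse voids the floor sits above the healthy-eye CV
(~0.124) and no heterogeneity setting can reach it; the default sizes
put the floor near 0.09-0.13 across the relevant coverage range, below
every group target.  Speckle is multiplicative log-normal with unit mean
(sigma 0.18), the standard first-order OCT speckle model, applied last
and followed by clipping to [0, 1].

### Superficial slab

Vessel networks grow as branching random walks on the pixel grid:
each tip advances to the 8-neighbour nearest its jittered heading,
branches with probability 0.08 per step, and dies when its lookahead
neighbourhood touches existing vasculature (Chebyshev radius 2, three
pixels ahead) — giving a quasi-planar, collision-avoiding network like a
capillary plexus.  Growth stops the moment total centerline length
reaches the target, so the recorded ground truth is exact.  Length is
accounted in the same 8-connected chain metric the skeleton estimator
uses (1 / sqrt(2) per step); defining generator truth and estimator in
one metric makes "recovery" well-posed on a pixel grid.  Centerlines are
dilated to ~3 px calibre (~17 um), rendered bright on a dark background,
and speckled (sigma 0.20).

### Cohort model

`generate_cohort()` draws 12 control, 15 diabetic-without-retinopathy and
18 retinopathy eyes (configurable) with demographics, inclusion-criterion
variables and per-eye *targets* for the image-derived channels.  All
continuous channels of an eye load on a single latent severity factor
`z ~ N(0,1)`:

    channel = mean_g + sd_g * (l * z + sqrt(1 - l^2) * eps)

Under this single-factor model the within-group correlation between two
channels is the product of their loadings, and the pooled correlation
additionally receives the between-group mean structure.  The default
loadings (CCFA 0.70, VLD 0.50, CV -0.654, PROS 0.204, RPE -0.497) were
solved from the closed form so that the *pooled* correlations at equal
group weights reproduce the published values (CCFA-VLD 0.572, CV-VLD
-0.578, CCFA-PROS 0.395, CCFA-RPE -0.445) given the group means and SDs;
the signs encode that healthier eyes have more flow, denser vessels,
longer photoreceptor outer segments and smaller RPE volume.  The RPE
volume of the middle group has no reference value; the preset
interpolates 0.39 +/- 0.025 between the reported 0.38 and 0.40.  The RPE
volume unit is stored verbatim as the reported "um^3" with a unit-string
field, since that unit is physically questionable for a macular volume.

Truncation (BCVA < 0.05 logMAR, axial length in a realistic adult range,
strictly positive labs) is enforced by resampling, which preserves means
approximately while guaranteeing the inclusion invariants.  Sex uses the
published group-specific male proportions (2/12, 8/15, 15/18); ages are
truncated to the published per-group ranges.

Each eye derives its RNG seed from the cohort seed and its index
(`(base_seed mod 21000) * 1e5 + 3 * index`, with the two adjacent offsets
reserved for its two image renders).  A purely additive seed would make
cohorts with consecutive base seeds share almost every eye — streams
overlap — so replicate cohorts would not be replicates; the multiplicative
scheme keeps determinism and byte-identical tables per configuration
while making cohorts with different seeds independent.

Systemic labs are drawn conditional on impaired-flow status through
logistic exceedance models whose default odds ratios are the published
age-adjusted ones (HbA1c >= 7.0%: 4.992; systolic BP >= 135 mmHg: 5.572;
the remaining exposures of the risk-factor table likewise).  Continuous
values are then drawn from truncated normals on the matching side of each
clinical cutoff, so indicators and values are always consistent.  The
HbA1c cutoff is taken in percent units (>= 7.0%); the alternative reading
"mg/dl" that appears in one table is a unit typo.

### Calibration

The simulator controls are not meaningful in physical units, so each
group preset is *self-calibrated* against the measurement pipeline
(`calibrate_preset()`): bisection on `void_param` until the mean measured
CCFA over 20 anchor eyes is within 0.5 points of the group target, then
bisection on `heterogeneity_param` until the mean measured tile CV is
within 0.01.  The same anchor-eye seeds are reused at every bisection
step (common random numbers), so each stage bisects a smooth monotone
function; bisection continues until the bracket is also narrow, so the
returned control does not inherit a tolerance-sized offset.  Because void
clustering feeds back weakly on the binarization bias, the two stages are
run in two alternating cycles; one pass left the mean CCFA 0.6 points
off its target.  The CV stage first measures the heterogeneity floor and
refuses targets below it, reporting the floor in the error.

Per-eye controls are then derived from the calibrated anchor: the void
coverage shifts one-for-one with the eye's CCFA target (percentage
points / 100) because coverage is exact by construction, and the
heterogeneity follows from inverting the variance decomposition
`cv^2 = floor^2 + (c h)^2` anchored at the calibrated group mean.

## Statistical pipeline

Group comparisons use the Kruskal-Wallis test with tie correction and
pairwise two-sided Mann-Whitney U tests (exact enumeration when both
groups have at most 8 untied observations, the tie/continuity-corrected
normal approximation otherwise — both conventions documented because
statistical packages differ).  Correlations are Pearson product-moment
with the t-transform p value.  ROC AUC is computed through the
Mann-Whitney U identity with ties counted one half; the Youden cutoff
maximizes sensitivity + specificity - 1, breaking ties toward the cutoff
closest to the pooled median (the least extreme threshold).  Marker
directions are fixed by configuration: low CCFA flags disease, high CV
flags disease.  2 x 2 odds ratios use the Woolf log-SE interval, the
Haldane-Anscombe +0.5 correction when a cell is zero (flagged), and a
Pearson chi-square p value, switching to Fisher's exact test when any
expected cell is below 5.  Logistic models are fitted by IRLS (`glm`);
complete or quasi-separation (non-convergence or any |coefficient| > 15)
sets a flag and suppresses the Wald interval.  Risk-factor tables fit one
exposure at a time adjusted for age: with ~45 eyes and nine collinear
lipid exposures a joint model would be unstable, and the one-at-a-time
layout is what such tables report.  Tests are two-sided at alpha 0.05
with no multiplicity correction, matching the reporting conventions of
the clinical analyses the package mirrors.

All analysis sections are assembled by `build_report()` into a
deterministic report (JSON + CSV tables).

## Problem sizes and what the validation shows

The default canvas is 512 x 512 px over a nominal 3 x 3 mm scan
(5.86 um/px, close to commercial device sampling); the packaged
validation runs ten 45-eye cohorts at the published group sizes, one
pooled 450-eye cohort for the flow-flow correlation, and tabular cohorts
of 5000 eyes for the logistic recovery — sizes chosen so the whole suite
runs comfortably on a desktop while leaving Monte-Carlo error well below
the tolerances being checked.

Passing tests show that the *measurement chain* recovers known truth on
scenes that emulate the first-order statistics of diseased
choriocapillaris (coverage, clustering, speckle) and that the
*statistical machinery* is calibrated (CI coverage, test identities).
They do not show device agreement: the simulator does not model the
device PSF, projection-artifact residues, slab-segmentation errors,
pulsatility, or the proprietary VLD algorithm, and real flow voids are
not ellipses.  Quantities that depend only on the analysis conventions
(thresholding, tiling, cutoffs, regression structure) transfer to real
images; absolute agreement with any particular device does not.

## Known limitations

* The Phansalkar window radius and constants materially change the CCFA
  ratio; cross-study comparisons require identical settings, which is
  why they are explicit configuration rather than constants.
* The tile CV has a floor set by void granularity and binarization
  noise; cohorts whose true CV is below the floor cannot be emulated at
  this tile size, and calibration reports this explicitly.
* The VLD estimator carries a residual density-dependent bias of up to
  about +/- 0.5 mm/mm^2 across 18-21 mm/mm^2 after the denoising-scale
  choice; it is measured against generator truth, not against a device.
* Only one eye per synthetic patient is generated; no longitudinal
  structure, no treatment effects, no between-eye correlation.
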