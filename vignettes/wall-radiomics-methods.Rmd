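---
title: "Bladder-wall radiomics: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bladder-wall radiomics: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(wallradiomics)
```

This vignette is the package's own account of its science: what each stage
assumes, which knobs matter, what the synthetic phantoms do and do not
emulate, and where a genuinely open design choice was made and why.

## The problem and the data model

The pipeline asks whether quantitative features of the urinary bladder
wall on T2-weighted MR images separate men with mild lower-urinary-tract
symptoms (IPSS 0–7, the *negative* class) from men with moderate-to-severe
symptoms (IPSS 8–35, *positive*). A case is a 3D scalar volume
(`volume_image`: array plus voxel spacing in mm), a co-registered binary
wall mask (`wall_mask`), and clinical covariates (age in years, BMI in
kg/m², prostate size in mL) with an IPSS score.

The wall mask must be a *hollow shell*: foreground enclosing at least one
background cavity (the lumen) with no 6-connected path to the grid border.
This invariant is checked at read time by flood fill from the border; it
is what makes "inner surface", "cavity volume" and "wall thickness"
well-defined. Cases with any missing clinical variable are excluded, not
imputed — with 87-case cohorts, imputation noise in three covariates is a
worse evil than losing a case.

Conventions frozen here because the field has no single standard: voxel
indices are 0-based with axis order (x, y, z) as stored in the NIfTI;
all geometry is computed in voxel space and converted to mm through the
header spacing only where units demand it (morphometry, phantom
construction). NIfTI stores spacing as 32-bit floats, so spacing survives
a round trip only to single precision.

## Intensity standardization

MR gray values are scanner- and session-relative. The two-phase landmark
method learns, from training volumes, a standard intensity scale and then
maps each volume onto it piecewise-linearly:

* landmarks: tail percentiles `pc_low = 1`, `pc_high = 99` plus the
  deciles 10..90 (configurable);
* standard range `[0, 4095]` — a conventional 12-bit display range; the
  method is invariant to this choice;
* training: each volume's landmarks are mapped linearly onto the range,
  anchored at the tails, and averaged per landmark;
* application: a monotone piecewise-linear map through the landmark knots,
  with end-segment extrapolation beyond the tails followed by clipping.

Properties the tests enforce: monotonicity (always, by construction),
invariance to affine intensity changes of the input (exact, because
percentiles are affine-equivariant), and idempotence — standardizing a
standardized volume moves landmarks by well under 1% of the range.
Idempotence drift comes from re-estimating quantiles on the mapped data;
it shrinks with voxel count, so the tests use volumes in the range of a
cropped pelvic ROI (64³ ≈ 2.6×10⁵ voxels).

One default deviates from the obvious choice deliberately: landmark
estimation uses **all** voxels (`fg_quantile = 0`) rather than excluding
the darkest 5%. A strict "above the 5th percentile" foreground rule breaks
idempotence structurally: the first pass clips a few percent of mass onto
the scale minimum, the second pass's threshold then excludes exactly that
pile, and the low landmark jumps by about 1% of the range. The tail
percentiles already provide the robustness the exclusion was meant to buy.
For real scans with a large air background the exclusion (or a body mask)
is available via configuration, and an inhomogeneity-correction hook
(`prestep`) can be plugged into both phases; phantoms carry no bias field,
so the default is the identity.

## Feature extraction

**Morphological** (units mm, mm², mm³): wall volume (voxel count × voxel
volume); wall and outer surface area by exposed-face counting — documented
as a staircase overestimate of a smooth surface (~1.5× for a sphere),
consistent across cases and therefore fine for discrimination, wrong for
absolute physics; sphericity of the outer surface; equivalent-sphere
diameters of outer region and cavity; bounding-box extents; and local wall
thickness as 2× the anisotropic Euclidean distance transform (exact
Felzenszwalb–Huttenlocher, compiled) sampled on the distance ridge
(voxels whose distance is a weak 6-neighbourhood maximum). On a hollow
sphere with 2 mm walls this recovers thickness to a few percent; the
phantom acceptance check uses R = 20 mm, r = 16 mm and requires volume
within 5% of the analytic shell and mean thickness within 4 ± 1 mm.

**Intensity**: first-order statistics over in-mask voxels; kurtosis is the
non-excess `m4/m2²`; histogram entropy uses 64 equal bins over the
standard range, in bits; skewness and correlation-like quantities are
defined as 0 for zero-variance inputs.

**Texture**: gray levels are quantized per volume over the robust in-mask
range (`[p1, p99]`, values clipped) into `b` equal-width bins, so all
windows of a case share one level scale. A `w × w` window slides in-plane
over every slice; a window qualifies when at least `min_mask_fraction`
(default 0.5) of its `w²` positions are in the mask, with out-of-grid
positions counted as background. Per window and offset, a symmetric
normalized co-occurrence matrix is accumulated from pairs whose **both**
endpoints lie in the window and in the mask, ten Haralick statistics are
computed (`0·log 0 = 0`; correlation 0 when a marginal SD vanishes), and
windows are pooled by the mean. Combinations with no qualifying window
yield sentinels, imputed at table assembly by the column median (a
rank-preserving choice, since the filter stage is rank-based); columns
that are sentinel in more than half the cases are dropped with a warning.

Texture is computed in 2D windows per slice because the motivating
acquisition is thick-slice sagittal T2 (≈4 mm slice gaps versus sub-mm
in-plane): a through-plane offset of one voxel is not comparable in tissue
terms to an in-plane one. A whole-ROI 3D mode (`volume_texture()`, 13
lattice directions, no windows) is provided for isotropic data. The
default sweep (4 angles × distances {1,2,4} × bins {8,16,32} × windows
{5,9,15} × 10 features = 3240 columns) is configuration, not contract;
tests and the acceptance script use reduced grids (between ~160 and ~480
texture columns) so a cohort extracts in seconds — the column count is a
closed-form product reported by `n_texture_columns()`.

The windowed kernel is compiled (Rcpp); its correctness is anchored to a
pure-R `glcm()`/`haralick()` implementation, which is in turn checked
against a brute-force pair-enumeration oracle and an independent
pair-list computation of the Haralick statistics.

## The phantom cohort generator

`synthetic_config()` defines the simulated cohort conditions;
`generate_cohort()` is
a pure function of (config, seed), with per-case seeds drawn once from the
master seed so any case regenerates independently.

Each case is a hollow ellipsoid: outer semi-axes uniform in 9–13 mm,
wall thickness uniform in 3.5–6 mm (resampled, with an error after 100
tries, if discretization would leave the wall under 2 voxels), centre
jittered ±1 mm, on a 36×36×28 grid at 1 mm isotropic spacing. Intensities:
dark background (60), bright cavity (330, urine on T2), wall 170 plus a
stationary correlated Gaussian field — white noise smoothed with a
Gaussian kernel and rescaled to SD 35 — plus global white noise (SD 8).

The class contrast lives in the *correlation length* of the wall field:
0.8 mm for negatives, plus `texture_effect` (default 1.2 mm) for
positives. Because the field is rescaled to a fixed marginal SD after
smoothing, first-order intensity statistics carry no signal; because the
thickness distribution is shared (unless `morphology_effect > 0`),
morphology carries none either; `intensity_effect` and
`morphology_effect` default to 0. Among clinical covariates only prostate
size differs (38 ± 13 vs 55 ± 13 mL); age and BMI are identically
distributed. IPSS is sampled uniformly within the class range ([0,7] or
[8,35]) — the real within-class IPSS distribution is unknown, and nothing
downstream uses the score beyond the threshold. With all effects 0 the two
classes are exchangeable by construction, which is what makes the null
calibration tests meaningful.

A smoothing-based field was chosen over, say, spectral synthesis because
it is simple, seedable, cheap, and provably moves exactly the quantity the
co-occurrence features measure. The default effect size (1.2 mm, roughly
a 2.5× change in correlation length) produces clearly separable classes —
deliberately strong, so that signal-recovery tests assert the *identity*
of the recovered features (texture, not morphology/intensity/clinical)
rather than a fragile effect size.

What the phantoms do **not** emulate: anatomical bladder shape, bias
fields, partial-volume effects at the wall surface, anisotropic
acquisition, inter-scanner variation, or any true IPSS–texture dose
response. Passing tests therefore demonstrate that the *pipeline*
recovers a texture contrast when one exists and stays at chance when none
does — not that real bladders behave like phantoms.

## Univariate analysis and selection

The filter statistic is Welch's unequal-variance t-test (vectorized over
columns), ranked by ascending p with ties broken by descending absolute
standardized mean difference, then name. The choice of an unequal-variance
test is deliberate: nothing guarantees equal class variances, and with
two classes the cost over pooled-variance t is negligible. A rank test
(Mann–Whitney) is available via configuration. No multiple-testing
correction enters the ranking — the p-values are a ranking device, not
inference — but Benjamini–Hochberg q-values are reported alongside.
Zero-variance-in-both-groups features get p = 1 when the means agree
(no evidence) and a sentinel rank-last p of NA when they differ
(infinite separation of constants, almost surely an artifact).

Selection proceeds: keep the `filter_pool_size` (default 200) lowest-p
features; prune any feature with `|r| > 0.9` against a better-ranked
keeper (scan in rank order — deterministic); then greedy forward search
with swap refinement, where each sweep tries every addition and, from
size 2, every single-feature replacement, accepting the single best move
if it improves the repeated-CV objective by more than 1e-6. The search
stops after `convergence_patience = 2` sweeps without an accepted move or
at `max_subset_size = 10`. Subset scores are cached; all folds derive
from the config seed, so the whole search is deterministic. The
"embedded" character of the method is realized by the swap step: the
classifier itself drives feature replacement during selection. Inner CV
uses fewer repeats (10) than the final evaluation (100) — the wrapper
needs a consistent ranking of subsets, not a publication-grade estimate.

On heavily redundant texture sweeps the pruned pool is often small and
the search converges to one or two features; that is the redundancy
structure of windowed GLCM features, not a failure of the search.

## Evaluation

Stratified folds: per-class shuffle then round-robin deal, so fold class
counts differ by at most one within each class. The default classifier is
a per-fold z-scaled (training statistics only, SD floored at 1e-12)
linear-kernel SVM at unit cost — the conventional small-n choice that
keeps the wrapper fast; unpenalized logistic regression is available.
Scores are oriented so positive favours the positive class and the class
rule thresholds at 0.

Metrics per repeat are computed from the validation predictions pooled
across the repeat's folds, then averaged over repeats: with only ~37
positives, per-fold AUCs are unstable and pooling is the stabler
convention. Balanced accuracy is exactly (sensitivity + specificity)/2
per repeat. AUC is the trapezoid rule over the score-swept ROC with tied
scores sharing a vertex, which equals the Mann–Whitney pair-counting
statistic with half credit for ties (tested to 1e-10 against a
pair-counting oracle). The naive majority classifier scores accuracy
equal to the majority fraction, balanced accuracy 0.5, and — being
threshold-free — has no ROC; its AUC is reported as 0.5 with an explicit
degenerate flag. Leakage is guarded by construction (scaling fitted on
training rows only) and by a canary test: a feature equal to the labels
must leak perfect accuracy, a feature equal to the labels only on
validation rows must not.

Every seeded internal saves and restores the caller's RNG state, so
user-level permutation loops around seeded functions behave as expected.

## Problem sizes and statistical caveats in the test-suite

The suite runs phantom cohorts of 40 cases (23/17, preserving the ~57/43
imbalance) with reduced texture sweeps; ten seeds for the
signal-recovery and selector-comparison properties; five seeds per effect
level for the monotonicity property at 20 cases. These sizes were chosen
so the whole suite runs in minutes on one CPU while keeping every
qualitative conclusion stable across seeds.

One check deserves a caveat. The null-calibration test applies a
Kolmogorov–Smirnov uniformity test to ~500 univariate p-values from a
single no-effect cohort. Those p-values have uniform margins but are
strongly positively dependent — all texture features are functionals of
the same per-case field realizations — so the iid KS reference
distribution over-rejects: the effective number of independent p-values
is far below 500, and across cohort seeds the KS p-value fluctuates
widely. The test is kept in its standard form with the package-default
seed; a rejection under a different seed would indicate this dependence,
not a miscalibrated t-test. The accompanying check that a wrapper-selected
subset performs within 3 SD of the label-permutation accuracy spread is
the sturdier half of the null calibration.

## Known limitations

* Surface areas are face-count estimates (staircase bias); use a
  marching-cubes implementation if absolute areas matter.
* 2D windowed texture ignores through-plane structure by design; the 3D
  mode is whole-ROI, not windowed.
* The wrapper is greedy-with-swaps; it will not find subsets whose value
  is purely joint (XOR-like). The search interface accepts alternative
  strategies.
* Phantom realism is deliberately minimal (see above); no claim about
  real bladder-wall biology follows from phantom performance.
* No bootstrap confidence intervals or calibration analysis; metrics are
  CV means with per-repeat SDs.
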