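---
title: "Quantifying dual-chromogen miRNA/protein co-expression: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying dual-chromogen miRNA/protein co-expression: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(andkit)
```

## The problem

In pancreatic neuroendocrine tumors (PanNETs), SSTR2 — the receptor
targeted by peptide receptor radionuclide therapy — is expressed
heterogeneously, and a circulating microRNA (hsa-miR-5096) is suspected of
suppressing it. Dual-stained FFPE sections carry two chromogens at once:
FastRed (alkaline-phosphatase detection) marking SSTR2 protein, and DAB
(brown) marking the microRNA detected by an LNA in situ hybridization
probe, with a haematoxylin counterstain on nuclei. `andkit` turns such RGB
fields of view into per-nucleus and per-region statistics: how much of the
tissue expresses SSTR2 at high / intermediate / no level, and what fraction
of nuclei in each of those compartments carries the microRNA marker. A
companion module implements the circulating-biomarker calculus used with
the same markers in plasma: qPCR fold enrichment, multiplicative predictor
scores and ROC-based cut-off selection.

## Image pipeline

Each 8-bit RGB field runs through five stages.

**1. Illumination correction.** The classic rolling-ball algorithm,
applied per RGB channel: a ball of radius `ball_radius` (px) rolls on top
of the intensity surface (brightfield: background is light), the traced
envelope — a grayscale closing with a spherical structuring element — is
the background estimate, and the output is `255 - (background - image)`,
which maps a flat light background to blank while preserving dark stained
structure. For radii above 10 px the image is reduced (block maximum),
the ball rolled at reduced scale and the envelope re-expanded bilinearly,
the standard acceleration of this algorithm; the reduction factor is
capped so at least ~32 samples per dimension remain. Out-of-field
neighbours are ignored, so the ball follows the image border.

Two practical consequences, both visible in the tests: the radius must
exceed the diameter of the largest dark structure that should survive
correction — a stained region about as wide as the ball that touches the
image border can be swallowed into the background estimate — and the
operation is only approximately idempotent (within ±2 intensity units on
noiseless fixtures). The default radius of 50 px suits fields whose
stained regions are either narrow or much wider than the ball; analyses
of fields with intermediate-width stained bands should raise
`preprocess.ball_radius` above the band width. The source of the
correction procedure names no radius, so the default is an explicit,
logged configuration choice, not an inference.

**2. Colour deconvolution.** Chromogens in brightfield obey the
Beer–Lambert law: per colour channel $c$, transmitted intensity is
$I_c = 255\cdot10^{-\sum_s A_{sc}\,x_s}$, where $x_s$ is the concentration
of stain $s$ and $A$ the 3×3 matrix of unit-norm optical-density
absorbance vectors. `deconvolve()` converts intensities to optical density
($\mathrm{od} = -\log_{10}(\max(I,1)/255)$, floored at intensity 1 so the
density stays finite), solves the linear system per pixel, clips negative
concentrations (pixels outside the stain simplex) to zero, and renders
each stain back to an 8-bit map (255 = no stain). The default `A` is the
published "FastRed FastBlue DAB" preset of the classic ImageJ/Fiji colour
deconvolution plugin, overridable via JSON/CSV. On continuous renders the
inversion is exact to machine precision; through 8-bit quantisation the
render–unmix–recompose round trip is within one intensity unit per
channel, which is the guarantee the tests pin.

**3. Zone partition.** The FastRed channel is split by two fixed
thresholds `Th1 = 100` and `Th2 = 190` into dark-red `[0, Th1)`
(high SSTR2), light-pink `[Th1, Th2)` (intermediate) and white
`[Th2, 255]` (negative). The source procedure states the ranges but not
the boundary membership; the half-open lower-inclusive convention used
here is a declared design decision that guarantees the three masks
partition every image exactly, and is pinned by tests. Thresholds are
defined once per analysis run and never tuned per image.

**4. Nuclear detection.** Nuclei are detected from the FastBlue and DAB
channels. Each channel is classified into three intensity levels — white
background, weak cytoplasmic signal, nuclear signal — by k-means on the
1-D intensity histogram. Because the data are one-dimensional the global
optimum is computed exactly by dynamic programming over the (at most 256)
unique intensity values, weighted by pixel counts: the result is
deterministic, needs no random initialisation and always attains the
minimum within-cluster sum of squares (the test suite verifies this
against an exhaustive 3-partition search). The darkest cluster is called
nuclear only if its mean lies at or below 200 — a guard against
quantisation-level "clusters" in channels that carry no stain at all.
Nuclear pixels from either channel are pooled (marker-positive nuclei may
lack counterstain), touching nuclei are split by the watershed transform
on the Euclidean distance map (basins below a `tolerance` depth are
suppressed, an h-maxima-style control), and objects outside
`[min_area, max_area]` = [30, 5000] px² are discarded; the source tool
reports no size bounds, so these are configurable defaults. A nucleus is
`DAB_pos` when at least half its pixels carry nuclear-level DAB signal
(`dab_fraction_threshold = 0.5`, configurable — per-nucleus positivity is
not defined quantitatively in the source), otherwise `FB_only`; it is
assigned the zone holding the plurality of its pixels, ties breaking
toward the higher-expression zone.

**5. Region statistics.** Per field: pixel counts and fractions per zone,
nucleus counts per zone × marker class, and the percentage of
marker-positive nuclei. "Analyzed cells" is read as the per-zone
denominator by default; a per-field denominator is available behind
`denominator = "roi"` because the phrasing is ambiguous in the source.
Zones with no nuclei propagate as missing, never as 0%, to avoid biasing
the downstream correlation. Fields aggregate per sample (10 fields per
sample in the intended design) by pooled pixel counts and unweighted means
of percentages; dropped fields are recorded with reasons. The tissue
result is the Spearman rank correlation between ordinal zone level
(white = 0 < light-pink = 1 < dark-red = 2) and percent marker-positive
nuclei; ties get average ranks, the two-sided p-value uses full
permutation enumeration for n ≤ 10 and the t-approximation beyond, and the
correlation can be computed at ROI or sample granularity — both are
exposed since the source does not fully specify which was pooled.

## Biomarker module

Fold enrichment is $2^{-\Delta C_T}$ with
$\Delta C_T = C_T(\text{target}) - C_T(\text{reference})$, the reference
being a stable endogenous miRNA (hsa-miR-30d in the intended assay).
Predictors multiply component fold enrichments: P1 = miR-4311 × let-7i-3p,
P2 = miR-5096 × let-7i-3p, P3 = miR-4311 × miR-5096, P = all three.
Dichotomization is strict — a score equal to the cut-off is "low"
(the "> 70 vs ≤ 70" rule). Non-amplified wells are dropped as missing
samples, never imputed at a maximum cycle count.

The ROC is empirical, thresholds at midpoints between consecutive distinct
scores; the AUC is the trapezoid area, identical to the pairwise
concordance probability with ties counted ½ (verified exactly against the
brute-force pairwise count). Confidence intervals and the two-AUC test use
the DeLong structural-component estimator; in paired mode the covariance
of components is subtracted. Cut-offs: Youden maximises
sensitivity + specificity − 1, Liu maximises their product; ties break
toward higher specificity, then the higher threshold. The published
single-miRNA cut-offs (0.85, 70, 0.72) ship as documented constants
(`reference_cutoffs`) since they derive from patient cohorts and cannot be
recomputed here.

## The synthetic-fixture generator

Patient images and plasma are not redistributable, so `scene_spec()` /
`render_scene()` produce fields with known ground truth through exactly
the forward model the pipeline inverts: vertical zone bands of graded
FastRed concentration (band geometry makes area fractions exact to one
column of rounding), nuclei stamped as discs of FastBlue (all) plus DAB
(marker-positive) concentration, Beer–Lambert composition with the shared
stain matrix, then a planar darkening ramp (the rolling-ball stage's
target) and i.i.d. Gaussian noise per channel, clipped to 8 bits.
Placement is rejection sampling capped at 100 × n attempts; isolated
nuclei keep 2 px of clearance, and a requested fraction of nuclei is
anchored at 0.8 × the sum of radii from an existing nucleus to create
controlled overlap. If the cap is hit the achieved count is reported and a
warning raised.

Default conditions mirror the reference tissue composition: zone area
fractions 0.27 / 0.22 / 0.51 (frankly positive / heterogeneous /
negative) with band intensities 60 / 150 / 255, nucleus radii 5–9 px,
noise SD 3 and shading 20 — the acquisition hardware is not modelled
(no magnification, optics or scanner noise spectrum is published for it),
so noise and shading defaults are stated, realistic desk-scale choices.
`simulate_ct_table()` builds two-group Ct tables in which the second
group's ΔCT is shifted by −`effect_log2`; Gaussian noise of SD `noise_sd`
is added independently to target and reference Ct, so per-sample ΔCT noise
is `noise_sd·√2`.

What passing on these fixtures does **not** show: robustness to real
tissue texture (chromatin structure, stain gradients inside nuclei,
folds, out-of-focus regions), to stain vectors that deviate from the
preset, or to clumped nucleus configurations beyond pairwise overlap. The
fixtures verify the algebra and the segmentation logic, not stain
chemistry.

## Numerical choices

- 8-bit quantisation everywhere is round-half-away-from-zero, then clip
  to [0, 255].
- Optical density floors intensities at 1 (od ≤ log₁₀ 255 ≈ 2.407).
- The stain matrix must be invertible; construction rejects condition
  numbers above 10⁸ naming the offending vectors.
- Degenerate intensity channels (fewer distinct values than classes)
  degrade to the available number of classes; a constant channel is all
  background with an empty nuclear mask.
- ROC curves are anchored by sentinel thresholds below the minimum and
  above the maximum score.
- `compare_auc` of a ROC with itself has zero variance; the z statistic is
  defined as 0 and p = 1.
- All randomness (scene placement, noise, Ct simulation) is seeded through
  the spec/argument, and generators save and restore the caller's RNG
  state, so identical inputs are bit-identical and the surrounding session
  is unaffected.

## Problem sizes used in the shipped checks

The test-suite and the acceptance script exercise: round trips on 10–20
fields from 64² to 512²; zone recovery on a 400 × 300 field plus 1,000
random partition checks; 1-D clustering against exhaustive search on 100
samples of up to 60 values; nucleus recovery on 448² scenes of 200 nuclei
(noiseless exact; 10 noisy/overlapping seeds within 5% count and 2
percentage points of DAB fraction); 100 cohort replicates for the
zone correlation; 500 random ROC sets against the concordance oracle; and
500–1,000 Ct-table replicates for null calibration (mean AUC ≈ 0.5) and
power (mean AUC > 0.95 at a 3-log₂ shift). These sizes were chosen so the
whole suite runs in well under a minute per module on one CPU while
keeping Monte-Carlo error far below the asserted margins.

## Known limitations

- The stain matrix is a fixed preset; no automatic stain-vector
  estimation (Macenko/Vahadane) is attempted.
- Thresholds are global and fixed by design; adaptive thresholding is a
  non-goal of the tool this package reimplements.
- The watershed splits pairwise-touching nuclei well; dense clumps of
  three or more may merge or oversplit, which is why the noisy/overlap
  recovery guarantee is 5% on counts rather than exact.
- Rolling-ball correction interacts with wide stained regions near field
  borders (see above); radii should be chosen above the largest stained
  structure's width.
- Survival modelling, time-dependent ROC and NGS differential expression
  are out of scope.
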