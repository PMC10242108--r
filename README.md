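# andkit

Single-nucleus quantification of dual-chromogen histology (DAB + FastRed
co-detection) and circulating-miRNA biomarker scoring, in R.

## What it is for

Pancreatic neuroendocrine tumors express SSTR2 — the target of
⁶⁸Ga-DOTATOC imaging and of peptide receptor radionuclide therapy —
heterogeneously, and the microRNA hsa-miR-5096 is a candidate suppressor
of it. Sections dual-stained by a combined ISH/IHC protocol carry the
microRNA as a brown DAB precipitate, SSTR2 protein as red FastRed, and
nuclei counterstained with haematoxylin. `andkit` reimplements the
analysis such slides require, as a tested library plus a small CLI:

- **Image pipeline** — rolling-ball illumination correction; colour
  deconvolution of 8-bit RGB fields into FastRed / FastBlue / DAB maps by
  Beer–Lambert optical-density algebra
  (`I_c = 255·10^(−Σ_s A_sc x_s)`, default `A` = the published
  "FastRed FastBlue DAB" preset); partition of the FastRed channel by two
  fixed thresholds (Th1 = 100, Th2 = 190) into dark-red / light-pink /
  white SSTR2 expression zones; nuclear detection by exact 1-D k-means
  intensity classification plus watershed splitting and size filtering;
  per-nucleus marker calls (`DAB_pos` vs `FB_only`) and zone assignment;
  region statistics and the Spearman correlation of %miR-positive nuclei
  against ordinal zone level.
- **Biomarker module** — qPCR fold enrichment `2^-ΔCT` against a
  reference miRNA, multiplicative predictors (P1, P2, P3, P), strict
  `> cutoff` dichotomization, empirical ROC with DeLong 95% CI,
  Youden/Liu cut-off selection and the DeLong two-AUC test.
- **Synthetic fixtures** — `scene_spec()`/`render_scene()` draw fields
  with known ground truth through the same stain-mixing model the
  pipeline inverts, so everything is testable without patient data;
  `simulate_ct_table()` does the same for Ct tables.

## Worked example

```r
library(andkit)

# a synthetic field: 27/22/51% zone composition, 60 nuclei, 40% DAB+
sp <- scene_spec(width_px = 192, height_px = 192, n_nuclei = 60,
                 noise_sd = 3, illumination_gradient = 15,
                 dab_positive_fraction = 0.4, seed = 42)
sc  <- render_scene(sp)
res <- analyze_field(sc$field, run_config(ball_radius = 150))
round(100 * res$quantification$pixel_fractions, 1)
#> dark_red light_pink      white
#>     25.3       24.1       50.6
res$quantification$nucleus_counts
#>            DAB_pos FB_only
#> dark_red         4       6
#> light_pink      11      11
#> white            9      19
res$quantification$total_nuclei
#> [1] 60
```

The measured pixel fractions recover the generated 27/22/51 composition
(band edges blur slightly under noise and illumination correction), all
60 generated nuclei are found, and per-zone `pct_mir_positive` gives the
percentage of DAB-positive nuclei among analyzed nuclei per zone — the
quantity correlated against zone level by `correlate_mir_vs_zone()`.

On the biomarker side:

```r
r <- roc_analysis(c(0.2, 0.8, 1.4, 70, 95, 160, 210, 350),
                  c(0, 0, 0, 0, 1, 1, 1, 1))
r
#> <roc_result> AUC 1.0000 (95% CI 1.0000-1.0000), 4 pos / 4 neg
select_cutoff(r, "youden")$cutoff
#> [1] 82.5
dichotomize(c(60, 70, 88), 70)   # strict: 70 is "low"
#> [1] "low"  "low"  "high"
```

## Command line

```sh
Rscript inst/cli/andkit.R synth     --out out/ --seed 7
Rscript inst/cli/andkit.R analyze   --input 'fields/*.png' --out results/ --ball-radius 150
Rscript inst/cli/andkit.R biomarker --ct ct.csv --predictor P2 --cutoff 70 --out results/
```

## Layout

- `R/` — modules: synthetic fixtures, preprocessing, stain separation,
  zone masking, nuclei detection, quantification, biomarker statistics,
  pipeline/config.
- `src/` — Rcpp kernels: ball morphology, exact Spearman permutation.
- `tests/testthat/` — unit, property and end-to-end suites with
  brute-force oracles.
- `vignettes/andkit-methods.Rmd` — models, parameters, design decisions
  and limitations.
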