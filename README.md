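# lesiontopo

Lesion-topology analysis for preclinical stroke MRI: quantify *where* an
ischemic infarct hit the brain, not just how big it is, and relate
structure-level damage to longitudinal motor and behavioral outcomes in
small cohorts.

## Who it's for and what it does

Researchers running atlas-registered stroke imaging studies (e.g. porcine
or other large-animal MCAO models) who have, per subject: a binary lesion
mask, hemisphere and ventricle masks, optionally a fractional-anisotropy
map with paired white-matter ROIs — all in a common atlas space — plus tidy
longitudinal outcome tables (gait, open field, modified Rankin Scale).

The package computes:

- **Canonical volumetrics** — lesion volume (cm³), lesion percent of the
  ipsilateral hemisphere, hemispheric swelling/atrophy
  `100 · (ipsi/contra − 1)`, and midline shift (signed mm, positive toward
  the contralateral hemisphere, measured from septum/midline-plane
  landmarks).
- **Lesion topology** — for every parcellation structure X:

  PoS(X) = 100 · (lesion ∩ X voxels) / (X voxels)
  PoL(X) = 100 · (lesion ∩ X voxels) / (lesion voxels)

  plus cohort lesion-incidence tables and PoS/PoL structure rankings.
- **White-matter asymmetry** — mean FA over paired corpus-callosum ROIs and
  a paired t-test of ipsilateral vs contralateral FA.
- **Outcome correlation** — Pearson r between acute imaging features (top
  PoS structures + canonical metrics) and each functional outcome, with a
  minimum-of-3-lesioned-subjects filter per structure and
  Benjamini–Hochberg FDR over each heatmap.
- **A synthetic phantom cohort** with exact, recorded ground truth (atlas,
  lesions hitting stated fractions of each structure, swelling producing a
  known midline shift, FA decrements, outcomes from a stated
  damage→deficit model), so the whole chain is testable without data.

Everything is tidyverse-native: data frames in, tibbles out, `tidy()` /
`glance()` on test objects, `autoplot()` on heatmaps.

## Worked example

Recompute a published-style one-sample test straight from printed
summaries — an acute cohort midline shift of 1.57 ± 0.83 mm (n = 7) tested
against 0:

```r
library(lesiontopo)
tidy(one_sample_t(mean = 1.57, sd = 0.83, n = 7, mu0 = 0))
#> # A tibble: 1 × 7
#>   statistic    df p_value estimate     n method            degenerate
#>       <dbl> <dbl>   <dbl>    <dbl> <dbl> <chr>             <lgl>
#> 1      5.00     6 0.00244     1.57     7 One-sample t-test FALSE
```

p = 0.0024: the acute shift is reliably different from the no-shift null.

Simulate a full phantom cohort (7 stroked, 5 controls) and run the whole
pipeline:

```r
cohort   <- simulate_cohort(seed = 1)
analysis <- analyze_cohort(cohort)
report   <- report_cohort(analysis)

dplyr::filter(report$metric_summary, timepoint_day == 1)
#>   timepoint_day                     metric   mean     sd n p_vs_normal
#> 1             1 hemispheric_change_percent 18.379 7.7349 7   0.0007539
#> 2             1     lesion_percent_of_ipsi  3.429 0.8459 7          NA
#> 3             1          lesion_volume_cm3  2.102 0.5231 7          NA
#> 4             1           midline_shift_mm  1.701 0.9577 7   0.0033271
```

Mean ± SD of each canonical metric at day 1, with the midline shift and
hemispheric swelling each tested against "no change" (both significant —
the phantom was generated with acute swelling). Which structures took the
most damage:

```r
head(analysis$ranking_pos, 3)
#>   structure_id       structure_name mean_score sd_score n_subjects
#> 1           11      claustrum_right     56.446   14.350          7
#> 2           12        putamen_right     42.414    6.126          7
#> 3           13 insular_cortex_right     32.418   16.220          7
```

The claustrum leads the PoS ranking (56% of it infarcted on cohort
average). White-matter integrity and the damage→outcome heatmap:

```r
analysis$fa_test
#> Paired t-test, ipsilateral vs contralateral FA
#>   statistic = -120.5195, df = 6, p = 2.2e-11 (estimate = -0.1351, n = 7)

dplyr::filter(analysis$heatmaps$day2, included) |>
  dplyr::arrange(p_fdr) |> head(4) |>
  dplyr::select(feature, outcome, r, p_raw, p_fdr)
#>             feature        outcome      r  p_raw p_fdr
#> 1 pos:putamen_right       velocity -0.697 0.0817 0.758
#> 2 pos:putamen_right    step_length -0.530 0.2210 0.758
#> 3 pos:putamen_right  swing_percent -0.558 0.1931 0.758
#> 4 pos:putamen_right stance_percent -0.552 0.1984 0.758
```

The FA of the ipsilateral corpus callosum is 0.135 lower than the
contralateral side (the phantom's built-in 30% decrement). Putamen damage
correlates negatively with gait velocity (r = −0.70) — the phantom's
outcome model loads motor deficits on the putamen — while at n = 7 nothing
survives FDR, the expected small-cohort behaviour.
`autoplot(analysis$heatmaps$day2)` renders the heatmap;
`write_cohort(cohort, "out/")` exports NIfTI volumes, CSVs and ground-truth
sidecars. A thin CLI over the same functions lives at
`inst/cli/lesiontopo.R` (`simulate` / `analyze` / `report`).

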