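---
title: "Lesion topology analysis: models, phantom design, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lesion topology analysis: models, phantom design, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lesiontopo)
library(dplyr)
```

## The problem

Standard clinical MRI metrics of ischemic stroke — lesion volume, midline
shift, hemispheric swelling — have only moderate prognostic value for motor
outcomes. Lesion *topology* asks a sharper question: **which** structures
were hit, and how badly? Given a co-registered parcellation atlas and a
binary lesion mask, each structure X gets two scores:

- **PoS** (percent of structure) = 100 × (lesion voxels overlapping X) /
  (voxels of X): how much of the structure is infarcted.
- **PoL** (percent of lesion) = 100 × (lesion voxels overlapping X) /
  (total lesion voxels): how much of the infarct lies in the structure.

Because atlas labels are mutually exclusive, the PoL values over all
structures plus the unlabeled lesion fraction conserve to 100% — an exact
voxel-count identity that the test suite asserts against a literal
triple-loop counter.

Structure-level damage is then correlated (Pearson) against longitudinal
functional outcomes — spatiotemporal gait parameters, open-field activity,
a pig-adapted modified Rankin Scale — in small cohorts, under
Benjamini–Hochberg FDR control, alongside the canonical MRI metrics.

This package implements that whole chain, plus a synthetic phantom cohort
with exact ground truth, so every stage is testable without animal data.

## Canonical volumetrics

All volumes are voxel counts times the voxel volume, which is identical to
the clinical per-slice area × slice-thickness summation for the same mask
(the default phantom spacing of 1 × 1 × 3 mm uses the typical 3.0 mm T2W
slice thickness). Hemisphere volumes exclude the lateral ventricles and the
cerebellum. Derived metrics:

- lesion percent of the ipsilateral hemisphere = 100 × lesion / ipsi;
- hemispheric change = 100 × (ipsi/contra − 1), positive = swelling,
  negative = atrophy (equivalently the ipsi:contra ratio expressed as a
  percent change from parity);
- midline shift = signed perpendicular distance from the septum pellucidum
  to the ideal midline plane, **positive toward the contralateral
  hemisphere** (acute swelling pushes the septum contralaterally; chronic
  atrophy pulls it back past the midline, hence negative chronic shifts).

Midline landmarks are explicit inputs (phantom sidecar or a landmarks CSV).
The clinical procedure is a manual three-line measurement; automating
septum detection from image intensities is out of scope by design.

## The phantom: what it emulates and what it does not

`generate_atlas()` packs axis-aligned ellipsoidal structures on a jittered
lattice in the left cerebral hemisphere of an ellipsoidal brain and mirrors
them exactly across the midline plane (the left–right grid dimension is
required to be even so reflection is a voxel permutation). A posterior cap
forms the cerebellum; one lateral ventricle per hemisphere sits near the
midline. This geometry is deliberately simple: it is trivially mirrorable
and volume-computable, which is what testing the overlap logic requires.

`generate_subject()` realises pathology with *exact* ground truth:

- **Lesion**: for each targeted structure, voxels are selected
  deterministically nearest-first from a lateral infarct focus, so achieved
  coverage is `round(fraction × n_voxels)` voxels — within one voxel of the
  target by construction.
- **Swelling/atrophy**: rather than a continuous lateral affine scale
  (whose voxelisation error grows with the surface area and cannot meet a
  ±1-voxel contract), exactly `round(p/100 × contralateral_count)` voxels
  are added to (or removed from) the ipsilateral hemisphere surface by
  deterministic dilation/erosion. The measured ipsi/contra ratio is then
  exact to the rounding voxel.
- **Midline shift**: the septum landmark is displaced rigidly by the
  specified millimetres; measurement recovers it exactly.
- **FA**: mirrored corpus-callosum ROIs straddle the midline; the
  ipsilateral ROI carries `baseline × (1 − decrement)` plus Gaussian noise,
  clipped to [0, 1].

Not emulated: MR contrast, bias fields, partial voluming, k-space
artifacts, registration error, or any deformable biomechanics. Passing
tests therefore demonstrate correctness of the *measurement and inference
chain*, not robustness to acquisition artifacts or imperfect registration —
both named limitations of atlas-based lesion analysis in real data.

Default cohort conditions mirror a typical porcine MCAO study: 7 stroked /
5 control subjects; acute (day 1) swelling of +15.17 ± 7.89% with a
+1.57 ± 0.83 mm shift; chronic (day 28) shift of −1.99 ± 1.00 mm with the
hemisphere settling below parity (−3.5 ± 3.63%); chronic lesions at 0.37 ×
acute coverage; an acute corpus-callosum FA decrement of 0.30. The phantom
brain is a scaled-down geometry (default 64 × 64 × 24 voxels), so absolute
phantom volumes are not calibrated to any particular species; all derived
metrics are ratios or differences and are scale-free.

## The damage → deficit outcome model

For parameter *p*, subject *s*, day *t ≥ 0*:

value = baseline_p × (1 − Σ_k β[p,k] · PoS[s,k]/100 · 2^(−t/τ_p)) + ε,
ε ~ N(0, σ_p)

with deficits recovering exponentially (default half-life τ = 7 days,
matching functional recovery over a four-week course) and no deficit before
stroke (t < 0). Positive β depresses an outcome; stance percent carries a
negative β because it rises after stroke. mRS is generated by thresholding
the latent deficit score onto the 0–6 integer scale; the six cut points are
fixed in the model configuration because no generative model for mRS exists
to copy. Noise defaults to 10% of each baseline. With β = 0 and σ = 0 every
value equals its baseline — a tested invariant.

The joint distribution of per-structure coverage across subjects is not
identifiable from published summaries, so the sampler is an explicit free
choice: each structure has an incidence probability and a Beta-distributed
coverage around a declining mean, times a subject-level severity multiplier
(severely infarcted subjects are damaged across structures, like a
territorial infarct). The multiplier range is a parameter; setting it to
`c(1, 1)` makes coverage independent across structures.

## Statistical engine

- `one_sample_t()` accepts raw vectors **or** printed (mean, SD, n)
  summaries, so published tables are first-class inputs. Recomputing from
  the printed acute cohort summaries: midline shift 1.57 ± 0.83 mm (n = 7)
  vs 0 gives p = 0.0024; chronic −1.99 ± 1.00 vs 0 gives p = 0.0019;
  hemispheric ratio 115.17 ± 7.89% vs 100 gives p ≈ 0.00225.
- All tests are two-sided (printed p-values are consistent with two-sided
  testing) and pure functions of their inputs.
- Zero-variance inputs yield a **degenerate-flagged** result (`NA`
  statistic and p) rather than an error or a spurious p = 0 — the honest
  behaviour when, e.g., all paired FA differences are identical in a tiny
  cohort.
- `bh_fdr()` is the Benjamini–Hochberg step-up (BH is the default reading
  of "FDR-corrected"; it is cross-checked against an independent
  implementation in the tests). The FDR family defaults to one heatmap per
  call; a per-outcome family is available since the published grouping is
  not stated.
- `rm_anova_sidak()` fits the split-plot ANOVA `value ~ group × timepoint +
  Error(subject)` (between: group; within: timepoint), reports no
  sphericity correction (none was applied in the emulated workflow) but
  emits a Greenhouse–Geisser epsilon for information, and attaches
  Sidak-adjusted pairwise comparisons, `p_adj = 1 − (1 − p)^k`: between
  groups at each timepoint and within group against baseline. Unbalanced
  designs are rejected with the missing cells named, since the split-plot
  decomposition assumes a complete subject × timepoint grid.

## Correlation pipeline

Features at the acute imaging timepoint (top-n structures by cohort-mean
PoS, plus the four canonical metrics) are correlated with outcomes at each
post-stroke timepoint, within the stroked group only, gait outcomes sliced
to the forelimb contralateral to the occlusion. Two filters precede FDR:

1. a PoS feature requires ≥ 3 subjects with a lesion in that structure
   (small-n correlations on 1–2 nonzero points are meaningless);
2. zero-variance features or outcomes are flagged and excluded.

Excluded cells never enter the FDR family, so they provably cannot perturb
the adjusted p-values of included cells (tested by deleting them and
comparing).

### Power and the recovery property

The pipeline's recovery property is checked over 200 simulated cohorts of
n = 12 stroked subjects with independent per-structure coverage, stated
betas, and noise at 10% of baseline. Two facts shape its design:

- Per-cohort **sign** recovery in ≥ 95% of cohorts needs a population
  correlation of roughly |ρ| ≳ 0.55 at n = 12 (Fisher z: the sampling SD
  of z is 1/3, so ρ = 0.55 puts the wrong-sign tail near 3%). The stated
  betas therefore put one dominant coupling on each outcome (velocity
  β = 0.6, stance β = −0.5 on the top structure) — the configuration the
  strong putamen–velocity relationship exemplifies. Several competing
  moderate betas would cap each feature's sign recovery near 90% no matter
  how the pipeline is implemented.
- Null features (β = 0) cannot have small mean |r|: at n = 12 the null
  expectation is E|r| = (2/(n−2))/B(1/2, (n−2)/2) ≈ 0.246. The meaningful
  null property is the absence of systematic bias — the across-cohort mean
  r per null feature stays within ±0.2 of zero (empirically within ±0.01)
  while mean |r| sits at the theoretical floor.

## Numerical choices and degenerate inputs

- Voxel indices are 0-based in world-coordinate computations; world
  coordinates are mm through the 4 × 4 affine. Volumes in cm³, shifts in
  mm, FA unitless in [0, 1].
- Structure rankings break ties alphabetically by structure name, so
  rankings are deterministic.
- Incidence is reported rounded to one decimal (2/7 → 28.6); the underlying
  counts are kept. The presence threshold defaults to one voxel
  ("any lesioned pixel marks the structure positive") and is configurable
  because partial-volume noise in real data may warrant more.
- PoS denominators default to the unilateral label; `merge_pairs = TRUE`
  pools bilateral partners. Cohort PoS/PoL means average across all stroked
  subjects, zeros included; `lesioned_only = TRUE` restricts to lesioned
  subjects. Neither convention is asserted as the published one — both are
  supported.
- `r = ±1` (collinear inputs) short-circuits to p = 0 rather than passing
  an infinite t statistic through `pt()`.
- All randomness flows through seeded generators (`withr::with_seed`);
  identical seeds and configs give byte-identical volumes and tables.

## Problem sizes used in the tests

The suite exercises 32³-and-smaller grids for oracle-equivalence loops, the
default 64 × 64 × 24 grid for end-to-end recovery, 200 cohorts × 12
subjects for correlation recovery, and 2,000 replicates for type-I and FDR
calibration — sizes chosen so each property is measured with useful
Monte-Carlo precision while the whole suite stays fast.

## Known limitations

- The phantom's geometry is convex and symmetric; real parcellations have
  folded, interdigitated structures where partial voluming matters.
- The outcome model is linear in PoS with independent Gaussian noise; real
  deficits saturate, interact across structures, and have heteroscedastic,
  sometimes floor-censored measurements.
- Midline shift relies on supplied landmarks; no intensity-based septum
  detection is provided.
- RM-ANOVA rejects incomplete grids instead of fitting mixed models;
  mixed-effects alternatives are out of scope.
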