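---
title: "Detecting cell-type composition shifts in irradiated lung transcriptomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting cell-type composition shifts in irradiated lung transcriptomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radioshift)
```

## The problem

A single thoracic radiation dose triggers, months later, a fibrotic
remodeling of the lung in which immune and mesenchymal populations —
macrophages, mast cells, dendritic cells, fibroblast-like mesenchymal
cells — expand at the expense of the resident endothelium and
epithelium. Blocking connective tissue growth factor (CTGF) with a
monoclonal antibody can reverse the injury, and with it the bulk
transcriptional signature. Bulk microarray profiles convolve two
signals: per-cell expression changes and shifts in cellular
composition. This package implements a marker-panel approach to
separating them: it first isolates the dominant treatment-associated
expression program from the arrays themselves, then asks whether genes
that distinguish individual cell types in purified-cell atlases are
over-represented in that program. Strong enrichment of a cell type's
distinguishing genes among radiation-elevated probes is the signature
of a composition shift rather than uniform per-cell re-regulation.

## Pipeline model and assumptions

The analysis chain (see `run_pipeline()`) assumes:

* **Intensity scale.** Raw values are nonnegative scanner intensities.
  Comparability across chips is restored by dividing each chip by the
  50th percentile of its own positive measurements — a rank-based
  scaling robust to the heavy right tail of expression distributions.
* **Contemporaneous controls.** The biological quantity of interest is
  the fold ratio to unirradiated lungs *of the same timepoint*; the
  per-probe median over timepoint-matched control arrays is the
  denominator. With two controls per timepoint the median equals their
  mean, which makes control arrays average to a ratio of exactly 1.
* **Background indistinguishability.** A probe whose raw signal is
  within a few multiples of the scanner noise floor on essentially all
  arrays carries no usable information. The noise floor is estimated
  per array as the SD-consistent median absolute deviation of the
  lowest-decile intensities — a documented, reproducible statistic
  standing in the role a proprietary vendor error model plays in the
  original software chain. The filter's decision rule (signal < 3× the
  coefficient on ≥ 28 arrays) is preserved as configuration.
* **Two-criterion differential screening.** Probes must show both a
  substantial (strictly > 2-fold, either direction) and a statistically
  significant (Welch's t, p strictly < 0.05) change. Tests run on log2
  ratios, where multiplicative noise is symmetric and variances are
  comparable between elevated and diminished probes; fold changes are
  reported on the linear scale. No multiple-testing correction is
  applied by default — list selection deliberately uses raw p-values,
  relying on the downstream pattern-correlation step (p < 0.001) to
  discard incoherent false positives; `select_altered(fdr = TRUE)`
  gates on Benjamini–Hochberg-adjusted values instead for users who
  prefer a controlled list on its own.
* **One dominant pattern.** The treatment response is modeled as a
  single shared expression program: PCA over the combined altered-probe
  matrix with probes as observations and arrays as variables, each
  probe centered across arrays, components from the covariance
  structure (no per-array rescaling — arrays are already on a common
  ratio scale, and rescaling would equalize timepoints with very
  different effect sizes). Probes correlated with the first component
  at p < 0.001 — the exact t transform on `n_arrays − 2` degrees of
  freedom, appropriate because the array count is small and fixed —
  form the coordinately regulated set, split by correlation sign into
  elevated and diminished probes.
* **Marker exclusivity.** A gene distinguishes a cell type when its
  mean atlas expression is strictly > 64× the pooled mean of all other
  atlas samples with a two-sided Mann–Whitney p < 0.001, and it
  qualifies for exactly one type. The pooled-mean comparator is the
  plain reading of "higher than all other samples"; a stricter
  max-over-other-type-means comparator is available
  (`derive_panels(comparator = "max")`).
* **Proportional representation.** For a panel with `N` probes on a
  platform of `T`, appearing `n` times in a query list of `t`, fold
  enrichment is `(n/t)/(N/T)` and significance comes from the 2×2 table
  `[n, t−n; N−n, (T−t)−(N−n)]` by Pearson's χ² without continuity
  correction (df = 1). Panels may originate from different platforms,
  so `T` is honored per panel.

## Tunable parameters

| Parameter | Default | Where | Meaning |
|---|---|---|---|
| `percentile` | 50 | `normalize_to_percentile()` | per-chip scaling percentile (% of positive values) |
| `multiplier` | 3 | `filter_low_intensity()` | multiples of the per-array background scale a signal must reach |
| `min_failing_arrays` | 28 | `filter_low_intensity()` | arrays on which a probe may fail before removal (the full default design) |
| `fc_min` | 2 | `select_altered()` | strict linear fold-change threshold |
| `p_max` | 0.05 | `select_altered()` | strict Welch-t p threshold |
| `p_max` | 0.001 | `correlate_with_pc1()` | strict PC1-correlation p threshold |
| `fold_min` | 64 | `derive_panels()` | strict linear mean-ratio threshold for markers |
| `p_max` | 0.001 | `derive_panels()` | strict Mann–Whitney p threshold |
| `denom_floor` | 1e-6 | `derive_panels()` | additive floor (intensity units) keeping marker ratios defined |

All thresholds are strict inequalities, matching the "greater than" /
"less than" phrasing of the selection rules: a probe at exactly 2-fold
or a marker at exactly 64× is excluded.

## The synthetic-data generator

`simulation_config()` fixes the study conditions the generators
emulate; they are the package's defaults and are not adjusted per
analysis.

* **Design.** 7 groups (two unirradiated, irradiation alone, and four
  antibody regimens started 2 days before or 2, 20 or 112 days after
  irradiation) × 2 timepoints (18 and 30 weeks) × 2 replicates
  = 28 arrays, the design referenced by the ≥ 28-array filter clause.
* **Atlas.** 6 lung-relevant cell types × 5 samples. Five atlas samples
  per type is the smallest replication at which a perfectly separating
  two-sided rank test of one type against the pooled rest (5 vs 25) can
  clear p < 0.001; real atlases have more, but more samples only make
  the test easier. Each type receives 40 exclusive markers planted at
  128× (twice the 64× screen, so estimation noise cannot mask them),
  on per-gene log-normal baselines (median 100 intensity units,
  log-SD 1).
* **Bulk mixtures.** Each array is the composition-weighted mean of the
  atlas cell-type mean profiles. The baseline composition (epithelial
  0.45, endothelial 0.25, macrophage 0.12, mesenchymal 0.10, dendritic
  0.05, mast 0.03) reflects a structural-cell-dominated healthy lung
  with a resident macrophage pool. Planted shifts multiply the
  macrophage/mesenchymal fractions by 5 and mast/dendritic by 6 in the
  irradiated groups not rescued by late treatment at 18 weeks, with
  half-strength persistence only in untreated irradiated lungs at 30
  weeks; fractions are renormalized to sum to 1, so the realized
  marker fold changes land near 2.1–2.6× (and the structural types are
  correspondingly diluted, seeding the diminished set). Multipliers
  were chosen so the planted biology sits just above the 2-fold screen
  — the regime where the screen's behavior is worth testing — rather
  than trivially far from it.
* **Noise.** Multiplicative mean-1 log-normal noise with coefficient of
  variation 0.2, the intensity-scale noise model standard for
  microarrays; a floor of 1 intensity unit keeps every value positive
  so ratio statistics stay defined. All randomness flows from the
  explicit `seed` field; the package never touches the global RNG
  stream (`with_seed()` saves and restores it).
* **Pattern fixture.** `generate_pattern_matrix()` plants two
  orthogonal array-space patterns (an irradiation-response contrast and
  a timepoint contrast) carrying 70% and 30% of the signal variance
  across 600 + 200 probes plus 200 pure-noise probes, for direct tests
  of variance-fraction recovery and sign partitioning.

What the generator does **not** emulate: probe-level feature
extraction, dye or spatial artifacts, probe–probe correlation beyond
shared cell-type origin, per-cell expression re-regulation (all
planted signal is compositional), and cross-species or cross-platform
identifier ambiguity (the platform map defaults to the identity).
Passing recovery tests therefore demonstrates that the pipeline's
statistics do what they claim under the stated noise model — not that
real arrays meet those assumptions.

## Numerical conventions

* Percentiles use linear interpolation between order statistics
  (`stats::quantile` type 7); the convention is fixed and documented
  because rank-based scaling is otherwise ambiguous.
* Medians over an even number of control arrays are the mean of the two
  central values. Probes whose control median is zero get `NA` ratios
  and are excluded from every downstream test rather than imputed.
* Degenerate Welch tests: two constant equal groups give t = 0, p = 1;
  constant unequal groups give an infinite statistic with p = 0,
  flagged `degenerate`.
* Mann–Whitney U uses midranks for ties; p is exact by enumeration of
  all group assignments when the pooled size is ≤ 12 (enumeration
  handles ties, unlike the classical exact distribution), otherwise a
  normal approximation with tie and continuity correction.
* PC1's sign is arbitrary, so it is oriented to make the mean loading
  over the untreated irradiated arrays at the first timepoint positive;
  "elevated" then means positively correlated with the irradiation
  response. Probes cannot have r = 0 in the selected set (p < 0.001
  excludes it), so the sign partition is total.
* Hierarchical ordering clusters probes by average linkage on
  1 − Pearson correlation of log2 profiles, with probes sorted
  lexicographically beforehand so ties resolve deterministically.
* χ² representation tests return `NaN` when a marginal of the 2×2 table
  is empty (e.g. the query equals the whole platform), and error on
  inconsistent counts; fold values are kept at full precision and
  rounded only for display.
* Run manifests checksum the stage outputs (xxHash via `rlang::hash`),
  so bit-identical re-runs are verifiable.

## Design choices that were genuinely open

* **Test scale.** The selection rules pair a linear fold threshold with
  a t-test whose scale is unstated in this kind of workflow; tests run
  on log2 ratios for variance symmetry while folds stay linear.
* **Treatment lists.** "Any treatment vs irradiation alone" can be read
  as one pooled contrast or per-regimen contrasts; the default unions
  the four per-regimen lists (each vs irradiation alone, per
  timepoint), since pooling heterogeneous regimens inflates
  within-group variance; `pipeline_config(treatment_mode = "pooled")`
  gives the other reading.
* **Marker ratio scale.** The 64× screen is applied to linear-scale
  means — the phrasing is a linear ratio — with a small additive floor
  on the denominator; log-scale means would be geometric and stricter.
* **Error model.** The original low-intensity filter references a
  vendor error model that is not publicly specified; the MAD-on-lowest-
  decile estimator is this package's own documented replacement,
  preserving the filter's intent (drop probes indistinguishable from
  background) with a reproducible statistic.
* **PCA preprocessing.** Covariance PCA on per-probe-centered log2
  ratios; a correlation-matrix PCA would weight all arrays equally and
  dilute the strong 18-week response that defines the pattern.

## Problem sizes and limitations

The shipped tests and the acceptance script run the generators at their
default sizes: 4,000 probes × 28 arrays per study, 6 × 5 atlas samples,
20 simulation seeds for pattern-recovery and end-to-end checks and 100
seeds for marker-panel operating characteristics. These sizes keep the
full suite fast while leaving every statistic in the same regime as a
44K-probe array (the low-intensity filter, for instance, removes the
same sub-background stratum it would at full scale).

Known limitations: enrichment records are marker-panel counts, not a
full deconvolution — fold enrichment ranks composition shifts but does
not estimate fractions; raw-p list selection is a faithfulness choice,
not a recommendation; the χ² p-values assume independent probe
sampling, which probe-level redundancy on real platforms violates; and
panels derived from a single atlas under the pooled-mean comparator
can, by construction, almost never contain a gene shared by two highly
expressing types — cross-atlas panel merges are where the uniqueness
filter earns its keep.
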