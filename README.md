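# radioshift

Thoracic irradiation remodels the cellular composition of the lung:
macrophages, mast cells, dendritic cells and mesenchymal cells expand
during the fibrotic response, and anti-CTGF (connective tissue growth
factor) antibody treatment can reverse both the injury and its
transcriptional signature. `radioshift` reimplements, as a tested R
pipeline, the microarray analysis workflow used to demonstrate this:
it detects radiation- and treatment-responsive expression programs in
bulk lung arrays and attributes them to cell-type composition shifts by
scoring cell-type marker panels derived from expression atlases.

It is aimed at transcriptomics analysts who want each stage of that
workflow as a composable, auditable function — with a synthetic-data
generator that emulates the study design (noisy mixtures of cell-type
profiles with planted composition shifts) so the whole pipeline is
testable without downloading any array data.

## The method

Starting from a raw probe × array intensity matrix over a
7-group × 2-timepoint × 2-replicate design (28 arrays):

1. **Normalization** — each chip is divided by the 50th percentile of its
   own measurements, then each probe is divided by the median of
   timepoint-matched unirradiated control arrays, giving control ratios.
2. **Low-intensity filter** — probes with raw signal below 3× a per-array
   robust background scale (MAD of the lowest-decile intensities) on
   ≥ 28 arrays are removed.
3. **Differential screen** — per contrast (irradiation vs control, and
   each antibody regimen vs irradiation alone, per timepoint), probes
   with a strict > 2-fold change and Welch's t-test p < 0.05 on log2
   ratios are flagged; per-contrast lists are unioned.
4. **Pattern extraction** — PCA over the combined list (probes as
   observations, arrays as variables, per-probe centering). Probes whose
   profiles correlate with the first component at p < 0.001 (exact t
   transform) are partitioned by correlation sign into
   radiation-elevated and radiation-diminished sets.
5. **Marker panels** — from a gene × sample cell-type atlas, genes with
   mean expression > 64× higher in one cell type than the pooled rest
   (Mann–Whitney p < 0.001), unique to a single type, form that type's
   distinguishing panel; panels are mapped onto the study platform.
6. **Enrichment** — each panel is scored in the elevated set by fold
   enrichment `(n/t)/(N/T)` — n panel probes in the query list of size
   t, against N panel probes among T platform probes — with a 2×2 χ²
   test of the observed vs platform proportion.

## Worked example

```r
library(radioshift)

cfg <- pipeline_config(sim = simulation_config(seed = 1))
run <- run_pipeline(cfg)
run
#> <pipeline_run>
#>   4000 probes x 28 arrays; 3886 retained after low-intensity filter
#>   combined altered list: 155 (RT 64, treatment 133)
#>   PC1 variance fraction 0.725; 146 correlated (99 elevated / 47 diminished)
#>   top enriched panel: mast_cell (fold 27.3)

run$representation
#> # A tibble: 6 × 8
#>   cell_type          n     N     t     T  fold   chi2         p
#>   <chr>          <int> <int> <int> <int> <dbl>  <dbl>     <dbl>
#> 1 mast_cell         27    40    99  4000  27.3 708.   6.10e-156
#> 2 dendritic_cell    27    40    99  4000  27.3 708.   6.10e-156
#> 3 macrophage        24    40    99  4000  24.2 554.   1.77e-122
#> 4 mesenchymal       21    40    99  4000  21.2 419.   4.24e- 93
#> 5 endothelial        0    40    99  4000   0     1.03 3.11e-  1
#> 6 epithelial         0    40    99  4000   0     1.03 3.11e-  1
```

The synthetic study plants an expansion of macrophage, mast-cell,
dendritic-cell and mesenchymal fractions in the irradiated groups that
late antibody treatment reverses. The pipeline recovers exactly that:
the four shifted cell types' panels are 21–27× over-represented among
radiation-elevated probes (χ² p ≪ 0.001), while the unshifted
endothelial and epithelial panels contribute no elevated probes. The
first principal component carries 72% of the variance of the combined
altered-probe matrix — the dominant irradiation-response pattern —
and `autoplot(run$pattern)` shows its per-array loadings by group and
timepoint; `plot_representation(run$representation)` draws the
enrichment table.

Each stage is also available on its own (`normalize_to_percentile()`,
`filter_low_intensity()`, `select_altered()`, `run_pca()`,
`derive_panels()`, `representation_table()`, ...), takes a tidy input
and returns a tibble or a fitted object with `tidy()`/`glance()`
methods, so intermediate results can be inspected or swapped for real
data read with `read_expr_matrix()` / `read_series_matrix()`.

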