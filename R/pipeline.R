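#' Configuration for the end-to-end analysis
#'
#' Bundles every stage's tunable parameters under their standard defaults:
#' per-chip 50th-percentile normalization, the 3x background multiplier
#' with the >= 28-array failure rule, the strict 2-fold / p < 0.05
#' differential screen, the p < 0.001 first-component correlation cut, and
#' the 64x / p < 0.001 marker-panel screen.
#'
#' @param sim A [simulation_config()] describing the synthetic inputs (and
#'   carrying the seed), or `NULL` when supplying your own matrices to the
#'   stage functions directly.
#' @param control_group Unirradiated control group label.
#' @param rt_group Irradiation-alone group label.
#' @param treated_groups Antibody-regimen group labels contrasted against
#'   `rt_group`; defaults to every `sim` group starting with `RT_FG`.
#' @param percentile Per-chip normalization percentile.
#' @param error_multiplier,min_failing_arrays Low-intensity filter
#'   parameters; see [filter_low_intensity()].
#' @param fc_min,p_max Differential-screen thresholds; see
#'   [select_altered()].
#' @param pc1_p_max First-component correlation threshold; see
#'   [correlate_with_pc1()].
#' @param marker_fold_min,marker_p_max Panel-derivation thresholds; see
#'   [derive_panels()].
#' @param treatment_mode `"union"` (default) screens each antibody regimen
#'   against irradiation alone and unions the per-regimen lists;
#'   `"pooled"` contrasts all treated arrays at once.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(sim = simulation_config(),
                            control_group = "noRT_IgG",
                            rt_group = "RT_IgG",
                            treated_groups = NULL,
                            percentile = 50,
                            error_multiplier = 3,
                            min_failing_arrays = 28,
                            fc_min = 2,
                            p_max = 0.05,
                            pc1_p_max = 0.001,
                            marker_fold_min = 64,
                            marker_p_max = 0.001,
                            treatment_mode = c("union", "pooled")) {
  treatment_mode <- match.arg(treatment_mode)
  if (is.null(treated_groups) && !is.null(sim)) {
    treated_groups <- grep("^RT_FG", sim$study_groups, value = TRUE)
  }
  structure(list(sim = sim, control_group = control_group,
                 rt_group = rt_group, treated_groups = treated_groups,
                 percentile = percentile,
                 error_multiplier = error_multiplier,
                 min_failing_arrays = min_failing_arrays,
                 fc_min = fc_min, p_max = p_max, pc1_p_max = pc1_p_max,
                 marker_fold_min = marker_fold_min,
                 marker_p_max = marker_p_max,
                 treatment_mode = treatment_mode),
            class = "pipeline_config")
}

#' Run the full analysis on synthetic (or supplied) data
#'
#' Executes the stages in order: generate the atlas and study
#' (or use `atlas`/`study` as given), estimate background and drop
#' low-intensity probes from the raw matrix, normalize per chip and then to
#' timepoint-matched controls, screen each contrast for altered probes
#' (irradiation versus control, and each antibody regimen versus
#' irradiation alone, per timepoint), union the lists, extract the dominant
#' pattern by PCA, select probes correlated with the first component and
#' partition them by sign, derive marker panels from the atlas, map them to
#' the study platform, and score their representation in the elevated set.
#'
#' @param cfg A [pipeline_config()].
#' @param atlas,study Optional pre-built [cell_atlas] / raw [expr_mat];
#'   defaults are generated from `cfg$sim`.
#' @param map Optional gene-to-probe map; defaults to the identity map.
#' @return An object of class `pipeline_run`: a list with the stage outputs
#'   (`ratios`, `contrasts`, `combined`, `pattern`, `pc1_correlation`,
#'   `partition`, `panels`, `representation`, `truth`) and `manifest`, a
#'   list of probe-count attrition records, the parameter snapshot and an
#'   output checksum. Re-running with the same config yields an identical
#'   manifest.
#' @export
run_pipeline <- function(cfg, atlas = NULL, study = NULL, map = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  truth <- list()
  if (is.null(atlas)) {
    gen <- generate_atlas(cfg$sim)
    atlas <- gen$atlas
    truth$markers <- gen$truth
  }
  if (is.null(study)) {
    gen <- generate_study(cfg$sim, atlas)
    study <- gen$study
    truth <- c(truth, gen$truth)
  }
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", what,
                    conditionMessage(e)))
    })
  }

  filt <- stage("low_intensity_filter",
                filter_low_intensity(study, cfg$error_multiplier,
                                     cfg$min_failing_arrays))
  retained <- filt$probe_id[filt$retained]
  ratios <- stage("normalization", {
    normalize_to_control_median(
      normalize_to_percentile(study, cfg$percentile),
      control_group = cfg$control_group)
  })
  ratios <- subset_probes(ratios, retained)

  tps <- unique(sample_info(study)$timepoint)
  contrasts <- list()
  for (tp in tps) {
    contrasts[[sprintf("RT_vs_control_%s", tp)]] <-
      contrast_spec(sprintf("RT_vs_control_%s", tp),
                    cfg$rt_group, cfg$control_group, timepoint = tp)
    if (cfg$treatment_mode == "pooled") {
      contrasts[[sprintf("treated_vs_RT_%s", tp)]] <-
        contrast_spec(sprintf("treated_vs_RT_%s", tp),
                      cfg$treated_groups, cfg$rt_group, timepoint = tp)
    } else {
      for (g in cfg$treated_groups) {
        nm <- sprintf("%s_vs_RT_%s", g, tp)
        contrasts[[nm]] <- contrast_spec(nm, g, cfg$rt_group, timepoint = tp)
      }
    }
  }
  results <- stage("differential_screen", {
    lapply(contrasts, function(ct) {
      select_altered(ratios, ct, fc_min = cfg$fc_min, p_max = cfg$p_max)
    })
  })
  altered <- lapply(results, function(r) r$probe_id[r$altered])
  rt_names <- grep("^RT_vs_control", names(altered), value = TRUE)
  rt_list <- suppressMessages(combine_lists(altered[rt_names]))
  drug_list <- suppressMessages(
    combine_lists(altered[setdiff(names(altered), rt_names)]))
  combined <- suppressMessages(combine_lists(list(rt_list, drug_list)))
  if (length(combined) < 2) {
    abort("Pipeline stage 'differential_screen' failed: fewer than 2 altered probes.")
  }

  pattern <- stage("pattern_extraction",
                   run_pca(ratios, combined, orient_group = cfg$rt_group))
  cor_tbl <- stage("pc1_correlation",
                   correlate_with_pc1(ratios, pattern, p_max = cfg$pc1_p_max))
  partition <- suppressMessages(partition_by_sign(cor_tbl))
  elevated <- partition$probe_id[partition$direction == "elevated"]
  diminished <- partition$probe_id[partition$direction == "diminished"]

  panels <- stage("marker_panels",
                  derive_panels(atlas, fold_min = cfg$marker_fold_min,
                                p_max = cfg$marker_p_max))
  if (is.null(map)) map <- identity_map(rownames(atlas$values))
  mapped <- suppressMessages(stage("platform_mapping",
                                   map_panels(panels, map)))
  platform <- probe_ids(study)
  representation <- stage("representation", {
    suppressWarnings(representation_table(elevated, mapped,
                                          platform_total = length(platform),
                                          universe = platform))
  })

  counts <- list(
    n_probes = nrow(study$values),
    n_arrays = ncol(study$values),
    n_retained = length(retained),
    altered_per_contrast = lengths(altered),
    n_rt_list = length(rt_list),
    n_drug_list = length(drug_list),
    n_combined = length(combined),
    n_pc1_selected = nrow(partition),
    n_elevated = length(elevated),
    n_diminished = length(diminished),
    pc1_variance_fraction = pattern$variance_fractions[[1]],
    n_panel_genes = nrow(panels))
  outputs <- list(ratios = ratios, contrasts = results,
                  rt_list = rt_list, drug_list = drug_list,
                  combined = combined, pattern = pattern,
                  pc1_correlation = cor_tbl, partition = partition,
                  panels = panels, mapped_panels = mapped,
                  representation = representation, truth = truth)
  manifest <- list(parameters = unclass(cfg), counts = counts,
                   checksum = rlang::hash(list(ratios$values, combined,
                                               partition, representation)))
  structure(c(outputs, list(manifest = manifest)), class = "pipeline_run")
}

#' @export
print.pipeline_run <- function(x, ...) {
  cts <- x$manifest$counts
  cat("<pipeline_run>\n")
  cat(sprintf("  %d probes x %d arrays; %d retained after low-intensity filter\n",
              cts$n_probes, cts$n_arrays, cts$n_retained))
  cat(sprintf("  combined altered list: %d (RT %d, treatment %d)\n",
              cts$n_combined, cts$n_rt_list, cts$n_drug_list))
  cat(sprintf("  PC1 variance fraction %.3f; %d correlated (%d elevated / %d diminished)\n",
              cts$pc1_variance_fraction, cts$n_pc1_selected, cts$n_elevated,
              cts$n_diminished))
  cat(sprintf("  top enriched panel: %s (fold %.1f)\n",
              x$representation$cell_type[[1]], x$representation$fold[[1]]))
  invisible(x)
}

#' @describeIn run_pipeline one-row summary of the manifest's attrition
#'   counts.
#' @param x A `pipeline_run`.
#' @param ... Unused.
#' @method glance pipeline_run
#' @export
glance.pipeline_run <- function(x, ...) {
  cts <- x$manifest$counts
  tibble(n_probes = cts$n_probes, n_arrays = cts$n_arrays,
         n_retained = cts$n_retained, n_combined = cts$n_combined,
         n_pc1_selected = cts$n_pc1_selected, n_elevated = cts$n_elevated,
         n_diminished = cts$n_diminished,
         pc1_variance_fraction = cts$pc1_variance_fraction,
         top_panel = x$representation$cell_type[[1]],
         top_fold = x$representation$fold[[1]])
}
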