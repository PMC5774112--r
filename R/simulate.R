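#' Configuration for the synthetic atlas and study generators
#'
#' The defaults emulate the design the pipeline targets: a cell-type atlas
#' with planted cell-type-exclusive markers, and a 7-group x 2-timepoint x
#' 2-replicate irradiated-lung study (28 arrays) whose bulk profiles are
#' noisy convex mixtures of the atlas cell-type profiles with planted
#' composition shifts. Irradiated groups not rescued by late antibody
#' treatment carry expanded macrophage, mast-cell, dendritic-cell and
#' mesenchymal fractions at 18 weeks, attenuated at 30 weeks; the
#' late-treatment groups revert to baseline composition.
#'
#' @param n_cell_types Number of atlas cell types.
#' @param cell_types Optional character vector of cell-type labels (length
#'   `n_cell_types`); defaults to six lung-relevant types.
#' @param n_atlas_samples_per_type Atlas samples (arrays) per cell type.
#' @param n_genes Genes on the (shared) platform.
#' @param n_markers_per_type Planted exclusive markers per cell type.
#' @param marker_fold Mean intensity of a marker in its own cell type
#'   relative to everywhere else, before noise (> 1).
#' @param study_groups Study group labels. `noRT_*` are unirradiated,
#'   `RT_IgG` is irradiation alone, `RT_FG_*` are irradiation plus antibody
#'   regimens started 2 days before (`dm2`) or 2, 20 or 112 days after
#'   irradiation.
#' @param timepoints Sacrifice timepoints.
#' @param replicates_per_cell Arrays per group x timepoint cell.
#' @param baseline_composition Named per-cell-type fractions summing to 1;
#'   the composition of unirradiated lung.
#' @param composition_shift Data frame (`group`, `timepoint`, `cell_type`,
#'   `multiplier`) of fraction multipliers applied before renormalization;
#'   `NULL` gives the default planted shifts described above.
#' @param noise_cv Coefficient of variation of the multiplicative
#'   log-normal measurement noise (mean 1).
#' @param floor_intensity Nonnegative intensity added to every value so
#'   ratio statistics stay defined.
#' @param seed Integer seed; all generator randomness flows from it.
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(n_cell_types = 6,
                              cell_types = NULL,
                              n_atlas_samples_per_type = 5,
                              n_genes = 4000,
                              n_markers_per_type = 40,
                              marker_fold = 128,
                              study_groups = c("noRT_IgG", "noRT_FG",
                                               "RT_IgG", "RT_FG_dm2",
                                               "RT_FG_d2", "RT_FG_d20",
                                               "RT_FG_d112"),
                              timepoints = c("18w", "30w"),
                              replicates_per_cell = 2,
                              baseline_composition = NULL,
                              composition_shift = NULL,
                              noise_cv = 0.2,
                              floor_intensity = 1,
                              seed = 1L) {
  chk_count <- function(x, nm, min = 1) {
    if (length(x) != 1 || !is.finite(x) || x < min || x != round(x)) {
      abort(sprintf("`%s` must be a single integer >= %d.", nm, min))
    }
  }
  chk_count(n_cell_types, "n_cell_types")
  chk_count(n_atlas_samples_per_type, "n_atlas_samples_per_type")
  chk_count(n_genes, "n_genes")
  chk_count(n_markers_per_type, "n_markers_per_type")
  chk_count(replicates_per_cell, "replicates_per_cell")
  if (!is.finite(marker_fold) || marker_fold <= 1) {
    abort("`marker_fold` must be > 1.")
  }
  if (!is.finite(noise_cv) || noise_cv < 0) abort("`noise_cv` must be >= 0.")
  if (!is.finite(floor_intensity) || floor_intensity < 0) {
    abort("`floor_intensity` must be >= 0.")
  }
  if (n_markers_per_type * n_cell_types > n_genes) {
    abort("`n_markers_per_type` x `n_cell_types` must not exceed `n_genes`.")
  }
  if (is.null(cell_types)) {
    default_types <- c("macrophage", "mast_cell", "dendritic_cell",
                       "mesenchymal", "endothelial", "epithelial")
    cell_types <- if (n_cell_types <= length(default_types)) {
      default_types[seq_len(n_cell_types)]
    } else {
      c(default_types, sprintf("cell_type_%02d",
                               seq_len(n_cell_types - length(default_types))))
    }
  }
  if (length(cell_types) != n_cell_types || anyDuplicated(cell_types)) {
    abort("`cell_types` must hold `n_cell_types` unique labels.")
  }
  if (is.null(baseline_composition)) {
    base <- c(macrophage = 0.12, mast_cell = 0.03, dendritic_cell = 0.05,
              mesenchymal = 0.10, endothelial = 0.25, epithelial = 0.45)
    baseline_composition <- if (setequal(names(base), cell_types)) {
      base[cell_types]
    } else {
      setNames(rep(1 / n_cell_types, n_cell_types), cell_types)
    }
  }
  if (!setequal(names(baseline_composition), cell_types)) {
    abort("`baseline_composition` must be named by the cell types.")
  }
  baseline_composition <- baseline_composition[cell_types]
  if (any(baseline_composition < 0) || any(baseline_composition > 1) ||
      abs(sum(baseline_composition) - 1) > 1e-8) {
    abort("`baseline_composition` fractions must lie in [0,1] and sum to 1.")
  }
  if (is.null(composition_shift)) {
    composition_shift <- default_composition_shift(study_groups, timepoints,
                                                   cell_types)
  }
  composition_shift <- as_tibble(composition_shift)
  need <- c("group", "timepoint", "cell_type", "multiplier")
  if (!all(need %in% names(composition_shift))) {
    abort("`composition_shift` needs columns group, timepoint, cell_type, multiplier.")
  }
  if (nrow(composition_shift)) {
    if (!all(composition_shift$group %in% study_groups)) {
      abort("`composition_shift` references an unknown group.")
    }
    if (!all(composition_shift$timepoint %in% timepoints)) {
      abort("`composition_shift` references an unknown timepoint.")
    }
    if (!all(composition_shift$cell_type %in% cell_types)) {
      abort("`composition_shift` references an unknown cell_type.")
    }
    if (any(composition_shift$multiplier < 0)) {
      abort("`composition_shift` multipliers must be >= 0.")
    }
  }
  chk_count(seed, "seed", min = 0)
  structure(list(n_cell_types = as.integer(n_cell_types),
                 cell_types = cell_types,
                 n_atlas_samples_per_type = as.integer(n_atlas_samples_per_type),
                 n_genes = as.integer(n_genes),
                 n_markers_per_type = as.integer(n_markers_per_type),
                 marker_fold = marker_fold,
                 study_groups = study_groups,
                 timepoints = timepoints,
                 replicates_per_cell = as.integer(replicates_per_cell),
                 baseline_composition = baseline_composition,
                 composition_shift = composition_shift,
                 noise_cv = noise_cv,
                 floor_intensity = floor_intensity,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Planted composition shifts: immune/mesenchymal expansion in irradiated
# groups not rescued by late antibody dosing (strong at 18w), persisting
# only in untreated irradiated lungs at 30w at half effect.
default_composition_shift <- function(groups, timepoints, cell_types) {
  mult <- c(macrophage = 5, mast_cell = 6, dendritic_cell = 6,
            mesenchymal = 5)
  mult <- mult[names(mult) %in% cell_types]
  if (!length(mult)) return(tibble(group = character(), timepoint = character(),
                                   cell_type = character(), multiplier = double()))
  shifted_18 <- intersect(c("RT_IgG", "RT_FG_dm2", "RT_FG_d2"), groups)
  shifted_30 <- intersect("RT_IgG", groups)
  rows <- list()
  if ("18w" %in% timepoints) {
    rows <- c(rows, lapply(shifted_18, function(g) {
      tibble(group = g, timepoint = "18w", cell_type = names(mult),
             multiplier = unname(mult))
    }))
  }
  if ("30w" %in% timepoints) {
    rows <- c(rows, lapply(shifted_30, function(g) {
      tibble(group = g, timepoint = "30w", cell_type = names(mult),
             multiplier = unname(1 + (mult - 1) / 2))
    }))
  }
  dplyr::bind_rows(rows)
}

# Per-gene baseline intensities and the gene -> cell-type marker assignment
# shared by atlas and study generation. Genes are "g%05d"; the first
# n_markers_per_type * n_cell_types are planted markers, in blocks.
simulation_blueprint <- function(config) {
  with_seed(config$seed, {
    genes <- sprintf("g%05d", seq_len(config$n_genes))
    baseline <- rlnorm(config$n_genes, meanlog = log(100), sdlog = 1)
    names(baseline) <- genes
    k <- config$n_markers_per_type
    markers <- lapply(seq_len(config$n_cell_types), function(i) {
      genes[((i - 1) * k + 1):(i * k)]
    })
    names(markers) <- config$cell_types
    # gene x cell-type matrix of pre-noise mean intensities
    means <- matrix(baseline, nrow = config$n_genes,
                    ncol = config$n_cell_types,
                    dimnames = list(genes, config$cell_types))
    for (ct in config$cell_types) {
      means[markers[[ct]], ct] <- config$marker_fold * baseline[markers[[ct]]]
    }
    list(genes = genes, baseline = baseline, markers = markers, means = means)
  })
}

# Multiplicative mean-1 log-normal noise factors with the configured CV.
lognormal_noise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic cell-type atlas with planted markers
#'
#' Each cell type receives `n_markers_per_type` exclusive marker genes whose
#' pre-noise mean intensity in that type's samples is `marker_fold` times
#' their mean everywhere else; all other genes share a per-gene baseline
#' drawn once from a log-normal intensity distribution. Samples are the
#' cell-type mean profile times multiplicative log-normal noise, plus
#' `floor_intensity`.
#'
#' @param config A [simulation_config()].
#' @return A list with `atlas` (a [cell_atlas]) and `truth`, a tibble
#'   (`cell_type`, `gene_id`) of the planted markers (pairwise disjoint
#'   across cell types by construction).
#' @export
generate_atlas <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  bp <- simulation_blueprint(config)
  n_samp <- config$n_cell_types * config$n_atlas_samples_per_type
  types <- rep(config$cell_types, each = config$n_atlas_samples_per_type)
  ids <- paste0(types, "_s",
                rep(seq_len(config$n_atlas_samples_per_type),
                    times = config$n_cell_types))
  vals <- with_seed(config$seed + 1L, {
    v <- bp$means[, types, drop = FALSE] *
      matrix(lognormal_noise(config$n_genes * n_samp, config$noise_cv),
             nrow = config$n_genes)
    v + config$floor_intensity
  })
  dimnames(vals) <- list(bp$genes, ids)
  truth <- tibble(cell_type = rep(names(bp$markers), lengths(bp$markers)),
                  gene_id = unlist(bp$markers, use.names = FALSE))
  list(atlas = cell_atlas(vals, types, atlas_id = "synthetic_atlas"),
       truth = truth)
}

#' Generate a synthetic bulk study from an atlas
#'
#' Builds the configured group x timepoint x replicate design. Each array's
#' pre-noise profile is the composition-weighted mean of the atlas cell-type
#' mean profiles, where the composition is the baseline with the configured
#' per-group/timepoint multipliers applied and renormalized to sum to 1.
#' Multiplicative log-normal noise and `floor_intensity` are then applied.
#'
#' @param config A [simulation_config()].
#' @param atlas A [cell_atlas] covering the configured cell types (normally
#'   from [generate_atlas()]).
#' @return A list with `study` (an [expr_mat], raw scale, with `group`,
#'   `timepoint`, `replicate` annotations) and `truth`, a list holding
#'   `composition` (tibble: `array_id`, `cell_type`, `fraction`) and
#'   `expected_direction` (tibble: `cell_type`, `direction` in
#'   elevated/diminished/unchanged, from the realized composition change of
#'   the untreated irradiated group versus baseline at the first timepoint).
#' @export
generate_study <- function(config, atlas) {
  stopifnot(inherits(config, "simulation_config"), inherits(atlas, "cell_atlas"))
  missing_ct <- setdiff(config$cell_types, atlas$samples$cell_type)
  if (length(missing_ct)) {
    abort(sprintf("Atlas lacks cell type(s): %s.",
                  paste(missing_ct, collapse = ", ")))
  }
  # cell-type mean profiles from the atlas
  profiles <- vapply(config$cell_types, function(ct) {
    idx <- atlas$samples$cell_type == ct
    rowMeans(atlas$values[, idx, drop = FALSE])
  }, numeric(nrow(atlas$values)))

  design <- tidyr::expand_grid(group = config$study_groups,
                               timepoint = config$timepoints,
                               replicate = seq_len(config$replicates_per_cell))
  design$array_id <- sprintf("%s_%s_r%d", design$group, design$timepoint,
                             design$replicate)
  comp <- t(vapply(seq_len(nrow(design)), function(i) {
    f <- config$baseline_composition
    sh <- config$composition_shift
    sh <- sh[sh$group == design$group[i] & sh$timepoint == design$timepoint[i], ]
    if (nrow(sh)) f[sh$cell_type] <- f[sh$cell_type] * sh$multiplier
    f / sum(f)
  }, numeric(config$n_cell_types)))
  rownames(comp) <- design$array_id

  vals <- with_seed(config$seed + 2L, {
    clean <- profiles %*% t(comp)
    clean * matrix(lognormal_noise(length(clean), config$noise_cv),
                   nrow = nrow(clean)) + config$floor_intensity
  })
  dimnames(vals) <- list(rownames(atlas$values), design$array_id)
  study <- expr_mat(vals, samples = design[, c("array_id", "group",
                                               "timepoint", "replicate")],
                    scale = "raw")

  composition <- tidyr::pivot_longer(
    dplyr::bind_cols(tibble(array_id = design$array_id), as_tibble(comp)),
    -"array_id", names_to = "cell_type", values_to = "fraction")
  expected <- expected_direction(config, comp, design)
  list(study = study,
       truth = list(composition = composition, expected_direction = expected))
}

# Direction each cell type's markers should move in the untreated
# irradiated group, from the realized (renormalized) fractions.
expected_direction <- function(config, comp, design, rt_group = "RT_IgG",
                               ref_group = "noRT_IgG") {
  tp <- config$timepoints[[1]]
  rt <- design$array_id[design$group == rt_group & design$timepoint == tp][1]
  ref <- design$array_id[design$group == ref_group & design$timepoint == tp][1]
  if (is.na(rt) || is.na(ref)) {
    return(tibble(cell_type = config$cell_types, direction = "unchanged"))
  }
  ratio <- comp[rt, ] / comp[ref, ]
  tibble(cell_type = config$cell_types,
         fraction_ratio = unname(ratio),
         direction = dplyr::case_when(ratio > 1.05 ~ "elevated",
                                      ratio < 0.95 ~ "diminished",
                                      TRUE ~ "unchanged"))
}

#' Generate a ratio matrix with two planted expression patterns
#'
#' Constructs a control-ratio [expr_mat] over the configured study design in
#' which the log2 ratios are a sum of two orthogonal array-space patterns
#' plus Gaussian noise: a primary irradiation-response pattern (high in the
#' non-rescued irradiated groups at 18 weeks, half-strength in untreated
#' irradiated lungs at 30 weeks) carried by `n_pattern_probes` probes with
#' scores +1 or -1, and a secondary timepoint pattern carried by
#' `n_secondary_probes` probes scaled so the two patterns hold the requested
#' split of the total signal variance. Used to test that principal-component
#' extraction recovers a planted variance fraction and that the
#' elevated/diminished partition recovers planted probe signs.
#'
#' @param n_pattern_probes,n_secondary_probes,n_null_probes Probe counts for
#'   the primary pattern, the secondary pattern, and pure-noise probes.
#' @param variance_split Length-2 positive weights for the primary and
#'   secondary pattern's share of the signal variance (default 70/30).
#' @param noise_sd SD of additive Gaussian noise on the log2 scale.
#' @param config A [simulation_config()] supplying the array design and seed.
#' @return A list with `ratios` (control-ratio [expr_mat]), `truth` (tibble:
#'   `probe_id`, `role` in primary/secondary/null, `direction` for primary
#'   probes), and `planted_fraction` (primary pattern's share of total
#'   planted signal variance, noise included in the denominator's
#'   expectation is not — the measured PC1 fraction is compared against
#'   this).
#' @export
generate_pattern_matrix <- function(n_pattern_probes = 600,
                                    n_secondary_probes = 200,
                                    n_null_probes = 200,
                                    variance_split = c(0.7, 0.3),
                                    noise_sd = 0.02,
                                    config = simulation_config()) {
  stopifnot(length(variance_split) == 2, all(variance_split > 0))
  design <- tidyr::expand_grid(group = config$study_groups,
                               timepoint = config$timepoints,
                               replicate = seq_len(config$replicates_per_cell))
  design$array_id <- sprintf("%s_%s_r%d", design$group, design$timepoint,
                             design$replicate)
  n_arr <- nrow(design)
  # primary pattern: irradiation response not rescued by late dosing
  a1 <- ifelse(design$group %in% c("RT_IgG", "RT_FG_dm2", "RT_FG_d2") &
                 design$timepoint == config$timepoints[[1]], 1,
               ifelse(design$group == "RT_IgG", 0.5, 0))
  a1 <- a1 - mean(a1)
  a1 <- a1 / sqrt(sum(a1^2))
  # secondary pattern: timepoint contrast, orthogonalized against a1
  a2 <- ifelse(design$timepoint == config$timepoints[[1]], 1, -1)
  a2 <- a2 - mean(a2)
  a2 <- a2 - sum(a2 * a1) * a1
  a2 <- a2 / sqrt(sum(a2^2))

  s2_scale <- sqrt((variance_split[[2]] / variance_split[[1]]) *
                     n_pattern_probes / n_secondary_probes)
  sign1 <- rep(c(1, -1), length.out = n_pattern_probes)
  sign2 <- rep(c(1, -1), length.out = n_secondary_probes)
  n_probes <- n_pattern_probes + n_secondary_probes + n_null_probes
  probes <- sprintf("p%05d", seq_len(n_probes))
  scores1 <- c(sign1, rep(0, n_secondary_probes + n_null_probes))
  scores2 <- c(rep(0, n_pattern_probes), sign2 * s2_scale,
               rep(0, n_null_probes))
  log2x <- with_seed(config$seed + 3L, {
    outer(scores1, a1) + outer(scores2, a2) +
      matrix(stats::rnorm(n_probes * n_arr, sd = noise_sd), nrow = n_probes)
  })
  dimnames(log2x) <- list(probes, design$array_id)
  truth <- tibble(probe_id = probes,
                  role = rep(c("primary", "secondary", "null"),
                             c(n_pattern_probes, n_secondary_probes,
                               n_null_probes)),
                  direction = c(ifelse(sign1 > 0, "elevated", "diminished"),
                                rep(NA_character_,
                                    n_secondary_probes + n_null_probes)))
  list(ratios = expr_mat(2^log2x,
                         samples = design[, c("array_id", "group",
                                              "timepoint", "replicate")],
                         scale = "control_ratio"),
       truth = truth,
       planted_fraction = variance_split[[1]] / sum(variance_split))
}
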