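test_that("config validation names the offending field", {
  expect_error(simulation_config(marker_fold = 1), "marker_fold")
  expect_error(simulation_config(noise_cv = -1), "noise_cv")
  expect_error(simulation_config(n_genes = 50, n_markers_per_type = 10,
                                 n_cell_types = 6), "n_markers_per_type")
  expect_error(simulation_config(baseline_composition = c(a = 0.5, b = 0.6),
                                 n_cell_types = 2, cell_types = c("a", "b")),
               "sum to 1")
  bad_shift <- tibble::tibble(group = "nope", timepoint = "18w",
                              cell_type = "macrophage", multiplier = 2)
  expect_error(simulation_config(composition_shift = bad_shift),
               "unknown group")
})

test_that("noise-free atlas plants markers at exactly marker_fold", {
  cfg <- small_sim(noise_cv = 0, floor_intensity = 0, seed = 7)
  gen <- generate_atlas(cfg)
  st <- gen$atlas$samples
  for (ct in unique(gen$truth$cell_type)) {
    g <- gen$truth$gene_id[gen$truth$cell_type == ct][1]
    own <- mean(gen$atlas$values[g, st$cell_type == ct])
    rest <- mean(gen$atlas$values[g, st$cell_type != ct])
    expect_equal(own / rest, cfg$marker_fold)
  }
})

test_that("generation is bitwise deterministic under a fixed seed", {
  cfg <- small_sim(seed = 11)
  a1 <- generate_atlas(cfg); a2 <- generate_atlas(cfg)
  expect_identical(a1$atlas$values, a2$atlas$values)
  s1 <- generate_study(cfg, a1$atlas); s2 <- generate_study(cfg, a2$atlas)
  expect_identical(s1$study$values, s2$study$values)
  expect_identical(s1$truth$composition, s2$truth$composition)
})

test_that("planted markers pass a mean-ratio >= 64 screen at default noise", {
  # Monte-Carlo pass fraction of the 64x screen over repeated atlases
  passes <- 0L; total <- 0L
  for (seed in 1:100) {
    gen <- generate_atlas(simulation_config(seed = seed))
    st <- gen$atlas$samples
    for (ct in unique(gen$truth$cell_type)) {
      genes <- gen$truth$gene_id[gen$truth$cell_type == ct]
      own <- rowMeans(gen$atlas$values[genes, st$cell_type == ct])
      rest <- rowMeans(gen$atlas$values[genes, st$cell_type != ct])
      passes <- passes + sum(own / rest >= 64)
      total <- total + length(genes)
    }
  }
  expect_gte(passes / total, 0.95)
})

test_that("pure-composition noise-free arrays equal the type profile plus floor", {
  cfg <- small_sim(noise_cv = 0, floor_intensity = 2, seed = 3,
                   baseline_composition = c(macrophage = 1, mast_cell = 0,
                                            dendritic_cell = 0, mesenchymal = 0,
                                            endothelial = 0, epithelial = 0))
  gen <- generate_atlas(cfg)
  study <- generate_study(cfg, gen$atlas)$study
  prof <- rowMeans(gen$atlas$values[, gen$atlas$samples$cell_type == "macrophage"])
  # atlas values already include the floor; mixing adds it once more
  expect_equal(unname(study$values[, 1]), unname(prof + 2), tolerance = 1e-12)
})

test_that("mixture linearity: noise-free bulk equals the convex combination", {
  cfg <- small_sim(noise_cv = 0, floor_intensity = 1, seed = 5)
  gen <- generate_atlas(cfg)
  out <- generate_study(cfg, gen$atlas)
  comp <- tidyr::pivot_wider(out$truth$composition, names_from = "cell_type",
                             values_from = "fraction")
  a1 <- comp$array_id[[1]]
  w <- unlist(comp[comp$array_id == a1, cfg$cell_types])
  prof <- vapply(cfg$cell_types, function(ct) {
    rowMeans(gen$atlas$values[, gen$atlas$samples$cell_type == ct, drop = FALSE])
  }, numeric(cfg$n_genes))
  expect_equal(unname(out$study$values[, a1]),
               unname(prof %*% w + 1)[, 1], tolerance = 1e-12)
})

test_that("composition rows sum to 1 and shifted marker ratios match closed form", {
  cfg <- simulation_config(seed = 13)
  gen <- generate_atlas(cfg)
  out <- generate_study(cfg, gen$atlas)
  sums <- dplyr::summarise(dplyr::group_by(out$truth$composition, array_id),
                           s = sum(fraction))
  expect_equal(sums$s, rep(1, nrow(sums)))

  # closed-form expectation: marker bulk intensity tracks its type fraction
  comp <- tidyr::pivot_wider(out$truth$composition, names_from = "cell_type",
                             values_from = "fraction")
  st <- out$study$samples
  rt <- st$array_id[st$group == "RT_IgG" & st$timepoint == "18w"]
  ref <- st$array_id[st$group == "noRT_IgG" & st$timepoint == "18w"]
  mac <- gen$truth$gene_id[gen$truth$cell_type == "macrophage"]
  obs <- mean(rowMeans(out$study$values[mac, rt]) /
                rowMeans(out$study$values[mac, ref]))
  f_rt <- comp$macrophage[comp$array_id == rt[[1]]]
  f_ref <- comp$macrophage[comp$array_id == ref[[1]]]
  # marker bulk mean ~ baseline * (f*(fold-1) + 1), up to the small floors
  prof_ratio <- function(f) f * (cfg$marker_fold - 1) + 1
  expected <- prof_ratio(f_rt) / prof_ratio(f_ref)
  expect_equal(obs, expected, tolerance = 0.15)
})

test_that("default design yields 28 annotated arrays", {
  cfg <- small_sim(seed = 2)
  study <- generate_study(cfg, generate_atlas(cfg)$atlas)$study
  expect_equal(ncol(study$values), 28)
  expect_setequal(unique(study$samples$group), cfg$study_groups)
  expect_equal(nrow(dplyr::distinct(study$samples[, c("group", "timepoint")])),
               14)
})

test_that("study generation rejects an atlas missing a configured cell type", {
  cfg <- small_sim(seed = 2)
  gen <- generate_atlas(cfg)
  keep <- gen$atlas$samples$cell_type != "macrophage"
  crippled <- cell_atlas(gen$atlas$values[, keep],
                         gen$atlas$samples$cell_type[keep])
  expect_error(generate_study(cfg, crippled), "macrophage")
})

test_that("pattern-matrix generator plants the requested variance split", {
  out <- generate_pattern_matrix(config = simulation_config(seed = 21))
  expect_s3_class(out$ratios, "expr_mat")
  expect_equal(out$planted_fraction, 0.7)
  expect_setequal(unique(out$truth$role), c("primary", "secondary", "null"))
  # orthogonal planted patterns: log2 signal cross-product vanishes
  x <- log2(out$ratios$values)
  expect_equal(dim(x), c(1000, 28))
})
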