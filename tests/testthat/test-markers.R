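test_that("Mann-Whitney exact p matches full enumeration", {
  res <- mann_whitney(c(5, 6, 7), c(1, 2, 3), alternative = "greater")
  expect_equal(res$u, 9)
  expect_equal(res$p, 1 / 20)   # 1 of the C(6,3)=20 assignments is as extreme
  expect_equal(res$method, "exact")
  two <- mann_whitney(c(5, 6, 7), c(1, 2, 3))
  expect_equal(two$p, 2 / 20)
  # a == b
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p, 1)
  # all values identical
  expect_equal(mann_whitney(c(2, 2), c(2, 2, 2))$p, 1)
})

test_that("Mann-Whitney agrees with wilcox.test where both apply", {
  set.seed(801)
  # exact, no ties, small n
  for (i in 1:5) {
    a <- stats::rnorm(4); b <- stats::rnorm(5)
    ref <- stats::wilcox.test(a, b, exact = TRUE)
    res <- mann_whitney(a, b)
    expect_equal(res$u, unname(ref$statistic))
    expect_equal(res$p, ref$p.value, tolerance = 1e-12)
  }
  # normal approximation with ties, larger n
  for (i in 1:5) {
    a <- sample(1:6, 10, replace = TRUE)
    b <- sample(1:8, 12, replace = TRUE)
    ref <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                               correct = TRUE))
    res <- mann_whitney(a, b)
    expect_equal(res$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Mann-Whitney p is invariant under monotone transforms", {
  set.seed(802)
  a <- stats::runif(6, 1, 10); b <- stats::runif(6, 1, 10)
  p0 <- mann_whitney(a, b)$p
  expect_equal(mann_whitney(log(a), log(b))$p, p0)
  expect_equal(mann_whitney(a^3, b^3)$p, p0)
})

test_that("panel derivation recovers noise-free planted markers and enforces uniqueness", {
  cfg <- small_sim(noise_cv = 0, seed = 51)
  gen <- generate_atlas(cfg)
  panels <- derive_panels(gen$atlas)
  joined <- dplyr::full_join(panels, gen$truth, by = "gene_id",
                             suffix = c("_called", "_true"))
  expect_true(all(panels$gene_id %in% gen$truth$gene_id))
  expect_true(all(gen$truth$gene_id %in% panels$gene_id))
  expect_equal(joined$cell_type_called, joined$cell_type_true)
  # pairwise disjoint
  expect_equal(anyDuplicated(panels$gene_id), 0L)
})

test_that("a gene qualifying for two cell types is removed from all panels", {
  # a gene equally high in A and B can reach at most ~(T-1)x the pooled
  # rest, so dual qualification is exercised at relaxed thresholds
  set.seed(803)
  types <- rep(c("A", "B", "C"), each = 40)
  vals <- matrix(stats::runif(3 * 120, 0.9, 1.1), nrow = 3,
                 dimnames = list(c("shared", "a_only", "null"),
                                 sprintf("s%03d", 1:120)))
  vals["shared", types %in% c("A", "B")] <- stats::runif(80, 99, 101)
  vals["a_only", types == "A"] <- stats::runif(40, 99, 101)
  atlas <- cell_atlas(vals, types)
  # sanity: the shared gene passes the screen for both A and B on its own
  for (ct in c("A", "B")) {
    own <- types == ct
    expect_gt(mean(vals["shared", own]) / mean(vals["shared", !own]), 1.5)
    expect_lt(mann_whitney(vals["shared", own], vals["shared", !own])$p,
              0.001)
  }
  panels <- derive_panels(atlas, fold_min = 1.5, p_max = 0.001)
  expect_false("shared" %in% panels$gene_id)
  expect_identical(panels$gene_id[panels$cell_type == "A"], "a_only")
  expect_equal(attr(panels, "provenance")$n_multi_panel_removed, 1)
})

test_that("panel derivation is invariant to sample and gene order", {
  cfg <- small_sim(seed = 53)
  gen <- generate_atlas(cfg)
  panels <- derive_panels(gen$atlas)
  set.seed(804)
  sp <- sample(ncol(gen$atlas$values)); gp <- sample(nrow(gen$atlas$values))
  shuffled <- cell_atlas(gen$atlas$values[gp, sp],
                         gen$atlas$samples$cell_type[sp])
  panels2 <- derive_panels(shuffled)
  expect_equal(dplyr::arrange(panels, cell_type, gene_id),
               dplyr::arrange(panels2, cell_type, gene_id),
               ignore_attr = TRUE)
})

test_that("raising the fold threshold never enlarges a panel", {
  cfg <- small_sim(seed = 55)
  gen <- generate_atlas(cfg)
  sizes <- vapply(c(16, 64, 256), function(f) {
    nrow(derive_panels(gen$atlas, fold_min = f))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
})

test_that("single-sample cell types are excluded with a warning", {
  set.seed(805)
  types <- c("A", "A", "A", "B")
  vals <- matrix(stats::runif(20 * 4, 50, 150), nrow = 20,
                 dimnames = list(sprintf("g%02d", 1:20), sprintf("s%d", 1:4)))
  expect_warning(panels <- derive_panels(cell_atlas(vals, types)),
                 "single atlas sample")
  expect_false("B" %in% panels$cell_type)
})

test_that("platform mapping keeps multi-probe genes and re-enforces disjointness", {
  panels <- tibble::tibble(cell_type = c("A", "A", "B"),
                           gene_id = c("g1", "g2", "g3"))
  # identity map leaves panels unchanged
  idm <- identity_map(c("g1", "g2", "g3"))
  mapped <- map_panels(panels, idm)
  expect_equal(mapped$probe_id, panels$gene_id)
  # one-to-many keeps both probes; unmapped genes are dropped with a note
  mp <- tibble::tibble(gene_id = c("g1", "g1", "g3"),
                       probe_id = c("p1a", "p1b", "p3"))
  expect_message(m2 <- map_panels(panels, mp), "1 unmapped")
  expect_setequal(m2$probe_id[m2$cell_type == "A"], c("p1a", "p1b"))
  # shared probe after mapping is removed from both panels
  mp2 <- tibble::tibble(gene_id = c("g1", "g3"), probe_id = c("pX", "pX"))
  suppressMessages(m3 <- map_panels(panels, mp2))
  expect_equal(nrow(m3), 0)
  expect_error(map_panels(panels, mp[0, ]), "empty")
})
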