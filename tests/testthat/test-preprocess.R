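test_that("percentile normalization follows the interpolated-quantile convention", {
  m <- make_expr(matrix(c(5, 5, 5, 5, 1, 2, 3, 4), nrow = 4))
  out <- normalize_to_percentile(m, 50)
  expect_equal(intensity_scale(out), "chip_normalized")
  # constant array: everything becomes 1
  expect_equal(unname(out$values[, 1]), rep(1, 4))
  # (1,2,3,4): linear-interpolation 50th percentile is 2.5
  expect_equal(unname(out$values[, 2]), c(1, 2, 3, 4) / 2.5)
})

test_that("percentile normalization is scale invariant per array", {
  m <- make_expr(matrix(stats::runif(40, 1, 10), nrow = 10))
  m10 <- make_expr(m$values * 10)
  expect_equal(normalize_to_percentile(m)$values,
               normalize_to_percentile(m10)$values)
  # and idempotent in output when a single array is rescaled
  m2 <- m
  m2$values[, 3] <- m2$values[, 3] * 7
  expect_equal(normalize_to_percentile(m)$values,
               normalize_to_percentile(m2)$values)
})

test_that("control-median normalization uses timepoint-matched controls only", {
  vals <- matrix(c(2, 4, 6, 8, 8, 20, 10, 10, 50), nrow = 1,
                 dimnames = list("p001", sprintf("a%d", 1:9)))
  m <- make_expr(vals,
                 groups = rep(c("noRT_IgG", "noRT_IgG", "RT_IgG"), 3),
                 timepoints = rep(c("18w", "30w", "30w"), each = 3))
  m$scale <- "chip_normalized"
  out <- normalize_to_control_median(m)
  # 18w controls (2,4): median 3 -> treated 6 becomes 2.0
  expect_equal(unname(out$values[1, 3]), 2.0)
  # equal controls become 1 at 30w (controls 8,8,10,10 -> median 9)
  expect_equal(unname(out$values[1, 4:5]), c(8, 8) / 9)
  # isolation: perturbing 18w controls leaves 30w ratios unchanged
  m2 <- m
  m2$values[1, 1:2] <- c(100, 200)
  out2 <- normalize_to_control_median(m2)
  expect_equal(out$values[1, 4:9], out2$values[1, 4:9])
  expect_false(isTRUE(all.equal(out$values[1, 3], out2$values[1, 3])))
})

test_that("control ratios of control arrays have per-probe median 1", {
  cfg <- small_sim(seed = 31)
  study <- generate_study(cfg, generate_atlas(cfg)$atlas)$study
  ratios <- normalize_to_control_median(normalize_to_percentile(study))
  s <- ratios$samples
  for (tp in unique(s$timepoint)) {
    ctrl <- which(s$group == "noRT_IgG" & s$timepoint == tp)
    med <- apply(ratios$values[, ctrl], 1, median)
    expect_equal(unname(med), rep(1, nrow(ratios$values)))
  }
})

test_that("zero control medians propagate as NA with a warning", {
  vals <- matrix(c(0, 0, 5, 1, 1, 1), nrow = 2, byrow = TRUE,
                 dimnames = list(c("p1", "p2"), c("a1", "a2", "a3")))
  m <- make_expr(vals, groups = c("noRT_IgG", "noRT_IgG", "RT_IgG"))
  m$scale <- "chip_normalized"
  expect_warning(out <- normalize_to_control_median(m), "undefined")
  expect_true(all(is.na(out$values["p1", ])))
  expect_false(anyNA(out$values["p2", ]))
})

test_that("error coefficient recovers a planted additive noise scale", {
  # 10% of probes form a constant low-intensity block plus Gaussian noise
  set.seed(401)
  s <- 2
  low <- 20 + stats::rnorm(4000, sd = s)
  high <- stats::runif(36000, 100, 1000)
  m <- make_expr(matrix(pmax(c(low, high), 0), ncol = 1))
  est <- estimate_error_coefficient(m)$coefficient
  expect_lt(abs(est - s) / s, 0.2)
  # noise-free low block -> coefficient 0
  m0 <- make_expr(matrix(c(rep(5, 10), stats::runif(90, 100, 200)), ncol = 1))
  expect_equal(estimate_error_coefficient(m0)$coefficient, 0)
  # invariant to probe order
  perm <- sample(nrow(m$values))
  mp <- expr_mat(m$values[perm, , drop = FALSE], m$samples, "raw")
  expect_equal(estimate_error_coefficient(mp)$coefficient, est)
})

test_that("low-intensity filter removes planted background probes", {
  # background block sits wholly below 3x its own noise scale
  set.seed(402)
  n_arr <- 6
  # 100 pure-background probes, a broad low-intensity population that sets
  # the per-array noise scale, and clearly expressed probes
  bg <- matrix(stats::runif(100 * n_arr, 0, 0.02), nrow = 100)
  spread <- matrix(stats::runif(2000 * n_arr, 0, 1), nrow = 2000)
  hi <- matrix(stats::runif(1900 * n_arr, 100, 1000), nrow = 1900)
  m <- make_expr(rbind(bg, spread, hi), groups = rep("g", n_arr),
                 timepoints = rep("18w", n_arr))
  suppressMessages(flt <- filter_low_intensity(m, multiplier = 3,
                                               min_failing_arrays = n_arr))
  expect_true(all(!flt$retained[1:100]))
  expect_true(all(flt$retained[2101:4000]))
})

test_that("filter boundary is exactly min_failing_arrays", {
  # probe failing on exactly k-1 arrays is retained; on k it is removed
  set.seed(403)
  base <- rbind(matrix(stats::runif(30 * 4, 0, 0.5), nrow = 30),
                matrix(stats::runif(170 * 4, 100, 1000), nrow = 170))
  rownames(base) <- sprintf("base%03d", 1:200)
  thr0 <- 3 * estimate_error_coefficient(
    make_expr(base, groups = rep("g", 4), timepoints = rep("18w", 4))
  )$coefficient
  p1 <- c(0.8 * thr0[1], 2 * thr0[2], 2 * thr0[3], 2 * thr0[4])
  p2 <- c(0.8 * thr0[1], 0.8 * thr0[2], 2 * thr0[3], 2 * thr0[4])
  m2 <- make_expr(rbind(base, boundary1 = p1, boundary2 = p2),
                  groups = rep("g", 4), timepoints = rep("18w", 4))
  # the two added probes barely move the per-array noise scale
  thr2 <- 3 * estimate_error_coefficient(m2)$coefficient
  expect_true(all(0.8 * thr0 < thr2) && all(2 * thr0 > thr2))
  suppressMessages(flt <- filter_low_intensity(m2, multiplier = 3,
                                               min_failing_arrays = 2))
  expect_equal(flt$n_below[match(c("boundary1", "boundary2"), flt$probe_id)],
               c(1L, 2L))
  expect_true(flt$retained[flt$probe_id == "boundary1"])
  expect_false(flt$retained[flt$probe_id == "boundary2"])
})

test_that("filter counts are monotone in its two parameters", {
  cfg <- small_sim(seed = 33)
  study <- generate_study(cfg, generate_atlas(cfg)$atlas)$study
  retained <- function(mult, k) {
    suppressMessages(sum(filter_low_intensity(study, mult, k)$retained))
  }
  r <- vapply(c(1, 3, 10, 30), retained, numeric(1), k = 14)
  expect_true(all(diff(r) <= 0))
  r2 <- vapply(c(5, 14, 28), retained, numeric(1), mult = 3)
  expect_true(all(diff(r2) >= 0))
  expect_error(filter_low_intensity(study, 3, 29), "exceeds")
})
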