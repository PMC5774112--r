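# Build a small annotated expr_mat from a plain matrix. Default design:
# arrays split between a control and a treated group at one timepoint.
make_expr <- function(values, groups = NULL, timepoints = NULL,
                      scale = "raw") {
  if (is.null(colnames(values))) {
    colnames(values) <- sprintf("a%02d", seq_len(ncol(values)))
  }
  if (is.null(rownames(values))) {
    rownames(values) <- sprintf("p%03d", seq_len(nrow(values)))
  }
  n <- ncol(values)
  samples <- tibble::tibble(
    array_id = colnames(values),
    group = groups %||% rep(c("noRT_IgG", "RT_IgG"), length.out = n),
    timepoint = timepoints %||% rep("18w", n),
    replicate = seq_len(n))
  expr_mat(values, samples, scale = scale)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# A fast small simulation config used where the full default sizes are not
# the point of the test.
small_sim <- function(...) {
  simulation_config(n_genes = 400, n_markers_per_type = 10, ...)
}

# Textbook 2x2 chi-squared from expected counts; independent oracle for
# chi2_representation().
chi2_expected_counts <- function(n, t, N, TT) {
  obs <- matrix(c(n, t - n, N - n, (TT - t) - (N - n)), 2, 2, byrow = TRUE)
  rs <- rowSums(obs); cs <- colSums(obs)
  expd <- outer(rs, cs) / sum(obs)
  chi2 <- sum((obs - expd)^2 / expd)
  c(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}
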