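#' Extract the dominant coordinate expression pattern
#'
#' Principal components analysis of the log2 control ratios over a probe
#' set, with probes as observations and arrays as variables: each probe's
#' profile is mean-centered across arrays and components are taken from the
#' resulting covariance structure (unscaled). The per-array loading vector
#' of the first component is the dominant shared expression pattern across
#' the study. Its sign is arbitrary, so it is oriented such that the mean
#' loading over the untreated irradiated arrays at the first timepoint is
#' positive — probes elevated by irradiation then correlate positively
#' with it.
#'
#' @param m A `control_ratio` [expr_mat].
#' @param probes Probe IDs to analyze (>= 2; typically the combined
#'   altered-probe list). Probes with missing ratios or zero variance are
#'   dropped.
#' @param orient_group,orient_timepoint Arrays defining the sign convention
#'   of the first component.
#' @return An object of class `pattern_fit` with elements
#'   `array_scores` (array x component matrix of loadings),
#'   `variance_fractions`, `probe_scores`, `probes`, `samples`, and
#'   `orientation`. See [tidy.pattern_fit()], [glance.pattern_fit()],
#'   [correlate_with_pc1()].
#' @export
run_pca <- function(m, probes, orient_group = "RT_IgG",
                    orient_timepoint = NULL) {
  stopifnot(inherits(m, "expr_mat"))
  if (m$scale != "control_ratio") abort("`m` must be on the control_ratio scale.")
  if (length(probes) < 2 || ncol(m$values) < 2) {
    abort("Need at least 2 probes and 2 arrays.")
  }
  x <- log2(subset_probes(m, probes)$values)
  ok <- !rowSums(is.na(x))
  x <- x[ok, , drop = FALSE]
  xc <- x - rowMeans(x)
  if (all(abs(xc) < 1e-12)) abort("Matrix has no variance over `probes`.")
  pc <- prcomp(xc, center = FALSE, scale. = FALSE)
  fractions <- pc$sdev^2 / sum(pc$sdev^2)
  if (is.null(orient_timepoint) && "timepoint" %in% names(m$samples)) {
    orient_timepoint <- sort(unique(m$samples$timepoint))[[1]]
  }
  flipped <- FALSE
  orient <- if ("group" %in% names(m$samples)) {
    select_arrays(m, orient_group, orient_timepoint)
  } else {
    integer()
  }
  if (length(orient) && mean(pc$rotation[orient, 1]) < 0) {
    pc$rotation[, 1] <- -pc$rotation[, 1]
    pc$x[, 1] <- -pc$x[, 1]
    flipped <- TRUE
  }
  structure(list(array_scores = pc$rotation,
                 variance_fractions = fractions,
                 probe_scores = pc$x,
                 probes = rownames(x),
                 samples = m$samples,
                 orientation = list(group = orient_group,
                                    timepoint = orient_timepoint,
                                    flipped = flipped)),
            class = "pattern_fit")
}

#' @export
print.pattern_fit <- function(x, ...) {
  cat(sprintf("<pattern_fit> %d probes x %d arrays; PC1 variance fraction %.3f\n",
              length(x$probes), nrow(x$array_scores),
              x$variance_fractions[[1]]))
  invisible(x)
}

#' @describeIn run_pca per-array first-component loadings joined to the
#'   sample annotations, one row per array per component (long format).
#' @param x A `pattern_fit`.
#' @param n_components Components to return.
#' @param ... Unused.
#' @method tidy pattern_fit
#' @export
tidy.pattern_fit <- function(x, n_components = 2, ...) {
  k <- min(n_components, ncol(x$array_scores))
  out <- tidyr::expand_grid(component = seq_len(k),
                            array_id = rownames(x$array_scores))
  out$score <- unlist(lapply(seq_len(k), function(j) x$array_scores[, j]),
                      use.names = FALSE)
  dplyr::left_join(out, x$samples, by = "array_id")
}

#' @describeIn run_pca one-row summary: probe/array counts and the variance
#'   fractions of the first two components.
#' @method glance pattern_fit
#' @export
glance.pattern_fit <- function(x, ...) {
  tibble(n_probes = length(x$probes),
         n_arrays = nrow(x$array_scores),
         pc1_variance_fraction = x$variance_fractions[[1]],
         pc2_variance_fraction = if (length(x$variance_fractions) > 1) {
           x$variance_fractions[[2]]
         } else NA_real_)
}

#' @describeIn run_pca plot the first-component loading per array, colored
#'   by group and faceted by timepoint.
#' @param object A `pattern_fit`.
#' @method autoplot pattern_fit
#' @export
autoplot.pattern_fit <- function(object, ...) {
  d <- tidy(object, n_components = 1)
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$score)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(y = "PC1 array loading", x = NULL) +
    ggplot2::theme_bw() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if ("timepoint" %in% names(d)) {
    p <- p + ggplot2::facet_wrap(~timepoint)
  }
  p
}

#' Correlate probe profiles with the first component
#'
#' Pearson correlation of each probe's (centered) array profile with the
#' first-component array loadings, with a two-sided p-value from the exact
#' t transform `t = r * sqrt((n-2)/(1-r^2))` on `n_arrays - 2` degrees of
#' freedom. Probes with `p < p_max` form the coordinately regulated set.
#'
#' @param m The `control_ratio` [expr_mat] the pattern was fitted on.
#' @param pattern A [run_pca()] fit over the same arrays.
#' @param p_max Selection threshold on the correlation p-value (strict).
#' @return A tibble (`probe_id`, `r`, `p`, `selected`). Zero-variance
#'   probes are excluded.
#' @export
correlate_with_pc1 <- function(m, pattern, p_max = 0.001) {
  stopifnot(inherits(m, "expr_mat"), inherits(pattern, "pattern_fit"))
  if (!identical(colnames(m$values), rownames(pattern$array_scores))) {
    abort("`pattern` was fitted on different arrays than `m`.")
  }
  x <- log2(subset_probes(m, pattern$probes)$values)
  a <- pattern$array_scores[, 1]
  ac <- a - mean(a)
  xc <- x - rowMeans(x)
  ssx <- rowSums(xc^2)
  keep <- ssx > 0
  r <- (xc[keep, , drop = FALSE] %*% ac) / sqrt(ssx[keep] * sum(ac^2))
  r <- pmin(pmax(as.vector(r), -1), 1)
  n <- ncol(x)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tt), n - 2)
  p[abs(r) == 1] <- 0
  tibble(probe_id = rownames(x)[keep], r = r, p = p, selected = p < p_max)
}

#' Partition correlated probes into elevated and diminished sets
#'
#' Probes selected by [correlate_with_pc1()] split by the sign of their
#' correlation with the oriented first component: positive r means the
#' probe follows the irradiation-response pattern (elevated), negative r
#' means it mirrors it (diminished). The two sets partition the selected
#' set.
#'
#' @param cor_tbl The tibble returned by [correlate_with_pc1()].
#' @return The selected rows with an added `direction` column
#'   (`"elevated"`/`"diminished"`); counts are reported via a message.
#' @export
partition_by_sign <- function(cor_tbl) {
  out <- dplyr::filter(cor_tbl, .data$selected)
  out <- dplyr::mutate(out,
                       direction = ifelse(.data$r > 0, "elevated", "diminished"))
  inform(sprintf("Partitioned %d probes: %d elevated, %d diminished.",
                 nrow(out), sum(out$direction == "elevated"),
                 sum(out$direction == "diminished")))
  out
}

#' Hierarchical probe ordering for heatmap export
#'
#' Average-linkage agglomerative clustering of probes on centered Pearson
#' correlation distance (1 - r between log2 profiles), returning the leaf
#' order. Probes are sorted lexicographically by ID before clustering so
#' ties resolve deterministically.
#'
#' @param m A `control_ratio` [expr_mat].
#' @param probes Probe IDs to order (>= 2, no zero-variance profiles).
#' @return Character vector of probe IDs in dendrogram leaf order, with
#'   attributes `linkage` ("average") and `distance` ("pearson").
#' @export
hierarchical_order <- function(m, probes) {
  stopifnot(inherits(m, "expr_mat"))
  if (length(probes) < 2) abort("Need at least 2 probes.")
  probes <- sort(probes)
  x <- log2(subset_probes(m, probes)$values)
  if (anyNA(x)) abort("Probes with missing ratios cannot be ordered.")
  sds <- apply(x, 1, stats::sd)
  if (any(sds == 0)) abort("Zero-variance probe profiles cannot be ordered.")
  d <- as.dist(1 - cor(t(x)))
  hc <- hclust(d, method = "average")
  structure(probes[hc$order], linkage = "average", distance = "pearson")
}
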