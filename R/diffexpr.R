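#' Welch's unequal-variance t-test
#'
#' The between-group test used throughout the differential screen, applied
#' to log2-transformed control ratios. Wraps [stats::t.test()] (Welch
#' statistic, Welch-Satterthwaite degrees of freedom, two-sided p from the
#' t distribution) and resolves the degenerate zero-variance cases
#' explicitly: equal constant groups give `t = 0, p = 1`; unequal constant
#' groups give an infinite statistic with `p = 0`, flagged degenerate.
#'
#' @param a,b Numeric vectors, each of length >= 2, finite.
#' @return A one-row tibble (`t`, `df`, `p`, `degenerate`).
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) abort("Both groups need >= 2 values.")
  if (!all(is.finite(a)) || !all(is.finite(b))) abort("Values must be finite.")
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble(t = 0, df = NA_real_, p = 1, degenerate = FALSE))
    }
    return(tibble(t = sign(mean(a) - mean(b)) * Inf, df = NA_real_, p = 0,
                  degenerate = TRUE))
  }
  tt <- t.test(a, b, var.equal = FALSE)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p = tt$p.value, degenerate = FALSE)
}

#' Linear-scale fold change
#'
#' Ratio of group means on the linear (ratio) scale, `mean(a) / mean(b)`.
#'
#' @param a,b Numeric vectors of positive values.
#' @return A positive scalar; `NA` with a warning when `mean(b)` is zero
#'   (the record is excluded downstream).
#' @export
fold_change <- function(a, b) {
  if (mean(b) == 0) {
    warn("Undefined fold change: mean of `b` is zero.")
    return(NA_real_)
  }
  mean(a) / mean(b)
}

#' Specify a between-group contrast
#'
#' @param name Label for the contrast.
#' @param group_a,group_b Character vectors of group labels selecting the
#'   numerator and denominator arrays; the selections must be disjoint.
#' @param timepoint Optional timepoint label(s) restricting both sides;
#'   `NULL` pools across timepoints.
#' @return An object of class `contrast_spec`.
#' @export
contrast_spec <- function(name, group_a, group_b, timepoint = NULL) {
  if (length(intersect(group_a, group_b))) {
    abort("`group_a` and `group_b` must be disjoint.")
  }
  structure(list(name = name, group_a = group_a, group_b = group_b,
                 timepoint = timepoint),
            class = "contrast_spec")
}

# Vectorized Welch t over matrix rows (columns split into two groups).
# Matches welch_t() row by row; tested against it.
row_welch <- function(A, B) {
  n1 <- ncol(A); n2 <- ncol(B)
  m1 <- rowMeans(A); m2 <- rowMeans(B)
  v1 <- rowSums((A - m1)^2) / (n1 - 1)
  v2 <- rowSums((B - m2)^2) / (n2 - 1)
  se2 <- v1 / n1 + v2 / n2
  t <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  p <- 2 * pt(-abs(t), df)
  zero <- se2 == 0
  if (any(zero)) {
    eq <- zero & (m1 == m2)
    t[eq] <- 0; p[eq] <- 1; df[eq] <- NA_real_
    ne <- zero & (m1 != m2)
    t[ne] <- sign(m1[ne] - m2[ne]) * Inf; p[ne] <- 0; df[ne] <- NA_real_
  }
  list(t = t, df = df, p = p)
}

#' Screen probes for substantial, significant expression changes
#'
#' For one contrast, computes per-probe linear fold changes of group means
#' and Welch t-tests on the log2 control ratios, and flags probes altered
#' when the fold change strictly exceeds `fc_min` (or falls strictly below
#' `1/fc_min`) and the p-value is strictly below `p_max`. No
#' multiple-testing correction is applied by default — list selection uses
#' raw p-values; set `fdr = TRUE` to additionally report
#' Benjamini-Hochberg-adjusted values and gate on those.
#'
#' @param m A `control_ratio` [expr_mat] (restrict to filtered probes
#'   beforehand with [subset_probes()] if desired).
#' @param contrast A [contrast_spec()].
#' @param fc_min Fold-change threshold (strict, both directions).
#' @param p_max P-value threshold (strict).
#' @param fdr If `TRUE`, gate on BH-adjusted p-values instead of raw ones.
#' @return A tibble (`probe_id`, `fold_change`, `t`, `df`, `p`, `altered`)
#'   over all testable probes (probes with missing ratios in the selected
#'   arrays are dropped). The altered list is
#'   `dplyr::filter(x, altered)$probe_id`.
#' @export
select_altered <- function(m, contrast, fc_min = 2, p_max = 0.05,
                           fdr = FALSE) {
  stopifnot(inherits(m, "expr_mat"), inherits(contrast, "contrast_spec"))
  if (m$scale != "control_ratio") {
    abort("`m` must be on the control_ratio scale.")
  }
  ia <- select_arrays(m, contrast$group_a, contrast$timepoint)
  ib <- select_arrays(m, contrast$group_b, contrast$timepoint)
  if (!length(ia) || !length(ib)) {
    abort(sprintf("Contrast '%s' selects an empty group.", contrast$name))
  }
  A <- m$values[, ia, drop = FALSE]
  B <- m$values[, ib, drop = FALSE]
  ok <- !rowSums(is.na(A)) & !rowSums(is.na(B))
  A <- A[ok, , drop = FALSE]; B <- B[ok, , drop = FALSE]
  fc <- rowMeans(A) / rowMeans(B)
  wt <- row_welch(log2(A), log2(B))
  p_gate <- if (fdr) stats::p.adjust(wt$p, "BH") else wt$p
  tibble(probe_id = rownames(m$values)[ok],
         fold_change = unname(fc),
         t = unname(wt$t), df = unname(wt$df), p = unname(wt$p),
         altered = (fc > fc_min | fc < 1 / fc_min) & p_gate < p_max)
}

#' Combine probe lists into a unique union
#'
#' Set union preserving first-seen order, used to merge per-contrast
#' altered-probe lists into one combined list for pattern extraction.
#'
#' @param ... Character vectors of probe IDs, or a single list of them.
#' @return Character vector of unique probe IDs; the size is reported via
#'   a message.
#' @export
combine_lists <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && is.list(lists[[1]])) lists <- lists[[1]]
  out <- unique(unlist(lists, use.names = FALSE))
  if (is.null(out)) out <- character()
  inform(sprintf("Combined %d list(s) into %d unique probes.",
                 length(lists), length(out)))
  out
}
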