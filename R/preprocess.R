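#' Per-chip percentile normalization
#'
#' Divides each array's intensities by that array's given percentile of its
#' own positive values, so chips become comparable despite global intensity
#' differences. The percentile is computed with linear interpolation
#' between order statistics ([stats::quantile()] type 7); with the default
#' 50 this is per-chip median scaling.
#'
#' @param m A raw-scale [expr_mat]; every array needs at least one positive
#'   value.
#' @param percentile Percentile in (0, 100) used as the per-chip scale.
#' @return The normalized [expr_mat] (`chip_normalized` scale).
#' @export
normalize_to_percentile <- function(m, percentile = 50) {
  stopifnot(inherits(m, "expr_mat"))
  if (m$scale != "raw") abort("`m` must be on the raw scale.")
  if (percentile <= 0 || percentile >= 100) {
    abort("`percentile` must lie strictly between 0 and 100.")
  }
  scales <- vapply(seq_len(ncol(m$values)), function(j) {
    v <- m$values[, j]
    v <- v[v > 0]
    if (!length(v)) {
      abort(sprintf("Array '%s' has no positive values.", colnames(m$values)[j]))
    }
    unname(quantile(v, percentile / 100, type = 7))
  }, numeric(1))
  zero <- which(scales == 0)
  if (length(zero)) {
    abort(sprintf("Array '%s' has a zero %gth percentile.",
                  colnames(m$values)[zero[[1]]], percentile))
  }
  expr_mat(sweep(m$values, 2, scales, "/"), m$samples,
           scale = "chip_normalized")
}

#' Normalize probes to contemporaneous unirradiated controls
#'
#' For every probe and timepoint, divides each array's value by the median
#' of that probe across the control-group arrays of the same timepoint, so
#' downstream values are fold ratios relative to time-matched unirradiated
#' lungs. With an even number of controls the median is the mean of the two
#' central values. Probes whose control median is zero at a timepoint get
#' `NA` ratios there and are excluded from downstream testing rather than
#' imputed.
#'
#' @param m A `chip_normalized` [expr_mat] with `group` and `timepoint`
#'   annotations.
#' @param control_group Group label of the unirradiated control arrays;
#'   every timepoint must contain at least one.
#' @return A `control_ratio` [expr_mat].
#' @export
normalize_to_control_median <- function(m, control_group = "noRT_IgG") {
  stopifnot(inherits(m, "expr_mat"))
  if (m$scale != "chip_normalized") {
    abort("`m` must be chip_normalized; run normalize_to_percentile() first.")
  }
  s <- m$samples
  if (!all(c("group", "timepoint") %in% names(s))) {
    abort("`m` needs group and timepoint annotations.")
  }
  out <- m$values
  n_undefined <- 0L
  for (tp in unique(s$timepoint)) {
    ctrl <- which(s$group == control_group & s$timepoint == tp)
    if (!length(ctrl)) {
      abort(sprintf("Timepoint '%s' has no '%s' control arrays.",
                    tp, control_group))
    }
    med <- apply(m$values[, ctrl, drop = FALSE], 1, median)
    tp_arrays <- which(s$timepoint == tp)
    ratio <- m$values[, tp_arrays, drop = FALSE] / med
    ratio[med == 0, ] <- NA_real_
    n_undefined <- n_undefined + sum(med == 0)
    out[, tp_arrays] <- ratio
  }
  if (n_undefined > 0) {
    warn(sprintf("%d probe/timepoint ratios undefined (control median 0); set to NA.",
                 n_undefined))
  }
  expr_mat(out, m$samples, scale = "control_ratio")
}

#' Per-array background-noise scale
#'
#' A robust additive-noise scale per array used by the low-intensity filter:
#' the median absolute deviation (scaled to be consistent with the SD of a
#' Gaussian) of the array's lowest-decile intensities. Probes whose raw
#' signal does not clear a small multiple of this coefficient are
#' statistically indistinguishable from background.
#'
#' @param m A raw-scale [expr_mat] with at least 10 probes.
#' @return A tibble (`array_id`, `coefficient`).
#' @export
estimate_error_coefficient <- function(m) {
  stopifnot(inherits(m, "expr_mat"))
  if (m$scale != "raw") abort("`m` must be on the raw scale.")
  if (nrow(m$values) < 10) abort("Need at least 10 probes per array.")
  coefs <- vapply(seq_len(ncol(m$values)), function(j) {
    v <- m$values[, j]
    low <- v[v <= quantile(v, 0.1, type = 7)]
    mad(low)
  }, numeric(1))
  tibble(array_id = colnames(m$values), coefficient = coefs)
}

#' Low-intensity probe filter
#'
#' Flags probes whose raw signal falls below `multiplier` times the
#' per-array background coefficient ([estimate_error_coefficient()]) on at
#' least `min_failing_arrays` arrays; such probes are background-level
#' across the study and are removed before differential testing.
#'
#' @param m A raw-scale [expr_mat].
#' @param multiplier Positive multiple of the background coefficient a
#'   probe's signal must reach.
#' @param min_failing_arrays A probe is removed when it fails on at least
#'   this many arrays (must not exceed the array count).
#' @return A tibble (`probe_id`, `n_below`, `retained`); retained probe IDs
#'   are `dplyr::filter(x, retained)$probe_id`. The removal count is
#'   reported via a message.
#' @export
filter_low_intensity <- function(m, multiplier = 3, min_failing_arrays = 28) {
  stopifnot(inherits(m, "expr_mat"))
  if (multiplier <= 0) abort("`multiplier` must be positive.")
  if (min_failing_arrays < 1) abort("`min_failing_arrays` must be >= 1.")
  if (min_failing_arrays > ncol(m$values)) {
    abort(sprintf("`min_failing_arrays` (%d) exceeds the array count (%d).",
                  min_failing_arrays, ncol(m$values)))
  }
  coefs <- estimate_error_coefficient(m)$coefficient
  below <- sweep(m$values, 2, multiplier * coefs, "<")
  n_below <- rowSums(below)
  retained <- n_below < min_failing_arrays
  inform(sprintf("Low-intensity filter removed %d of %d probes (%d retained).",
                 sum(!retained), length(retained), sum(retained)))
  tibble(probe_id = rownames(m$values), n_below = as.integer(n_below),
         retained = retained)
}
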