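#' Mann-Whitney rank-sum test
#'
#' Rank-sum U with midrank ties. When the pooled sample size is at most 12
#' the p-value is exact, by enumeration of all group assignments of the
#' pooled values (which handles ties, unlike the textbook exact tables);
#' otherwise a normal approximation with tie correction and continuity
#' correction is used. Two-sided by default.
#'
#' @param a,b Numeric vectors (each non-empty).
#' @param alternative `"two.sided"` (default), `"greater"` (a tends larger)
#'   or `"less"`.
#' @param exact_max Pooled size at or below which enumeration is used.
#' @return A one-row tibble (`u`, `p`, `method`). `u` counts pairs (i, j)
#'   with `a[i] > b[j]`, ties counted one half. All pooled values identical
#'   gives `p = 1`.
#' @export
mann_whitney <- function(a, b, alternative = c("two.sided", "greater", "less"),
                         exact_max = 12) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) abort("Both groups must be non-empty.")
  res <- mw_test(a, b, alternative, exact_max)
  tibble(u = res$u, p = res$p, method = res$method)
}

# Internal scalar Mann-Whitney used by mann_whitney() and derive_panels().
mw_test <- function(a, b, alternative = "two.sided", exact_max = 12) {
  m <- length(a); n <- length(b); nn <- m + n
  pooled <- c(a, b)
  r <- rank(pooled)
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  if (nn <= exact_max) {
    idx <- combn(nn, m)
    rsums <- colSums(matrix(r[idx], nrow = m))
    us <- rsums - m * (m + 1) / 2
    p_ge <- mean(us >= u)
    p_le <- mean(us <= u)
    p <- switch(alternative,
                greater = p_ge,
                less = p_le,
                two.sided = min(1, 2 * min(p_ge, p_le)))
    return(list(u = u, p = p, method = "exact"))
  }
  ties <- table(pooled)
  mu <- m * n / 2
  sig2 <- (m * n / 12) * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
  if (sig2 == 0) return(list(u = u, p = 1, method = "normal"))
  z_num <- switch(alternative,
                  greater = u - mu - 0.5,
                  less = u - mu + 0.5,
                  two.sided = u - mu - sign(u - mu) * 0.5)
  z <- z_num / sqrt(sig2)
  p <- switch(alternative,
              greater = pnorm(z, lower.tail = FALSE),
              less = pnorm(z),
              two.sided = min(1, 2 * pnorm(-abs(z))))
  list(u = u, p = p, method = "normal")
}

#' Derive cell-type distinguishing gene panels from an atlas
#'
#' A gene enters cell type c's panel when its mean intensity across c's
#' atlas samples strictly exceeds `fold_min` times its mean across all
#' other atlas samples (pooled; linear scale) and a two-sided Mann-Whitney
#' test of c's samples against all others gives `p < p_max`. Genes
#' qualifying for more than one cell type are then removed from every
#' panel, so the final panels are pairwise disjoint. Cell types with fewer
#' than two atlas samples are excluded with a warning (the rank test needs
#' replication).
#'
#' @param atlas A [cell_atlas].
#' @param fold_min Mean-ratio threshold (strict).
#' @param p_max Rank-test p threshold (strict).
#' @param comparator `"pooled"` (default) compares against the pooled mean
#'   of all other samples; `"max"` against the largest per-type mean among
#'   the other cell types (stricter).
#' @param denom_floor Small positive constant added to the denominator mean
#'   so the ratio stays defined for background-level genes.
#' @return A tibble (`cell_type`, `gene_id`) of the final panels, with a
#'   `provenance` attribute recording the thresholds, comparator, atlas id
#'   and the number of multi-panel genes removed.
#' @export
derive_panels <- function(atlas, fold_min = 64, p_max = 0.001,
                          comparator = c("pooled", "max"),
                          denom_floor = 1e-6) {
  stopifnot(inherits(atlas, "cell_atlas"))
  comparator <- match.arg(comparator)
  types <- unique(atlas$samples$cell_type)
  sizes <- table(atlas$samples$cell_type)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warn(sprintf("Excluding cell type(s) with a single atlas sample: %s.",
                 paste(small, collapse = ", ")))
    types <- setdiff(types, small)
  }
  type_means <- vapply(types, function(ct) {
    rowMeans(atlas$values[, atlas$samples$cell_type == ct, drop = FALSE])
  }, numeric(nrow(atlas$values)))
  hits <- lapply(types, function(ct) {
    own <- atlas$samples$cell_type == ct
    mean_own <- type_means[, ct]
    denom <- if (comparator == "pooled") {
      rowMeans(atlas$values[, !own, drop = FALSE])
    } else {
      apply(type_means[, setdiff(types, ct), drop = FALSE], 1, max)
    }
    ratio <- mean_own / (denom + denom_floor)
    cand <- which(ratio > fold_min)
    keep <- cand[vapply(cand, function(g) {
      mw_test(atlas$values[g, own], atlas$values[g, !own])$p < p_max
    }, logical(1))]
    rownames(atlas$values)[keep]
  })
  names(hits) <- types
  panel <- tibble(cell_type = rep(types, lengths(hits)),
                  gene_id = unlist(hits, use.names = FALSE))
  dup <- unique(panel$gene_id[duplicated(panel$gene_id)])
  panel <- dplyr::filter(panel, !.data$gene_id %in% dup)
  attr(panel, "provenance") <- list(fold_min = fold_min, p_max = p_max,
                                    comparator = comparator,
                                    atlas_id = atlas$atlas_id,
                                    n_multi_panel_removed = length(dup))
  panel
}

#' Map marker panels onto the study platform
#'
#' Replaces each atlas gene by its probe(s) on the study platform via an
#' identifier-mapping table. A gene mapping to several probes contributes
#' all of them (panel counts are probe counts); unmapped genes are dropped
#' and counted. Probes shared between panels after mapping are removed
#' from all panels, restoring pairwise disjointness.
#'
#' @param panels Tibble (`cell_type`, `gene_id`) from [derive_panels()].
#' @param map Tibble (`gene_id`, `probe_id`) of identifier pairs; duplicate
#'   pairs are collapsed. Must be non-empty.
#' @return A tibble (`cell_type`, `probe_id`); the number of dropped
#'   (unmapped) genes is reported via a message.
#' @export
map_panels <- function(panels, map) {
  map <- dplyr::distinct(as_tibble(map))
  if (!nrow(map)) abort("`map` is empty.")
  if (!all(c("gene_id", "probe_id") %in% names(map))) {
    abort("`map` needs gene_id and probe_id columns.")
  }
  mapped <- dplyr::inner_join(panels, map, by = "gene_id",
                              relationship = "many-to-many")
  n_unmapped <- length(setdiff(panels$gene_id, map$gene_id))
  if (n_unmapped) {
    inform(sprintf("Dropped %d unmapped gene(s).", n_unmapped))
  }
  out <- dplyr::distinct(mapped[, c("cell_type", "probe_id")])
  shared <- unique(out$probe_id[duplicated(out$probe_id)])
  dplyr::filter(out, !.data$probe_id %in% shared)
}

#' Identity gene-to-probe map
#'
#' Convenience for studies profiled on the same identifier space as the
#' atlas, as in the synthetic design.
#'
#' @param gene_ids Character vector of identifiers.
#' @return A tibble (`gene_id`, `probe_id`) with `probe_id == gene_id`.
#' @export
identity_map <- function(gene_ids) {
  tibble(gene_id = gene_ids, probe_id = gene_ids)
}
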