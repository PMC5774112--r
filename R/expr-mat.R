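#' Probe-by-array expression matrix with sample annotations
#'
#' `expr_mat()` bundles a numeric probe x array intensity matrix with a
#' per-array annotation table and a scale flag recording where the values
#' sit in the normalization chain: `"raw"` intensities off the scanner,
#' `"chip_normalized"` after per-chip percentile scaling, or
#' `"control_ratio"` after division by the median of timepoint-matched
#' unirradiated control arrays.
#'
#' @param values Numeric matrix, probes in rows and arrays in columns, with
#'   unique `rownames` (probe IDs) and `colnames` (array IDs). `NA` entries
#'   are only permitted on the `control_ratio` scale, where they mark ratios
#'   whose control median was zero.
#' @param samples Data frame of per-array annotations with at least an
#'   `array_id` column matching `colnames(values)`; typically also `group`,
#'   `timepoint` and `replicate`. Defaults to a bare `array_id` table.
#' @param scale One of `"raw"`, `"chip_normalized"`, `"control_ratio"`.
#' @return An object of class `expr_mat`.
#' @seealso [sample_info()], [read_expr_matrix()], [write_expr_matrix()]
#' @export
expr_mat <- function(values, samples = NULL, scale = "raw") {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry probe IDs as rownames and array IDs as colnames.")
  }
  if (anyDuplicated(rownames(values))) abort("Duplicate probe IDs in `values`.")
  if (anyDuplicated(colnames(values))) abort("Duplicate array IDs in `values`.")
  scale <- match.arg(scale, c("raw", "chip_normalized", "control_ratio"))
  if (scale != "control_ratio" && anyNA(values)) {
    abort("Missing values are only allowed on the control_ratio scale.")
  }
  if (any(!is.finite(values) & !is.na(values))) {
    abort("`values` must be finite (NA only on the control_ratio scale).")
  }
  if (scale != "control_ratio" && any(values < 0)) {
    abort("Intensities must be nonnegative.")
  }
  if (is.null(samples)) {
    samples <- tibble(array_id = colnames(values))
  }
  samples <- as_tibble(samples)
  if (!"array_id" %in% names(samples)) abort("`samples` needs an `array_id` column.")
  if (!setequal(samples$array_id, colnames(values)) ||
      anyDuplicated(samples$array_id)) {
    abort("`samples$array_id` must match the array columns exactly.")
  }
  samples <- samples[match(colnames(values), samples$array_id), ]
  structure(list(values = values, samples = samples, scale = scale),
            class = "expr_mat")
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d probes x %d arrays [%s scale]\n",
              nrow(x$values), ncol(x$values), x$scale))
  extra <- setdiff(names(x$samples), "array_id")
  if (length(extra)) cat("annotations:", paste(extra, collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Accessors for expression containers
#'
#' @param m An [expr_mat] or [cell_atlas].
#' @return `sample_info()` returns the per-array (or per-atlas-sample)
#'   annotation tibble; `probe_ids()` and `array_ids()` return character
#'   vectors; `intensity_scale()` returns the scale flag of an `expr_mat`.
#' @export
sample_info <- function(m) m$samples

#' @rdname sample_info
#' @export
probe_ids <- function(m) rownames(m$values)

#' @rdname sample_info
#' @export
array_ids <- function(m) colnames(m$values)

#' @rdname sample_info
#' @export
intensity_scale <- function(m) m$scale

# Subset an expr_mat to a probe set, preserving annotations.
subset_probes <- function(m, probes) {
  missing <- setdiff(probes, rownames(m$values))
  if (length(missing)) {
    abort(sprintf("%d probe(s) not present in the matrix (e.g. %s).",
                  length(missing), missing[[1]]))
  }
  expr_mat(m$values[probes, , drop = FALSE], m$samples, m$scale)
}

# Column indices of arrays matching a group selector (character vector of
# group labels) and optionally a timepoint.
select_arrays <- function(m, groups, timepoint = NULL) {
  s <- m$samples
  keep <- s$group %in% groups
  if (!is.null(timepoint)) keep <- keep & s$timepoint %in% timepoint
  which(keep)
}

#' Gene-by-sample cell-type expression atlas
#'
#' A compendium of purified cell-type expression profiles: a positive
#' gene x sample intensity matrix where every atlas sample carries a
#' cell-type label. Marker-panel derivation ([derive_panels()]) screens
#' each gene's expression in one cell type against all remaining samples.
#'
#' @param values Positive numeric matrix, genes x atlas samples, with unique
#'   rownames (gene IDs) and colnames (sample IDs).
#' @param cell_types Character vector of per-sample cell-type labels, one per
#'   column of `values`.
#' @param atlas_id Optional identifier recorded in panel provenance.
#' @return An object of class `cell_atlas`.
#' @export
cell_atlas <- function(values, cell_types, atlas_id = "atlas") {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    abort("`values` must carry gene IDs as rownames and sample IDs as colnames.")
  }
  if (anyDuplicated(rownames(values))) abort("Duplicate gene IDs in atlas.")
  if (anyDuplicated(colnames(values))) abort("Duplicate sample IDs in atlas.")
  if (any(!is.finite(values)) || any(values <= 0)) {
    abort("Atlas intensities must be finite and strictly positive.")
  }
  if (length(cell_types) != ncol(values)) {
    abort("`cell_types` must have one label per atlas sample.")
  }
  structure(list(values = values,
                 samples = tibble(sample_id = colnames(values),
                                  cell_type = as.character(cell_types)),
                 atlas_id = atlas_id),
            class = "cell_atlas")
}

#' @export
print.cell_atlas <- function(x, ...) {
  cat(sprintf("<cell_atlas> %d genes x %d samples, %d cell types\n",
              nrow(x$values), ncol(x$values),
              length(unique(x$samples$cell_type))))
  invisible(x)
}

#' Read and write tab-delimited expression matrices
#'
#' The on-disk dialect is a plain TSV: a header row of array IDs, probe IDs
#' in the first column, one probe per row. Annotations travel in a companion
#' TSV with one row per array (`array_id`, `group`, `timepoint`,
#' `replicate`). Atlases use the same matrix dialect with a `cell_type`
#' annotation column.
#'
#' @param path Path of the matrix TSV.
#' @param annot_path Optional path of the annotation TSV.
#' @param scale Scale flag to stamp on the result (the file does not record
#'   it); see [expr_mat()].
#' @return [read_expr_matrix()] returns an [expr_mat];
#'   [write_expr_matrix()] returns `path` invisibly.
#' @export
read_expr_matrix <- function(path, annot_path = NULL, scale = "raw") {
  tab <- parse_matrix_lines(readLines(path), path)
  samples <- if (!is.null(annot_path)) {
    as_tibble(utils::read.delim(annot_path, sep = "\t",
                                colClasses = "character"))
  }
  if (!is.null(samples) && "replicate" %in% names(samples)) {
    samples$replicate <- as.integer(samples$replicate)
  }
  expr_mat(tab, samples = samples, scale = scale)
}

#' @rdname read_expr_matrix
#' @param m An [expr_mat] (or [cell_atlas]) to serialize.
#' @export
write_expr_matrix <- function(m, path, annot_path = NULL) {
  vals <- m$values
  header <- paste(c("probe_id", colnames(vals)), collapse = "\t")
  body <- vapply(seq_len(nrow(vals)), function(i) {
    # %.17g round-trips doubles exactly
    paste(c(rownames(vals)[i], sprintf("%.17g", vals[i, ])), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  if (!is.null(annot_path)) {
    utils::write.table(m$samples, annot_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a series-matrix style expression file
#'
#' Accepts both the GEO series-matrix dialect (a `!key<TAB>value...` header
#' block with the numeric table fenced between `!series_matrix_table_begin`
#' and `!series_matrix_table_end`) and the plain TSV dialect of
#' [read_expr_matrix()]. `!Sample_*` header lines become annotation columns.
#'
#' @param path File path.
#' @param scale Scale flag for the result.
#' @return An [expr_mat]; if a `!Sample_characteristics_cell_type` (or a
#'   `cell_type` annotation) is present the result can be converted with
#'   [as_cell_atlas()].
#' @export
read_series_matrix <- function(path, scale = "raw") {
  lines <- readLines(path)
  if (!any(startsWith(lines, "!"))) {
    return(expr_mat(parse_matrix_lines(lines, path), scale = scale))
  }
  begin <- which(lines == "!series_matrix_table_begin")
  end <- which(lines == "!series_matrix_table_end")
  if (length(begin) != 1L || length(end) != 1L || end <= begin) {
    abort(sprintf("%s: malformed series-matrix table fences.", path))
  }
  tab <- parse_matrix_lines(lines[(begin + 1L):(end - 1L)], path,
                            line_offset = begin)
  meta <- lines[startsWith(lines, "!Sample_")]
  samples <- tibble(array_id = colnames(tab))
  for (ln in meta) {
    parts <- gsub('^"|"$', "", strsplit(ln, "\t", fixed = TRUE)[[1]])
    key <- sub("^!Sample_", "", parts[[1]])
    if (length(parts) == ncol(tab) + 1L) {
      samples[[key]] <- parts[-1]
    }
  }
  expr_mat(tab, samples = samples, scale = scale)
}

# Parse TSV matrix lines (header of array IDs + probe rows) into a numeric
# matrix; ragged rows and duplicate IDs raise errors naming the line.
parse_matrix_lines <- function(lines, path, line_offset = 0L) {
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) abort(sprintf("%s: no data rows.", path))
  split <- strsplit(lines, "\t", fixed = TRUE)
  split <- lapply(split, function(p) gsub('^"|"$', "", p))
  ncols <- length(split[[1]])
  widths <- lengths(split)
  bad <- which(widths != ncols)
  if (length(bad)) {
    abort(sprintf("%s: ragged row at line %d (%d fields, expected %d).",
                  path, bad[[1]] + line_offset, widths[bad[[1]]], ncols))
  }
  arrays <- split[[1]][-1]
  ids <- vapply(split[-1], `[[`, character(1), 1L)
  if (anyDuplicated(ids)) {
    dup <- which(duplicated(ids))[[1]] + 1L
    abort(sprintf("%s: duplicate probe ID '%s' at line %d.",
                  path, ids[dup - 1L], dup + line_offset))
  }
  if (anyDuplicated(arrays)) abort(sprintf("%s: duplicate array IDs.", path))
  vals <- matrix(NA_real_, nrow = length(ids), ncol = length(arrays),
                 dimnames = list(ids, arrays))
  for (i in seq_along(ids)) {
    row <- suppressWarnings(as.numeric(split[[i + 1L]][-1]))
    if (anyNA(row)) {
      abort(sprintf("%s: non-numeric value at line %d.", path,
                    i + 1L + line_offset))
    }
    vals[i, ] <- row
  }
  vals
}

#' Convert an annotated expression matrix to a cell-type atlas
#'
#' @param m An [expr_mat] whose annotations contain a cell-type column.
#' @param cell_type_col Name of that column.
#' @param atlas_id Identifier recorded in panel provenance.
#' @return A [cell_atlas].
#' @export
as_cell_atlas <- function(m, cell_type_col = "cell_type", atlas_id = "atlas") {
  s <- sample_info(m)
  hit <- intersect(c(cell_type_col, "characteristics_cell_type"), names(s))
  if (!length(hit)) abort("No cell-type annotation column found.")
  cell_atlas(m$values, s[[hit[[1]]]], atlas_id = atlas_id)
}
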