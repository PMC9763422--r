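#' Per-cell binned copy-number matrix
#'
#' Container for single-cell copy-number calls: one row per cell, one column
#' per genomic bin of the associated [binned_genome()]. Values may be integer
#' states or real-valued calls; negatives and missing values are rejected at
#' construction rather than imputed.
#'
#' @param values Numeric matrix, cells x bins, all values >= 0, no NA.
#' @param genome A `binned_genome` whose bin count matches `ncol(values)`.
#' @param cell_ids Unique cell identifiers (default `cell1..cellN`).
#' @param passage Passage label, free text (e.g. `"P3"`).
#' @return A `cell_cn_matrix` object.
#' @export
cell_cn_matrix <- function(values, genome, cell_ids = NULL, passage = "P0") {
  stopifnot(inherits(genome, "binned_genome"))
  values <- as.matrix(values)
  if (ncol(values) != genome$n_bins)
    stop(sprintf("bin count mismatch: genome has %d bins, matrix has %d columns",
                 genome$n_bins, ncol(values)), call. = FALSE)
  if (anyNA(values))
    stop("missing copy-number values are not allowed", call. = FALSE)
  if (any(values < 0))
    stop("copy-number values must be >= 0", call. = FALSE)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (length(cell_ids) != nrow(values))
    stop("'cell_ids' length must equal the number of rows", call. = FALSE)
  if (anyDuplicated(cell_ids))
    stop("'cell_ids' must be unique", call. = FALSE)
  dimnames(values) <- list(cell_ids, bin_names(genome))
  structure(list(values = values, genome = genome,
                 cell_ids = as.character(cell_ids), passage = passage),
            class = "cell_cn_matrix")
}

#' @export
print.cell_cn_matrix <- function(x, ...) {
  cat(sprintf("cell_cn_matrix: %d cells x %d bins (passage %s)\n",
              nrow(x$values), ncol(x$values), x$passage))
  invisible(x)
}

#' @export
dim.cell_cn_matrix <- function(x) dim(x$values)

#' Bulk per-bin copy-number profile
#'
#' A single averaged copy-number track over a binned genome, e.g. a
#' SNP-array-derived 1 Mb profile of a bulk sample.
#'
#' @param values Numeric vector, one value >= 0 per bin.
#' @param genome A `binned_genome`.
#' @param sample_label Sample name.
#' @return A `bulk_cn_profile` object.
#' @export
bulk_cn_profile <- function(values, genome, sample_label = "sample") {
  stopifnot(inherits(genome, "binned_genome"))
  values <- as.numeric(values)
  if (length(values) != genome$n_bins)
    stop(sprintf("bin count mismatch: genome has %d bins, profile has %d values",
                 genome$n_bins, length(values)), call. = FALSE)
  if (anyNA(values) || any(values < 0))
    stop("profile values must be >= 0 with no NA", call. = FALSE)
  structure(list(values = stats::setNames(values, bin_names(genome)),
                 genome = genome, sample_label = sample_label),
            class = "bulk_cn_profile")
}

#' @export
print.bulk_cn_profile <- function(x, ...) {
  cat(sprintf("bulk_cn_profile '%s': %d bins, mean CN %.2f\n",
              x$sample_label, length(x$values), mean(x$values)))
  invisible(x)
}

# ---- TSV dialect -----------------------------------------------------------

#' Read and write per-cell matrices in the package TSV dialect
#'
#' The dialect is one header line, first column `cell_id`, then one column
#' per bin named `chrom:start-end` in genome order. `read_cell_matrix`
#' validates the header against `genome` and refuses negative values.
#' Round-trips are bit-exact for integer calls and within 1e-9 for reals.
#'
#' @param path File path.
#' @param genome A `binned_genome` the columns must match.
#' @param passage Passage label attached to the read matrix.
#' @param matrix A `cell_cn_matrix` to write.
#' @return `read_cell_matrix` returns a `cell_cn_matrix`.
#' @export
read_cell_matrix <- function(path, genome, passage = "P0") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L || names(df)[1L] != "cell_id")
    stop("malformed header: first column must be 'cell_id'", call. = FALSE)
  if (ncol(df) - 1L != genome$n_bins)
    stop(sprintf("bin count mismatch: expected %d bin columns, observed %d",
                 genome$n_bins, ncol(df) - 1L), call. = FALSE)
  if (!identical(names(df)[-1L], bin_names(genome)))
    stop("malformed header: bin columns do not match the genome's bins",
         call. = FALSE)
  vals <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(vals) || anyNA(vals))
    stop("malformed matrix: non-numeric or missing copy-number values",
         call. = FALSE)
  cell_cn_matrix(vals, genome, cell_ids = df$cell_id, passage = passage)
}

#' @rdname read_cell_matrix
#' @export
write_cell_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "cell_cn_matrix"))
  df <- data.frame(cell_id = matrix$cell_ids, matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write bulk profiles (single-row TSV dialect)
#'
#' Same column layout as the cell matrix dialect but a single data row and a
#' `sample_id` first column.
#'
#' @inheritParams read_cell_matrix
#' @param profile A `bulk_cn_profile` to write.
#' @export
read_bulk_profile <- function(path, genome) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "sample_id")
    stop("malformed header: first column must be 'sample_id'", call. = FALSE)
  if (nrow(df) != 1L)
    stop("bulk profile file must contain exactly one data row", call. = FALSE)
  if (ncol(df) - 1L != genome$n_bins)
    stop(sprintf("bin count mismatch: expected %d bin columns, observed %d",
                 genome$n_bins, ncol(df) - 1L), call. = FALSE)
  bulk_cn_profile(as.numeric(df[1L, -1L]), genome, sample_label = df$sample_id[1L])
}

#' @rdname read_bulk_profile
#' @export
write_bulk_profile <- function(profile, path) {
  stopifnot(inherits(profile, "bulk_cn_profile"))
  df <- data.frame(sample_id = profile$sample_label,
                   rbind(unname(profile$values)), check.names = FALSE)
  names(df)[-1L] <- bin_names(profile$genome)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- profile arithmetic ----------------------------------------------------

#' Average copy-number profile over cells
#'
#' Component-wise arithmetic mean of the per-bin copy number over a set of
#' cells, e.g. the population-averaged profile plotted beneath per-cluster
#' heatmaps.
#'
#' @param matrix A `cell_cn_matrix`.
#' @param cells Optional character vector of cell ids to average over
#'   (default: all cells).
#' @return Named numeric vector, one mean per bin.
#' @export
average_profile <- function(matrix, cells = NULL) {
  stopifnot(inherits(matrix, "cell_cn_matrix"))
  if (is.null(cells)) cells <- matrix$cell_ids
  if (length(cells) == 0L)
    stop("'cells' must name at least one cell", call. = FALSE)
  unknown <- setdiff(cells, matrix$cell_ids)
  if (length(unknown))
    stop("unknown cell id(s): ", paste(utils::head(unknown, 3), collapse = ", "),
         call. = FALSE)
  colMeans(matrix$values[cells, , drop = FALSE])
}

#' Estimate the total chromosome number from a binned profile
#'
#' Sums, over chromosomes, the mean copy number of each chromosome's bins:
#' a diploid genome of 23 chromosome pairs gives 46. By default every bin
#' counts equally within its chromosome (the remainder bin included);
#' `weight = "length"` weights bins by their base-pair length instead.
#'
#' @param profile Per-bin numeric vector matching `genome`.
#' @param genome A `binned_genome`.
#' @param weight `"equal"` (default) or `"length"`.
#' @return The estimated chromosome count (real-valued).
#' @export
estimate_chromosome_number <- function(profile, genome,
                                       weight = c("equal", "length")) {
  stopifnot(inherits(genome, "binned_genome"))
  weight <- match.arg(weight)
  profile <- as.numeric(profile)
  if (length(profile) != genome$n_bins)
    stop(sprintf("profile length %d does not match %d genome bins",
                 length(profile), genome$n_bins), call. = FALSE)
  ch <- factor(genome$bins$chrom, levels = genome$chrom_order)
  if (weight == "equal") {
    sum(tapply(profile, ch, mean))
  } else {
    w <- bin_lengths(genome)
    sum(tapply(profile * w, ch, sum) / tapply(w, ch, sum))
  }
}

#' Percentage of cells in a set of clusters
#'
#' Reports `100 * (cells in the named clusters) / (total cells)` rounded to
#' one decimal, the convention used for clonal proportions (e.g. 303 of 744
#' cells is 40.7).
#'
#' @param x A `cn_clusters` object or a plain vector of per-cell cluster
#'   labels.
#' @param cluster_ids Cluster labels to pool; an empty selection gives 0.0.
#' @return Percentage rounded to one decimal place.
#' @export
proportion_of <- function(x, cluster_ids) {
  assignments <- if (inherits(x, "cn_clusters")) x$assignments else x
  valid <- if (inherits(x, "cn_clusters")) seq_len(x$k) else unique(assignments)
  unknown <- setdiff(cluster_ids, valid)
  if (length(unknown))
    stop("unknown cluster id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  round(100 * sum(assignments %in% cluster_ids) / length(assignments), 1)
}
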