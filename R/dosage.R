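#' Reads-per-kilobase-million normalization
#'
#' `rpkm = count / total_reads_millions / gene_length_kb`: each gene's read
#' count normalized by the sample's sequencing depth (in millions of reads)
#' and by the gene's length (in kilobases).
#'
#' @param counts Per-gene read counts (>= 0).
#' @param gene_length_kb Per-gene lengths in kb (> 0).
#' @param total_reads_millions Library size in millions of reads (> 0).
#' @return Per-gene RPKM values.
#' @export
rpkm <- function(counts, gene_length_kb, total_reads_millions) {
  if (any(total_reads_millions <= 0))
    stop("'total_reads_millions' must be > 0", call. = FALSE)
  if (any(gene_length_kb <= 0))
    stop("'gene_length_kb' must be > 0", call. = FALSE)
  if (any(counts < 0))
    stop("'counts' must be >= 0", call. = FALSE)
  counts / total_reads_millions / gene_length_kb
}

#' Validate a gene expression table
#'
#' A gene table is a data.frame with columns `gene_id`, `chrom`, `start`,
#' `end`, `length_kb` and either raw counts (`count_A`, `count_B`) or
#' precomputed RPKM (`rpkm_A`, `rpkm_B`) for the two samples.
#'
#' @param genes Data frame to validate.
#' @return The validated data frame, invisibly classed `gene_table`.
#' @export
gene_table <- function(genes) {
  need <- c("gene_id", "chrom", "start", "end", "length_kb")
  miss <- setdiff(need, names(genes))
  if (length(miss))
    stop("gene table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  has_counts <- all(c("count_A", "count_B") %in% names(genes))
  has_rpkm <- all(c("rpkm_A", "rpkm_B") %in% names(genes))
  if (!has_counts && !has_rpkm)
    stop("gene table needs count_A/count_B or rpkm_A/rpkm_B columns",
         call. = FALSE)
  if (any(genes$length_kb <= 0))
    stop("gene lengths must be positive", call. = FALSE)
  if (anyDuplicated(genes$gene_id))
    stop("gene ids must be unique", call. = FALSE)
  class(genes) <- c("gene_table", "data.frame")
  genes
}

#' Read / write the gene table TSV dialect
#' @param path File path.
#' @param genes A `gene_table` to write.
#' @export
read_gene_table <- function(path) {
  gene_table(utils::read.table(path, sep = "\t", header = TRUE,
                               stringsAsFactors = FALSE))
}

#' @rdname read_gene_table
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

gene_rpkm <- function(genes, sample) {
  col <- paste0("rpkm_", sample)
  if (col %in% names(genes)) return(genes[[col]])
  cnt <- genes[[paste0("count_", sample)]]
  rpkm(cnt, genes$length_kb, sum(cnt) / 1e6)
}

#' Per-bin mean expression log2 fold change
#'
#' Computes each gene's `log2((rpkm_A + pseudocount) / (rpkm_B +
#' pseudocount))`, assigns the gene to the genome bin containing its start
#' coordinate, and averages (unweighted) within each bin. Bins without
#' genes are `NA`.
#'
#' @param genes A `gene_table` (counts are RPKM-normalized on the fly).
#' @param genome A `binned_genome` (typically 1 Mb bins).
#' @param pseudocount RPKM pseudocount guarding log of zero (default 0.1).
#' @return List with `log2fc` (per-bin mean, NA where empty) and `n_genes`
#'   (genes per bin).
#' @export
binned_log2fc <- function(genes, genome, pseudocount = 0.1) {
  genes <- gene_table(genes)
  stopifnot(inherits(genome, "binned_genome"))
  a <- gene_rpkm(genes, "A")
  b <- gene_rpkm(genes, "B")
  lfc <- log2((a + pseudocount) / (b + pseudocount))
  idx <- bin_index_of(genome, genes$chrom, genes$start, what = genes$gene_id)
  means <- rep(NA_real_, genome$n_bins)
  n <- integer(genome$n_bins)
  agg <- tapply(lfc, idx, mean)
  means[as.integer(names(agg))] <- agg
  cnt <- table(idx)
  n[as.integer(names(cnt))] <- as.integer(cnt)
  list(log2fc = stats::setNames(means, bin_names(genome)), n_genes = n)
}

#' Per-bin log2 copy-number ratio between two bulk profiles
#'
#' `log2((cn_A + epsilon) / (cn_B + epsilon))` per bin; `epsilon` guards
#' zero copy number.
#'
#' @param cn_a,cn_b `bulk_cn_profile` objects (or per-bin vectors) on the
#'   same genome.
#' @param genome The shared `binned_genome` (taken from profiles if given).
#' @param epsilon Copy-number pseudocount (default 0.1).
#' @return Per-bin numeric vector.
#' @export
binned_log2cnv <- function(cn_a, cn_b, genome = NULL, epsilon = 0.1) {
  if (inherits(cn_a, "bulk_cn_profile")) {
    genome <- cn_a$genome
    cn_a <- cn_a$values
  }
  if (inherits(cn_b, "bulk_cn_profile")) cn_b <- cn_b$values
  if (length(cn_a) != length(cn_b))
    stop("profiles differ in length", call. = FALSE)
  out <- log2((as.numeric(cn_a) + epsilon) / (as.numeric(cn_b) + epsilon))
  if (!is.null(genome)) names(out) <- bin_names(genome)
  out
}

#' Assemble the per-bin dosage table
#'
#' Pairs the binned expression fold-change track with the binned
#' copy-number ratio track; bins missing in either (no genes, or undefined
#' CN ratio) are marked NA and dropped pairwise by [dosage_correlation()].
#'
#' @param log2fc Output of [binned_log2fc()] (or its `log2fc` vector).
#' @param log2cnv Output of [binned_log2cnv()].
#' @param n_genes Optional per-bin gene counts.
#' @return A `dosage_table` data.frame with columns `bin`, `log2fc`,
#'   `log2cnv`, `n_genes`.
#' @export
dosage_table <- function(log2fc, log2cnv, n_genes = NULL) {
  if (is.list(log2fc)) {
    if (is.null(n_genes)) n_genes <- log2fc$n_genes
    log2fc <- log2fc$log2fc
  }
  if (length(log2fc) != length(log2cnv))
    stop("tracks differ in length", call. = FALSE)
  if (is.null(n_genes)) n_genes <- ifelse(is.na(log2fc), 0L, NA_integer_)
  df <- data.frame(bin = seq_along(log2fc),
                   log2fc = as.numeric(log2fc),
                   log2cnv = as.numeric(log2cnv),
                   n_genes = n_genes)
  class(df) <- c("dosage_table", "data.frame")
  df
}

#' Pearson correlation between copy-number variation and expression change
#'
#' Drops bins missing in either track, then computes the Pearson
#' correlation and its two-sided p-value from the t transform with n - 2
#' degrees of freedom (via [stats::cor.test()]).
#'
#' @param table A `dosage_table`.
#' @return A `dosage_cor` object: `r`, `p`, `n` (bins used).
#' @export
dosage_correlation <- function(table) {
  ok <- is.finite(table$log2fc) & is.finite(table$log2cnv)
  x <- table$log2cnv[ok]
  y <- table$log2fc[ok]
  if (length(x) < 3L)
    stop("need at least 3 bins with both tracks defined", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: a track has zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  structure(list(r = unname(ct$estimate), p = ct$p.value, n = length(x)),
            class = "dosage_cor")
}

#' @export
print.dosage_cor <- function(x, ...) {
  cat(sprintf("dosage correlation: R = %.3f over %d bins (p %s)\n",
              x$r, x$n,
              if (x$p < 1e-4) "< 0.0001" else sprintf("= %.3g", x$p)))
  invisible(x)
}

#' Export a ranked gene list for preranked gene-set tools
#'
#' Two-column TSV (gene_id, log2FC) sorted by decreasing fold change,
#' compatible with preranked-GSEA input; gene-set analysis itself is left
#' to the dedicated external tools.
#'
#' @param genes A `gene_table`.
#' @param path Output path.
#' @param pseudocount RPKM pseudocount.
#' @export
write_ranked_list <- function(genes, path, pseudocount = 0.1) {
  genes <- gene_table(genes)
  lfc <- log2((gene_rpkm(genes, "A") + pseudocount) /
                (gene_rpkm(genes, "B") + pseudocount))
  df <- data.frame(gene_id = genes$gene_id, log2fc = lfc)
  df <- df[order(-df$log2fc), ]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
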