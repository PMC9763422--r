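#' Write cluster profiles in the bulk-profile TSV dialect
#'
#' One row per cluster: `sample_id` first, then one column per bin holding
#' the cluster's mean copy number.
#'
#' @param profiles A `cluster_profiles` object.
#' @param path Output path.
#' @param field `"mean_cn"` (default) or `"state_cn"`.
#' @export
write_profiles <- function(profiles, path, field = c("mean_cn", "state_cn")) {
  field <- match.arg(field)
  genome <- attr(profiles, "genome")
  m <- profile_matrix(profiles, field)
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE)
  names(df)[-1L] <- bin_names(genome)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read cluster profiles written by [write_profiles()]
#'
#' @param path File path.
#' @param genome The `binned_genome` the columns must match.
#' @param passage Passage label attached to each profile.
#' @return A `cluster_profiles` object.
#' @export
read_profiles <- function(path, genome, passage = "P0") {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (names(df)[1L] != "sample_id")
    stop("malformed header: first column must be 'sample_id'", call. = FALSE)
  if (ncol(df) - 1L != genome$n_bins)
    stop(sprintf("bin count mismatch: expected %d bin columns, observed %d",
                 genome$n_bins, ncol(df) - 1L), call. = FALSE)
  profs <- lapply(seq_len(nrow(df)), function(i)
    cluster_profile(round_half_up(as.numeric(df[i, -1L])), genome,
                    label = df$sample_id[i], passage = passage,
                    mean_cn = as.numeric(df[i, -1L])))
  cluster_profiles(profs, genome)
}

#' Copy-number heatmap of cells or cluster profiles
#'
#' Simple genome-ordered heatmap (blue below 2 copies, white at 2, red
#' above) with chromosome boundaries marked.
#'
#' @param x A `cell_cn_matrix` or `cluster_profiles` object.
#' @param max_cn Copy number at which the color scale saturates.
#' @param ... Passed to [graphics::image()].
#' @export
plot_cn_heatmap <- function(x, max_cn = 6, ...) {
  if (inherits(x, "cell_cn_matrix")) {
    m <- x$values
    genome <- x$genome
  } else if (inherits(x, "cluster_profiles")) {
    m <- profile_matrix(x, "mean_cn")
    genome <- attr(x, "genome")
  } else stop("cannot plot object of class ", class(x)[1L], call. = FALSE)
  m <- pmin(m, max_cn)
  pal <- grDevices::colorRampPalette(c("steelblue", "white", "firebrick"))(64)
  graphics::image(x = seq_len(ncol(m)), y = seq_len(nrow(m)), z = t(m),
                  zlim = c(0, max_cn) + c(0, 1e-9), col = pal,
                  xlab = "genomic bin", ylab = "", yaxt = "n", ...)
  ch <- genome$bins$chrom
  graphics::abline(v = which(ch[-1L] != ch[-length(ch)]) + 0.5, col = "grey40")
  invisible(x)
}
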