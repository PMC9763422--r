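#' Tile a genome into fixed-width bins
#'
#' Builds the coordinate system the whole package indexes into: ordered,
#' non-overlapping, half-open `[start, end)` bins of width `bin_width` tiling
#' each chromosome left to right (0-based coordinates, BED convention). The
#' last bin of a chromosome may be shorter than `bin_width`.
#'
#' @param chromosome_lengths Named numeric vector of chromosome lengths in
#'   base pairs; names give the chromosome order.
#' @param bin_width Bin width in base pairs (e.g. `5e6` for 5 Mb windows).
#' @return A `binned_genome` object: a list with `bins` (data.frame of
#'   `chrom`, `start`, `end`), `bin_width`, `chrom_order`, `chrom_lengths`
#'   and `n_bins`.
#' @examples
#' g <- binned_genome(c(chr1 = 12e6), bin_width = 5e6)
#' g$bins  # [0,5M), [5M,10M), [10M,12M)
#' @export
binned_genome <- function(chromosome_lengths, bin_width) {
  if (is.null(names(chromosome_lengths)) || anyNA(names(chromosome_lengths)) ||
      any(names(chromosome_lengths) == ""))
    stop("'chromosome_lengths' must be a fully named vector", call. = FALSE)
  if (anyDuplicated(names(chromosome_lengths)))
    stop("duplicated chromosome names", call. = FALSE)
  if (!is.numeric(chromosome_lengths) || any(chromosome_lengths <= 0))
    stop("chromosome lengths must all be positive", call. = FALSE)
  if (!is.numeric(bin_width) || length(bin_width) != 1L || bin_width <= 0)
    stop("'bin_width' must be a single positive number", call. = FALSE)

  bins <- do.call(rbind, lapply(names(chromosome_lengths), function(ch) {
    len <- chromosome_lengths[[ch]]
    starts <- seq(0, len - 1, by = bin_width)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + bin_width, len),
               stringsAsFactors = FALSE)
  }))
  rownames(bins) <- NULL
  structure(list(bins = bins,
                 bin_width = bin_width,
                 chrom_order = names(chromosome_lengths),
                 chrom_lengths = chromosome_lengths,
                 n_bins = nrow(bins)),
            class = "binned_genome")
}

#' @export
print.binned_genome <- function(x, ...) {
  cat(sprintf("binned_genome: %d chromosomes, %d bins of %s bp (%.1f Mb genome)\n",
              length(x$chrom_order), x$n_bins, format(x$bin_width, big.mark = ","),
              sum(x$chrom_lengths) / 1e6))
  invisible(x)
}

#' Per-bin lengths in base pairs
#' @param genome A `binned_genome`.
#' @return Numeric vector, one length per bin.
#' @export
bin_lengths <- function(genome) {
  stopifnot(inherits(genome, "binned_genome"))
  genome$bins$end - genome$bins$start
}

#' Canonical bin names of the form "chrom:start-end"
#' @param genome A `binned_genome`.
#' @return Character vector of bin names.
#' @export
bin_names <- function(genome) {
  stopifnot(inherits(genome, "binned_genome"))
  sprintf("%s:%d-%d", genome$bins$chrom,
          as.integer(genome$bins$start), as.integer(genome$bins$end))
}

#' Map genomic positions to bin indices
#'
#' Returns the (1-based) index of the bin containing each position; bins are
#' half-open so a position equal to a bin end falls in the next bin.
#'
#' @param genome A `binned_genome`.
#' @param chrom Character vector of chromosome names.
#' @param pos Numeric vector of 0-based positions.
#' @param what Optional labels (e.g. gene ids) used in error messages.
#' @return Integer vector of global bin indices.
#' @export
bin_index_of <- function(genome, chrom, pos, what = NULL) {
  stopifnot(inherits(genome, "binned_genome"))
  if (length(chrom) != length(pos))
    stop("'chrom' and 'pos' must have equal length", call. = FALSE)
  lab <- if (is.null(what)) paste0(chrom, ":", pos) else as.character(what)
  bad <- !(chrom %in% genome$chrom_order)
  if (any(bad))
    stop("position outside genome (unknown chromosome): ", lab[which(bad)[1L]],
         call. = FALSE)
  lens <- genome$chrom_lengths[chrom]
  out <- pos < 0 | pos >= lens
  if (any(out))
    stop("position outside genome: ", lab[which(out)[1L]], call. = FALSE)
  nb <- ceiling(genome$chrom_lengths / genome$bin_width)
  offset <- c(0, cumsum(nb))[match(chrom, genome$chrom_order)]
  as.integer(offset + floor(pos / genome$bin_width) + 1)
}

#' A small six-chromosome demonstration genome
#'
#' Six chromosomes of 100-250 Mb: large enough to carry whole- and
#' partial-chromosome events, small enough for fast simulation.
#'
#' @param bin_width Bin width in base pairs (default 5 Mb, the single-cell
#'   profiling resolution).
#' @return A `binned_genome`.
#' @export
demo_genome <- function(bin_width = 5e6) {
  binned_genome(c(chr1 = 250e6, chr2 = 220e6, chr3 = 180e6,
                  chr4 = 150e6, chr5 = 120e6, chr6 = 100e6),
                bin_width = bin_width)
}

#' hg19 chromosome lengths
#'
#' Standard hg19/GRCh37 chromosome lengths (chr1-22, X, Y) for realistic runs.
#'
#' @return Named numeric vector of lengths in base pairs.
#' @export
hg19_lengths <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566, chrX = 155270560, chrY = 59373566)
}

#' Write / read bin definitions as BED3+1
#'
#' Tab-separated BED-style file with columns chrom, start, end, bin_index and
#' no header.
#'
#' @param genome A `binned_genome`.
#' @param path File path.
#' @return `read_bins_bed` returns a `binned_genome` (bin width inferred as
#'   the maximal bin length); `write_bins_bed` returns `path` invisibly.
#' @export
write_bins_bed <- function(genome, path) {
  stopifnot(inherits(genome, "binned_genome"))
  df <- cbind(genome$bins, bin_index = seq_len(genome$n_bins))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bins_bed
#' @export
read_bins_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "bin_index"),
                          stringsAsFactors = FALSE)
  df <- df[order(df$bin_index), , drop = FALSE]
  chroms <- unique(df$chrom)
  lens <- vapply(chroms, function(ch) max(df$end[df$chrom == ch]), numeric(1))
  binned_genome(stats::setNames(lens, chroms),
                bin_width = max(df$end - df$start))
}

#' Write / read a two-column chromosome length table
#'
#' @param chromosome_lengths Named numeric vector (write) to serialise.
#' @param path File path of the TSV (chromosome, length; no header).
#' @return `read_genome_table` returns a named numeric vector.
#' @export
write_genome_table <- function(chromosome_lengths, path) {
  utils::write.table(data.frame(names(chromosome_lengths),
                                chromosome_lengths),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_genome_table
#' @export
read_genome_table <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.numeric(df[[2]]), df[[1]])
}
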