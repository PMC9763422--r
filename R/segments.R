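#' Merge bins into cross-cluster comparable segments
#'
#' Collapses runs of bins over which every cluster's integer copy-number
#' state is constant into single segments: breakpoints are the union, over
#' clusters, of positions where any cluster's state changes, plus chromosome
#' boundaries, so merging is maximal while every cluster remains constant
#' within every segment ("vertically comparable"). Segments whose state is
#' identical across all clusters are then dropped - they carry no
#' heterogeneity and cannot affect the phylogeny (beyond a shared offset
#' from the diploid root, which the tree does not model).
#'
#' @param profiles A `cluster_profiles` object (or list of `cluster_profile`
#'   on a shared genome) for >= 2 clusters.
#' @param genome The shared `binned_genome`; taken from `profiles` when
#'   bundled.
#' @return A `cn_segments` object: `segments` (data.frame chrom, start, end,
#'   length_bp), `states` (clusters x segments integer matrix, rownames =
#'   cluster labels), `cluster_labels`, plus the full `bin_states` matrix and
#'   `genome` retained for bin-level recomputations.
#' @export
merge_segments <- function(profiles, genome = attr(profiles, "genome")) {
  if (is.null(genome))
    stop("profiles carry no genome; pass 'genome' explicitly", call. = FALSE)
  stopifnot(inherits(genome, "binned_genome"))
  if (length(profiles) < 2L)
    stop("need at least two cluster profiles to merge", call. = FALSE)
  if (any(vapply(profiles, function(p) length(p$state_cn), integer(1)) !=
          genome$n_bins))
    stop("profiles and genome have mismatched bin counts", call. = FALSE)
  s <- profile_matrix(profiles, "state_cn")
  segment_bin_states(s, genome)
}

# Core segmentation over a clusters x bins integer state matrix.
segment_bin_states <- function(s, genome) {
  nb <- ncol(s)
  chrom <- genome$bins$chrom
  new_chrom <- c(TRUE, chrom[-1L] != chrom[-nb])
  changed <- c(TRUE, colSums(s[, -1L, drop = FALSE] !=
                               s[, -nb, drop = FALSE]) > 0)
  seg_id <- cumsum(new_chrom | changed)
  lens <- bin_lengths(genome)
  first <- match(unique(seg_id), seg_id)
  segs <- data.frame(
    chrom = chrom[first],
    start = genome$bins$start[first],
    end = as.numeric(tapply(genome$bins$end, seg_id, max)),
    length_bp = as.numeric(tapply(lens, seg_id, sum)),
    stringsAsFactors = FALSE)
  states <- s[, first, drop = FALSE]
  # drop segments invariant across all clusters
  keep <- apply(states, 2, function(col) length(unique(col)) > 1L)
  structure(list(segments = segs[keep, , drop = FALSE],
                 states = states[, keep, drop = FALSE],
                 cluster_labels = rownames(s),
                 bin_states = s,
                 bin_segment = seg_id,
                 retained = which(keep),
                 genome = genome),
            class = "cn_segments")
}

#' Construct a segment table directly
#'
#' For callers that already have segment coordinates and per-cluster states
#' (e.g. hand-built examples); bypasses bin-level merging.
#'
#' @param segments Data frame with columns chrom, start, end and optionally
#'   length_bp (default `end - start`).
#' @param states Integer matrix clusters x segments, rownames = labels.
#' @return A `cn_segments` object (without bin-level backing).
#' @export
cn_segments <- function(segments, states) {
  stopifnot(is.data.frame(segments),
            all(c("chrom", "start", "end") %in% names(segments)),
            nrow(segments) == ncol(states))
  if (is.null(segments$length_bp))
    segments$length_bp <- segments$end - segments$start
  if (is.null(rownames(states)))
    rownames(states) <- paste0("C", seq_len(nrow(states)))
  structure(list(segments = segments, states = states,
                 cluster_labels = rownames(states),
                 bin_states = NULL, bin_segment = NULL, retained = NULL,
                 genome = NULL),
            class = "cn_segments")
}

#' @export
print.cn_segments <- function(x, ...) {
  cat(sprintf("cn_segments: %d clusters x %d segments (%.1f Mb variable)\n",
              nrow(x$states), ncol(x$states), sum(x$segments$length_bp) / 1e6))
  invisible(x)
}

#' Write a segment table as BED-like TSV
#'
#' Columns chrom, start, end, length_bp, then one integer state column per
#' cluster.
#'
#' @param table A `cn_segments`.
#' @param path Output path.
#' @export
write_segments <- function(table, path) {
  stopifnot(inherits(table, "cn_segments"))
  df <- cbind(table$segments, as.data.frame(t(table$states)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
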