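# Shared fixtures and independent oracles for the test suite. Oracles are
# written as plain, loop-heavy recomputations so they share no code path
# with the package internals they check.

toy_genome <- function(bins_per_chrom = c(chr1 = 4L, chr2 = 3L),
                       bin_width = 1e6) {
  binned_genome(bins_per_chrom * bin_width, bin_width)
}

random_cell_matrix <- function(n_cells, genome, seed, integer = TRUE,
                               passage = "P0") {
  set.seed(seed)
  v <- matrix(sample(0:6, n_cells * genome$n_bins, TRUE),
              n_cells, genome$n_bins)
  if (!integer) v <- v + matrix(runif(length(v)), nrow(v))
  cell_cn_matrix(v, genome, passage = passage)
}

# random parsimony instance: n leaves x nseg segments, states 0..maxs,
# on a single-chromosome segment table with varying segment lengths
random_instance <- function(n, nseg = 10, maxs = 5, seed = 1) {
  set.seed(seed)
  lens <- sample(1:10, nseg, TRUE) * 1e6
  ends <- cumsum(lens)
  segs <- data.frame(chrom = "chr1", start = c(0, ends[-nseg]), end = ends)
  st <- matrix(sample(0:maxs, n * nseg, TRUE), n,
               dimnames = list(sprintf("L%02d", seq_len(n)), NULL))
  cn_segments(segs, st)
}

# Independent Sankoff dynamic program over one tree topology: per-segment
# explicit loops, no shared code with the package scorer. Returns the
# minimum total number of weighted changes with node 1 fixed at state 2.
oracle_sankoff <- function(tree, table, criterion = "unordered") {
  E <- tree$edges
  nseg <- nrow(table$segments)
  maxs <- max(table$states, 2L)
  sts <- 0:maxs
  w <- function(i, j) if (criterion == "unordered") as.numeric(i != j) else abs(i - j)
  kids_of <- function(v) E$child[E$parent == v]
  total <- 0
  for (seg in seq_len(nseg)) {
    cost_of <- function(v) {
      lab <- tree$labels[v]
      fixed <- if (v == 1L) 2L
      else if (lab %in% rownames(table$states)) table$states[lab, seg]
      else NA
      c0 <- if (is.na(fixed)) rep(0, length(sts)) else
        ifelse(sts == fixed, 0, Inf)
      for (k in kids_of(v)) {
        ck <- cost_of(k)
        add <- sapply(sts, function(s) min(sapply(sts, function(t)
          w(s, t) + ck[t + 1L])))
        c0 <- c0 + add
      }
      c0
    }
    total <- total + cost_of(1L)[3L]  # root state 2
  }
  total
}

# Changes implied by the tree's own node labeling (counted per edge per
# segment from the stored states), for comparison against the search score.
labeled_changes <- function(tree, criterion = "unordered") {
  E <- tree$edges
  tot <- 0
  for (r in seq_len(nrow(E))) {
    a <- tree$node_states[E$parent[r], ]
    b <- tree$node_states[E$child[r], ]
    tot <- tot + if (criterion == "unordered") sum(a != b) else sum(abs(a - b))
  }
  tot
}

# Newick with the diploid anchor as an explicit zero-distance tip, so that
# external tools score the tree under the diploid constraint.
newick_diploid_tip <- function(tr) {
  E <- tr$edges
  kids <- split(E$child, E$parent)
  elen <- function(v) E$length_mb[match(v, E$child)]
  fmt <- function(v) {
    ks <- kids[[as.character(v)]]
    if (is.null(ks)) return(tr$labels[v])
    paste0("(", paste(vapply(ks, function(k)
      paste0(fmt(k), ":", elen(k)), character(1)), collapse = ","), ")")
  }
  top <- kids[["1"]][1]
  inner <- sub("\\)$", paste0(",diploid:", elen(top), ")"), fmt(top))
  paste0(inner, ";")
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# unrooted leaf bipartitions induced by a cn_tree's internal edges,
# each side sorted, smaller side first (canonical)
tree_splits <- function(tree) {
  E <- tree$edges
  leaves <- tree$labels[tree$is_leaf]
  below <- function(v) {
    ks <- E$child[E$parent == v]
    if (length(ks) == 0L) return(tree$labels[v])
    unlist(lapply(ks, below))
  }
  sp <- lapply(E$child[!E$child %in% which(tree$is_leaf)], function(v) {
    a <- sort(intersect(below(v), leaves))
    b <- sort(setdiff(leaves, a))
    if (length(a) == 0 || length(b) == 0) return(NULL)
    if (paste(a, collapse = ",") < paste(b, collapse = ",")) list(a, b) else list(b, a)
  })
  unique(Filter(Negate(is.null), sp))
}
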