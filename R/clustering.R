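#' Embed cells in two dimensions with t-SNE
#'
#' Runs Barnes-Hut t-SNE on the per-cell copy-number vectors (Euclidean
#' metric). Deterministic for a fixed seed; requires more than
#' `3 * perplexity` cells, the usual heuristic guard. A degenerate input in
#' which every cell is identical yields the all-zero embedding rather than
#' an error.
#'
#' @param matrix A `cell_cn_matrix`.
#' @param perplexity t-SNE perplexity (default 30).
#' @param seed Integer random seed (default 42).
#' @param ... Further arguments passed to [Rtsne::Rtsne()].
#' @return Numeric matrix, cells x 2, rownames = cell ids.
#' @export
embed_tsne <- function(matrix, perplexity = 30, seed = 42, ...) {
  stopifnot(inherits(matrix, "cell_cn_matrix"))
  n <- nrow(matrix$values)
  if (n <= 3 * perplexity)
    stop(sprintf(paste("too few cells (%d) for perplexity %g; need more than",
                       "3*perplexity cells - lower 'perplexity' or add cells"),
                 n, perplexity), call. = FALSE)
  x <- matrix$values
  if (all(x == rep(x[1L, ], each = n))) {
    emb <- base::matrix(0, n, 2)
    rownames(emb) <- matrix$cell_ids
    return(emb)
  }
  set.seed(seed)
  fit <- Rtsne::Rtsne(x, dims = 2, perplexity = perplexity,
                      check_duplicates = FALSE, pca = FALSE,
                      num_threads = 1, ...)
  emb <- fit$Y
  rownames(emb) <- matrix$cell_ids
  colnames(emb) <- c("tsne1", "tsne2")
  emb
}

# Normalized graph Laplacian spectrum of a Gaussian-kernel affinity.
# sigma defaults to the median pairwise distance (median heuristic).
laplacian_spectrum <- function(x, sigma = NULL) {
  d <- as.matrix(stats::dist(x))
  if (is.null(sigma)) {
    sigma <- stats::median(d[upper.tri(d)])
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  w <- exp(-d^2 / (2 * sigma^2))
  diag(w) <- 0
  deg <- rowSums(w)
  deg[deg == 0] <- 1
  s <- 1 / sqrt(deg)
  lsym <- diag(nrow(w)) - (s * w) * rep(s, each = nrow(w))
  eig <- eigen(lsym, symmetric = TRUE)
  # ascending eigenvalues, matching eigenvector columns
  ord <- order(eig$values)
  list(values = eig$values[ord], vectors = eig$vectors[, ord, drop = FALSE])
}

#' Partition cells by spectral clustering
#'
#' Standard normalized spectral clustering (Ng-Jordan-Weiss): Gaussian
#' affinity with median-distance bandwidth, symmetric normalized Laplacian,
#' row-normalized eigenvector embedding, k-means. By default it runs on a
#' 2-D t-SNE embedding of the cells (`on = "embedding"`); `on = "matrix"`
#' clusters the raw copy-number vectors instead. When `k` is omitted it is
#' chosen by the eigengap heuristic: the `k` in `k_range` maximizing the gap
#' between consecutive Laplacian eigenvalues.
#'
#' @param matrix A `cell_cn_matrix`.
#' @param k Number of clusters; `NULL` (default) selects k by eigengap.
#' @param seed Integer seed for t-SNE and k-means.
#' @param on `"embedding"` (default) or `"matrix"`.
#' @param perplexity t-SNE perplexity when `on = "embedding"`.
#' @param k_range Candidate k values for the eigengap heuristic.
#' @param embedding Optional precomputed cells x 2 embedding (skips t-SNE).
#' @return A `cn_clusters` object with per-cell `assignments` (contiguous
#'   labels `1..k`, ordered by first appearance), `k`, the 2-D `embedding`
#'   (if used), the Laplacian `eigenvalues` and the `seed`.
#' @export
spectral_cluster <- function(matrix, k = NULL, seed = 42,
                             on = c("embedding", "matrix"),
                             perplexity = 30, k_range = 2:12,
                             embedding = NULL) {
  stopifnot(inherits(matrix, "cell_cn_matrix"))
  on <- match.arg(on)
  n <- nrow(matrix$values)
  if (!is.null(k)) {
    if (k < 1 || k > n)
      stop(sprintf("k = %d must be between 1 and the number of cells (%d)",
                   k, n), call. = FALSE)
  }
  if (on == "embedding" && is.null(embedding))
    embedding <- embed_tsne(matrix, perplexity = perplexity, seed = seed)
  x <- if (on == "embedding") embedding else matrix$values

  if (!is.null(k) && k == 1L) {
    assignments <- rep(1L, n)
    eigenvalues <- NULL
  } else {
    sp <- laplacian_spectrum(x)
    eigenvalues <- sp$values
    if (is.null(k)) {
      kr <- k_range[k_range >= 2 & k_range < n]
      gaps <- sp$values[kr + 1L] - sp$values[kr]
      k <- kr[which.max(gaps)]
    }
    v <- sp$vectors[, seq_len(k), drop = FALSE]
    norms <- sqrt(rowSums(v^2))
    norms[norms == 0] <- 1
    v <- v / norms
    set.seed(seed)
    km <- stats::kmeans(v, centers = k, nstart = 10, iter.max = 100)
    assignments <- km$cluster
  }
  # deterministic contiguous labels: number clusters by first appearance
  first <- match(unique(assignments), assignments)
  relab <- match(assignments, assignments[sort(first)])
  structure(list(assignments = as.integer(relab), k = as.integer(k),
                 embedding = embedding, cell_ids = matrix$cell_ids,
                 passage = matrix$passage, eigenvalues = eigenvalues,
                 seed = seed),
            class = "cn_clusters")
}

#' @export
print.cn_clusters <- function(x, ...) {
  cat(sprintf("cn_clusters: %d cells in %d clusters (passage %s)\n",
              length(x$assignments), x$k, x$passage))
  print(table(cluster = x$assignments))
  invisible(x)
}

#' @export
summary.cn_clusters <- function(object, ...) {
  sizes <- as.integer(table(object$assignments))
  data.frame(cluster = seq_len(object$k), cells = sizes,
             percent = vapply(seq_len(object$k),
                              function(i) proportion_of(object, i), numeric(1)))
}

#' @export
plot.cn_clusters <- function(x, ...) {
  if (is.null(x$embedding))
    stop("no embedding stored; cluster with on = 'embedding'", call. = FALSE)
  graphics::plot(x$embedding, col = x$assignments, pch = 19,
                 xlab = "t-SNE 1", ylab = "t-SNE 2",
                 main = sprintf("%d clusters (%s)", x$k, x$passage), ...)
  invisible(x)
}

#' Per-cluster averaged copy-number profiles
#'
#' For each cluster: the per-bin mean copy number over member cells, the
#' integer state vector obtained by half-up rounding of the mean, the cell
#' count and the estimated chromosome number.
#'
#' @param matrix A `cell_cn_matrix`.
#' @param clusters A matching `cn_clusters` object.
#' @return A `cluster_profiles` object: a list of `cluster_profile` entries
#'   (fields `cluster_id`, `label`, `cell_count`, `mean_cn`, `state_cn`,
#'   `chromosome_estimate`, `passage`) with the shared `genome` attached.
#' @export
make_cluster_profiles <- function(matrix, clusters) {
  stopifnot(inherits(matrix, "cell_cn_matrix"), inherits(clusters, "cn_clusters"))
  if (!identical(matrix$cell_ids, clusters$cell_ids))
    stop("matrix and clusters refer to different cells", call. = FALSE)
  profs <- lapply(seq_len(clusters$k), function(i) {
    members <- matrix$cell_ids[clusters$assignments == i]
    m <- average_profile(matrix, members)
    structure(list(cluster_id = i,
                   label = sprintf("%s_C%d", matrix$passage, i),
                   cell_count = length(members),
                   mean_cn = m,
                   state_cn = round_half_up(m),
                   chromosome_estimate = estimate_chromosome_number(m, matrix$genome),
                   passage = matrix$passage),
              class = "cluster_profile")
  })
  structure(profs, genome = matrix$genome, class = "cluster_profiles")
}

#' Construct a cluster profile directly from a state vector
#'
#' Convenience constructor used when profiles come from a simulator or an
#' external caller rather than from [make_cluster_profiles()].
#'
#' @param state_cn Integer per-bin copy-number vector.
#' @param genome A `binned_genome`.
#' @param label Cluster label.
#' @param cell_count Number of member cells.
#' @param passage Passage label.
#' @param mean_cn Optional real-valued mean profile (defaults to `state_cn`).
#' @return A `cluster_profile`.
#' @export
cluster_profile <- function(state_cn, genome, label, cell_count = 1L,
                            passage = "P0", mean_cn = NULL) {
  stopifnot(inherits(genome, "binned_genome"),
            length(state_cn) == genome$n_bins, all(state_cn >= 0))
  if (is.null(mean_cn)) mean_cn <- as.numeric(state_cn)
  structure(list(cluster_id = NA_integer_, label = label,
                 cell_count = as.integer(cell_count),
                 mean_cn = stats::setNames(as.numeric(mean_cn), bin_names(genome)),
                 state_cn = stats::setNames(as.integer(round_half_up(state_cn)),
                                            bin_names(genome)),
                 chromosome_estimate = estimate_chromosome_number(mean_cn, genome),
                 passage = passage),
            class = "cluster_profile")
}

#' Bundle cluster profiles that share a genome
#' @param profiles List of `cluster_profile` objects.
#' @param genome The shared `binned_genome`.
#' @return A `cluster_profiles` object.
#' @export
cluster_profiles <- function(profiles, genome) {
  stopifnot(all(vapply(profiles, inherits, logical(1), "cluster_profile")))
  structure(profiles, genome = genome, class = "cluster_profiles")
}

#' @export
print.cluster_profiles <- function(x, ...) {
  cat(sprintf("cluster_profiles: %d clusters\n", length(x)))
  for (p in x)
    cat(sprintf("  %-12s %5d cells  chr estimate %.1f\n",
                p$label, p$cell_count, p$chromosome_estimate))
  invisible(x)
}

# Extract a clusters x bins matrix of a given field from profiles
profile_matrix <- function(profiles, field = "state_cn") {
  m <- do.call(rbind, lapply(profiles, `[[`, field))
  rownames(m) <- vapply(profiles, `[[`, character(1), "label")
  m
}

#' Canberra distance matrix between profiles
#'
#' `d(x, y) = sum_i |x_i - y_i| / (|x_i| + |y_i|)` over bins, with terms
#' whose numerator and denominator are both zero contributing 0 (no
#' rescaling of the sum).
#'
#' @param m Numeric matrix, one row per profile.
#' @return A `dist` object.
#' @export
canberra_dist <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
    num <- abs(m[i, ] - m[j, ])
    den <- abs(m[i, ]) + abs(m[j, ])
    term <- ifelse(den == 0, 0, num / den)
    d[i, j] <- d[j, i] <- sum(term)
  }
  stats::as.dist(d)
}

#' Hierarchical clustering cross-check of cluster profiles
#'
#' Agglomerates the cluster-averaged profiles by Canberra distance with
#' complete linkage - an independent view of cluster relatedness used to
#' corroborate the phylogeny.
#'
#' @param profiles A `cluster_profiles` object (>= 2 profiles).
#' @param field Which per-bin track to compare: `"mean_cn"` (default) or
#'   `"state_cn"`.
#' @param linkage Agglomeration method for [stats::hclust()].
#' @return A `linkage_result`: list with `labels`, `merge_history`
#'   (data.frame left, right, height), `distance_metric`, and the underlying
#'   `hclust` object.
#' @export
hierarchical_check <- function(profiles, field = c("mean_cn", "state_cn"),
                               linkage = "complete") {
  field <- match.arg(field)
  if (length(profiles) < 2L)
    stop("need at least two profiles to cluster", call. = FALSE)
  m <- profile_matrix(profiles, field)
  hc <- stats::hclust(canberra_dist(m), method = linkage)
  structure(list(labels = rownames(m),
                 merge_history = data.frame(left = hc$merge[, 1],
                                            right = hc$merge[, 2],
                                            height = hc$height),
                 distance_metric = "canberra",
                 hclust = hc),
            class = "linkage_result")
}

#' @export
print.linkage_result <- function(x, ...) {
  cat(sprintf("linkage_result: %d profiles, %s distance, heights %.3g..%.3g\n",
              length(x$labels), x$distance_metric,
              min(x$merge_history$height), max(x$merge_history$height)))
  invisible(x)
}

#' @export
plot.linkage_result <- function(x, ...) {
  graphics::plot(x$hclust, xlab = "", sub = "",
                 main = "Canberra hierarchical clustering", ...)
  invisible(x)
}
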