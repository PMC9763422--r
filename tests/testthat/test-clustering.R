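# three clones separated by distinct whole-chromosome events
three_clone_pop <- function(noise = 0.02, n = c(240L, 240L), seed = 11) {
  c1 <- clone_spec("c1", data.frame(chrom = "chr1", start_bin = 1L,
                                    end_bin = 50L, delta = 1L))
  c2 <- clone_spec("c2", data.frame(chrom = "chr2", start_bin = 1L,
                                    end_bin = 44L, delta = 1L))
  c3 <- clone_spec("c3", data.frame(chrom = "chr3", start_bin = 1L,
                                    end_bin = 36L, delta = -1L))
  population_spec(list(c1, c2, c3),
                  proportions_early = c(c1 = 1/3, c2 = 1/3, c3 = 1/3),
                  proportions_late = c(c1 = 0.2, c2 = 0.2, c3 = 0.6),
                  n_cells = n, noise_rate = noise, seed = seed)
}

test_that("t-SNE embedding is deterministic, finite, and guards perplexity", {
  g <- demo_genome()
  sim <- sample_cells(three_clone_pop(n = c(150L, 150L)), g)
  e1 <- embed_tsne(sim$early, perplexity = 20, seed = 42)
  e2 <- embed_tsne(sim$early, perplexity = 20, seed = 42)
  expect_identical(e1, e2)
  expect_true(all(is.finite(e1)))
  expect_error(embed_tsne(sim$early, perplexity = 60), "perplexity")
})

test_that("identical cells embed to finite coordinates", {
  g <- toy_genome(c(chr1 = 10L))
  m <- cell_cn_matrix(matrix(2, 40, 10), g)
  e <- embed_tsne(m, perplexity = 5)
  expect_true(all(is.finite(e)))
})

test_that("well-separated clones land in separated embedding blobs", {
  g <- demo_genome()
  # two clones differing by +2 copies over half the genome
  a <- clone_spec("a")
  b <- clone_spec("b", data.frame(chrom = c("chr1", "chr2", "chr3"),
                                  start_bin = 1L, end_bin = c(50L, 44L, 8L),
                                  delta = 2L))
  pop <- population_spec(list(a, b), c(a = .5, b = .5), c(a = .5, b = .5),
                         n_cells = c(200L, 2L), noise_rate = 0, seed = 3)
  sim <- sample_cells(pop, g)
  emb <- embed_tsne(sim$early, seed = 42)
  lab <- sim$truth$clone_id[sim$truth$passage == "early"]
  cent <- rbind(colMeans(emb[lab == "a", ]), colMeans(emb[lab == "b", ]))
  inter <- sqrt(sum((cent[1, ] - cent[2, ])^2))
  radius <- function(cl) {
    d <- sqrt(rowSums((emb[lab == cl, ] -
                         rep(cent[(cl == "b") + 1, ],
                             each = sum(lab == cl)))^2))
    quantile(d, 0.95)
  }
  expect_gt(inter, max(radius("a"), radius("b")))
})

test_that("spectral clustering recovers three clones (ARI >= 0.9) and picks k by eigengap", {
  g <- demo_genome()
  sim <- sample_cells(three_clone_pop(), g)
  truth <- sim$truth$clone_id[sim$truth$passage == "early"]

  cl_fixed <- spectral_cluster(sim$early, k = 3, seed = 42)
  expect_gte(ari(cl_fixed$assignments, truth), 0.9)

  cl_auto <- spectral_cluster(sim$early, seed = 42)
  expect_equal(cl_auto$k, 3L)
  expect_gte(ari(cl_auto$assignments, truth), 0.9)

  # labels are contiguous 1..k and cover all cells
  expect_setequal(unique(cl_auto$assignments), seq_len(cl_auto$k))
  expect_length(cl_auto$assignments, nrow(sim$early$values))
})

test_that("k = 1 and out-of-range k behave as documented", {
  g <- toy_genome()
  m <- random_cell_matrix(12, g, seed = 6)
  cl <- spectral_cluster(m, k = 1, seed = 1, on = "matrix")
  expect_equal(cl$assignments, rep(1L, 12))
  expect_error(spectral_cluster(m, k = 13, seed = 1), "between 1 and")
})

test_that("duplicating every cell leaves the partition structure unchanged", {
  g <- demo_genome()
  sim <- sample_cells(three_clone_pop(noise = 0, n = c(90L, 2L), seed = 5), g)
  m <- sim$early
  dup <- cell_cn_matrix(rbind(m$values, m$values), g,
                        cell_ids = c(m$cell_ids, paste0(m$cell_ids, "_d")))
  cl1 <- spectral_cluster(m, k = 3, seed = 42, on = "matrix")
  cl2 <- spectral_cluster(dup, k = 3, seed = 42, on = "matrix")
  n <- length(cl1$assignments)
  expect_equal(ari(cl2$assignments[1:n], cl2$assignments[(n + 1):(2 * n)]), 1)
  expect_equal(ari(cl1$assignments, cl2$assignments[1:n]), 1)
})

test_that("cluster proportions sum to 100 within rounding", {
  g <- demo_genome()
  sim <- sample_cells(three_clone_pop(), g)
  cl <- spectral_cluster(sim$early, k = 3, seed = 42)
  tot <- sum(vapply(seq_len(cl$k), function(i) proportion_of(cl, i), numeric(1)))
  expect_lt(abs(tot - 100), 0.1 * cl$k)
})

test_that("cluster profiles average members and round half-up to states", {
  g <- binned_genome(c(chr1 = 2e6), 1e6)
  m <- cell_cn_matrix(rbind(c(2, 2), c(3, 3)), g, c("a", "b"))
  cl <- structure(list(assignments = c(1L, 1L), k = 1L, embedding = NULL,
                       cell_ids = c("a", "b"), passage = "P0",
                       eigenvalues = NULL, seed = 1),
                  class = "cn_clusters")
  p <- make_cluster_profiles(m, cl)
  expect_equal(unname(p[[1]]$mean_cn), c(2.5, 2.5))
  expect_equal(unname(p[[1]]$state_cn), c(3L, 3L))  # half-up
  expect_equal(p[[1]]$cell_count, 2L)
})

test_that("state profiles recover clone truth on >= 99% of bins at 5% noise", {
  g <- demo_genome()
  pop <- three_clone_pop(noise = 0.05, n = c(600L, 2L), seed = 9)
  sim <- sample_cells(pop, g)
  truth_lab <- sim$truth$clone_id[sim$truth$passage == "early"]
  cl <- spectral_cluster(sim$early, k = 3, seed = 42)
  profs <- make_cluster_profiles(sim$early, cl)
  for (i in seq_len(3)) {
    clone <- names(which.max(table(truth_lab[cl$assignments == i])))
    agree <- mean(profs[[i]]$state_cn == sim$profiles[clone, ])
    expect_gte(agree, 0.99)
  }
})

test_that("Canberra distances match the formula and drive the linkage", {
  p1 <- cluster_profile(c(1L, 0L), binned_genome(c(chr1 = 2e6), 1e6), "p1")
  p2 <- cluster_profile(c(0L, 1L), binned_genome(c(chr1 = 2e6), 1e6), "p2")
  d <- canberra_dist(rbind(a = c(1, 0), b = c(0, 1)))
  expect_equal(as.numeric(d), 2.0)
  # both-zero terms contribute 0
  expect_equal(as.numeric(canberra_dist(rbind(c(0, 1), c(0, 2)))), 1 / 3)

  g <- toy_genome(c(chr1 = 12L))
  set.seed(7)
  profs <- cluster_profiles(lapply(1:5, function(i)
    cluster_profile(sample(0:5, 12, TRUE), g, paste0("c", i))), g)
  lr <- hierarchical_check(profs, field = "state_cn")
  m <- do.call(rbind, lapply(profs, function(p) as.numeric(p$state_cn)))
  brute <- matrix(0, 5, 5)
  for (i in 1:5) for (j in 1:5) {
    s <- 0
    for (b in 1:12) {
      den <- abs(m[i, b]) + abs(m[j, b])
      if (den > 0) s <- s + abs(m[i, b] - m[j, b]) / den
    }
    brute[i, j] <- s
  }
  got <- as.matrix(canberra_dist(m))
  expect_lt(max(abs(got - brute)), 1e-12)
  expect_error(hierarchical_check(profs[1]), "at least two")
})

test_that("identical profiles merge first at height zero", {
  g <- toy_genome(c(chr1 = 6L))
  profs <- cluster_profiles(list(
    cluster_profile(rep(3L, 6), g, "a"),
    cluster_profile(rep(3L, 6), g, "b"),
    cluster_profile(c(2L, 2L, 2L, 4L, 4L, 4L), g, "c")), g)
  lr <- hierarchical_check(profs)
  expect_equal(lr$merge_history$height[1], 0)
  # leaves a (1) and b (2) merge first
  expect_setequal(c(-lr$merge_history$left[1], -lr$merge_history$right[1]),
                  c(1, 2))
})

test_that("closest pair agrees between Canberra linkage and Mb metric on clean clones", {
  g <- demo_genome()
  profiles <- realize_clone_profiles(four_leaf_clones(g), g)
  leaves <- c("A", "B", "C", "D")
  profs <- cluster_profiles(lapply(leaves, function(l)
    cluster_profile(profiles[l, ], g, l)), g)
  tab <- merge_segments(profs)
  m <- do.call(rbind, lapply(profs, function(p) as.numeric(p$mean_cn)))
  cd <- as.matrix(canberra_dist(m))
  dimnames(cd) <- list(leaves, leaves)
  md <- matrix(0, 4, 4, dimnames = list(leaves, leaves))
  for (i in leaves) for (j in leaves)
    md[i, j] <- edge_length_mb(tab$states[i, ], tab$states[j, ], tab)
  diag(cd) <- diag(md) <- Inf
  expect_equal(which(cd == min(cd), arr.ind = TRUE)[1, ],
               which(md == min(md), arr.ind = TRUE)[1, ])
})
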