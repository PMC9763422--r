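test_that("a single aberrant leaf hangs off the diploid root at the segment length", {
  tab <- cn_segments(data.frame(chrom = "chr1", start = 0, end = 5e6),
                     matrix(3L, 1, 1, dimnames = list("L1", NULL)))
  tr <- parsimony_tree(tab)
  expect_equal(tr$score, 1L)
  expect_equal(nrow(tr$edges), 1L)
  expect_equal(tr$edges$length_mb, 5.0)
  expect_equal(root_distance(tr, "L1"), 5.0)
})

test_that("the three-leaf worked example pairs the two gain-sharing leaves", {
  segs <- data.frame(chrom = "chr1", start = c(0, 1e6), end = c(1e6, 2e6))
  st <- rbind(L1 = c(3L, 2L), L2 = c(3L, 4L), L3 = c(2L, 2L))
  tab <- cn_segments(segs, st)
  tr <- parsimony_tree(tab)
  # unordered optimum: one 2->3 change (segment 1, shared by L1 and L2)
  # plus one 2->4 change (segment 2, L2's terminal edge)
  expect_equal(tr$score, 2L)
  # ordered (Wagner) charges |2 - 4| = 2 for the second segment
  expect_equal(parsimony_tree(tab, criterion = "wagner")$score, 3)
  # both search modes and the independent DP agree
  expect_identical(parsimony_tree(tab, method = "branchbound")$score, 2L)
  expect_equal(oracle_sankoff(tr, tab), 2)
  # L1 and L2 are sisters: the tree has a split {L1,L2} | {L3}
  sp <- tree_splits(tr)
  expect_true(any(sapply(sp, function(s) identical(s[[1]], c("L1", "L2")))))
  # the L1-L2 ancestor carries the minimum-change state (3, 2)
  parent_l1 <- tr$edges$parent[tr$edges$child == which(tr$labels == "L1")]
  expect_equal(unname(tr$node_states[parent_l1, ]), c(3L, 2L))
})

test_that("branch-and-bound equals exhaustive search on random instances", {
  for (seed in 1:8) {
    n <- 4 + seed %% 3
    tab <- random_instance(n, nseg = 10, maxs = 5, seed = seed)
    ex <- parsimony_tree(tab, method = "exhaustive")
    bb <- parsimony_tree(tab, method = "branchbound")
    expect_identical(bb$score, ex$score)
    expect_identical(write_newick(bb), write_newick(ex))
  }
})

test_that("search score matches the independent Sankoff DP and the labeling", {
  for (seed in 1:5) {
    tab <- random_instance(5, nseg = 8, maxs = 4, seed = 100 + seed)
    tr <- parsimony_tree(tab, method = "branchbound")
    expect_equal(labeled_changes(tr), tr$score)
    expect_equal(oracle_sankoff(tr, tab), tr$score)
  }
})

test_that("the optimum matches phangorn's exact score over all topologies", {
  skip_if_not_installed("phangorn")
  for (seed in 1:3) {
    tab <- random_instance(5, nseg = 8, maxs = 5, seed = 200 + seed)
    tr <- parsimony_tree(tab, method = "exhaustive")
    states <- rbind(diploid = rep(2L, 8), tab$states)
    m <- matrix(as.character(states), nrow(states), dimnames = dimnames(states))
    pd <- phangorn::phyDat(m, type = "USER", levels = as.character(0:5))
    cost <- 1 - diag(6)
    dimnames(cost) <- list(as.character(0:5), as.character(0:5))
    phy <- ape::read.tree(text = newick_diploid_tip(tr))
    expect_equal(phangorn::parsimony(phy, pd, method = "sankoff", cost = cost),
                 tr$score)
    allt <- phangorn::allTrees(6, tip.label = rownames(states))
    opt <- min(sapply(allt, function(t)
      phangorn::parsimony(t, pd, method = "sankoff", cost = cost)))
    expect_equal(opt, tr$score)
  }
})

test_that("the Wagner criterion charges copy-number magnitude", {
  tab <- cn_segments(data.frame(chrom = "chr1", start = 0, end = 5e6),
                     matrix(5L, 1, 1, dimnames = list("L1", NULL)))
  expect_equal(parsimony_tree(tab)$score, 1L)                      # one change
  expect_equal(parsimony_tree(tab, criterion = "wagner")$score, 3) # |5 - 2|
  # ordered cost dominates unordered on any instance
  tab2 <- random_instance(4, nseg = 6, maxs = 5, seed = 17)
  expect_gte(parsimony_tree(tab2, criterion = "wagner")$score,
             parsimony_tree(tab2)$score)
})

test_that("ties in topology and labeling resolve deterministically", {
  # two leaves equidistant from the root: any labeling order must reproduce
  segs <- data.frame(chrom = "chr1", start = c(0, 2e6), end = c(2e6, 4e6))
  st <- rbind(La = c(3L, 2L), Lb = c(2L, 3L))
  tab <- cn_segments(segs, st)
  t1 <- parsimony_tree(tab)
  t2 <- parsimony_tree(tab)
  expect_identical(write_newick(t1), write_newick(t2))
  expect_identical(t1$node_states, t2$node_states)
})

test_that("edge lengths follow the differing-segment megabase formula", {
  tab <- random_instance(3, nseg = 7, maxs = 4, seed = 5)
  u <- tab$states[1, ]; v <- tab$states[2, ]
  expect_equal(edge_length_mb(u, u, tab), 0)
  brute <- 0
  for (k in seq_len(7))
    if (u[k] != v[k]) brute <- brute + tab$segments$length_bp[k]
  expect_equal(edge_length_mb(u, v, tab), brute / 1e6)
  expect_equal(edge_length_mb(u, v, tab), edge_length_mb(v, u, tab))
  expect_error(edge_length_mb(u, v[-1], tab), "length")

  tab1 <- cn_segments(data.frame(chrom = "chr1", start = 0, end = 2.5e6),
                      matrix(c(2L, 3L), 2, 1, dimnames = list(c("a", "b"), NULL)))
  expect_equal(edge_length_mb(tab1$states[1, ], tab1$states[2, ], tab1), 2.5)
})

test_that("root distances accumulate along the path", {
  tab <- random_instance(6, nseg = 10, maxs = 4, seed = 31)
  tr <- parsimony_tree(tab)
  expect_equal(root_distance(tr, 1L), 0)
  # independent traversal: walk up via the edge table
  for (lab in rownames(tab$states)) {
    v <- which(tr$labels == lab)
    d <- 0
    repeat {
      r <- which(tr$edges$child == v)
      if (length(r) == 0) break
      d <- d + tr$edges$length_mb[r]
      v <- tr$edges$parent[r]
    }
    expect_equal(root_distance(tr, lab), d)
  }
})

test_that("a late cluster identical to an early leaf attaches there at distance 0", {
  g <- demo_genome()
  profiles <- realize_clone_profiles(four_leaf_clones(g), g)
  leaves <- c("A", "B", "C", "D")
  early <- cluster_profiles(lapply(leaves, function(l)
    cluster_profile(profiles[l, ], g, l, passage = "P3")), g)
  tab <- merge_segments(early)
  tr <- parsimony_tree(tab)
  late <- cluster_profiles(list(
    cluster_profile(profiles["A", ], g, "late1", passage = "P14")), g)
  tr2 <- attach_late_clusters(tr, late)
  lg <- tr2$attachment_log$pairs
  expect_equal(lg$host, "A")
  expect_equal(lg$distance_mb, 0)
  expect_equal(root_distance(tr2, "late1"), root_distance(tr2, "A"))
})

test_that("attachment is greedy: a late cluster waits for its closer late kin", {
  g <- demo_genome()
  clones <- four_leaf_clones(g)
  # late1 = leaf A plus a small extra event; late2 = late1 plus a tiny event,
  # so late2 is far closer to late1 than to any early leaf
  nb <- table(factor(g$bins$chrom, levels = g$chrom_order))
  late1 <- clone_spec("late1", parent_id = "A", events = data.frame(
    chrom = "chr4", start_bin = 1L, end_bin = 4L, delta = 1L))
  late2 <- clone_spec("late2", parent_id = "late1", events = data.frame(
    chrom = "chr5", start_bin = 1L, end_bin = 1L, delta = 1L))
  profiles <- realize_clone_profiles(c(clones, list(late1, late2)), g)
  leaves <- c("A", "B", "C", "D")
  early <- cluster_profiles(lapply(leaves, function(l)
    cluster_profile(profiles[l, ], g, l)), g)
  tr <- parsimony_tree(merge_segments(early))
  late <- cluster_profiles(lapply(c("late1", "late2"), function(l)
    cluster_profile(profiles[l, ], g, l)), g)
  tr2 <- attach_late_clusters(tr, late)
  lg <- tr2$attachment_log$pairs
  expect_equal(lg$attached, c("late1", "late2"))
  expect_equal(lg$host, c("A", "late1"))
  # brute-force pairwise distances confirm each recorded minimum
  w <- bin_lengths(g)
  d <- function(a, b) sum(w[profiles[a, ] != profiles[b, ]]) / 1e6
  expect_equal(lg$distance_mb[1], min(sapply(leaves, d, a = "late1"),
                                      sapply(leaves, d, a = "late2")))
  expect_equal(lg$distance_mb[2], d("late2", "late1"))
  # early topology, states and score untouched
  expect_identical(tr2$edges[seq_len(nrow(tr$edges)), ], tr$edges)
  expect_identical(tr2$node_states[seq_len(nrow(tr$node_states)), ],
                   tr$node_states)
  expect_identical(tr2$score, tr$score)
})

test_that("attachment distance ties break deterministically and reproducibly", {
  segs <- data.frame(chrom = "chr1", start = c(0, 1e6), end = c(1e6, 2e6))
  st <- rbind(E1 = c(3L, 2L), E2 = c(2L, 3L))
  tab <- cn_segments(segs, st)
  tr <- parsimony_tree(tab)
  # both late clusters tie at distance 1 Mb to both early leaves
  late <- rbind(X1 = c(2L, 2L), X2 = c(3L, 3L))
  r1 <- attach_late_clusters(tr, late)
  r2 <- attach_late_clusters(tr, late)
  expect_identical(r1$attachment_log$pairs, r2$attachment_log$pairs)
  expect_equal(r1$attachment_log$pairs$attached[1], "X1")
  expect_equal(r1$attachment_log$pairs$host[1], "E1")
})

test_that("newick output round-trips through an external parser", {
  # degenerate root-only variants
  tab <- cn_segments(data.frame(chrom = "c", start = 0, end = 1e6),
                     matrix(3L, 1, 1, dimnames = list("solo", NULL)))
  tr1 <- parsimony_tree(tab)
  expect_match(write_newick(tr1), "^\\(solo:1\\)diploid;$")

  for (seed in 1:10) {
    n <- 3 + seed %% 4
    tab <- random_instance(n, nseg = 8, maxs = 4, seed = 300 + seed)
    tr <- parsimony_tree(tab, method = "branchbound")
    phy <- ape::read.tree(text = write_newick(tr))
    expect_setequal(phy$tip.label, rownames(tab$states))
    # root-to-tip distances survive the round trip
    depths <- ape::node.depth.edgelength(phy)
    for (lab in rownames(tab$states)) {
      got <- depths[match(lab, phy$tip.label)]
      expect_equal(got, root_distance(tr, lab), tolerance = 1e-9)
    }
  }
})

test_that("trees with more than twelve leaves are refused", {
  tab <- random_instance(13, nseg = 4, maxs = 3, seed = 1)
  expect_error(parsimony_tree(tab), "12")
})
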