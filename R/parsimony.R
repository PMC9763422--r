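# Maximum-parsimony phylogeny over per-segment copy-number states.
#
# Internal tree representation during search: an edge matrix (parent, child)
# over node ids; node 1 is the fixed diploid anchor (state 2 on every
# segment), nodes 2..n+1 are the early-passage cluster leaves in canonical
# (sorted-label) order, higher ids are internal nodes created by stepwise
# insertion. The diploid anchor has exactly one child; every internal node
# is binary. The search space of rooted binary trees over n leaves is
# enumerated by inserting leaf k into any edge of the partial tree, giving
# the usual (2n-3)!! topologies.

children_map <- function(E, nnode) {
  kids <- vector("list", nnode)
  for (r in seq_len(nrow(E))) {
    p <- E[r, 1L]
    kids[[p]] <- c(kids[[p]], E[r, 2L])
  }
  kids
}

# Fitch (unordered-state) parsimony score with states encoded as bitmasks.
# taxa_masks: (n_taxa x nseg) integer matrix, row v = bitmask of node v's
# fixed state (row 1 = diploid). Internal nodes carry no own mask.
fitch_score <- function(E, taxa_masks) {
  n_taxa <- nrow(taxa_masks)
  kids <- children_map(E, max(E))
  changes <- 0L
  rec <- function(v) {
    ks <- kids[[v]]
    s <- if (v <= n_taxa) taxa_masks[v, ] else rec(ks[[1L]])
    rest <- if (v <= n_taxa) ks else ks[-1L]
    for (k in rest) {
      t <- rec(k)
      i <- bitwAnd(s, t)
      z <- i == 0L
      if (any(z)) {
        i[z] <- bitwOr(s, t)[z]
        changes <<- changes + sum(z)
      }
      s <- i
    }
    s
  }
  rec(1L)
  changes
}

# Sankoff DP over explicit states with an arbitrary cost matrix W
# (n_states x n_states, state s at row/column s+1). taxa_states:
# n_taxa x nseg integer matrix (row 1 = diploid, all 2).
# Returns total minimum cost with the root fixed at state 2.
sankoff_cost_matrices <- function(E, taxa_states, W) {
  n_taxa <- nrow(taxa_states)
  nseg <- ncol(taxa_states)
  n_states <- nrow(W)
  kids <- children_map(E, max(E))
  C <- vector("list", max(E))
  minc <- function(M) {
    # row i of result: min_j W[i,j] + M[j,]
    out <- matrix(0, n_states, nseg)
    for (i in seq_len(n_states))
      out[i, ] <- do.call(pmin, lapply(seq_len(n_states),
                                       function(j) W[i, j] + M[j, ]))
    out
  }
  rec <- function(v) {
    own <- matrix(0, n_states, nseg)
    if (v <= n_taxa) {
      own[] <- Inf
      own[cbind(taxa_states[v, ] + 1L, seq_len(nseg))] <- 0
    }
    for (k in kids[[v]]) {
      rec(k)
      own <- own + minc(C[[k]])
    }
    C[[v]] <<- own
    invisible(NULL)
  }
  rec(1L)
  C
}

sankoff_score <- function(E, taxa_states, W) {
  C <- sankoff_cost_matrices(E, taxa_states, W)
  sum(C[[1L]][3L, ])  # root fixed at state 2
}

# Minimum-change labeling of every node by Sankoff backtrace with the
# deterministic tie-break: among cost-minimal states prefer the one closest
# to the parent's state, then the smallest state.
sankoff_label <- function(E, taxa_states, W) {
  C <- sankoff_cost_matrices(E, taxa_states, W)
  nseg <- ncol(taxa_states)
  n_states <- nrow(W)
  nnode <- max(E)
  kids <- children_map(E, nnode)
  states <- matrix(NA_integer_, nnode, nseg)
  states[1L, ] <- 2L
  assign_kids <- function(v) {
    for (k in kids[[v]]) {
      for (seg in seq_len(nseg)) {
        sp <- states[v, seg]
        cost <- C[[k]][, seg] + W[sp + 1L, ]
        cand <- which(cost == min(cost)) - 1L
        cand <- cand[order(abs(cand - sp), cand)]
        states[k, seg] <<- cand[1L]
      }
      assign_kids(k)
    }
  }
  assign_kids(1L)
  states
}

cost_matrix <- function(criterion, n_states) {
  s <- seq_len(n_states) - 1L
  if (criterion == "unordered") 1 - diag(n_states) else abs(outer(s, s, "-"))
}

# Canonical signature of the tree below the diploid anchor: sorted nested
# parenthetical of leaf labels; used for deterministic topology tie-breaks.
tree_signature <- function(E, labels) {
  n_taxa <- length(labels)
  kids <- children_map(E, max(E))
  rec <- function(v) {
    ks <- kids[[v]]
    if (is.null(ks)) return(labels[v])
    parts <- sort(vapply(ks, rec, character(1)))
    paste0("(", paste(parts, collapse = ","), ")")
  }
  rec(kids[[1L]][1L])
}

insert_leaf <- function(E, row, leaf, internal) {
  p <- E[row, 1L]; ch <- E[row, 2L]
  rbind(E[-row, , drop = FALSE],
        c(p, internal), c(internal, ch), c(internal, leaf))
}

# Stepwise-addition search. scorer(E) must be monotone non-decreasing under
# leaf insertion (true for parsimony). prune = FALSE enumerates every
# topology (scoring only complete trees); prune = TRUE is branch-and-bound,
# cutting any partial tree whose score already exceeds the incumbent.
# Ties on the final score are broken by the lexicographically smallest
# canonical leaf-label signature.
search_parsimony <- function(scorer, n_leaves, labels, prune,
                             init = NULL) {
  best <- if (is.null(init)) list(score = Inf, E = NULL, sig = "￿") else init
  consider <- function(E, sc) {
    sig <- tree_signature(E, c("", labels))
    if (sc < best$score || (sc == best$score && sig < best$sig))
      best <<- list(score = sc, E = E, sig = sig)
  }
  recurse <- function(E, next_leaf, next_internal) {
    if (prune && scorer(E) > best$score) return(invisible(NULL))
    if (next_leaf > n_leaves) {
      consider(E, scorer(E))
      return(invisible(NULL))
    }
    for (r in seq_len(nrow(E)))
      recurse(insert_leaf(E, r, next_leaf + 1L, next_internal),
              next_leaf + 1L, next_internal + 1L)
    invisible(NULL)
  }
  E0 <- matrix(c(1L, 2L), 1L, 2L)
  if (n_leaves == 1L) consider(E0, scorer(E0)) else recurse(E0, 2L, n_leaves + 2L)
  best
}

# Greedy stepwise addition: each leaf goes into the edge minimizing the
# score. Provides the branch-and-bound upper bound.
greedy_tree <- function(scorer, n_leaves, labels) {
  E <- matrix(c(1L, 2L), 1L, 2L)
  internal <- n_leaves + 2L
  if (n_leaves >= 2L) for (lf in 2L:n_leaves) {
    cands <- lapply(seq_len(nrow(E)), function(r)
      insert_leaf(E, r, lf + 1L, internal))
    scores <- vapply(cands, scorer, numeric(1))
    E <- cands[[which.min(scores)]]
    internal <- internal + 1L
  }
  list(score = scorer(E), E = E, sig = tree_signature(E, c("", labels)))
}

#' Megabase distance between two copy-number state vectors
#'
#' The package's evolutionary metric: the total genomic length of the
#' segments whose copy number differs between the two states, in megabases.
#' Symmetric and zero exactly when the states are identical.
#'
#' @param state_u,state_v Equal-length integer state vectors over the
#'   table's segments.
#' @param table A `cn_segments` providing `length_bp` per segment.
#' @return Distance in Mb.
#' @export
edge_length_mb <- function(state_u, state_v, table) {
  if (length(state_u) != length(state_v))
    stop("state vectors differ in length", call. = FALSE)
  if (length(state_u) != nrow(table$segments))
    stop("state vectors do not match the segment table", call. = FALSE)
  sum(table$segments$length_bp[state_u != state_v]) / 1e6
}

mb_dist_bins <- function(u, v, genome) sum(bin_lengths(genome)[u != v]) / 1e6

#' Diploid-rooted maximum-parsimony tree of cluster states
#'
#' Searches rooted binary topologies over the early-passage cluster leaves,
#' anchored at a fixed copy-number-neutral diploid root (state 2 on every
#' segment). The default criterion is unordered-state parsimony: any change
#' of a segment's copy-number state along an edge costs 1 (Fitch);
#' `criterion = "wagner"` instead charges the absolute copy-number
#' difference (ordered states, Sankoff). The search is exhaustive up to 7
#' leaves and branch-and-bound (stepwise addition with a greedy upper bound)
#' up to 12; more leaves are refused. Score ties are broken by the
#' lexicographically smallest canonical leaf-label signature, and internal
#' node states come from a minimum-change Sankoff labeling whose per-segment
#' ties prefer the state closest to the parent, then the smallest state.
#' Edge lengths are [edge_length_mb()]: megabases of genome at a different
#' copy number between the edge's endpoints.
#'
#' @param table A `cn_segments` of integer states (from [merge_segments()]
#'   or [cn_segments()]).
#' @param early_labels Cluster labels to use as leaves (default: all rows of
#'   the table).
#' @param criterion `"unordered"` (default) or `"wagner"`.
#' @param method `"auto"` (default: exhaustive <= 7 leaves, branch-and-bound
#'   above), `"exhaustive"` or `"branchbound"`.
#' @return A `cn_tree`: edges (parent, child, length_mb, changes), node
#'   labels ("diploid" root, cluster labels, internal "n<k>"), per-node
#'   state matrix over segments, the parsimony `score`, and the segment
#'   table.
#' @export
parsimony_tree <- function(table, early_labels = NULL,
                           criterion = c("unordered", "wagner"),
                           method = c("auto", "exhaustive", "branchbound")) {
  stopifnot(inherits(table, "cn_segments"))
  criterion <- match.arg(criterion)
  method <- match.arg(method)
  if (is.null(early_labels)) early_labels <- table$cluster_labels
  miss <- setdiff(early_labels, table$cluster_labels)
  if (length(miss))
    stop("unknown cluster label(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  labels <- sort(early_labels)          # canonical leaf order
  n <- length(labels)
  if (n > 12L)
    stop("more than 12 leaf clusters: exact parsimony search refused; ",
         "reduce the cluster set", call. = FALSE)
  S <- table$states[labels, , drop = FALSE]
  storage.mode(S) <- "integer"
  nseg <- ncol(S)

  if (nseg == 0L) {
    # all clusters identical: degenerate star on the diploid root
    E <- cbind(1L, seq_len(n) + 1L)
    node_states <- matrix(integer(0), n + 1L, 0L)
    return(new_cn_tree(E, c("diploid", labels), node_states, table,
                       score = 0L, criterion = criterion, method = "star"))
  }
  taxa_states <- rbind(rep(2L, nseg), S)
  n_states <- max(taxa_states, 2L) + 1L
  W <- cost_matrix(criterion, n_states)
  scorer <- if (criterion == "unordered") {
    masks <- matrix(bitwShiftL(1L, taxa_states), nrow(taxa_states))
    function(E) fitch_score(E, masks)
  } else {
    function(E) sankoff_score(E, taxa_states, W)
  }

  if (method == "auto") method <- if (n <= 7L) "exhaustive" else "branchbound"
  best <- if (n == 1L) {
    search_parsimony(scorer, 1L, labels, prune = FALSE)
  } else if (method == "exhaustive") {
    search_parsimony(scorer, n, labels, prune = FALSE)
  } else {
    search_parsimony(scorer, n, labels, prune = TRUE,
                     init = greedy_tree(scorer, n, labels))
  }
  node_states <- sankoff_label(best$E, taxa_states, W)
  tree <- new_cn_tree(best$E, c("diploid", labels), node_states, table,
                      score = best$score, criterion = criterion,
                      method = method)
  if (criterion == "unordered" && sum(tree$edges$changes) != best$score)
    stop("internal error: labeling changes disagree with search score")
  tree
}

# Assemble the user-facing tree object from an edge matrix. Internal nodes
# beyond the taxa get labels n<k> in preorder.
new_cn_tree <- function(E, taxa_labels, node_states, table, score,
                        criterion, method) {
  nnode <- max(E, length(taxa_labels))
  labels <- character(nnode)
  labels[seq_along(taxa_labels)] <- taxa_labels
  kids <- children_map(E, nnode)
  nxt <- 1L
  preorder <- function(v) {
    if (labels[v] == "") {
      labels[v] <<- paste0("n", nxt)
      nxt <<- nxt + 1L
    }
    for (k in kids[[v]]) preorder(k)
  }
  preorder(1L)
  lens <- numeric(nrow(E))
  chg <- integer(nrow(E))
  if (ncol(node_states) > 0L) {
    segl <- table$segments$length_bp
    for (r in seq_len(nrow(E))) {
      diffseg <- node_states[E[r, 1L], ] != node_states[E[r, 2L], ]
      lens[r] <- sum(segl[diffseg]) / 1e6
      chg[r] <- sum(diffseg)
    }
  }
  is_leaf <- !(seq_len(nnode) %in% E[, 1L])
  structure(list(edges = data.frame(parent = E[, 1L], child = E[, 2L],
                                    length_mb = lens, changes = chg),
                 labels = labels,
                 node_states = node_states,
                 is_leaf = is_leaf,
                 segments = table,
                 score = score,
                 criterion = criterion,
                 method = method,
                 leaf_bin_states = NULL,
                 attachment_log = NULL),
            class = "cn_tree")
}

node_id <- function(tree, node) {
  if (is.character(node)) {
    id <- match(node, tree$labels)
    if (is.na(id)) stop("unknown node: ", node, call. = FALSE)
    id
  } else {
    if (!node %in% seq_along(tree$labels))
      stop("unknown node id: ", node, call. = FALSE)
    as.integer(node)
  }
}

#' Path length from the diploid root to a node
#'
#' Sums the megabase edge lengths along the root-to-node path: the node's
#' total copy-number divergence from the diploid ancestor as accumulated
#' along the tree.
#'
#' @param tree A `cn_tree`.
#' @param node Node label or id.
#' @return Distance in Mb.
#' @export
root_distance <- function(tree, node) {
  stopifnot(inherits(tree, "cn_tree"))
  v <- node_id(tree, node)
  d <- 0
  while (v != 1L) {
    r <- match(v, tree$edges$child)
    d <- d + tree$edges$length_mb[r]
    v <- tree$edges$parent[r]
  }
  d
}

#' Greedy minimal-distance attachment of late-passage clusters
#'
#' Implements the iterative pairing rule that relates late-passage clusters
#' to an existing early-passage tree. Let A be the late clusters not yet
#' placed and B the cluster leaves already on the tree (early leaves, then
#' attached late clusters; the diploid root and unnamed internal nodes are
#' not hosts). At each step the pair (x in A, y in B) with the smallest
#' megabase distance is taken, x becomes a daughter of y with edge length
#' d(x, y), and x moves to B; this repeats until A is empty. Distance ties
#' are broken by the lexicographically smallest (x label, y label) pair.
#'
#' Distances are computed on full-resolution bin-level state vectors when
#' the segment table is bin-backed (the result is identical to re-merging
#' segments jointly over early and late clusters, because merging never
#' changes the megabase metric); a plain matrix of states over the table's
#' segments is also accepted.
#'
#' @param tree A `cn_tree` built from a bin-backed [merge_segments()] table.
#' @param late_profiles A `cluster_profiles` object for the late passage, or
#'   an integer matrix (late clusters x segments) on the tree's segments.
#' @return The extended `cn_tree`; its `attachment_log` field holds a
#'   data.frame (step, attached, host, distance_mb) plus per-step snapshots
#'   of the A and B sets.
#' @export
attach_late_clusters <- function(tree, late_profiles) {
  stopifnot(inherits(tree, "cn_tree"))
  table <- tree$segments
  bin_backed <- !is.null(table$bin_states) &&
    inherits(late_profiles, "cluster_profiles")
  if (bin_backed) {
    late_states <- profile_matrix(late_profiles, "state_cn")
    storage.mode(late_states) <- "integer"
    if (ncol(late_states) != table$genome$n_bins)
      stop("late profiles and tree genome have mismatched bin counts",
           call. = FALSE)
    early_states <- table$bin_states
    dfun <- function(u, v) mb_dist_bins(u, v, table$genome)
  } else {
    late_states <- if (is.matrix(late_profiles)) late_profiles else
      profile_matrix(late_profiles, "state_cn")
    storage.mode(late_states) <- "integer"
    if (ncol(late_states) != nrow(table$segments))
      stop("late states do not match the tree's segment table", call. = FALSE)
    early_states <- table$states
    dfun <- function(u, v) edge_length_mb(u, v, table)
  }
  if (is.null(rownames(late_states)))
    stop("late clusters must be labeled", call. = FALSE)
  if (any(rownames(late_states) %in% tree$labels))
    stop("late cluster labels collide with existing node labels", call. = FALSE)

  placed <- early_states[intersect(tree$labels, rownames(early_states)),
                         , drop = FALSE]
  state_of <- function(lab)
    if (lab %in% rownames(placed)) placed[lab, ] else late_states[lab, ]
  A <- sort(rownames(late_states))
  B <- sort(rownames(placed))
  log <- data.frame(step = integer(0), attached = character(0),
                    host = character(0), distance_mb = numeric(0),
                    stringsAsFactors = FALSE)
  snapshots <- list()
  step <- 0L
  while (length(A) > 0L) {
    step <- step + 1L
    snapshots[[step]] <- list(A = A, B = B)
    pairs <- expand.grid(x = A, y = B, stringsAsFactors = FALSE)
    pairs$d <- mapply(function(x, y) dfun(state_of(x), state_of(y)),
                      pairs$x, pairs$y)
    pairs <- pairs[order(pairs$d, pairs$x, pairs$y), , drop = FALSE]
    x <- pairs$x[1L]; y <- pairs$y[1L]; d <- pairs$d[1L]
    tree <- add_daughter(tree, host = y, label = x,
                         states = late_states[x, ], length_mb = d,
                         bin_backed = bin_backed)
    log <- rbind(log, data.frame(step = step, attached = x, host = y,
                                 distance_mb = d, stringsAsFactors = FALSE))
    placed <- rbind(placed, late_states[x, , drop = FALSE])
    A <- setdiff(A, x)
    B <- sort(c(B, x))
  }
  tree$attachment_log <- structure(list(pairs = log, snapshots = snapshots),
                                   class = "attachment_log")
  tree
}

#' @export
print.attachment_log <- function(x, ...) {
  cat("attachment_log:\n")
  print(x$pairs, row.names = FALSE)
  invisible(x)
}

add_daughter <- function(tree, host, label, states, length_mb, bin_backed) {
  hid <- node_id(tree, host)
  nid <- length(tree$labels) + 1L
  tree$labels <- c(tree$labels, label)
  tree$edges <- rbind(tree$edges,
                      data.frame(parent = hid, child = nid,
                                 length_mb = length_mb,
                                 changes = NA_integer_))
  tree$is_leaf[hid] <- FALSE
  tree$is_leaf <- c(tree$is_leaf, TRUE)
  seg_states <- if (bin_backed)
    states_on_segments(states, tree$segments) else states
  tree$node_states <- rbind(tree$node_states,
                            matrix(seg_states, nrow = 1L))
  if (bin_backed)
    tree$leaf_bin_states <- rbind(tree$leaf_bin_states,
                                  matrix(states, nrow = 1L,
                                         dimnames = list(label, NULL)))
  tree
}

# Re-express a bin-level state vector on the table's retained segments by
# the length-weighted modal state (a late cluster need not be constant
# within an early segment; used for display only).
states_on_segments <- function(bin_states, table) {
  vapply(table$retained, function(sid) {
    idx <- which(table$bin_segment == sid)
    w <- tapply(bin_lengths(table$genome)[idx], bin_states[idx], sum)
    as.integer(names(w)[order(-w, as.integer(names(w)))][1L])
  }, integer(1))
}

#' @export
print.cn_tree <- function(x, ...) {
  nl <- sum(x$is_leaf)
  ncl <- sum(x$labels != "diploid" & !grepl("^n[0-9]+$", x$labels))
  cat(sprintf("cn_tree: %d cluster nodes, parsimony score %d (%s, %s)\n",
              ncl, x$score, x$criterion, x$method))
  cat(sprintf("  %d leaves, total span %.1f Mb\n", nl, sum(x$edges$length_mb)))
  if (!is.null(x$attachment_log))
    cat(sprintf("  %d late clusters attached\n", nrow(x$attachment_log$pairs)))
  invisible(x)
}

#' @export
summary.cn_tree <- function(object, ...) {
  cl <- setdiff(which(object$is_leaf | !grepl("^n[0-9]+$", object$labels)), 1L)
  data.frame(cluster = object$labels[cl],
             root_distance_mb = vapply(cl, function(v)
               root_distance(object, v), numeric(1)))
}

#' Serialize a tree as Newick
#'
#' Branch lengths are megabases; internal nodes (and the diploid root) keep
#' their labels. The output parses back (e.g. with `ape::read.tree`) to an
#' isomorphic tree with identical lengths.
#'
#' @param tree A `cn_tree`.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @param digits Significant digits for branch lengths.
#' @return The Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  stopifnot(inherits(tree, "cn_tree"))
  kids <- children_map(as.matrix(tree$edges[, c("parent", "child")]),
                       length(tree$labels))
  elen <- function(v)
    tree$edges$length_mb[match(v, tree$edges$child)]
  fmt <- function(v) {
    ks <- kids[[v]]
    lab <- tree$labels[v]
    if (is.null(ks)) return(lab)
    paste0("(", paste(vapply(ks, function(k)
      paste0(fmt(k), ":", format(elen(k), digits = digits)),
      character(1)), collapse = ","), ")", lab)
  }
  nwk <- paste0(fmt(1L), ";")
  if (is.null(path)) return(nwk)
  writeLines(nwk, path)
  invisible(nwk)
}

#' @export
plot.cn_tree <- function(x, ...) {
  phy <- ape::read.tree(text = write_newick(x))
  phy <- ape::collapse.singles(phy)
  ape::plot.phylo(phy, show.node.label = TRUE, ...)
  invisible(x)
}

#' Write the attachment log as TSV
#' @param tree A `cn_tree` with an attachment log.
#' @param path Output path.
#' @export
write_attachment_log <- function(tree, path) {
  stopifnot(inherits(tree, "cn_tree"), !is.null(tree$attachment_log))
  utils::write.table(tree$attachment_log$pairs, path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
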