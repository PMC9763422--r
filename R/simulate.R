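#' Specify a clone by copy-number events on a parent
#'
#' Clones form a tree rooted at an implicit diploid ancestor (`parent_id =
#' NA`). Each clone is its parent's profile plus a list of events; an event
#' adds `delta` copies to bins `start_bin..end_bin` (1-based, inclusive,
#' within-chromosome indices).
#'
#' @param clone_id Clone name.
#' @param events Data frame with columns `chrom`, `start_bin`, `end_bin`,
#'   `delta` (signed integer copies); may be empty.
#' @param parent_id Parent clone name, or `NA` for a child of the diploid
#'   ancestor.
#' @param baseline Copy number of the diploid ancestor (default 2).
#' @return A `clone_spec`.
#' @export
clone_spec <- function(clone_id, events = NULL, parent_id = NA,
                       baseline = 2L) {
  if (is.null(events))
    events <- data.frame(chrom = character(0), start_bin = integer(0),
                         end_bin = integer(0), delta = integer(0))
  stopifnot(all(c("chrom", "start_bin", "end_bin", "delta") %in% names(events)))
  structure(list(clone_id = clone_id, parent_id = parent_id,
                 events = events, baseline = as.integer(baseline)),
            class = "clone_spec")
}

#' Realize clone copy-number profiles along the clone tree
#'
#' Applies each clone's events on top of its parent's realized profile,
#' starting from the constant-baseline diploid ancestor. Deterministic; an
#' event that would drive any bin below copy number 0 is an error.
#'
#' @param clones List of [clone_spec()] objects.
#' @param genome A `binned_genome`.
#' @return Integer matrix, clones x bins, rownames = clone ids.
#' @export
realize_clone_profiles <- function(clones, genome) {
  stopifnot(inherits(genome, "binned_genome"))
  ids <- vapply(clones, `[[`, character(1), "clone_id")
  if (anyDuplicated(ids)) stop("duplicate clone ids", call. = FALSE)
  names(clones) <- ids
  nb_per_chrom <- table(factor(genome$bins$chrom, levels = genome$chrom_order))
  offsets <- stats::setNames(c(0, cumsum(nb_per_chrom))[seq_along(genome$chrom_order)],
                             genome$chrom_order)
  profiles <- matrix(NA_integer_, length(clones), genome$n_bins,
                     dimnames = list(ids, bin_names(genome)))
  realize <- function(id) {
    if (!anyNA(profiles[id, ])) return(profiles[id, ])
    sp <- clones[[id]]
    base <- if (is.na(sp$parent_id)) {
      rep(sp$baseline, genome$n_bins)
    } else {
      if (!sp$parent_id %in% ids)
        stop("unknown parent clone: ", sp$parent_id, call. = FALSE)
      realize(sp$parent_id)
    }
    ev <- sp$events
    for (i in seq_len(nrow(ev))) {
      ch <- ev$chrom[i]
      if (!ch %in% genome$chrom_order)
        stop("event on unknown chromosome: ", ch, call. = FALSE)
      nb <- nb_per_chrom[[ch]]
      if (ev$start_bin[i] < 1 || ev$end_bin[i] > nb ||
          ev$start_bin[i] > ev$end_bin[i])
        stop(sprintf("event outside %s (%d bins): %d-%d", ch, nb,
                     ev$start_bin[i], ev$end_bin[i]), call. = FALSE)
      idx <- offsets[[ch]] + ev$start_bin[i]:ev$end_bin[i]
      base[idx] <- base[idx] + ev$delta[i]
    }
    if (any(base < 0))
      stop("clone '", id, "': events drive copy number below 0", call. = FALSE)
    profiles[id, ] <<- as.integer(base)
    profiles[id, ]
  }
  for (id in ids) realize(id)
  profiles
}

#' Specify a two-passage clone population
#'
#' @param clones List of [clone_spec()] objects.
#' @param proportions_early,proportions_late Named per-clone fractions
#'   summing to 1 for each passage.
#' @param n_cells Length-2 integer vector: cells sampled at the early and
#'   late passage.
#' @param noise_rate Probability that any (cell, bin) call deviates by
#'   plus or minus one copy (floored at 0): the "intermittent" per-cell
#'   noise seen in shallow single-cell profiles.
#' @param seed Integer seed.
#' @param passage_labels Labels for the two passages.
#' @return A `population_spec`.
#' @export
population_spec <- function(clones, proportions_early, proportions_late,
                            n_cells, noise_rate = 0.05, seed = 1,
                            passage_labels = c("early", "late")) {
  ids <- vapply(clones, `[[`, character(1), "clone_id")
  for (p in list(proportions_early, proportions_late)) {
    if (!setequal(names(p), ids))
      stop("proportions must be named by clone id", call. = FALSE)
    if (abs(sum(p) - 1) > 1e-8)
      stop("proportions must sum to 1", call. = FALSE)
  }
  if (noise_rate < 0 || noise_rate > 1)
    stop("'noise_rate' must be in [0, 1]", call. = FALSE)
  stopifnot(length(n_cells) == 2L, all(n_cells >= 1))
  structure(list(clones = clones,
                 proportions_early = proportions_early[ids],
                 proportions_late = proportions_late[ids],
                 n_cells = as.integer(n_cells),
                 noise_rate = noise_rate, seed = as.integer(seed),
                 passage_labels = passage_labels),
            class = "population_spec")
}

#' Sample single-cell matrices for both passages
#'
#' Each cell draws a clone according to its passage's proportions, copies
#' the clone's realized profile, and then each (cell, bin) call is
#' independently perturbed by plus or minus one copy (equal probability,
#' floored at 0) with probability `noise_rate`. Bit-reproducible for a
#' fixed spec and seed.
#'
#' @param pop A [population_spec()].
#' @param genome A `binned_genome`.
#' @return List with `early` and `late` (`cell_cn_matrix`), `truth`
#'   (data.frame passage, cell_id, clone_id) and the realized clone
#'   `profiles`.
#' @export
sample_cells <- function(pop, genome) {
  stopifnot(inherits(pop, "population_spec"), inherits(genome, "binned_genome"))
  profiles <- realize_clone_profiles(pop$clones, genome)
  set.seed(pop$seed)
  one_passage <- function(n, props, label) {
    draws <- sample(rownames(profiles), n, replace = TRUE, prob = props)
    vals <- profiles[draws, , drop = FALSE]
    flip <- matrix(stats::runif(n * ncol(vals)) < pop$noise_rate, n)
    sign <- matrix(sample(c(-1L, 1L), n * ncol(vals), replace = TRUE), n)
    vals <- pmax(vals + flip * sign, 0)
    ids <- sprintf("%s_cell%04d", label, seq_len(n))
    list(matrix = cell_cn_matrix(vals, genome, cell_ids = ids, passage = label),
         truth = data.frame(passage = label, cell_id = ids, clone_id = draws,
                            stringsAsFactors = FALSE))
  }
  early <- one_passage(pop$n_cells[1L], pop$proportions_early,
                       pop$passage_labels[1L])
  late <- one_passage(pop$n_cells[2L], pop$proportions_late,
                      pop$passage_labels[2L])
  list(early = early$matrix, late = late$matrix,
       truth = rbind(early$truth, late$truth), profiles = profiles)
}

#' The package's reference two-clone culture simulation
#'
#' Emulates the clonal structure and drift the pipeline is designed to
#' detect: a major aneuploid clone and a minor sibling carrying one extra
#' copy of two whole chromosomes plus partial-chromosome gains, with the
#' minor clone expanding from 8.7% of 705 cells at the early passage to
#' 40.7% of 744 cells at the late one, and 5% per-(cell, bin) intermittent
#' noise - the culture-drift regime reported for patient-derived organoid
#' populations.
#'
#' @param genome A `binned_genome` (default [demo_genome()]).
#' @param seed Integer seed.
#' @return A `population_spec`.
#' @export
two_clone_population <- function(genome = demo_genome(), seed = 1) {
  nb <- table(factor(genome$bins$chrom, levels = genome$chrom_order))
  half <- function(ch) max(1L, nb[[ch]] %/% 2L)
  major <- clone_spec("major", data.frame(
    chrom = "chr2", start_bin = 1L, end_bin = nb[["chr2"]], delta = 1L))
  minor <- clone_spec("minor", parent_id = "major", events = data.frame(
    chrom = c("chr5", "chr6", "chr1", "chr3"),
    start_bin = c(1L, 1L, 1L, 1L),
    end_bin = c(nb[["chr5"]], nb[["chr6"]], half("chr1"), half("chr3")),
    delta = 1L))
  population_spec(list(major, minor),
                  proportions_early = c(major = 0.913, minor = 0.087),
                  proportions_late = c(major = 0.593, minor = 0.407),
                  n_cells = c(705L, 744L), noise_rate = 0.05, seed = seed)
}

#' A known four-leaf clone tree for recovery checks
#'
#' Two cherries below the diploid ancestor - ((A, B), (C, D)) - with at
#' least a one-copy event on every branch and all branch events distinct,
#' so the topology is identifiable from noise-free leaf profiles.
#'
#' @param genome A `binned_genome` (default [demo_genome()]).
#' @return List of [clone_spec()]s for ancAB, ancCD (internal) and leaves
#'   A, B, C, D; the leaves carry attribute `truth_split` = the non-trivial
#'   leaf bipartition `list(c("A","B"), c("C","D"))`.
#' @export
four_leaf_clones <- function(genome = demo_genome()) {
  nb <- table(factor(genome$bins$chrom, levels = genome$chrom_order))
  whole <- function(ch, d) data.frame(chrom = ch, start_bin = 1L,
                                      end_bin = nb[[ch]], delta = as.integer(d))
  part <- function(ch, d) data.frame(chrom = ch, start_bin = 1L,
                                     end_bin = max(1L, nb[[ch]] %/% 2L),
                                     delta = as.integer(d))
  clones <- list(
    clone_spec("ancAB", whole("chr1", 1)),
    clone_spec("A", part("chr2", 1), parent_id = "ancAB"),
    clone_spec("B", whole("chr3", 1), parent_id = "ancAB"),
    clone_spec("ancCD", whole("chr4", -1)),
    clone_spec("C", whole("chr5", 1), parent_id = "ancCD"),
    clone_spec("D", part("chr6", 1), parent_id = "ancCD"))
  attr(clones, "truth_split") <- list(c("A", "B"), c("C", "D"))
  clones
}

#' Specify a dosage-coupled expression simulation
#'
#' Per gene g and sample s, `log2 expression = baseline_g +
#' dosage_coefficient * log2(CN_s(g) / 2) + Normal(0, gene_noise_sd)`, with
#' `baseline_g ~ Normal(baseline_mean, baseline_sd)` shared between
#' samples; expression is exported as RPKM. A coefficient of 1 is the pure
#' gene-dosage model (expression proportional to copy number); 0 decouples
#' expression from copy number.
#'
#' @param n_genes Number of genes placed uniformly over the genome.
#' @param baseline_mean,baseline_sd Per-gene baseline log2-RPKM
#'   distribution (defaults 5 and 1).
#' @param dosage_coefficient Slope of log2 expression on log2(CN/2).
#' @param gene_noise_sd Per-gene, per-sample expression noise (log2 scale).
#' @param seed Integer seed.
#' @return A `dosage_spec`.
#' @export
dosage_spec <- function(n_genes = 20000, baseline_mean = 5, baseline_sd = 1,
                        dosage_coefficient = 1, gene_noise_sd = 0.5,
                        seed = 1) {
  stopifnot(n_genes >= 1, baseline_sd >= 0, gene_noise_sd >= 0)
  structure(list(n_genes = as.integer(n_genes), baseline_mean = baseline_mean,
                 baseline_sd = baseline_sd,
                 dosage_coefficient = dosage_coefficient,
                 gene_noise_sd = gene_noise_sd, seed = as.integer(seed)),
            class = "dosage_spec")
}

# Deterministic uniform gene placement (chromosome by length, position
# uniform); shared by the sampler and the noise calibrator.
place_genes <- function(genome, n_genes, seed) {
  set.seed(seed)
  lens <- genome$chrom_lengths
  chrom <- sample(names(lens), n_genes, replace = TRUE, prob = lens)
  start <- floor(stats::runif(n_genes) * (lens[chrom] - 1))
  len_bp <- pmin(round(stats::runif(n_genes, 1e3, 1e5)), lens[chrom] - start)
  data.frame(gene_id = sprintf("g%05d", seq_len(n_genes)),
             chrom = chrom, start = start, end = start + len_bp,
             length_kb = len_bp / 1e3, stringsAsFactors = FALSE)
}

#' Sample a dosage-coupled gene expression table
#'
#' Places genes uniformly over the genome and draws per-sample RPKM from
#' the dosage model in [dosage_spec()], reading each gene's copy number
#' from the bulk profile bin containing its start.
#'
#' @param dspec A `dosage_spec`.
#' @param cn_a,cn_b `bulk_cn_profile` objects for the two samples.
#' @param genome The shared `binned_genome`.
#' @return A `gene_table` with `rpkm_A` and `rpkm_B` columns.
#' @export
sample_expression <- function(dspec, cn_a, cn_b, genome) {
  stopifnot(inherits(dspec, "dosage_spec"),
            inherits(cn_a, "bulk_cn_profile"), inherits(cn_b, "bulk_cn_profile"))
  genes <- place_genes(genome, dspec$n_genes, dspec$seed)
  idx <- bin_index_of(genome, genes$chrom, genes$start, what = genes$gene_id)
  set.seed(dspec$seed + 1L)
  baseline <- stats::rnorm(dspec$n_genes, dspec$baseline_mean, dspec$baseline_sd)
  draw <- function(cn) {
    mu <- baseline + dspec$dosage_coefficient * log2(cn$values[idx] / 2)
    2^(mu + stats::rnorm(dspec$n_genes, 0, dspec$gene_noise_sd))
  }
  genes$rpkm_A <- draw(cn_a)
  genes$rpkm_B <- draw(cn_b)
  gene_table(genes)
}

#' Calibrate gene noise for a target population dosage correlation
#'
#' Solves for the `gene_noise_sd` at which the binned expression
#' fold-change track correlates with the binned copy-number-ratio track at
#' a chosen population Pearson r, given the spec's gene placement. With
#' per-gene, per-sample noise sd sigma, a bin holding g genes carries
#' fold-change noise variance `2 sigma^2 / g`, so
#' `r^2 = cov(x, s)^2 / (var(x) (var(s) + 2 sigma^2 mean(1/g)))` where x is
#' the copy-ratio track and s the noise-free binned signal; the equation is
#' inverted for sigma.
#'
#' @param dspec A `dosage_spec` (its `gene_noise_sd` is ignored).
#' @param cn_a,cn_b `bulk_cn_profile` objects for the two samples.
#' @param genome The shared `binned_genome`.
#' @param target_r Desired population Pearson correlation.
#' @param pseudocount,epsilon The downstream log2FC/log2CNV guards.
#' @return The calibrated `gene_noise_sd`.
#' @export
calibrate_dosage_noise <- function(dspec, cn_a, cn_b, genome, target_r,
                                   pseudocount = 0.1, epsilon = 0.1) {
  stopifnot(inherits(dspec, "dosage_spec"), target_r > 0, target_r < 1)
  genes <- place_genes(genome, dspec$n_genes, dspec$seed)
  idx <- bin_index_of(genome, genes$chrom, genes$start, what = genes$gene_id)
  sig_gene <- dspec$dosage_coefficient * log2(cn_a$values[idx] / cn_b$values[idx])
  s <- tapply(sig_gene, idx, mean)
  g <- tapply(sig_gene, idx, length)
  x <- binned_log2cnv(cn_a, cn_b, epsilon = epsilon)[as.integer(names(s))]
  covxs <- stats::cov(x, s)
  vreq <- (covxs / (stats::sd(x) * target_r))^2 - stats::var(s)
  if (vreq <= 0)
    stop("target_r exceeds the noise-free correlation for this design",
         call. = FALSE)
  sqrt(vreq / (2 * mean(1 / g)))
}
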