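---
title: "Clonal decomposition and copy-number phylogenetics with cnclone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Clonal decomposition and copy-number phylogenetics with cnclone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnclone)
```

## The problem

Cultured tumour organoids are genomically unstable: a population founded from
one tumour is in reality a mixture of clones whose karyotypes differ by whole-
and partial-chromosome copy-number (CN) events, and the clonal composition
drifts as the culture is passaged. Shallow single-cell whole-genome sequencing
measures each cell's CN profile over fixed genomic bins (typically 5 Mb at
0.01-0.05x coverage; bulk SNP-array profiles resolve 1 Mb). `cnclone`
implements the downstream analysis of such data:

1. **Clonal decomposition** - embed the cells x bins CN matrix with t-SNE and
   partition it with spectral clustering into clusters of near-identical
   cells.
2. **Cluster profiles** - average CN per cluster, integerize to CN states,
   and estimate each cluster's total chromosome number.
3. **Copy-number phylogeny** - merge bins into cross-cluster segments, build
   a maximum-parsimony tree of the early-passage clusters rooted at a
   CN-neutral diploid ancestor, measure every edge in megabases of altered
   genome, and attach late-passage clusters by greedy minimal-distance
   pairing.
4. **Culture shift** - megabases gained and lost between the averaged
   profiles of two passages.
5. **Gene dosage** - the Pearson correlation between per-1 Mb expression
   fold change and per-1 Mb CN ratio of two samples.

A seeded simulator generates clone mixtures with known ground truth, so every
stage is testable without access-controlled patient data.

## Data model

A `binned_genome` fixes the coordinate system: 0-based, half-open `[start,
end)` bins of one width tiling each chromosome, the last bin of a chromosome
possibly shorter (BED convention; it avoids off-by-one bookkeeping when
segments are merged). Per-cell calls live in a `cell_cn_matrix`, bulk tracks
in a `bulk_cn_profile`. Missing bins are rejected at ingest rather than
imputed - upstream CN callers emit complete per-bin calls, and any imputation
rule here would be invented biology. X and Y are ordinary chromosomes; no
ploidy special-casing is applied.

The **chromosome-number estimate** of a profile is the sum over chromosomes
of the mean CN of that chromosome's bins, so an all-2 profile over 23
chromosomes gives 46. Bins count equally within a chromosome by default; the
remainder bin is at most one part in `chrom_length / bin_width`, so at genome
scale the difference from length-weighting (available via
`weight = "length"`) is negligible.

## Clustering

`spectral_cluster()` is the standard normalized-Laplacian algorithm: Gaussian
affinity with the median pairwise distance as bandwidth, symmetric normalized
Laplacian, row-normalized eigenvector embedding, k-means (`nstart = 10`). By
default it runs on a 2-D t-SNE embedding of the cells (perplexity 30, seed
42, Euclidean metric on CN vectors); `on = "matrix"` clusters the raw CN
vectors instead. Both inputs are supported because either is defensible for
this data; the embedding is the default as it is what gets inspected
visually.

When `k` is not given it is chosen by the eigengap heuristic over k in
[2, 12]: the k maximizing the gap between consecutive Laplacian eigenvalues.
This range covers the cluster counts realistically present in an organoid
passage; an explicit `k` overrides it. t-SNE requires more than
`3 * perplexity` cells and is seeded, so results are reproducible; a
degenerate all-identical input embeds to the origin rather than erroring.

Cluster means are integerized **half-up** (2.5 becomes 3). Some fixed rule is
needed to turn real-valued means into parsimony states, the choice only
matters for means sitting exactly between states, and rounding 2.5 up treats
gains and losses around the diploid state symmetrically in sub-triploid
genomes where means above 2 dominate.

`hierarchical_check()` offers an independent view of cluster relatedness:
Canberra distance (`sum |x - y| / (|x| + |y|)`, both-zero terms contributing
0, no rescaling of partial sums - implemented directly because `stats::dist`
rescales omitted terms) with complete linkage. On clean fixtures the closest
pair under Canberra is also the closest pair under the megabase tree metric,
and a test asserts exactly that.

## Segments and the parsimony tree

`merge_segments()` collapses runs of bins over which *every* cluster is
constant; breakpoints are the union of all clusters' state changes plus
chromosome boundaries, so merging is maximal while keeping segments
"vertically comparable" across clusters. Segments with identical states in
all clusters are then dropped: they carry no heterogeneity. Merging is
provably lossless for the megabase metric below, and the suite checks the
merged-versus-bin-level identity on random fixtures.

`parsimony_tree()` searches rooted binary topologies over the early-passage
cluster leaves plus a fixed diploid anchor (state 2 on every segment). Two
criteria are available:

* **unordered** (default): any change of a segment's state along an edge
  costs 1. This matches a criterion of "minimum number of CN state changes":
  a 2 to 4 jump is one event, which is also the biologically natural reading
  since a single mis-segregation can change CN by more than one copy.
* **wagner**: an edge's cost on a segment is `|CN_parent - CN_child|`,
  charging magnitude rather than events, for sensitivity analysis.

Scoring uses Fitch set operations (bitmask-encoded) for the unordered
criterion and a Sankoff dynamic program for the ordered one. The search is
exhaustive stepwise enumeration up to 7 leaves ((2n-3)!! topologies = 10,395
at n = 7) and branch-and-bound above, pruning partial trees whose score
already exceeds a greedy-addition upper bound; beyond 12 leaves the function
refuses rather than silently going heuristic, since per-passage cluster
counts in this domain stay well below that. Branch-and-bound is verified
against exhaustive enumeration, and scores against an independently coded
Sankoff DP and against `phangorn` on the same topologies.

Determinism is guaranteed by explicit tie-breaks: equal-score topologies
resolve to the lexicographically smallest canonical leaf-label signature;
among minimum-change internal labelings each node takes, per segment, the
state closest to its parent's and then the smallest state (biasing toward
gradual change); attachment-distance ties take the smallest (attached label,
host label) pair.

**Edge lengths** convert parsimony edges into genomic distance: the summed
length of all segments whose state differs between the edge's endpoints,
divided by 1e6 - copy-number change measured in megabases. `root_distance()`
accumulates these along the root path.

`attach_late_clusters()` implements the two-step design that keeps early and
late passages from being conflated: the tree is built from early clusters
only, then each late cluster is attached greedily - repeatedly taking the
globally closest (unplaced late cluster, placed cluster) pair - as a daughter
of its host, at its megabase distance. Hosts are cluster leaves (early, plus
late ones once placed), not unnamed internal nodes: the procedure pairs
*clusters*. Distances are computed on full-resolution bin-level state
vectors; because merging never changes the metric, this is identical to
re-merging segments jointly over early plus late clusters and measuring
there, without re-deriving a segmentation at each step. Attachment never
alters the early tree's topology, states, score or edge lengths.

Trees serialize to Newick with megabase branch lengths and internal-node
labels (the diploid root appears as a degree-one root node); `ape` parses
them back for round-trip checks and plotting.

## Culture shift

`cnv_shift()` reduces the per-bin difference of two averaged profiles (late
minus early) to megabases gained and lost. How real-valued averaged deltas
should be reduced to a single Mb figure is genuinely underdetermined, so both
defensible rules ship:

* `copyweighted` (default, threshold 0): `sum(max(delta, 0) * bin_length) /
  1e6` - one copy gained over 1 Mb counts 1 Mb, half a copy counts 0.5 Mb.
  It uses all signal and can produce values that are not multiples of the
  bin width.
* `span` (default threshold 0.5 copies): the plain genomic span of bins
  whose delta clears the threshold.

Swapping the two passages swaps gains and losses exactly, and raising the
span threshold can only shrink both.

## Gene dosage

Expression is RPKM-normalized (`count / total_reads_in_millions /
gene_length_kb`). Per gene, `log2((rpkm_A + 0.1) / (rpkm_B + 0.1))` is
averaged per 1 Mb bin (genes assigned by start coordinate - the simplest
deterministic rule; overlap-weighting would change little at 1 Mb); the CN
track is `log2((cn_A + 0.1) / (cn_B + 0.1))`. The 0.1 pseudocounts guard
logs of zero and are configurable. Bins empty in either track are dropped
pairwise, the only rule that keeps the correlation well defined;
`dosage_correlation()` then reports Pearson r with the two-sided p-value
from the t transform on n - 2 degrees of freedom, erroring (not NaN) on
zero-variance tracks. Gene-set enrichment is deliberately not reimplemented;
`write_ranked_list()` exports a preranked list for the dedicated tools.

## The simulator, and what passing tests do and do not show

`sample_cells()` realizes clones by applying signed CN events along a clone
tree rooted at a diploid ancestor, draws each cell's clone from per-passage
proportions, and flips each (cell, bin) call by one copy (floored at 0) with
probability `noise_rate` - the simplest mechanism reproducing the
intermittent per-cell gains and losses seen in shallow single-cell CN calls.
A read-count-level noise model is intentionally out of scope. The reference
conditions (`two_clone_population()`) mirror the culture-drift regime the
pipeline targets: a minor clone carrying one extra copy of two whole
chromosomes plus two partial-chromosome gains at 8.7% of 705 cells early,
expanding to 40.7% of 744 cells late, at 5% bin noise. The default demo
genome is six chromosomes of 100-250 Mb at 5 Mb bins - large enough for
whole- and partial-chromosome events, small enough for fast tests; an
hg19-length table ships for realistic runs.

`sample_expression()` realizes the dosage model directly: `log2 expression =
baseline_g + coefficient * log2(CN/2) + Normal(0, sigma)` per sample, with
`baseline_g ~ Normal(5, 1)` on the log2-RPKM scale.
`calibrate_dosage_noise()` inverts the induced bin-level correlation
`r^2 = cov(x, s)^2 / (var(x) (var(s) + 2 sigma^2 mean(1/g_b)))` to hit a
target population r (a bin with `g_b` genes carries fold-change noise
variance `2 sigma^2 / g_b`); at 2,500 bins the realized r lands within a few
hundredths of the target.

These generators emulate the statistical *structure* the analysis assumes -
clone mixtures, proportion drift, dosage coupling - not the measurement
process: no read sampling, no GC or mappability bias, no amplification
artifacts, no doublets. Recovery on simulated data therefore demonstrates
the correctness of the algorithms, not the robustness of the end-to-end
laboratory pipeline on real libraries.

## Problem sizes and numerical checks

The shipped verification suite runs clone recovery at 705 + 744 cells on the
204-bin demo genome; parsimony correctness on fifty random 4-7-leaf,
10-segment instances with states 0-5 (branch-and-bound vs exhaustive vs
independent DP); metric fidelity on twenty random segment fixtures; and
dosage recovery at 2,500 one-megabase bins with 20,000 genes. These sizes
were chosen to exercise every code path at the scale of a typical organoid
passage while keeping a full run in minutes on one core.

## Known limitations

* Cluster-level trees only: per-cell phylogenies, allele-specific CN and SNV
  evidence are out of scope, as is CN calling itself.
* Maximum parsimony with a diploid anchor assumes CN states are comparable
  across clusters after segment merging; regions of catastrophic
  rearrangement (e.g. chromothripsis-like oscillation) satisfy this formally
  but their event count under either criterion understates the underlying
  mechanism.
* The eigengap heuristic inherits the usual weakness of spectral model
  selection: clusters of very unequal density or size can shift the gap;
  explicit `k` is the escape hatch.
* The Mb shift between passages is descriptive; no significance test is
  attached, and none is defined for it here.
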