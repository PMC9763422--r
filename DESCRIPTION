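Package: cnclone
Title: Clonal Decomposition and Copy-Number Phylogenetics for Single-Cell CNV Profiles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing clonal heterogeneity and drift in single-cell
    copy-number (CN) data from cultured tumour organoids. Cells profiled at a
    fixed genomic bin width are embedded with t-SNE and partitioned by spectral
    clustering into clonal clusters; cluster-averaged CN profiles are merged
    into cross-cluster segments and related by a diploid-rooted maximum
    parsimony phylogeny whose edge lengths measure copy-number change in
    megabases, with greedy minimal-distance attachment of late-passage
    clusters. Additional stages quantify megabases gained and lost between
    passages and test the gene-dosage relationship between copy-number
    variation and expression fold change. A seeded simulator generates clone
    mixtures with known ground truth so the whole pipeline is testable without
    access-controlled study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rtsne,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    mclust,
    optparse
Config/testthat/edition: 3
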