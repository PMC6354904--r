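Package: stageDE
Title: Staged Differentiation Differential Expression and GWAS Locus Enrichment
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for analysing staged in vitro differentiation time courses
    of bulk RNA-seq and relating stage-specific expression to GWAS loci.
    Implements expression filtering, log-CPM normalisation with precision
    weights, per-gene weighted linear models with donor blocking and
    empirical-Bayes moderated statistics, peak-stage assignment of
    differentially expressed genes, mapping of GWAS credible intervals to
    genes at configurable distance bins, hypergeometric enrichment with a
    permutation null, gene-based association scoring from SNP summary
    statistics, and weighted Kolmogorov-Smirnov gene set enrichment analysis.
    A synthetic-data module generates staged negative-binomial counts, gene
    annotation, credible intervals and SNP statistics with known ground truth
    so the whole pipeline is testable without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma
Config/testthat/edition: 3
RoxygenNote: 7.3.3
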