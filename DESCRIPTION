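Package: accessdyn
Title: Chromatin Accessibility Dynamics from ATAC-Seq Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for time-course ATAC-seq experiments in
    non-model genomes: text-format genomics I/O (BED, narrowPeak, GTF,
    bedGraph), fragment coverage, a Poisson sliding-window peak caller,
    consensus peak merging, stable-gene and spike-in normalization,
    empirical-Bayes moderated t-tests for differential accessibility,
    K-means accessibility archetypes, PCA, HOMER-style genomic feature
    annotation, interval-set overlap statistics, Fisher/FDR GO enrichment,
    fragment-length nucleosome spectra and V-plot aggregation. Includes a
    fully deterministic synthetic-data generator that emulates the signal
    structure of a baculovirus infection time course (four sample groups,
    two replicates, four accessibility archetypes, a nucleosomal
    fragment-length mixture whose multi-nucleosomal component collapses in
    the final condition, stably expressed normalization genes) together
    with a ground-truth table for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma,
    mclust,
    IRanges,
    jsonlite
Config/testthat/edition: 3
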