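Package: dehostbench
Title: Benchmarking Host-Read Removal for Metagenomic Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for benchmarking host-read (human) decontamination of
    metagenomic sequencing data against an adjudicated gold standard.
    Provides a synthetic-data generator with known read origins (host
    genomes carrying satellite repeat arrays, legacy references lacking
    designated exclusive regions, microbial genomes with planted host
    contamination), per-read host labeling from SAM alignments,
    Kraken-style classifications or a built-in k-mer classifier, a
    consensus/category-concordance/BLAST-fallback adjudication cascade,
    sensitivity/specificity/Matthews-correlation evaluation, a paired
    nonparametric comparison framework (Kruskal-Wallis omnibus, one-sided
    exact Wilcoxon signed-rank, Benjamini-Hochberg adjustment),
    false-negative read characterization (GC, k-mer spectra, placement),
    and a k-mer contamination screen of microbial assemblies against
    reference-exclusive regions with contamination-ratio reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    S4Vectors,
    data.table,
    methods,
    stats,
    stringi,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
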