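Package: ssrtools
Title: Microsatellite Mining, Genotype Quality Control and Population
    Differentiation for Transcriptome-Derived SSR Markers
Version: 0.1.0
Authors@R:
    person("ssrtools", "maintainers", email = "ssrtools@example.org",
           role = c("aut", "cre"))
Description: A toolkit for developing and quality-controlling simple sequence
    repeat (SSR, microsatellite) markers mined from assembled transcriptome
    contigs. Enumerates canonical di-, tri- and tetra-nucleotide motif classes,
    scans FASTA contigs for perfect repeat tracts and extracts primer-design
    flanks; reads and writes GenePop genotype tables and computes per-locus
    summary statistics (allele counts, observed and expected heterozygosity,
    missingness); tests Hardy-Weinberg equilibrium per locus and population by
    chi-square and provides null-allele diagnostics (heterozygote deficit
    versus missingness correlation, missingness-by-multiplex ANOVA); estimates
    pairwise Weir-Cockerham Fst between populations and tests concordance of
    two distance matrices with a permutation Mantel test. A seeded simulator
    (planted-repeat contigs; Balding-Nichols island-model genotypes with
    configurable Fst and null-allele rates) makes every stage testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
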