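Package: metagenotyper
Title: Metagenotyping of Microbial Populations from Shotgun Metagenomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Calls intra-species genetic variants of microbial species
    directly from shotgun metagenomic reads. Builds custom reference
    databases (universal single-copy marker genes, representative genomes
    and species pangenomes) from any genome collection described by a
    table-of-contents file, screens each sample for the species it
    contains via marker-gene coverage, produces paired-end-aware
    per-sample single-nucleotide-variant pileups against a
    sample-customized alignment target, pools pileups across samples in
    independent position chunks to call population SNVs, estimates
    pangenome gene copy numbers normalized by marker depth, and detects
    strain mixtures from within-sample allele-frequency spectra. A
    deterministic synthetic-community simulator with complete planted
    ground truth (strain genotypes, mixture proportions, gene
    duplications and deletions, read provenance) makes every stage
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    methods,
    parallel,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
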