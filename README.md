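# metagenotyper

Metagenotyping — calling intra-species genetic variants of microbial
species directly from shotgun metagenomic reads — turns a stack of
FASTQ files into population-genetic observables: which species are
present and at what depth, where their strains differ from the
reference at single-nucleotide resolution across a cohort, which genes
vary in copy number, and whether an individual sample carries one
dominant strain or a mixture. `metagenotyper` implements this whole
chain at desk scale for microbiome researchers who want a
self-contained, fully testable pipeline over their own genome
collections, with no cloud services or external databases.

## What it computes

Starting from a *table-of-contents* file assigning genome FASTAs to
species (one representative genome per species), the package builds a
three-part reference database — universal single-copy **marker genes**,
**representative genomes**, and greedily clustered species
**pangenomes** (centroid identity ≥ 0.95 by global alignment,
matches/alignment-columns). Each sample is then processed as:

1. **Species screen.** Reads map to the marker catalog; species depth is
   the median marker coverage over the 15-family panel (missing
   families count 0), and species with median ≥ 2× form the
   sample-customized alignment target.
2. **Single-sample SNV step.** Alignments against the customized target
   pass MAPQ/identity/coverage/base-quality and proper-pair filters;
   overlapping mates are resolved so a sequenced *fragment* never
   contributes more than one observation per site (agreeing overlap →
   counted once at the higher quality; disagreement → higher-quality
   base; tie → nothing). Per-site A/C/G/T counts are kept in full — no
   single-strain-per-sample assumption.
3. **Across-samples population SNVs.** Sites are scanned in independent
   position chunks; a site counts in a sample when its depth is within
   `[5, 3 × mean]`, and is reported when ≥ 80% of samples qualify.
   Pooled major/minor alleles come from summed counts (or per-sample
   majority vote), and the output is byte-identical for any chunk size
   or worker count.
4. **Gene copy numbers.** Per-centroid vertical coverage divided by the
   same sample's median marker coverage; copy number ≈ 1 for single-copy
   genes, presence threshold 0.35.
5. **Strain mixtures.** The fraction of well-covered sites whose
   within-sample minor-allele frequency lies in [0.10, 0.50] (with ≥ 2
   supporting reads); clonal samples sit orders of magnitude below the
   0.002 cutoff, mixtures above it.

A deterministic community simulator (`sim_collection`,
`mutate_strain`, `plant_cnv`, `simulate_reads`) generates genomes,
strains, planted duplications/deletions and paired-end reads with exact
ground truth, so every one of those stages is validated end-to-end with
no downloads. The methods vignette
(`vignettes/metagenotyping-methods.Rmd`) documents every model,
parameter and design choice.

## Worked example

```r
library(metagenotyper)

# 1. Simulate a toy genome collection (3 species, 2 genomes each: a
#    representative and a strain diverged from it by 1%) and build a
#    reference database from its table-of-contents file
col <- sim_collection("collection", n_species = 3, genomes_per_species = 2,
                      genome_length = 10000, strain_divergence = 0.01, seed = 1)
db  <- build_db(parse_toc(col$toc), out_dir = "db")
db
#> <midas_db> 3 species at db
#>   markers: 45 | pangenome centroids: 90

# 2. Screen a sample containing the non-reference strain of species 1 at
#    ~20x and of species 2 at ~5x; species 3 is absent
profile <- screen_sample(r1, r2, db)   # r1/r2: simulated read pairs
profile
#>   species_id median_marker_coverage relative_abundance n_markers_covered
#> 1        s01              12.666667           0.826087                15
#> 2        s02               2.666667           0.173913                15
select_species(profile, min_median_coverage = 2)
#> [1] "s01" "s02"

# 3. Pileup against the sample-customized target; the strain's planted
#    substitutions surface as consensus SNVs (major allele != reference)
target <- build_custom_target(select_species(profile, 2), db)
res <- snv_single_sample(r1, r2, target)
snv <- res$s01$snv
cons <- snv[!is.na(snv$major_allele) & snv$major_allele != snv$ref & snv$depth >= 10, ]
nrow(cons); nrow(col$truth$s01$strains[["s01.2"]])
#> [1] 88     # consensus SNVs found at depth >= 10
#> [1] 94     # substitutions planted in the strain
head(cons[, c("contig_id", "pos", "ref", "depth", "major_allele", "major_freq")], 3)
#>     contig_id pos ref depth major_allele major_freq
#> 282  s01.1_c1 282   A    14            C          1
#> 348  s01.1_c1 348   C    10            G          1
#> 435  s01.1_c1 435   C    13            A          1

# 4. Strain-mixture check on the same (clonal) sample
strain_mix_calls(list(sample1 = res$s01$pileup))
#>   species_id sample_id n_eligible_sites intermediate_fraction            call
#> 1        s01   sample1             9567                     0 single_dominant
```

The screen reads ~12.7× for a 20× genome because marker coverage counts
only reads fully contained in a 300-bp gene; the copy-number module
divides by the same quantity, so the geometry cancels where it matters.
Multi-sample merging (`snv_merge`), copy numbers (`cnv_sample`) and the
one-call pipeline (`run_pipeline`) continue from these objects; see the
vignette.

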