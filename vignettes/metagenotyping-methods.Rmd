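---
title: "Metagenotyping methods: models, filters and design choices"
author: "metagenotyper"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metagenotyping methods: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# Scope

`metagenotyper` calls intra-species genetic variation of microbial species
directly from shotgun metagenomic reads: single-nucleotide variants (SNVs)
characterized across many samples ("population SNVs"), gene copy-number
variants against a species pangenome, and a per-sample indicator of strain
mixtures. Everything runs at desk scale from a user-supplied genome
collection; a fully deterministic community simulator provides planted
ground truth for every stage.

This vignette is the package's methods reference: the statistical model
behind each stage, every tunable parameter with its default and rationale,
the numerical conventions, and the known limitations. It states no
empirical result that the test suite and `scripts/acceptance.R` do not
themselves compute.

# Reference databases

A database is built from a *table of contents* (TOC): a TSV assigning each
genome FASTA (and its gene FASTA) to a species and designating exactly one
*representative* genome per species. Three components are derived:

* **Marker genes** — universal single-copy families used to estimate
  species presence and depth. Families are declared by a
  `marker_family=<label>` tag in the gene description line against a fixed
  15-family panel (`marker_panel()`). Identification of markers in novel
  collections is delegated to upstream annotation: an external
  profile-HMM search can be folded in through `apply_marker_hits()`,
  which rewrites a gene FASTA with the same tags. This keeps the builder
  free of an HMM dependency while preserving the contract that each
  representative contributes at most one gene per family (two genes with
  one family is an error, because coverage of a multi-copy "marker" would
  no longer estimate cellular depth).
* **Representative genomes** — the per-species SNV coordinate system.
* **Pangenomes** — all genes of all the species' genomes, clustered;
  cluster centroids are the copy-number alignment targets.

## Pangenome clustering

Clustering is single-tier greedy centroid clustering, the classic
length-sorted rule: genes are sorted by descending length (ties broken
lexicographically by gene id); each gene joins the first cluster whose
centroid it matches at `identity >= identity_threshold` (default 0.95),
else founds a new cluster. Identity is matches over alignment columns of
a global (Needleman–Wunsch) alignment, computed with
`Biostrings::pairwiseAlignment`. Two shortcuts keep this fast without
changing results in practice: equal-length pairs whose ungapped identity
already reaches the threshold are accepted outright (an ungapped global
alignment attains that identity), and pairs sharing fewer than 10% of
their distinct 12-mers are rejected without alignment — the standard
word-count prefilter of greedy clustering tools. The 10% rule is a
heuristic: a pair at the 0.95 threshold over ~300 bp retains well over
a third of its 12-mers, while unrelated sequences share essentially none,
so the gap between the two regimes is wide. Tests verify the clustering
against a brute-force all-pairs implementation on small inputs.

All database outputs are written in fixed sort orders, and the manifest
records an MD5 checksum per file, so rebuilding from identical inputs is
byte-identical and `load_db()` can detect any post-build modification.

# Species screening

Screening estimates which species are actually present so that SNV
alignment happens against a sample-customized target rather than every
representative in the database.

Reads are mapped to the marker catalog with the internal aligner; each
read keeps at most one hit — the one with the most identical bases,
subject to `min_identity` (default 0.94) and `min_aln_len` (default
50 bp). Ties within one species break lexicographically by marker id;
ties across species discard the read. The cross-species discard is the
conservative unique-mapping rule: a read that cannot distinguish two
species should vote for neither, trading a little sensitivity for a lower
false-positive rate.

Marker coverage is mapped bases over marker length. The species depth
estimate is the **median over the full 15-family panel, with families
missing from the database or without mapped bases counted as 0**. The
median (rather than the mean) is robust to a few spuriously recruited
or dropped markers; counting absent families as zero makes a species
with only 2 of 15 markers covered look absent, which is the desired
behaviour for spurious low-level recruitment. Species at median coverage
`>= min_cov` (default 2x, the customary screening point in this tool
family) are selected, and their representatives are concatenated into
the alignment target with contigs renamed `<species_id>|<contig_id>`.

# Single-sample SNV step

## Post-alignment filters

Alignment records (from the internal aligner or any SAM-producing
aligner) pass a fixed gauntlet, each record keeping the first reason it
fails for auditability:

| parameter            | default | meaning                                      |
|----------------------|---------|----------------------------------------------|
| `min_mapq`           | 10      | drops ambiguous placements (internal aligner reports ties as MAPQ 0) |
| `min_read_identity`  | 0.90    | `1 - NM / alignment columns`                 |
| `min_aln_cov`        | 0.75    | aligned read bases / read length             |
| `min_baseq`          | 30      | Phred floor per counted base                 |
| `require_proper_pair`| TRUE    | FR orientation, both mates mapped            |
| `max_template_len`   | 1000 bp | insert-size sanity bound                     |

These values follow the conventions of the MIDAS family of
metagenotypers; every one is exposed programmatically and on the command
line. A missing NM tag is recomputed from the MD tag (configurable to a
hard error instead).

## Paired-end fragment contract

The unit of evidence is the sequenced *fragment*, not the read: a
fragment may never contribute more than 1 to any site's depth. Where
mates overlap, an agreeing base is counted once at the higher of the two
qualities; a disagreement resolves to the higher-quality base; a
disagreement at equal quality contributes nothing (the sequencer has, in
effect, retracted its claim about that position). This is the concrete
mechanism by which paired-end information reduces false positives:
overlap positions are the positions with two physical observations of
the same molecule.

## Pileup and per-sample calls

Fragment bases with quality at or above `min_baseq` are tallied into
per-site A/C/G/T vectors; alignment columns carrying indels contribute
nothing (SNV-only scope). Sites outside `[min_depth, max_depth]`
(defaults 2 and 10000; the cap guards collapsed-repeat pileups — the
site is omitted, never truncated) are no-calls. At called sites the
major allele is the count argmax and the minor allele the second-largest
nonzero count, ties always to the lexicographically smallest base so
results are reproducible. The full count vector is retained: no
single-strain-per-sample assumption is made anywhere, which is what
keeps mixtures representable downstream.

Coordinates are 0-based half-open internally (chunks) and 1-based
inclusive in every TSV output, following the samtools pileup convention.

# Across-samples population SNVs

For each species, genomic sites are scanned once across all samples. A
site is *relevant* in a sample when its depth is at least
`site_min_depth` (default 5) and at most `site_max_depth_fold` (default
3) times that sample's species-wide mean depth — the upper bound again
guards repeats. Sites relevant in fewer than `min_sample_prevalence`
(default 0.8) of the samples are excluded from output.

Pooling supports two statistics, both defensible readings of
"population major allele", which differ under uneven depth:

* `"counts"` (default): argmax of allele counts summed over relevant
  samples — each read one vote;
* `"prevalence"`: argmax of the number of relevant samples in which the
  allele is the within-sample major — each sample one vote.

The pooled minor allele is the runner-up by the same statistic with
nonzero support; ties are lexicographic. The per-sample minor-allele
frequency matrix is reported for the pooled minor only; tri- and
quad-allelic sites are retained and labeled by allele class. An allele
counts toward the class only at pooled frequency `>= allele_min_freq`
(default 0.01): residual sequencing error after the q30 base filter sits
near 10^-3 per base, so without this floor a single erroneous read at a
deeply pooled site would promote a genuine bi-allelic SNV to
"tri-allelic". The 0.01 default sits an order of magnitude above that
error floor and well below any minor-allele frequency of interest
(the reporting threshold used in validation is 0.05).

## Chunked, order-independent merging

Contigs are tiled with half-open chunks of `chunk_size` sites (default
100000). Each chunk is processed into a self-contained accumulator —
no cross-chunk state exists — and accumulators are merged by sorted
concatenation after a disjointness check. The engineering contract,
verified byte-for-byte in the tests, is that the final output is
invariant to chunk size, to the number of workers, and to accumulator
arrival order. Workers are a forked pool (`parallel::mclapply`);
correctness never depends on the worker count.

# Gene copy numbers

Reads are aligned to the species' pangenome centroids; per-centroid
vertical coverage (mapped bases / centroid length, mate overlaps
deduplicated as above) is divided by the **same median marker coverage
the screen computed for that sample**, so numerator and denominator
share one depth scale and single-copy genes land near copy number 1.
The presence threshold defaults to 0.35 copies. Filters are the SNV
defaults minus the proper-pair requirement (a fragment straddling a gene
boundary legitimately has only one mate inside the centroid).

Two known biases are documented rather than corrected: reads are
assigned to centroids only, so near-identical centroids can cross-recruit;
and the full-read aligner does not place reads that overhang gene ends,
which depresses absolute coverage near boundaries. The second effect
cancels in the copy-number ratio because marker genes — the denominator —
are measured with exactly the same geometry. Because a single 300-bp gene
at 20x carries substantial counting noise (relative SD around 10%), the
bundled validation scenario averages copy numbers over 4 replicate
samples of the same strain.

# Strain mixtures

A sample dominated by one strain shows within-sample minor-allele
frequencies piled at 0; a two-strain mixture leaves a band of
intermediate frequencies at the strains' divergent sites. The statistic
used here — declared as this package's own operationalization, not an
implementation of any published method — is the fraction of *eligible*
sites (depth `>= min_site_depth`, default 10; monomorphic sites count
with frequency 0) whose minor-allele frequency falls in the inclusive
band `[0.10, 0.50]`. A sample is called a `mixture` when the fraction
reaches `cutoff`, `single_dominant` otherwise, and `insufficient_data`
below `min_sites` (default 100) eligible sites.

The cutoff default (0.002) comes from a pre-hoc binomial separation
argument. Background: under sequencing error `eps <= 0.001` surviving
the q30 filter, a site at depth ~20 needs two same-base errors to reach
minor frequency 0.10, so the per-site band probability is of order
1e-4 and the expected fraction sits near 1e-4 — an order of magnitude
below the cutoff. Signal: a mixture at minor proportion `p = 0.3` puts
a divergent site's minor count at Binomial(depth, 0.3), which lands in
the band with probability ~0.95 at depth 20, so between-strain
divergence `d` yields an expected fraction near `0.95 d` — at or above
the cutoff for every `d >= 0.25%`, with divergences of interest (0.5%
and up) clearing it several-fold. A cutoff of 0.01, by contrast, would
be unreachable for mixtures below 1% divergence regardless of depth, so
it would misclassify precisely the moderately diverged strain pairs the
statistic exists to flag. In addition, a site counts as intermediate
only when its minor allele is supported by at least `min_minor_count`
reads (default 2): a single read is indistinguishable from a sequencing
error, and at the depth floor one error read lands exactly on the band
edge (1/10 = 0.10), which would otherwise leak ~1% of low-depth
eligible sites into the band in perfectly clonal samples. Every
constant is exposed.

The statistic is symmetric in the mixing proportion (minor-allele
folding), rises monotonically with divergence, and carries no
information about *how many* strains are mixed — deconvolution and
phasing are out of scope.

# The simulator

`make_genome` draws i.i.d. bases at a requested GC content and places
non-overlapping 300-bp genes at regular spacing, the first 15 tagged
with the marker panel. `mutate_strain` substitutes sites independently
at a stated divergence (or plants an exact count), recording the exact
truth list. `plant_cnv` deletes a gene span or appends tandem duplicate
copies, remapping downstream coordinates. `simulate_reads` draws
`coverage x length / (2 x read_len)` fragments with uniform starts and
normal lengths, allocates them to strains multinomially by proportion x
length, flips read-1 strand with probability 1/2, applies i.i.d.
substitution errors at rate `eps`, and assigns the constant quality
`round(-10 log10 eps)`. Read ids encode strain, coordinates and strand,
so every read is traceable and `validate_reads` can re-extract all
error-free reads.

What the simulator deliberately does **not** emulate: quality decay
along the read, indel errors, GC-coverage bias, optical/PCR duplicates,
contamination, and adapter artefacts. Consequences for interpretation:
passing tests demonstrate the correctness of the pipeline's contracts
(counting, filtering, pooling, invariances) and its statistical
behaviour under the stated error model; they do not certify performance
on real instruments, where the indel and bias terms the simulator omits
are exactly what the MAPQ/identity/base-quality filters exist to absorb.
The constant-quality model also means the base-quality filter is
all-or-nothing per run: tests that exercise quality-dependent behaviour
construct per-base qualities directly.

# Numerical conventions and problem sizes

All randomness flows through explicit integer seeds (kept below 2^31);
derived seeds are affine functions of the scenario seed. Every sort has
a deterministic tie-break (lexicographic id after the primary key).
Frequencies in TSV output are fixed at four decimals; matrices use `NA`
for samples where a site was not relevant. Re-running any stage — or the
whole pipeline — on identical inputs rewrites identical bytes
(timestamps appear only in log messages on stderr).

The bundled validation scenarios use 5–10 kb genomes, 10–40 samples,
20x depth, 100 planted SNV sites, 0.5% strain divergence and error rate
10^-3. These sizes were chosen so each scenario isolates one claim with
comfortable statistical margins while remaining quick to run; the same
generators accept larger values unchanged.

# Known limitations

* The internal aligner is ungapped (seed-and-extend by Hamming
  distance): appropriate for the simulator's substitution-only regime
  and for intra-species short-read placement, but reads spanning indels
  or junctions are left unplaced. Externally produced SAM (e.g. from
  bowtie2; CIGARs with indels and clips are fully parsed) drops in at
  the same interface.
* Copy-number estimates inherit centroid cross-mapping and cannot
  resolve member-level (non-centroid) gene variation.
* The strain-mixture call is binary; it does not estimate strain count
  or proportions.
* No duplicate marking: simulated data has none, and real data is
  assumed deduplicated upstream.
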