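# Canonical simulation scenarios. Each function bundles one study design
# used to validate a pipeline stage — sample sizes, coverages, divergences
# and error rates are the scenario's defaults, not tuning knobs — and
# returns both the pipeline inputs and the planted truth needed to score
# the result. Tests and the acceptance script both run these.

#' Two-strain, multi-sample population-SNV cohort
#'
#' One species whose samples carry mixtures of a reference strain and a
#' derived strain with exactly `n_divergent_sites` planted substitutions;
#' mixing proportions vary across samples on an even grid. Each sample is
#' sequenced, aligned and piled up against the reference.
#'
#' @param seed integer seed.
#' @param n_samples number of samples.
#' @param genome_length,n_genes genome parameters.
#' @param n_divergent_sites planted divergent sites between the strains.
#' @param coverage per-sample depth (x).
#' @param error_rate per-base sequencing error.
#' @return list: `ref`, `strain` (mutated sequence + truth SNVs),
#'   `proportions`, `pileups` (named list of per-sample pileup
#'   data.frames), `contigs`, `target`.
#' @export
sim_two_strain_cohort <- function(seed = 1L, n_samples = 10L,
                                  genome_length = 10000L, n_genes = 30L,
                                  n_divergent_sites = 100L, coverage = 20,
                                  error_rate = 0.001) {
  ref <- make_genome(genome_length, n_genes = n_genes, seed = sub_seed(seed, 1L))
  mut <- mutate_strain(ref$seq, n_sites = n_divergent_sites,
                       seed = sub_seed(seed, 2L))
  proportions <- seq(0.1, 0.9, length.out = n_samples)
  target <- stats::setNames(ref$seq, "sp01|c1")
  pileups <- list()
  for (i in seq_len(n_samples)) {
    sim <- simulate_reads(list(
      list(strain_id = "A", seq = ref$seq, proportion = 1 - proportions[i]),
      list(strain_id = "B", seq = mut$seq, proportion = proportions[i])),
      coverage = coverage, error_rate = error_rate,
      seed = sub_seed(seed, 10L + i))
    res <- snv_single_sample(sim$r1, sim$r2, target)
    pileups[[sprintf("sample%02d", i)]] <- res$sp01$pileup
  }
  list(ref = ref, strain = mut, proportions = proportions, pileups = pileups,
       contigs = data.frame(species_id = "sp01", contig_id = "c1",
                            length = genome_length, stringsAsFactors = FALSE),
       target = target)
}

#' Aliquot pair: same community, independent read draws
#'
#' Two read sets simulated from the same two-species community (exact
#' reference genomes, no strain divergence) with different read seeds,
#' each aligned and piled up against the exact source genomes. Any
#' consensus-allele difference between the aliquots at well-covered sites
#' is a false positive.
#'
#' @param seed integer seed.
#' @param genome_length genome length per species.
#' @param coverage per-species depth (x); the two species contribute
#'   equally to the community.
#' @param error_rate per-base sequencing error.
#' @return list: `pileups` (two named pileup sets), `target`, `contigs`.
#' @export
sim_aliquot_pair <- function(seed = 1L, genome_length = 10000L, coverage = 20,
                             error_rate = 0.001) {
  gA <- make_genome(genome_length, n_genes = 30L, seed = sub_seed(seed, 1L))
  gB <- make_genome(genome_length, n_genes = 30L, seed = sub_seed(seed, 2L))
  target <- stats::setNames(c(gA$seq, gB$seq), c("spA|c1", "spB|c1"))
  community <- list(list(strain_id = "spA", seq = gA$seq, proportion = 0.5),
                    list(strain_id = "spB", seq = gB$seq, proportion = 0.5))
  pileups <- list()
  for (i in 1:2) {
    sim <- simulate_reads(community, coverage = 2 * coverage,
                          error_rate = error_rate,
                          seed = sub_seed(seed, 10L + i))
    res <- snv_single_sample(sim$r1, sim$r2, target)
    pileups[[paste0("aliquot", i)]] <-
      do.call(rbind, lapply(res, `[[`, "pileup"))
  }
  list(pileups = pileups, target = target,
       contigs = data.frame(species_id = c("spA", "spB"), contig_id = "c1",
                            length = genome_length, stringsAsFactors = FALSE))
}

#' Labeled strain-mixture detection panel
#'
#' One species; half the samples carry a single strain (itself diverged
#' from the reference, so reference divergence cannot masquerade as a
#' mixture signal) and half carry a 30/70 two-strain mixture at the given
#' between-strain divergence. Pileups are taken against the reference.
#'
#' @param seed integer seed.
#' @param n_single,n_mixed panel sizes.
#' @param genome_length,n_genes genome parameters.
#' @param divergence between-strain (and strain-to-reference) divergence.
#' @param mix_prop minor-strain proportion in mixed samples.
#' @param coverage per-sample depth (x).
#' @param error_rate per-base sequencing error.
#' @return list: `pileups` (named list), `labels` (named character,
#'   "single" or "mixture").
#' @export
sim_mixture_panel <- function(seed = 1L, n_single = 20L, n_mixed = 20L,
                              genome_length = 5000L, n_genes = 15L,
                              divergence = 0.005, mix_prop = 0.3,
                              coverage = 20, error_rate = 0.001) {
  ref <- make_genome(genome_length, n_genes = n_genes, seed = sub_seed(seed, 1L))
  target <- stats::setNames(ref$seq, "sp01|c1")
  pileups <- list()
  labels <- character(0)
  n <- n_single + n_mixed
  for (i in seq_len(n)) {
    mixed <- i > n_single
    sA <- mutate_strain(ref$seq, divergence = divergence,
                        seed = sub_seed(seed, 100L + i))
    strains <- if (mixed) {
      sB <- mutate_strain(sA$seq, divergence = divergence,
                          seed = sub_seed(seed, 200L + i))
      list(list(strain_id = "A", seq = sA$seq, proportion = 1 - mix_prop),
           list(strain_id = "B", seq = sB$seq, proportion = mix_prop))
    } else {
      list(list(strain_id = "A", seq = sA$seq, proportion = 1))
    }
    sim <- simulate_reads(strains, coverage = coverage,
                          error_rate = error_rate,
                          seed = sub_seed(seed, 300L + i))
    res <- snv_single_sample(sim$r1, sim$r2, target)
    sid <- sprintf("panel%02d", i)
    pileups[[sid]] <- res$sp01$pileup
    labels[sid] <- if (mixed) "mixture" else "single"
  }
  list(pileups = pileups, labels = labels)
}

#' Planted gene duplication and deletion scenario
#'
#' One species whose sequenced strain carries a tandem duplication
#' (2 copies) of one gene and a deletion of another. Several replicate
#' samples are sequenced at the same depth; each is screened for marker
#' coverage and its reads aligned to the pangenome centroids (here the
#' reference's genes). Copy numbers are averaged over replicates.
#'
#' @param seed integer seed.
#' @param n_replicates replicate samples.
#' @param genome_length,n_genes genome parameters.
#' @param dup_gene,del_gene gene ids to duplicate/delete.
#' @param coverage per-sample depth (x).
#' @param error_rate per-base sequencing error.
#' @return list: `copy_number` (per-gene mean over replicates, data.frame
#'   gene_id/copy_number/present), `dup_gene`, `del_gene`, `per_replicate`
#'   (list of full tables).
#' @export
sim_cnv_scenario <- function(seed = 1L, n_replicates = 4L,
                             genome_length = 10000L, n_genes = 30L,
                             dup_gene = "g020", del_gene = "g025",
                             coverage = 20, error_rate = 0.001) {
  ref <- make_genome(genome_length, n_genes = n_genes, seed = sub_seed(seed, 1L))
  p1 <- plant_cnv(ref$seq, ref$genes, dup_gene, 2L)
  p2 <- plant_cnv(p1$seq, p1$genes, del_gene, 0L)
  gene_seqs <- substring(ref$seq, ref$genes$start, ref$genes$end)
  centroids <- stats::setNames(gene_seqs, ref$genes$gene_id)
  is_marker <- !is.na(ref$genes$marker_family)
  markers <- data.frame(species_id = "sp01",
                        marker_family = ref$genes$marker_family[is_marker],
                        gene_id = ref$genes$gene_id[is_marker],
                        length = nchar(gene_seqs[is_marker]),
                        sequence = gene_seqs[is_marker],
                        stringsAsFactors = FALSE)
  per_replicate <- list()
  for (r in seq_len(n_replicates)) {
    sim <- simulate_reads(list(list(strain_id = "S", seq = p2$seq,
                                    proportion = 1)),
                          coverage = coverage, error_rate = error_rate,
                          seed = sub_seed(seed, 50L + r))
    hits <- map_to_markers(sim$r1, sim$r2, markers)
    prof <- profile_species(hits, markers)
    aln <- align_to_target(sim$r1, sim$r2, centroids)
    cov <- gene_coverage(aln, centroids)
    per_replicate[[r]] <- estimate_copy_number(
      cov, prof$median_marker_coverage[prof$species_id == "sp01"])
  }
  cn <- rowMeans(do.call(cbind, lapply(per_replicate, `[[`, "copy_number")))
  list(copy_number = data.frame(gene_id = per_replicate[[1L]]$gene_id,
                                copy_number = cn,
                                present = cn >= 0.35, stringsAsFactors = FALSE),
       dup_gene = dup_gene, del_gene = del_gene,
       per_replicate = per_replicate)
}

#' Three-species screening scenario
#'
#' A three-species database; the sample contains reads from the first two
#' species at high and low depth and none from the third.
#'
#' @param seed integer seed.
#' @param coverages per-species depths (x); third entry is 0.
#' @param genome_length genome length per species.
#' @return list: `db`, `profile`, `selected` (at the default 2x
#'   threshold), `coverages`, `reads` (r1/r2 data.frames).
#' @export
sim_screen_scenario <- function(seed = 1L, coverages = c(20, 5, 0),
                                genome_length = 10000L) {
  stopifnot(length(coverages) == 3L)
  dir <- tempfile("screen_collection")
  col <- sim_collection(dir, n_species = 3L, genomes_per_species = 1L,
                        genome_length = genome_length, seed = sub_seed(seed, 1L))
  db <- build_db(parse_toc(col$toc), out_dir = tempfile("screen_db"))
  r1 <- NULL; r2 <- NULL
  for (i in 1:3) {
    if (coverages[i] <= 0) next
    sp <- sprintf("s%02d", i)
    sim <- simulate_reads(list(list(strain_id = sp, seq = col$truth[[sp]]$seq,
                                    proportion = 1)),
                          coverage = coverages[i], error_rate = 0.001,
                          seed = sub_seed(seed, 10L + i))
    r1 <- rbind(r1, sim$r1); r2 <- rbind(r2, sim$r2)
  }
  prof <- screen_sample(r1, r2, db)
  list(db = db, profile = prof, selected = select_species(prof, 2.0),
       coverages = coverages, reads = list(r1 = r1, r2 = r2))
}
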