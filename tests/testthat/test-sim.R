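# The simulator itself: determinism, planted-truth exactness, the error
# model's calibration, and read provenance.

test_that("genomes are reproducible and carry the planted gene layout", {
  g1 <- make_genome(20000, n_genes = 30, seed = 1)
  g2 <- make_genome(20000, n_genes = 30, seed = 1)
  expect_identical(g1, g2)
  expect_identical(nrow(g1$genes), 30L)
  expect_identical(g1$genes$end - g1$genes$start + 1L, rep(300L, 30))
  expect_identical(g1$genes$marker_family[1:15], marker_panel())
  expect_true(all(is.na(g1$genes$marker_family[16:30])))
  # genes do not overlap
  expect_true(all(diff(g1$genes$start) >= 300L))
})

test_that("genome GC content matches the request within 3 binomial SDs", {
  L <- 100000
  g <- make_genome(L, gc = 0.5, n_genes = 0, seed = 2)
  gc <- sum(strsplit(g$seq, "")[[1]] %in% c("G", "C")) / L
  expect_lt(abs(gc - 0.5), 3 * sqrt(0.25 / L))
  g <- make_genome(L, gc = 0.3, n_genes = 0, seed = 3)
  gc <- sum(strsplit(g$seq, "")[[1]] %in% c("G", "C")) / L
  expect_lt(abs(gc - 0.3), 3 * sqrt(0.3 * 0.7 / L))
})

test_that("a zero-gene genome is a valid FASTA with empty annotation", {
  g <- make_genome(1000, n_genes = 0, seed = 4)
  expect_identical(nchar(g$seq), 1000L)
  expect_identical(nrow(g$genes), 0L)
})

test_that("infeasible gene packing is rejected", {
  expect_error(make_genome(3000, n_genes = 30, seed = 1), "infeasible packing")
})

test_that("strain mutation: truth list is exact and seed-stable", {
  g <- make_genome(10000, n_genes = 0, seed = 5)
  m0 <- mutate_strain(g$seq, divergence = 0, seed = 6)
  expect_identical(m0$seq, g$seq)
  expect_identical(nrow(m0$snvs), 0L)

  m1 <- mutate_strain(g$seq, divergence = 0.01, seed = 7)
  m2 <- mutate_strain(g$seq, divergence = 0.01, seed = 7)
  expect_identical(m1, m2)
  # binomial count: |truth| within 3 SDs of L * divergence
  expect_lt(abs(nrow(m1$snvs) - 100), 3 * sqrt(10000 * 0.01 * 0.99))
  # truth entries are exact substitutions
  expect_true(all(substring(g$seq, m1$snvs$pos, m1$snvs$pos) == m1$snvs$ref))
  expect_true(all(substring(m1$seq, m1$snvs$pos, m1$snvs$pos) == m1$snvs$alt))
  expect_true(all(m1$snvs$ref != m1$snvs$alt))
  # exact-count planting
  me <- mutate_strain(g$seq, n_sites = 42, seed = 8)
  expect_identical(nrow(me$snvs), 42L)
  expect_identical(anyDuplicated(me$snvs$pos), 0L)
})

test_that("planted CNVs change genome length and remap coordinates", {
  g <- make_genome(10000, n_genes = 30, seed = 9)
  mut <- mutate_strain(g$seq, n_sites = 20, seed = 10)
  snvs <- mut$snvs
  dup <- plant_cnv(mut$seq, g$genes, "g010", 2, snvs = snvs)
  expect_identical(nchar(dup$seq), 10300L)
  del <- plant_cnv(mut$seq, g$genes, "g010", 0, snvs = snvs)
  expect_identical(nchar(del$seq), 9700L)
  expect_false("g010" %in% del$genes$gene_id)
  tri <- plant_cnv(mut$seq, g$genes, "g010", 3)
  expect_identical(nchar(tri$seq), 10600L)

  # downstream genes shift; upstream genes do not
  i <- match("g010", g$genes$gene_id)
  expect_identical(dup$genes$start[i + 1], g$genes$start[i + 1] + 300L)
  expect_identical(dup$genes$start[i - 1], g$genes$start[i - 1])
  # remapped SNVs still describe the modified genome
  expect_true(all(substring(dup$seq, dup$snvs$pos, dup$snvs$pos) == dup$snvs$alt))
  # deletion drops SNVs inside the deleted span
  gspan <- g$genes[i, ]
  inside <- snvs$pos >= gspan$start & snvs$pos <= gspan$end
  expect_identical(nrow(del$snvs), sum(!inside))
  expect_true(all(substring(del$seq, del$snvs$pos, del$snvs$pos) == del$snvs$alt))

  # duplicated copy is tandem and identical
  gene_seq <- substring(mut$seq, gspan$start, gspan$end)
  expect_identical(substring(dup$seq, gspan$end + 1, gspan$end + 300), gene_seq)

  # overlapping planted events are rejected
  expect_error(plant_cnv(dup$seq, dup$genes, "g010", 0),
               "overlapping planted events")
})

test_that("error-free reads are exact substrings, fully traceable", {
  g <- make_genome(10000, n_genes = 0, seed = 11)
  strains <- list(list(strain_id = "ref", seq = g$seq, proportion = 1))
  sim <- simulate_reads(strains, coverage = 20, error_rate = 0, seed = 12)
  # fragment count formula: coverage * L / (2 * read_len)
  expect_identical(nrow(sim$r1), 1000L)
  expect_identical(sim$r1$id, sim$r2$id)
  expect_identical(sim$quality, 40L)
  expect_identical(validate_reads(sim, strains), 1)
  # determinism
  sim2 <- simulate_reads(strains, coverage = 20, error_rate = 0, seed = 12)
  expect_identical(sim, sim2)
})

test_that("the realized base-error rate matches epsilon within 3 SDs", {
  g <- make_genome(10000, n_genes = 0, seed = 13)
  strains <- list(list(strain_id = "ref", seq = g$seq, proportion = 1))
  sim <- simulate_reads(strains, coverage = 50, error_rate = 0.001, seed = 14)
  n_bases <- sum(nchar(sim$r1$seq)) + sum(nchar(sim$r2$seq))
  expect_gte(n_bases, 5e5)
  expect_identical(sim$quality, 30L)
  # count mismatches against the traced source coordinates
  fr <- sim$fragments
  fwd <- substring(g$seq, fr$start, fr$start + 99)
  rev <- revcomp(substring(g$seq, fr$end - 99, fr$end))
  exp_r1 <- ifelse(fr$r1_strand == "+", fwd, rev)
  exp_r2 <- ifelse(fr$r1_strand == "+", rev, fwd)
  mm <- sum(vapply(seq_len(nrow(fr)), function(i) {
    sum(charToRaw(sim$r1$seq[i]) != charToRaw(exp_r1[i])) +
      sum(charToRaw(sim$r2$seq[i]) != charToRaw(exp_r2[i]))
  }, numeric(1)))
  rate <- mm / n_bases
  expect_lt(abs(rate - 0.001), 3 * sqrt(0.001 / n_bases))
})

test_that("realized strain composition converges to requested proportions", {
  g <- make_genome(10000, n_genes = 0, seed = 15)
  m <- mutate_strain(g$seq, divergence = 0.01, seed = 16)
  strains <- list(list(strain_id = "A", seq = g$seq, proportion = 0.8),
                  list(strain_id = "B", seq = m$seq, proportion = 0.2))
  sim <- simulate_reads(strains, coverage = 40, error_rate = 0, seed = 17)
  n <- nrow(sim$fragments)
  fA <- mean(sim$fragments$strain_id == "A")
  expect_lt(abs(fA - 0.8), 3 * sqrt(0.8 * 0.2 / n))
})

test_that("simulated collections land on disk deterministically", {
  d1 <- sim_collection(withr::local_tempdir(), n_species = 1,
                       genome_length = 5000, n_genes = 15, seed = 18)
  d2 <- sim_collection(withr::local_tempdir(), n_species = 1,
                       genome_length = 5000, n_genes = 15, seed = 18)
  t1 <- read_fasta(parse_toc(d1$toc)$records$genome_path[1])
  t2 <- read_fasta(parse_toc(d2$toc)$records$genome_path[1])
  expect_identical(as.character(t1), as.character(t2))
  expect_identical(d1$truth$s01$seq, d2$truth$s01$seq)
})
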