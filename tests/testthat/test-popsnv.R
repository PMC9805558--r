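# Across-samples pooling: chunking, site relevance, pooling (against an
# explicit oracle), chunk-invariant merging and the conservation and
# monotonicity properties.

test_that("chunks tile contigs exactly with half-open intervals", {
  contigs <- data.frame(species_id = "s", contig_id = "c", length = 10L)
  ch <- make_chunks(contigs, 4L)
  expect_identical(ch$start, c(0L, 4L, 8L))
  expect_identical(ch$end, c(4L, 8L, 10L))
  # chunk size >= L: one chunk
  ch <- make_chunks(contigs, 50L)
  expect_identical(nrow(ch), 1L)
  expect_identical(ch$end - ch$start, 10L)
  # partition property over several sizes and contigs
  contigs <- data.frame(species_id = c("s", "s"), contig_id = c("c1", "c2"),
                        length = c(1037L, 250L))
  for (cs in c(1L, 7L, 100L, 5000L)) {
    ch <- make_chunks(contigs, cs)
    expect_identical(sum(ch$end - ch$start), 1287L)
    expect_true(all(ch$end > ch$start))
  }
})

test_that("site relevance applies depth floor and repeat guard", {
  f <- site_filters(site_min_depth = 5L, site_max_depth_fold = 3)
  expect_true(site_relevance(10L, 10, f))
  expect_false(site_relevance(100L, 10, f))    # 100 > 3 * 10
  expect_false(site_relevance(4L, 10, f))      # below floor
  expect_false(site_relevance(10L, 0, f))      # no coverage: mean 0
  expect_identical(site_relevance(c(5L, 31L, 30L), 10, f),
                   c(TRUE, FALSE, TRUE))
})

test_that("pooling follows the spec examples", {
  cnt <- rbind(c(9, 1, 0, 0), c(8, 2, 0, 0))
  p <- pool_site(cnt, method = "counts")
  expect_identical(p$pooled_major, "A")
  expect_identical(p$pooled_minor, "C")
  expect_equal(unname(p$pooled_counts), c(17, 3, 0, 0))
  # majority-vote pooling: majors A, A, C -> pooled major A
  cnt <- rbind(c(9, 1, 0, 0), c(7, 3, 0, 0), c(2, 8, 0, 0))
  p <- pool_site(cnt, method = "prevalence")
  expect_identical(p$pooled_major, "A")
  expect_identical(p$pooled_minor, "C")
  # lexicographic ties
  p <- pool_site(rbind(c(5, 5, 0, 0)), method = "counts")
  expect_identical(p$pooled_major, "A")
  expect_identical(p$pooled_minor, "C")
  # monomorphic site has no minor
  p <- pool_site(rbind(c(5, 0, 0, 0)), method = "counts")
  expect_true(is.na(p$pooled_minor))
})

test_that("pooling matches the explicit brute-force oracle on random sites", {
  for (seed in 201:205) {
    cnt <- withr::with_seed(seed, matrix(rpois(20, 4), 5, 4))
    for (m in c("counts", "prevalence")) {
      p <- pool_site(cnt, method = m)
      o <- oracle_pool(cnt, m)
      expect_identical(p$pooled_major, o$major, info = paste(seed, m))
      expect_identical(p$pooled_minor, o$minor, info = paste(seed, m))
    }
  }
})

# small synthetic pileup set used by several blocks below
toy_pileups <- function(n_samples = 4L, L = 200L, seed = 210L) {
  g <- make_genome(L, n_genes = 0, seed = seed)
  m <- mutate_strain(g$seq, n_sites = 8L, seed = seed + 1L)
  target <- stats::setNames(g$seq, "sp|c1")
  pus <- list()
  for (i in seq_len(n_samples)) {
    sim <- simulate_reads(list(
      list(strain_id = "A", seq = g$seq, proportion = 0.5),
      list(strain_id = "B", seq = m$seq, proportion = 0.5)),
      coverage = 20, error_rate = 0, seed = seed + 10L + i)
    pus[[paste0("s", i)]] <- snv_single_sample(sim$r1, sim$r2, target)$sp$pileup
  }
  list(pileups = pus, truth = m$snvs,
       contigs = data.frame(species_id = "sp", contig_id = "c1", length = L,
                            stringsAsFactors = FALSE))
}

test_that("prevalence filtering excludes sites covered in too few samples", {
  tp <- toy_pileups()
  # drop one sample's coverage of the first half of the contig
  tp$pileups$s1 <- tp$pileups$s1[tp$pileups$s1$pos > 100, ]
  full <- snv_merge(tp$pileups, tp$contigs,
                    site_filters(min_sample_prevalence = 1.0))
  part <- snv_merge(tp$pileups, tp$contigs,
                    site_filters(min_sample_prevalence = 0.75))
  expect_true(all(full$info$position > 100))
  expect_gt(sum(part$info$position <= 100), 0)
  # prevalence monotonicity: raising the threshold never adds sites
  key <- function(x) paste(x$info$contig_id, x$info$position)
  expect_true(all(key(full) %in% key(part)))
  expect_true(all(full$info$n_relevant_samples >= 4L))
})

test_that("pooled counts conserve per-sample depths", {
  tp <- toy_pileups()
  res <- snv_merge(tp$pileups, tp$contigs)
  pooled <- res$info$pooled_count_A + res$info$pooled_count_C +
    res$info$pooled_count_G + res$info$pooled_count_T
  expect_equal(pooled, res$info$pooled_depth)
  expect_equal(res$info$pooled_depth,
               rowSums(as.matrix(res$depth), na.rm = TRUE))
})

test_that("merge output is invariant to chunk size, workers and order", {
  tp <- toy_pileups()
  base <- snv_merge(tp$pileups, tp$contigs, chunk_size = 100000L)
  for (cs in c(1L, 7L, 64L)) {
    alt <- snv_merge(tp$pileups, tp$contigs, chunk_size = cs)
    expect_identical(alt, base, info = paste("chunk_size", cs))
  }
  w2 <- snv_merge(tp$pileups, tp$contigs, chunk_size = 7L, workers = 2L)
  expect_identical(w2, base)
  # reversed accumulator order merges identically
  mats <- metagenotyper:::build_pileup_mats(tp$pileups, tp$contigs)
  chunks <- make_chunks(tp$contigs, 13L)
  accs <- lapply(split(chunks, chunks$chunk_id), process_chunk, pileups = mats)
  expect_identical(merge_chunks(rev(accs)), merge_chunks(accs))
})

test_that("overlapping chunk accumulators are rejected", {
  tp <- toy_pileups()
  mats <- metagenotyper:::build_pileup_mats(tp$pileups, tp$contigs)
  c1 <- process_chunk(list(chunk_id = 1L, species_id = "sp", contig_id = "c1",
                           start = 0L, end = 100L), mats)
  c2 <- process_chunk(list(chunk_id = 2L, species_id = "sp", contig_id = "c1",
                           start = 50L, end = 150L), mats)
  expect_error(merge_chunks(list(c1, c2)), "overlapping chunks")
})

test_that("an empty accumulator set merges to well-formed empty output", {
  res <- merge_chunks(list())
  expect_s3_class(res, "mgt_popsnv")
  expect_identical(nrow(res$info), 0L)
  d <- tempfile()
  write_snv_matrices(res, d)
  expect_true(dir.exists(d))
})

test_that("unsorted pileup input is reported with sample and position", {
  tp <- toy_pileups(n_samples = 2L)
  bad <- tp$pileups
  bad$s1 <- bad$s1[c(2, 1, 3:nrow(bad$s1)), ]
  expect_error(snv_merge(bad, tp$contigs), "sample s1 is not position-sorted")
})

test_that("planted strain sites surface as bi-allelic pooled SNVs", {
  tp <- toy_pileups()
  res <- snv_merge(tp$pileups, tp$contigs)
  called <- res$info[res$info$allele_class == "bi" &
                       res$info$pooled_minor_freq >= 0.05, ]
  # 50/50 mixtures at 20x, no errors: every covered planted site must appear
  covered <- tp$truth$pos[tp$truth$pos %in% res$info$position]
  expect_true(all(covered %in% called$position))
  # and the pooled minor allele is the planted alternative
  hit <- called[match(covered, called$position), ]
  truth <- tp$truth[match(covered, tp$truth$pos), ]
  expect_true(all(hit$pooled_minor == truth$alt | hit$pooled_major == truth$alt))
})

test_that("count and prevalence pooling may disagree only in the statistic", {
  tp <- toy_pileups()
  a <- snv_merge(tp$pileups, tp$contigs, method = "counts")
  b <- snv_merge(tp$pileups, tp$contigs, method = "prevalence")
  expect_identical(a$info$position, b$info$position)
  expect_identical(a$depth, b$depth)
})
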