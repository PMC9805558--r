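# Database construction: TOC parsing and validation, marker extraction,
# greedy pangenome clustering (checked against an independent oracle) and
# deterministic database builds.

write_toy_genome <- function(dir, gid, seed, markers = character(0)) {
  genome <- file.path(dir, paste0(gid, ".fa"))
  genes <- file.path(dir, paste0(gid, ".genes.fa"))
  writeLines(c(paste0(">", gid, "_c1"), rand_dna(500, seed)), genome)
  lines <- character(0)
  fams <- c(markers, rep(NA, max(0, 2 - length(markers))))
  for (i in seq_along(fams)) {
    hdr <- sprintf(">%s_g%02d", gid, i)
    if (!is.na(fams[i])) hdr <- paste0(hdr, " marker_family=", fams[i])
    lines <- c(lines, hdr, rand_dna(120, seed * 100 + i))
  }
  writeLines(lines, genes)
  c(genome = genome, genes = genes)
}

write_toy_toc <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  df <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  utils::write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  f
}

test_that("a valid TOC parses into a collection; invariants are enforced", {
  d <- withr::local_tempdir()
  g1 <- write_toy_genome(d, "s1.1", 1)
  g2 <- write_toy_genome(d, "s1.2", 2)
  g3 <- write_toy_genome(d, "s2.1", 3)
  row <- function(gid, sp, rep, paths) {
    list(genome_id = gid, species_id = sp, is_representative = rep,
         genome_path = paths[["genome"]], genes_path = paths[["genes"]])
  }
  toc <- write_toy_toc(list(row("s1.1", "s1", TRUE, g1),
                            row("s1.2", "s1", FALSE, g2),
                            row("s2.1", "s2", TRUE, g3)))
  coll <- parse_toc(toc)
  expect_s3_class(coll, "genome_collection")
  expect_identical(coll$species, c("s1", "s2"))
  expect_identical(nrow(coll$records), 3L)

  # two representatives for one species
  bad <- write_toy_toc(list(row("s1.1", "s1", TRUE, g1),
                            row("s1.2", "s1", TRUE, g2)))
  expect_error(parse_toc(bad), "s1 has 2 representative")
  # zero representatives
  bad <- write_toy_toc(list(row("s1.1", "s1", FALSE, g1)))
  expect_error(parse_toc(bad), "s1 has 0 representative")
  # duplicate genome id
  bad <- write_toy_toc(list(row("s1.1", "s1", TRUE, g1),
                            row("s1.1", "s2", TRUE, g2)))
  expect_error(parse_toc(bad), "duplicate genome_id.*s1\\.1")
  # missing referenced file
  gone <- g1; gone[["genome"]] <- file.path(d, "nope.fa")
  bad <- write_toy_toc(list(row("s1.1", "s1", TRUE, gone)))
  expect_error(parse_toc(bad), "nope\\.fa")
})

test_that("a header-only TOC yields an empty collection", {
  f <- tempfile(fileext = ".tsv")
  writeLines("genome_id\tspecies_id\tis_representative\tgenome_path\tgenes_path", f)
  coll <- parse_toc(f)
  expect_identical(length(coll$species), 0L)
  expect_identical(nrow(coll$records), 0L)
})

test_that("marker extraction filters by tag and enforces single copy", {
  d <- withr::local_tempdir()
  g1 <- write_toy_genome(d, "s1.1", 11, markers = c("B000032", "B000039"))
  toc <- write_toy_toc(list(list(genome_id = "s1.1", species_id = "s1",
                                 is_representative = TRUE,
                                 genome_path = g1[["genome"]],
                                 genes_path = g1[["genes"]])))
  mk <- extract_markers(parse_toc(toc))
  expect_identical(nrow(mk), 2L)
  expect_identical(mk$marker_family, c("B000032", "B000039"))
  expect_identical(mk$length, nchar(mk$sequence))

  # untagged representative: no markers, but permitted (with a message)
  g2 <- write_toy_genome(d, "s2.1", 12)
  toc <- write_toy_toc(list(list(genome_id = "s2.1", species_id = "s2",
                                 is_representative = TRUE,
                                 genome_path = g2[["genome"]],
                                 genes_path = g2[["genes"]])))
  expect_message(mk <- extract_markers(parse_toc(toc)), "unscreenable")
  expect_identical(nrow(mk), 0L)

  # duplicated family on one representative violates single-copy
  g3genes <- file.path(d, "s3.genes.fa")
  writeLines(c(">s3_g1 marker_family=B000032", rand_dna(120, 31),
               ">s3_g2 marker_family=B000032", rand_dna(120, 32)), g3genes)
  g3 <- write_toy_genome(d, "s3.1", 13)
  toc <- write_toy_toc(list(list(genome_id = "s3.1", species_id = "s3",
                                 is_representative = TRUE,
                                 genome_path = g3[["genome"]],
                                 genes_path = g3genes)))
  expect_error(extract_markers(parse_toc(toc)), "s3.*B000032.*single-copy")
})

test_that("simulated collection has the full planted marker complement", {
  coll <- parse_toc(fx_collection()$toc)
  mk <- extract_markers(coll)
  expect_identical(nrow(mk), 15L * 3L)
  expect_identical(sort(unique(mk$marker_family)), sort(marker_panel()))
})

test_that("greedy clustering handles the trivial identity cases", {
  s <- rand_dna(300, 21)
  # identical pair -> one cluster with 2 members
  cl <- build_pangenome(data.frame(gene_id = c("a", "b"),
                                   sequence = c(s, s)), 0.95)
  expect_length(cl, 1L)
  expect_setequal(cl[[1]]$member_gene_ids, c("a", "b"))
  expect_true(cl[[1]]$centroid_gene_id %in% cl[[1]]$member_gene_ids)
  # unrelated pair -> two singletons
  cl <- build_pangenome(data.frame(gene_id = c("a", "b"),
                                   sequence = c(s, rand_dna(300, 22))), 0.95)
  expect_length(cl, 2L)
})

test_that("five 99%-identity pairs at 50% cross-identity give 5 clusters of 2", {
  genes <- NULL
  withr::with_seed(40, {
    for (p in 1:5) {
      base <- rand_dna(300, 400 + p)
      mutp <- mutate_strain(base, n_sites = 3, seed = 500 + p)$seq
      genes <- rbind(genes, data.frame(
        gene_id = sprintf("p%d_%s", p, c("x", "y")),
        sequence = c(base, mutp), stringsAsFactors = FALSE))
    }
  })
  cl <- build_pangenome(genes, 0.95)
  expect_length(cl, 5L)
  expect_true(all(lengths(lapply(cl, `[[`, "member_gene_ids")) == 2L))
  # matches the independent all-pairs greedy oracle
  oracle <- oracle_greedy_cluster(genes, 0.95)
  expect_identical(lapply(cl, `[[`, "member_gene_ids"),
                   lapply(oracle, `[[`, "member_gene_ids"))
})

test_that("clustering agrees with the brute-force oracle on random sets", {
  for (seed in c(61, 62)) {
    genes <- NULL
    withr::with_seed(seed, {
      n_fam <- sample(3:5, 1)
      k <- 0
      for (fmly in seq_len(n_fam)) {
        base <- rand_dna(sample(250:350, 1), seed * 10 + fmly)
        for (m in seq_len(sample(1:4, 1))) {
          k <- k + 1
          sq <- if (m == 1) base else
            mutate_strain(base, divergence = sample(c(0.01, 0.03, 0.08), 1),
                          seed = seed * 100 + k)$seq
          genes <- rbind(genes, data.frame(
            gene_id = sprintf("g%02d", k), sequence = sq,
            stringsAsFactors = FALSE))
        }
      }
    })
    cl <- build_pangenome(genes, 0.95)
    oracle <- oracle_greedy_cluster(genes, 0.95)
    expect_identical(lapply(cl, `[[`, "member_gene_ids"),
                     lapply(oracle, `[[`, "member_gene_ids"),
                     info = paste("seed", seed))
    # partition property
    members <- unlist(lapply(cl, `[[`, "member_gene_ids"))
    expect_setequal(members, genes$gene_id)
    expect_identical(anyDuplicated(members), 0L)
    # centroid is the longest member (ties by id)
    for (c1 in cl) {
      lens <- nchar(genes$sequence[match(c1$member_gene_ids, genes$gene_id)])
      expect_identical(nchar(c1$centroid_sequence), max(lens))
    }
  }
})

test_that("database build is complete and byte-deterministic", {
  db <- fx_db()
  expect_identical(nrow(db$manifest), 3L)
  expect_identical(db$manifest$n_genomes, rep(2L, 3))
  expect_identical(db$manifest$n_markers, rep(15L, 3))
  expect_true(all(db$manifest$n_centroids >= 30L))
  expect_setequal(names(db$representatives), db$manifest$species_id)
  expect_setequal(names(db$pangenomes), db$manifest$species_id)
  # rebuild from the same inputs: identical checksums
  db2 <- build_db(parse_toc(fx_collection()$toc), out_dir = tempfile("fxdb2"))
  expect_identical(db$manifest[, c("rep_md5", "centroids_md5", "markers_md5")],
                   db2$manifest[, c("rep_md5", "centroids_md5", "markers_md5")])
})

test_that("every cluster member re-aligns to its centroid above threshold", {
  db <- fx_db()
  coll <- fx_collection()
  # check one species' clusters by re-alignment
  genes <- NULL
  rec <- parse_toc(coll$toc)$records
  for (p in rec$genes_path[rec$species_id == "s01"]) {
    g <- read_fasta(p)
    genes <- rbind(genes, data.frame(gene_id = names(g),
                                     sequence = unname(as.character(g)),
                                     stringsAsFactors = FALSE))
  }
  for (cl in db$pangenomes[["s01"]]) {
    for (m in cl$member_gene_ids) {
      sq <- genes$sequence[genes$gene_id == m]
      expect_gte(oracle_identity(sq, cl$centroid_sequence), 0.95)
    }
  }
})

test_that("a single-genome species database reduces to that genome", {
  d <- withr::local_tempdir()
  col <- sim_collection(d, n_species = 1, genomes_per_species = 1,
                        genome_length = 5000, n_genes = 15, seed = 99)
  db <- build_db(parse_toc(col$toc), out_dir = file.path(d, "db"))
  expect_identical(db$manifest$n_centroids, 15L)
  rep_seq <- read_fasta(db$representatives[["s01"]])
  expect_identical(unname(as.character(rep_seq)), col$truth$s01$seq)
})

test_that("load_db restores a built database and verifies checksums", {
  d <- withr::local_tempdir()
  col <- sim_collection(d, n_species = 2, genomes_per_species = 1,
                        genome_length = 5000, n_genes = 15, seed = 98)
  db <- build_db(parse_toc(col$toc), out_dir = file.path(d, "db"))
  back <- load_db(file.path(d, "db"))
  expect_identical(back$manifest, db$manifest)
  expect_identical(back$markers$gene_id, db$markers$gene_id)
  # tamper with a file: checksum mismatch must be caught
  cat("X", file = db$representatives[["s01"]], append = TRUE)
  expect_error(load_db(file.path(d, "db")), "checksum mismatch")
})

test_that("external marker hit tables can annotate untagged gene files", {
  d <- withr::local_tempdir()
  genes <- file.path(d, "genes.fa")
  writeLines(c(">gA", rand_dna(120, 71), ">gB", rand_dna(120, 72)), genes)
  out <- file.path(d, "tagged.fa")
  apply_marker_hits(genes, data.frame(gene_id = "gB",
                                      marker_family = "B000062"), out)
  tagged <- read_fasta(out)
  expect_match(attr(tagged, "description")[2], "marker_family=B000062")
  expect_false(grepl("marker_family", attr(tagged, "description")[1]))
})
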