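# Synthetic-community simulator with complete planted ground truth.
#
# Every pipeline stage is validated against data from this module: genomes
# with annotated genes (15 of which carry universal single-copy marker
# tags), strains derived from a reference by point mutation, planted gene
# duplications/deletions, and paired-end reads with a uniform positional
# error model and constant base qualities. Every random draw is governed by
# an explicit seed, so all outputs are reproducible byte-for-byte.

#' Generate a random genome with annotated genes
#'
#' Bases are i.i.d. at the requested GC content. `n_genes` non-overlapping
#' 300-bp genes are placed deterministically at regular spacing; the first
#' 15 genes (or all of them if fewer) are tagged with the universal
#' single-copy marker panel of [marker_panel()].
#'
#' @param length genome length in bases.
#' @param gc GC fraction in (0,1).
#' @param n_genes number of 300-bp genes to place.
#' @param seed integer seed.
#' @return list with `seq` (character genome sequence) and `genes`
#'   (data.frame: gene_id, start, end, strand, marker_family with NA for
#'   untagged genes). Coordinates are 1-based inclusive.
#' @export
make_genome <- function(length, gc = 0.5, n_genes = 30L, seed = 1L) {
  stopifnot(length >= 1, gc > 0, gc < 1, n_genes >= 0)
  length <- as.integer(length)
  n_genes <- as.integer(n_genes)
  gene_len <- 300L
  if (n_genes > 0) {
    spacing <- length %/% n_genes
    if (spacing < gene_len + 10L) {
      stop(sprintf("infeasible packing: %d genes of %d bp do not fit in %d bp",
                   n_genes, gene_len, length))
    }
  }
  seq <- withr::with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
  })
  genes <- if (n_genes > 0) {
    start <- (seq_len(n_genes) - 1L) * (length %/% n_genes) + 1L
    panel <- marker_panel()
    fam <- rep(NA_character_, n_genes)
    k <- min(n_genes, length(panel))
    fam[seq_len(k)] <- panel[seq_len(k)]
    data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
               start = start, end = start + gene_len - 1L,
               strand = "+", marker_family = fam,
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_id = character(0), start = integer(0), end = integer(0),
               strand = character(0), marker_family = character(0),
               stringsAsFactors = FALSE)
  }
  list(seq = seq, genes = genes)
}

#' Derive a strain from a genome by point mutation
#'
#' Either each site is substituted independently with probability
#' `divergence`, or exactly `n_sites` sites (sampled uniformly without
#' replacement) are substituted. The substituted base is drawn uniformly
#' from the three alternatives. The returned truth list is exact.
#'
#' @param seq genome sequence (character scalar).
#' @param divergence per-base substitution probability in \[0, 0.1\].
#' @param n_sites plant exactly this many substitutions instead of using
#'   `divergence`.
#' @param seed integer seed.
#' @return list with `seq` (mutated sequence) and `snvs` (data.frame:
#'   pos, ref, alt; 1-based positions, sorted).
#' @export
mutate_strain <- function(seq, divergence = NULL, n_sites = NULL, seed = 1L) {
  L <- nchar(seq)
  stopifnot(xor(is.null(divergence), is.null(n_sites)))
  if (!is.null(divergence)) stopifnot(divergence >= 0, divergence <= 0.1)
  withr::with_seed(seed, {
    pos <- if (!is.null(n_sites)) {
      sort(sample.int(L, n_sites))
    } else {
      which(stats::runif(L) < divergence)
    }
    if (length(pos) == 0) {
      return(list(seq = seq,
                  snvs = data.frame(pos = integer(0), ref = character(0),
                                    alt = character(0), stringsAsFactors = FALSE)))
    }
    ref <- substring(seq, pos, pos)
    alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), "",
                  USE.NAMES = FALSE)
    chars <- strsplit(seq, "", fixed = TRUE)[[1]]
    chars[pos] <- alt
    list(seq = paste(chars, collapse = ""),
         snvs = data.frame(pos = pos, ref = ref, alt = alt,
                           stringsAsFactors = FALSE))
  })
}

#' Plant a gene copy-number event into a genome
#'
#' `copies = 0` deletes the gene span; `copies >= 2` inserts `copies - 1`
#' tandem duplicates immediately after the gene. Gene coordinates (and an
#' optional strain SNV truth table) downstream of the event are remapped to
#' the modified genome. A deleted gene is dropped from the returned
#' annotation; tandem duplicate copies are not annotated separately.
#'
#' @param seq genome sequence.
#' @param genes gene annotation data.frame as from [make_genome()].
#' @param gene_id gene to modify.
#' @param copies integer in {0, 2, 3}.
#' @param snvs optional SNV truth data.frame (pos, ref, alt) to remap;
#'   SNVs inside a deleted span are dropped.
#' @return list with `seq`, `genes`, `snvs` (remapped or NULL) and `cnv`
#'   (one-row data.frame: gene_id, copies).
#' @export
plant_cnv <- function(seq, genes, gene_id, copies, snvs = NULL) {
  copies <- as.integer(copies)
  stopifnot(copies %in% c(0L, 2L, 3L))
  i <- match(gene_id, genes$gene_id)
  if (is.na(i)) stop(sprintf("unknown gene_id: %s", gene_id))
  planted <- attr(genes, "cnv_planted") %||% character(0)
  if (gene_id %in% planted) {
    stop(sprintf("overlapping planted events on gene %s", gene_id))
  }
  s <- genes$start[i]; e <- genes$end[i]
  glen <- e - s + 1L
  gene_seq <- substring(seq, s, e)
  if (copies == 0L) {
    new_seq <- paste0(substring(seq, 1L, s - 1L),
                      substring(seq, e + 1L, nchar(seq)))
    delta <- -glen
  } else {
    extra <- strrep(gene_seq, copies - 1L)
    new_seq <- paste0(substring(seq, 1L, e), extra,
                      substring(seq, e + 1L, nchar(seq)))
    delta <- glen * (copies - 1L)
  }
  shift <- function(p) ifelse(p > e, p + delta, p)
  new_genes <- genes
  new_genes$start <- shift(new_genes$start)
  new_genes$end <- shift(new_genes$end)
  if (copies == 0L) new_genes <- new_genes[-i, , drop = FALSE]
  attr(new_genes, "cnv_planted") <- c(planted, gene_id)
  new_snvs <- NULL
  if (!is.null(snvs)) {
    keep <- if (copies == 0L) !(snvs$pos >= s & snvs$pos <= e) else rep(TRUE, nrow(snvs))
    new_snvs <- snvs[keep, , drop = FALSE]
    new_snvs$pos <- shift(new_snvs$pos)
  }
  list(seq = new_seq, genes = new_genes, snvs = new_snvs,
       cnv = data.frame(gene_id = gene_id, copies = as.integer(copies),
                        stringsAsFactors = FALSE))
}

#' Simulate paired-end reads from a strain mixture
#'
#' Fragment count is `coverage * total_length / (2 * read_len)` with
#' `total_length` the proportion-weighted mean strain length; fragments are
#' allocated to strains multinomially with weights proportion x length.
#' Fragment starts are uniform, fragment lengths normal (clipped to at
#' least `2 * read_len`). Each fragment yields a forward/reverse read pair;
#' with probability 1/2 read 1 comes from the reverse strand. Base-call
#' errors are i.i.d. with probability `error_rate`, substituting a uniform
#' different base; base quality is constant at
#' `round(-10 * log10(error_rate))` (40 when `error_rate = 0`). Read ids
#' encode strain, fragment coordinates and read-1 strand so that every read
#' is traceable to its source.
#'
#' @param strains list of lists with fields `strain_id`, `seq`,
#'   `proportion`; proportions must sum to 1.
#' @param coverage target mean depth over the community (x units).
#' @param read_len read length in bases.
#' @param frag_mean,frag_sd fragment length mean/SD in bases.
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @return list with `r1` and `r2` (data.frames id/seq/qual, mates
#'   synchronized), `fragments` (truth table: id, strain_id, start, end,
#'   r1_strand) and `quality` (the constant Phred score used).
#' @export
simulate_reads <- function(strains, coverage, read_len = 100L,
                           frag_mean = 300L, frag_sd = 30L,
                           error_rate = 0.001, seed = 1L) {
  props <- vapply(strains, `[[`, 0, "proportion")
  lens <- vapply(strains, function(s) nchar(s$seq), integer(1))
  sids <- vapply(strains, `[[`, "", "strain_id")
  stopifnot(abs(sum(props) - 1) < 1e-9, all(lens >= 2L * read_len))
  total_len <- sum(props * lens)
  n_frag <- as.integer(round(coverage * total_len / (2 * read_len)))
  q <- if (error_rate > 0) as.integer(round(-10 * log10(error_rate))) else 40L
  qchar <- rawToChar(as.raw(q + 33L))
  withr::with_seed(seed, {
    alloc <- as.integer(stats::rmultinom(1L, n_frag, prob = props * lens))
    strain_of <- rep.int(seq_along(strains), alloc)
    L <- lens[strain_of]
    flen <- pmin(pmax(as.integer(round(stats::rnorm(n_frag, frag_mean, frag_sd))),
                      2L * read_len), L)
    start <- as.integer(floor(stats::runif(n_frag) * (L - flen + 1))) + 1L
    end <- start + flen - 1L
    flip <- stats::runif(n_frag) < 0.5
    fwd <- character(n_frag); rev <- character(n_frag)
    for (k in seq_along(strains)) {
      idx <- which(strain_of == k)
      if (!length(idx)) next
      fwd[idx] <- substring(strains[[k]]$seq, start[idx], start[idx] + read_len - 1L)
      rev[idx] <- revcomp(substring(strains[[k]]$seq, end[idx] - read_len + 1L, end[idx]))
    }
    r1_seq <- ifelse(flip, rev, fwd)
    r2_seq <- ifelse(flip, fwd, rev)
    if (error_rate > 0) {
      r1_seq <- add_read_errors(r1_seq, error_rate)
      r2_seq <- add_read_errors(r2_seq, error_rate)
    }
    ids <- sprintf("f%07d:%s:%d:%d:%s", seq_len(n_frag), sids[strain_of],
                   start, end, ifelse(flip, "-", "+"))
    qual <- strrep(qchar, read_len)
    list(r1 = data.frame(id = ids, seq = r1_seq, qual = qual,
                         stringsAsFactors = FALSE),
         r2 = data.frame(id = ids, seq = r2_seq, qual = qual,
                         stringsAsFactors = FALSE),
         fragments = data.frame(id = ids, strain_id = sids[strain_of],
                                start = start, end = end,
                                r1_strand = ifelse(flip, "-", "+"),
                                stringsAsFactors = FALSE),
         quality = q)
  })
}

# substitute bases i.i.d. with probability eps (uniform different base)
add_read_errors <- function(seqs, eps) {
  rl <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), rl, eps)
  hit <- which(n_err > 0)
  for (i in hit) {
    pos <- sample.int(rl[i], n_err[i])
    for (p in pos) {
      b <- substring(seqs[i], p, p)
      substring(seqs[i], p, p) <- sample(setdiff(BASES, b), 1L)
    }
  }
  seqs
}

#' Validate read provenance against source strains
#'
#' Re-extracts every read from its source strain using the coordinates
#' encoded in the read id and checks identity (exact for error-free reads).
#'
#' @param sim output of [simulate_reads()].
#' @param strains the strain list the reads were simulated from.
#' @return fraction of reads matching their source exactly.
#' @export
validate_reads <- function(sim, strains) {
  seqs <- stats::setNames(vapply(strains, `[[`, "", "seq"),
                          vapply(strains, `[[`, "", "strain_id"))
  fr <- sim$fragments
  rl <- nchar(sim$r1$seq[1])
  fwd <- substring(seqs[fr$strain_id], fr$start, fr$start + rl - 1L)
  rev <- revcomp(substring(seqs[fr$strain_id], fr$end - rl + 1L, fr$end))
  r1_ok <- ifelse(fr$r1_strand == "+", sim$r1$seq == fwd, sim$r1$seq == rev)
  r2_ok <- ifelse(fr$r1_strand == "+", sim$r2$seq == rev, sim$r2$seq == fwd)
  mean(r1_ok & r2_ok)
}

#' Write a simulated genome collection to disk
#'
#' Builds a toy multi-species genome collection in the on-disk layout the
#' database builder consumes: per-genome genome FASTA and gene FASTA (with
#' `marker_family=` tags in the descriptions of marker genes), plus the
#' table-of-contents TSV assigning genomes to species and designating one
#' representative per species. Non-representative genomes are strains
#' derived from the representative by point mutation.
#'
#' @param out_dir directory to create files in.
#' @param n_species number of species.
#' @param genomes_per_species genomes per species (first is representative).
#' @param genome_length genome length in bases.
#' @param n_genes genes per genome.
#' @param strain_divergence per-base divergence of non-representative
#'   genomes from the representative.
#' @param seed integer seed.
#' @return list with `toc` (path to the table-of-contents TSV) and `truth`
#'   (per species: reference sequence, gene table, per-strain SNV tables).
#' @export
sim_collection <- function(out_dir, n_species = 3L, genomes_per_species = 1L,
                           genome_length = 10000L, n_genes = 30L,
                           strain_divergence = 0.01, seed = 1L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  toc <- NULL
  truth <- list()
  for (s in seq_len(n_species)) {
    sp <- sprintf("s%02d", s)
    ref <- make_genome(genome_length, n_genes = n_genes,
                       seed = sub_seed(seed, s))
    truth[[sp]] <- list(seq = ref$seq, genes = ref$genes, strains = list())
    for (g in seq_len(genomes_per_species)) {
      gid <- sprintf("%s.%d", sp, g)
      if (g == 1L) {
        gseq <- ref$seq
        snvs <- NULL
      } else {
        mut <- mutate_strain(ref$seq, divergence = strain_divergence,
                             seed = sub_seed(seed, 100L * s + g))
        gseq <- mut$seq
        snvs <- mut$snvs
      }
      truth[[sp]]$strains[[gid]] <- snvs
      genome_path <- file.path(out_dir, paste0(gid, ".fa"))
      genes_path <- file.path(out_dir, paste0(gid, ".genes.fa"))
      contig <- paste0(gid, "_c1")
      gseqs <- stats::setNames(gseq, contig)
      write_fasta(gseqs, genome_path)
      gn <- ref$genes
      if (nrow(gn)) {
        gene_seqs <- substring(gseq, gn$start, gn$end)
        ids <- paste0(gid, "_", gn$gene_id)
        desc <- ifelse(is.na(gn$marker_family), ids,
                       paste0(ids, " marker_family=", gn$marker_family))
        out <- stats::setNames(gene_seqs, ids)
        attr(out, "description") <- desc
        write_fasta(out, genes_path)
      } else {
        writeLines(character(0), genes_path)
      }
      toc <- rbind(toc, data.frame(
        genome_id = gid, species_id = sp,
        is_representative = (g == 1L),
        genome_path = genome_path, genes_path = genes_path,
        stringsAsFactors = FALSE))
    }
  }
  toc_path <- file.path(out_dir, "toc.tsv")
  write_tsv(toc, toc_path)
  list(toc = toc_path, truth = truth)
}
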