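# Single-sample SNV step: mate-overlap-aware pileup of filtered alignments
# and per-sample SNV calls. No single-strain-per-sample assumption is made:
# the full A/C/G/T count vector is retained at every site, so mixtures stay
# representable.

# per-record aligned bases: list(refpos, base, qual) with qual as integer
record_bases <- function(pos, cigar, seq, qual, contig_len) {
  if (grepl("^\\d+M$", cigar)) {
    n <- nchar(seq)
    refpos <- pos:(pos + n - 1L)
    qpos <- seq_len(n)
  } else {
    ap <- aligned_pairs(cigar, pos)
    refpos <- ap$refpos
    qpos <- ap$qpos
  }
  if (length(refpos) && max(refpos) > contig_len) {
    stop(sprintf("malformed alignment: CIGAR %s at pos %d runs past contig end (%d)",
                 cigar, pos, contig_len))
  }
  list(refpos = refpos,
       base = substring(seq, qpos, qpos),
       qual = utf8ToInt(qual)[qpos] - 33L)
}

#' Resolve the overlap of two mates into per-fragment bases
#'
#' A sequenced fragment must contribute at most one base per reference
#' position. Positions covered by a single mate take that mate's base and
#' quality. Positions covered by both mates take: the agreeing base at the
#' higher of the two qualities; the higher-quality base when the mates
#' disagree; and nothing when the mates disagree at equal quality.
#'
#' @param m1,m2 lists with `refpos`, `base`, `qual` for each mate (as
#'   produced internally from one alignment record; `qual` integer Phred).
#' @return list with `refpos`, `base`, `qual` for the fragment.
#' @export
resolve_mate_overlap <- function(m1, m2) {
  shared <- intersect(m1$refpos, m2$refpos)
  if (length(shared) == 0) {
    return(list(refpos = c(m1$refpos, m2$refpos),
                base = c(m1$base, m2$base),
                qual = c(m1$qual, m2$qual)))
  }
  i1 <- match(shared, m1$refpos)
  i2 <- match(shared, m2$refpos)
  b1 <- m1$base[i1]; q1 <- m1$qual[i1]
  b2 <- m2$base[i2]; q2 <- m2$qual[i2]
  agree <- b1 == b2
  take1 <- agree | q1 > q2
  take2 <- !agree & q2 > q1
  keep <- agree | q1 != q2
  res_base <- ifelse(take1, b1, b2)
  res_qual <- pmax(q1, q2)
  only1 <- setdiff(seq_along(m1$refpos), i1)
  only2 <- setdiff(seq_along(m2$refpos), i2)
  list(refpos = c(m1$refpos[only1], m2$refpos[only2], shared[keep]),
       base = c(m1$base[only1], m2$base[only2], res_base[keep]),
       qual = c(m1$qual[only1], m2$qual[only2], res_qual[keep]))
}

#' Compute per-site pileups from filtered alignments
#'
#' Applies [filter_alignment()], resolves mate overlaps per fragment, and
#' counts fragment bases with quality >= `params$min_baseq` into per-site
#' A/C/G/T vectors. Alignment columns carrying indels or N bases contribute
#' nothing. Sites with depth 0 are omitted.
#'
#' @param aln alignment data.frame.
#' @param targets named character vector of reference sequences.
#' @param params a [filter_params()] object.
#' @return data.frame with columns contig, pos (1-based), ref, A, C, G, T,
#'   depth, sorted by (contig, pos).
#' @export
compute_pileup <- function(aln, targets, params = filter_params()) {
  reason <- filter_alignment(aln, params)
  kept <- aln[is.na(reason), , drop = FALSE]
  acc_pos <- list(); acc_base <- list()
  if (nrow(kept)) {
    key <- paste(kept$qname, kept$rname, sep = "\r")
    groups <- split(seq_len(nrow(kept)), key)
    out_pos <- vector("list", length(groups))
    out_base <- vector("list", length(groups))
    gi <- 0L
    for (g in groups) {
      gi <- gi + 1L
      rec1 <- kept[g[1L], ]
      if (!rec1$rname %in% names(targets)) {
        stop(sprintf("alignment to unknown target: %s", rec1$rname))
      }
      clen <- nchar(targets[[rec1$rname]])
      b1 <- record_bases(rec1$pos, rec1$cigar, rec1$seq, rec1$qual, clen)
      frag <- if (length(g) >= 2L) {
        rec2 <- kept[g[2L], ]
        b2 <- record_bases(rec2$pos, rec2$cigar, rec2$seq, rec2$qual, clen)
        resolve_mate_overlap(b1, b2)
      } else b1
      ok <- frag$qual >= params$min_baseq & frag$base %in% BASES
      out_pos[[gi]] <- frag$refpos[ok]
      out_base[[gi]] <- match(frag$base[ok], BASES)
      names(out_pos)[gi] <- rec1$rname
    }
    acc_pos <- out_pos; acc_base <- out_base
  }
  res <- NULL
  contigs <- unique(names(acc_pos))
  for (ct in sort(contigs)) {
    sel <- which(names(acc_pos) == ct)
    p <- unlist(acc_pos[sel], use.names = FALSE)
    b <- unlist(acc_base[sel], use.names = FALSE)
    L <- nchar(targets[[ct]])
    tab <- tabulate(p + (b - 1L) * L, nbins = 4L * L)
    cnt <- matrix(tab, nrow = L, ncol = 4L)
    depth <- rowSums(cnt)
    w <- which(depth > 0)
    if (length(w)) {
      res <- rbind(res, data.frame(
        contig = ct, pos = w, ref = substring(targets[[ct]], w, w),
        A = cnt[w, 1L], C = cnt[w, 2L], G = cnt[w, 3L], T = cnt[w, 4L],
        depth = as.integer(depth[w]), stringsAsFactors = FALSE))
    }
  }
  if (is.null(res)) {
    res <- data.frame(contig = character(0), pos = integer(0), ref = character(0),
                      A = integer(0), C = integer(0), G = integer(0),
                      T = integer(0), depth = integer(0), stringsAsFactors = FALSE)
  }
  res
}

#' Call per-sample SNVs from a pileup
#'
#' Sites with depth outside `[min_depth, max_depth]` are no-calls and are
#' dropped. At called sites the major allele is the argmax of the counts
#' (ties to the lexicographically smallest base) and the minor allele the
#' second-largest nonzero count under the same tie rule (absent when the
#' site is monomorphic). The full count vector is retained.
#'
#' @param pileup data.frame from [compute_pileup()].
#' @param min_depth,max_depth inclusive depth bounds for a site to be
#'   callable (the cap guards repeat-driven pileups).
#' @return the callable subset of `pileup` with added columns
#'   major_allele, minor_allele (NA if monomorphic), major_freq,
#'   minor_freq.
#' @export
call_sample_snv <- function(pileup, min_depth = 2L, max_depth = 10000L) {
  stopifnot(min_depth >= 1)
  keep <- pileup$depth >= min_depth & pileup$depth <= max_depth
  out <- pileup[keep, , drop = FALSE]
  if (nrow(out) == 0) {
    out$major_allele <- character(0); out$minor_allele <- character(0)
    out$major_freq <- numeric(0); out$minor_freq <- numeric(0)
    return(out)
  }
  cnt <- as.matrix(out[, BASES])
  maj <- max.col(cnt, ties.method = "first") # column order A<C<G<T = lexicographic
  cnt2 <- cnt
  cnt2[cbind(seq_len(nrow(cnt)), maj)] <- -1L
  min_i <- max.col(cnt2, ties.method = "first")
  min_cnt <- cnt2[cbind(seq_len(nrow(cnt)), min_i)]
  out$major_allele <- BASES[maj]
  out$minor_allele <- ifelse(min_cnt > 0, BASES[min_i], NA_character_)
  out$major_freq <- cnt[cbind(seq_len(nrow(cnt)), maj)] / out$depth
  out$minor_freq <- ifelse(min_cnt > 0, min_cnt / out$depth, 0)
  out
}

# "<species>|<contig>" -> list(species, contig); plain contigs get species NA
split_target_name <- function(x) {
  has <- grepl("|", x, fixed = TRUE)
  sp <- ifelse(has, sub("\\|.*$", "", x), NA_character_)
  ct <- ifelse(has, sub("^[^|]*\\|", "", x), x)
  list(species = sp, contig = ct)
}

#' Run the single-sample SNV step
#'
#' Aligns a read pair set to the (sample-customized) representative target
#' with the internal aligner — or ingests an externally produced SAM
#' against the same target — filters, pileups, and calls per-sample SNVs.
#' Target contigs named `<species_id>|<contig_id>` (as written by
#' [build_custom_target()]) are split back into their species.
#'
#' @param r1,r2 read data.frames (`id`, `seq`, `qual`) or FASTQ paths; or
#'   NULL when `sam` is given.
#' @param target named character vector of reference sequences or a FASTA
#'   path.
#' @param sam optional path to a SAM file against `target` (skips the
#'   internal aligner).
#' @param params a [filter_params()] object.
#' @param min_depth,max_depth passed to [call_sample_snv()].
#' @param out_dir if non-NULL, write one `<species>.snps_pileup.tsv` per
#'   species (1-based positions; columns species_id, contig_id, position,
#'   ref_allele, depth, count_A..count_T, major_allele, minor_allele,
#'   major_freq).
#' @return named list per species with elements `pileup` (all covered
#'   sites) and `snv` (callable sites with allele calls).
#' @export
snv_single_sample <- function(r1 = NULL, r2 = NULL, target, sam = NULL,
                              params = filter_params(),
                              min_depth = 2L, max_depth = 10000L,
                              out_dir = NULL) {
  if (is.character(target) && length(target) == 1L && file.exists(target)) {
    target <- read_fasta(target)
  }
  aln <- if (!is.null(sam)) {
    parse_sam(sam)
  } else {
    if (is.character(r1)) r1 <- read_fastq(r1)
    if (is.character(r2)) r2 <- read_fastq(r2)
    align_to_target(r1, r2, target,
                    max_template_len = params$max_template_len)
  }
  pu <- compute_pileup(aln, target, params)
  parts <- split_target_name(pu$contig)
  pu$species_id <- ifelse(is.na(parts$species), "NA", parts$species)
  pu$contig_id <- parts$contig
  out <- list()
  for (sp in sort(unique(pu$species_id))) {
    sub <- pu[pu$species_id == sp, , drop = FALSE]
    rownames(sub) <- NULL
    snv <- call_sample_snv(sub, min_depth, max_depth)
    out[[sp]] <- list(pileup = sub, snv = snv)
    if (!is.null(out_dir)) {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      calls <- snv[, c("contig_id", "pos", "major_allele", "minor_allele",
                       "major_freq")]
      m <- merge(sub, calls, by = c("contig_id", "pos"), all.x = TRUE,
                 sort = FALSE)
      m <- m[order(m$contig_id, m$pos), , drop = FALSE]
      tsv <- data.frame(species_id = m$species_id, contig_id = m$contig_id,
                        position = m$pos, ref_allele = m$ref, depth = m$depth,
                        count_A = m$A, count_C = m$C, count_G = m$G,
                        count_T = m$T, major_allele = m$major_allele,
                        minor_allele = m$minor_allele,
                        major_freq = fmt4(m$major_freq),
                        stringsAsFactors = FALSE)
      write_tsv(tsv, file.path(out_dir, paste0(sp, ".snps_pileup.tsv")))
    }
  }
  out
}

#' Read a single-sample pileup TSV back into the internal layout
#'
#' @param path a `<species>.snps_pileup.tsv` written by
#'   [snv_single_sample()].
#' @return data.frame in [compute_pileup()] layout plus species_id and
#'   contig_id columns.
#' @export
read_pileup_tsv <- function(path) {
  x <- read_tsv(path)
  data.frame(contig = paste0(x$species_id, "|", x$contig_id),
             pos = as.integer(x$position), ref = x$ref_allele,
             A = as.integer(x$count_A), C = as.integer(x$count_C),
             G = as.integer(x$count_G), T = as.integer(x$count_T),
             depth = as.integer(x$depth),
             species_id = x$species_id, contig_id = x$contig_id,
             stringsAsFactors = FALSE)
}
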