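# Internal exact-seed read aligner.
#
# A deliberately simple ungapped aligner sufficient for reads whose true
# source differs from the target by substitutions only (the simulator's
# regime, and the dominant regime for short reads within a species): 21-mer
# exact seeds at a ladder of offsets locate candidate positions on either
# strand, candidates are scored by Hamming distance over the full read, and
# the unique best hit is reported SAM-style. Reads whose best score is tied
# across distinct positions are reported with MAPQ 0 so that downstream
# mapping-quality filters discard them (unique-alignment rule). The
# pipeline equally accepts externally produced SAM against the same
# targets; everything downstream of the alignment data.frame is
# backend-independent.

#' Build a k-mer seed index over target sequences
#'
#' @param targets named character vector of target sequences.
#' @param k seed length in bases.
#' @return an object of class `mgt_seed_index`.
#' @export
seed_index <- function(targets, k = 21L) {
  stopifnot(!is.null(names(targets)), !anyDuplicated(names(targets)))
  keys <- character(0); contig <- integer(0); pos <- integer(0)
  for (i in seq_along(targets)) {
    L <- nchar(targets[[i]])
    if (L < k) next
    p <- seq_len(L - k + 1L)
    keys <- c(keys, substring(targets[[i]], p, p + k - 1L))
    contig <- c(contig, rep.int(i, length(p)))
    pos <- c(pos, p)
  }
  structure(list(index = split(seq_along(keys), keys),
                 contig = contig, pos = pos,
                 targets = unname(targets), names = names(targets),
                 lens = unname(nchar(targets)), k = as.integer(k)),
            class = "mgt_seed_index")
}

#' @export
print.mgt_seed_index <- function(x, ...) {
  cat(sprintf("<mgt_seed_index> %d target(s), %d bp total, k = %d\n",
              length(x$targets), sum(x$lens), x$k))
  invisible(x)
}

# Hamming distance between two equal-length strings
hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

#' Align reads to an indexed target (single-end)
#'
#' @param reads data.frame with columns `id`, `seq`, `qual` (as from
#'   [read_fastq()]).
#' @param index an [seed_index()] object.
#' @param max_mismatch_frac maximum Hamming distance as a fraction of read
#'   length for a candidate to be reported.
#' @return alignment data.frame (SAM column layout, see [parse_sam()]);
#'   `seq`/`qual` are stored reference-forward (SAM convention). Unmapped
#'   reads are absent; ambiguous best hits carry MAPQ 0.
#' @export
align_reads <- function(reads, index, max_mismatch_frac = 0.25) {
  stopifnot(inherits(index, "mgt_seed_index"))
  n <- nrow(reads)
  if (n == 0) return(empty_alignments())
  k <- index$k
  rl <- nchar(reads$seq)
  sf <- reads$seq
  sr <- revcomp(reads$seq)
  # gather seed candidates over both orientations and a ladder of offsets
  cand_read <- integer(0); cand_orient <- integer(0)
  cand_contig <- integer(0); cand_start <- integer(0)
  max_r <- max(0L, as.integer(ceiling((max(rl) - k) / k)))
  for (o in 1:2) {
    ss <- if (o == 1L) sf else sr
    for (r in 0:max_r) {
      # seed offsets 1, 1+k, 1+2k, ... plus one final clamped offset at
      # rl-k+1 so the read tail is always covered by a seed
      off <- pmin(1L + r * k, rl - k + 1L)
      live <- if (r == 0L) rl >= k else 1L + (r - 1L) * k < rl - k + 1L
      if (!any(live)) break
      kk <- substring(ss, off, off + k - 1L)
      kk[!live] <- ""
      hits <- index$index[kk]
      nh <- lengths(hits)
      w <- which(nh > 0 & live)
      if (length(w)) {
        j <- unlist(hits[w], use.names = FALSE)
        reps <- nh[w]
        cand_read <- c(cand_read, rep.int(w, reps))
        cand_orient <- c(cand_orient, rep.int(o, length(j)))
        cand_contig <- c(cand_contig, index$contig[j])
        cand_start <- c(cand_start, index$pos[j] - rep.int(off[w], reps) + 1L)
      }
    }
  }
  if (length(cand_read) == 0) return(empty_alignments())
  keep <- cand_start >= 1L &
    cand_start + rl[cand_read] - 1L <= index$lens[cand_contig]
  cand_read <- cand_read[keep]; cand_orient <- cand_orient[keep]
  cand_contig <- cand_contig[keep]; cand_start <- cand_start[keep]
  dup <- duplicated(data.frame(cand_read, cand_orient, cand_contig, cand_start))
  cand_read <- cand_read[!dup]; cand_orient <- cand_orient[!dup]
  cand_contig <- cand_contig[!dup]; cand_start <- cand_start[!dup]
  # score candidates: exact string equality first, Hamming loop for the rest
  refseg <- substring(index$targets[cand_contig], cand_start,
                      cand_start + rl[cand_read] - 1L)
  readstr <- ifelse(cand_orient == 1L, sf[cand_read], sr[cand_read])
  nm <- integer(length(cand_read))
  inexact <- which(refseg != readstr)
  for (i in inexact) nm[i] <- hamming(refseg[i], readstr[i])
  ok <- nm <= floor(max_mismatch_frac * rl[cand_read])
  if (!any(ok)) return(empty_alignments())
  cand_read <- cand_read[ok]; cand_orient <- cand_orient[ok]
  cand_contig <- cand_contig[ok]; cand_start <- cand_start[ok]
  readstr <- readstr[ok]; nm <- nm[ok]
  # unique best hit per read; ties across distinct positions -> MAPQ 0
  ord <- order(cand_read, nm, cand_contig, cand_start, cand_orient)
  cr <- cand_read[ord]; cn <- nm[ord]
  pos_first <- which(!duplicated(cr))
  fi <- ord[pos_first]
  second <- pos_first + 1L
  has_second <- second <= length(cr)
  second[!has_second] <- 1L # placeholder, masked below
  tied <- has_second & cr[second] == cr[pos_first] & cn[second] == cn[pos_first]
  rlen <- rl[cand_read[fi]]
  qual <- reads$qual[cand_read[fi]]
  rev_sel <- cand_orient[fi] == 2L
  qual[rev_sel] <- str_rev(qual[rev_sel])
  tie_rname <- rep(NA_character_, length(fi))
  tie_rname[tied] <- index$names[cand_contig[ord[second[tied]]]]
  data.frame(
    qname = reads$id[cand_read[fi]],
    flag = ifelse(rev_sel, FLAG_REVERSE, 0L),
    rname = index$names[cand_contig[fi]],
    pos = cand_start[fi],
    mapq = ifelse(tied, 0L, 42L),
    cigar = sprintf("%dM", rlen),
    rnext = "*", pnext = 0L, tlen = 0L,
    seq = readstr[fi],
    qual = qual,
    nm = nm[fi],
    md = NA_character_,
    tie_rname = tie_rname,
    stringsAsFactors = FALSE
  )
}

#' Align paired-end reads to an indexed target
#'
#' Aligns each mate independently with [align_reads()], then sets SAM pair
#' flags and template lengths. A pair is flagged proper when both mates map
#' to the same contig on opposite strands in forward–reverse orientation
#' with template length at most `max_template_len`.
#'
#' @param r1,r2 mate data.frames (`id`, `seq`, `qual`), synchronized by id.
#' @param index an [seed_index()] object.
#' @param max_template_len largest template length still flagged proper.
#' @param max_mismatch_frac passed to [align_reads()].
#' @return alignment data.frame with both mates' records.
#' @export
align_read_pairs <- function(r1, r2, index, max_template_len = 1000L,
                             max_mismatch_frac = 0.25) {
  a1 <- align_reads(r1, index, max_mismatch_frac)
  a2 <- align_reads(r2, index, max_mismatch_frac)
  if (nrow(a1)) a1$flag <- a1$flag + FLAG_PAIRED + FLAG_FIRST
  if (nrow(a2)) a2$flag <- a2$flag + FLAG_PAIRED + FLAG_LAST
  i2 <- match(a1$qname, a2$qname)
  i1 <- match(a2$qname, a1$qname)
  pair_up <- function(a, b, ib) {
    # a: records to annotate; b: mate table; ib: index of mate in b
    mate_mapped <- !is.na(ib)
    a$flag <- a$flag + ifelse(mate_mapped, 0L, FLAG_MUNMAPPED)
    if (any(mate_mapped)) {
      m <- which(mate_mapped)
      bm <- b[ib[m], ]
      a$rnext[m] <- ifelse(bm$rname == a$rname[m], "=", bm$rname)
      a$pnext[m] <- bm$pos
      a$flag[m] <- a$flag[m] +
        ifelse(has_flag(bm$flag, FLAG_REVERSE), FLAG_MREVERSE, 0L)
      same <- bm$rname == a$rname[m]
      end_a <- a$pos[m] + cigar_ref_span(a$cigar[m]) - 1L
      end_b <- bm$pos + cigar_ref_span(bm$cigar) - 1L
      tl <- pmax(end_a, end_b) - pmin(a$pos[m], bm$pos) + 1L
      opp <- has_flag(a$flag[m], FLAG_REVERSE) != has_flag(bm$flag, FLAG_REVERSE)
      # forward-reverse orientation: the leftmost mate is on the forward strand
      fwd_left <- ifelse(has_flag(a$flag[m], FLAG_REVERSE),
                         bm$pos <= a$pos[m], a$pos[m] <= bm$pos)
      proper <- same & opp & fwd_left & tl <= max_template_len
      sign <- ifelse(a$pos[m] < bm$pos | (a$pos[m] == bm$pos &
                       !has_flag(a$flag[m], FLAG_REVERSE)), 1L, -1L)
      a$tlen[m] <- ifelse(same, sign * tl, 0L)
      a$flag[m] <- a$flag[m] + ifelse(proper, FLAG_PROPER, 0L)
    }
    a
  }
  out <- rbind(pair_up(a1, a2, i2), pair_up(a2, a1, i1))
  out[order(out$rname, out$pos, out$qname, out$flag), , drop = FALSE]
}

#' Align a read pair set to arbitrary target sequences
#'
#' Convenience wrapper: builds the seed index and runs
#' [align_read_pairs()].
#'
#' @inheritParams align_read_pairs
#' @param targets named character vector of target sequences.
#' @param k seed length.
#' @return alignment data.frame.
#' @export
align_to_target <- function(r1, r2, targets, k = 21L,
                            max_template_len = 1000L,
                            max_mismatch_frac = 0.25) {
  align_read_pairs(r1, r2, seed_index(targets, k = k),
                   max_template_len = max_template_len,
                   max_mismatch_frac = max_mismatch_frac)
}
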