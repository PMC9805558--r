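# SAM text parsing/writing and CIGAR arithmetic.
#
# Alignments are held as a plain data.frame with the mandatory SAM columns
# (qname, flag, rname, pos, mapq, cigar, rnext, pnext, tlen, seq, qual) plus
# an integer `nm` column (NM tag; NA when absent) and the MD tag string in
# `md` (NA when absent). The internal read aligner emits the same layout, so
# all downstream filtering/pileup code is alignment-backend independent.

# SAM flag bits
FLAG_PAIRED <- 0x1L
FLAG_PROPER <- 0x2L
FLAG_UNMAPPED <- 0x4L
FLAG_MUNMAPPED <- 0x8L
FLAG_REVERSE <- 0x10L
FLAG_MREVERSE <- 0x20L
FLAG_FIRST <- 0x40L
FLAG_LAST <- 0x80L
FLAG_SECONDARY <- 0x100L
FLAG_SUPPLEMENTARY <- 0x800L

has_flag <- function(flag, bit) bitwAnd(as.integer(flag), bit) != 0L

# split CIGAR strings into op-length pairs; returns list of
# list(len = integer, op = character) per input string
cigar_ops <- function(cigar) {
  lapply(cigar, function(cg) {
    if (is.na(cg) || cg == "*") return(list(len = integer(0), op = character(0)))
    m <- gregexpr("\\d+[MIDNSHP=X]", cg)[[1]]
    toks <- regmatches(cg, list(m))[[1]]
    if (length(toks) == 0 || sum(nchar(toks)) != nchar(cg)) {
      stop(sprintf("malformed CIGAR string: %s", cg))
    }
    list(len = as.integer(sub("[MIDNSHP=X]$", "", toks)),
         op = sub("^\\d+", "", toks))
  })
}

cigar_sum <- function(cigar, ops_wanted) {
  vapply(cigar_ops(cigar), function(co) {
    sum(co$len[co$op %in% ops_wanted])
  }, integer(1))
}

# columns of the pairwise alignment: matches/mismatches + indels
cigar_aligned_columns <- function(cigar) cigar_sum(cigar, c("M", "=", "X", "I", "D"))
# read bases that take part in the alignment (excludes clips)
cigar_aligned_read_bases <- function(cigar) cigar_sum(cigar, c("M", "=", "X", "I"))
# full read length implied by the CIGAR (includes soft clips)
cigar_query_length <- function(cigar) cigar_sum(cigar, c("M", "=", "X", "I", "S"))
# reference span of the alignment
cigar_ref_span <- function(cigar) cigar_sum(cigar, c("M", "=", "X", "D", "N"))

# (refpos, qpos) pairs for aligned (M/=/X) columns of one record
aligned_pairs <- function(cigar, pos) {
  co <- cigar_ops(cigar)[[1]]
  refp <- integer(0); qp <- integer(0)
  r <- as.integer(pos); q <- 1L
  for (i in seq_along(co$op)) {
    len <- co$len[i]
    switch(co$op[i],
      "M" = , "=" = , "X" = {
        refp <- c(refp, r:(r + len - 1L))
        qp <- c(qp, q:(q + len - 1L))
        r <- r + len; q <- q + len
      },
      "I" = { q <- q + len },
      "S" = { q <- q + len },
      "D" = , "N" = { r <- r + len },
      "H" = , "P" = NULL)
  }
  list(refpos = refp, qpos = qp)
}

# Recompute NM from the MD tag plus CIGAR insertions.
# NM = mismatches (plain letters in MD) + deleted bases (letters after ^)
#    + inserted bases (I ops).
md_to_nm <- function(md, cigar) {
  mismatch <- vapply(md, function(s) {
    if (is.na(s)) return(NA_integer_)
    s <- gsub("\\^[A-Z]+", "", s)
    sum(nchar(gsub("[^A-Z]", "", s)))
  }, integer(1), USE.NAMES = FALSE)
  del <- vapply(md, function(s) {
    if (is.na(s)) return(NA_integer_)
    runs <- regmatches(s, gregexpr("\\^[A-Z]+", s))[[1]]
    sum(nchar(runs)) - length(runs)
  }, integer(1), USE.NAMES = FALSE)
  mismatch + del + cigar_sum(cigar, "I")
}

#' Parse a SAM file
#'
#' Reads plain-text SAM into the package's alignment data.frame layout.
#' Covers CIGAR operations M/I/D/N/S/H/P/=/X and the NM and MD optional
#' tags. Header lines are skipped (reference lengths are taken from the
#' alignment target FASTA, not the header).
#'
#' @param path path to a SAM file.
#' @return data.frame with columns qname, flag, rname, pos, mapq, cigar,
#'   rnext, pnext, tlen, seq, qual, nm, md.
#' @export
parse_sam <- function(path) {
  if (!file.exists(path)) stop_input("SAM file not found: %s", path)
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  body <- lines[!startsWith(lines, "@")]
  body <- body[nzchar(body)]
  if (length(body) == 0) return(empty_alignments())
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    bad <- which(nf < 11L)[1L]
    stop_input("SAM line %d has %d fields (11 required)", bad, nf[bad])
  }
  get <- function(i) vapply(fields, `[`, "", i)
  tagval <- function(prefix) {
    vapply(fields, function(f) {
      tags <- f[-(1:11)]
      hit <- tags[startsWith(tags, prefix)]
      if (length(hit)) sub(prefix, "", hit[1L], fixed = TRUE) else NA_character_
    }, "")
  }
  data.frame(
    qname = get(1L),
    flag = as.integer(get(2L)),
    rname = get(3L),
    pos = as.integer(get(4L)),
    mapq = as.integer(get(5L)),
    cigar = get(6L),
    rnext = get(7L),
    pnext = as.integer(get(8L)),
    tlen = as.integer(get(9L)),
    seq = toupper(get(10L)),
    qual = get(11L),
    nm = suppressWarnings(as.integer(tagval("NM:i:"))),
    md = tagval("MD:Z:"),
    tie_rname = NA_character_,
    stringsAsFactors = FALSE
  )
}

empty_alignments <- function() {
  data.frame(qname = character(0), flag = integer(0), rname = character(0),
             pos = integer(0), mapq = integer(0), cigar = character(0),
             rnext = character(0), pnext = integer(0), tlen = integer(0),
             seq = character(0), qual = character(0), nm = integer(0),
             md = character(0), tie_rname = character(0),
             stringsAsFactors = FALSE)
}

#' Write alignments to a SAM file
#'
#' @param aln alignment data.frame as produced by [parse_sam()] or
#'   [align_read_pairs()].
#' @param targets named character vector of reference sequences (used for
#'   `@SQ` header lines).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, targets, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(targets), nchar(targets)))
  tag <- ifelse(is.na(aln$nm), "", sprintf("\tNM:i:%d", aln$nm))
  mdtag <- ifelse(is.na(aln$md), "", sprintf("\tMD:Z:%s", aln$md))
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t%s\t%s%s%s",
                  aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq,
                  aln$cigar, aln$rnext, aln$pnext, aln$tlen, aln$seq,
                  aln$qual, tag, mdtag)
  writeLines(c(hdr, body), path)
  invisible(path)
}
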