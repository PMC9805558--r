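# Post-alignment filters. These are what separate a raw aligner's output
# from the fragments that are allowed to contribute to pileups; they are
# the main determinant of false-positive consensus SNVs.

#' Post-alignment filter parameters
#'
#' Defaults follow the conventions of the MIDAS lineage of metagenotypers:
#' mapping quality >= 10 (discards ambiguous placements, including this
#' package's internal-aligner MAPQ-0 ties), read identity >= 0.90, at least
#' 75% of the read aligned, bases counted only at Phred quality >= 30, and
#' proper pairs with template length <= 1000 bp required. All values are
#' exposed here and on the command line.
#'
#' @param min_mapq minimum mapping quality.
#' @param min_read_identity minimum `1 - NM / aligned_columns`.
#' @param min_aln_cov minimum fraction of the read length aligned.
#' @param min_baseq minimum base quality (Phred) for a base to be counted.
#' @param require_proper_pair drop records not in a proper pair.
#' @param max_template_len drop proper-pair records with larger template.
#' @param on_missing_nm `"md"` to recompute NM from the MD tag when the NM
#'   tag is absent, `"error"` to fail.
#' @return a list of class `mgt_filter_params`.
#' @export
filter_params <- function(min_mapq = 10L, min_read_identity = 0.90,
                          min_aln_cov = 0.75, min_baseq = 30L,
                          require_proper_pair = TRUE,
                          max_template_len = 1000L,
                          on_missing_nm = c("md", "error")) {
  stopifnot(min_mapq >= 0, min_baseq >= 0, max_template_len >= 0,
            min_read_identity >= 0, min_read_identity <= 1,
            min_aln_cov >= 0, min_aln_cov <= 1)
  structure(list(min_mapq = as.integer(min_mapq),
                 min_read_identity = min_read_identity,
                 min_aln_cov = min_aln_cov,
                 min_baseq = as.integer(min_baseq),
                 require_proper_pair = isTRUE(require_proper_pair),
                 max_template_len = as.integer(max_template_len),
                 on_missing_nm = match.arg(on_missing_nm)),
            class = "mgt_filter_params")
}

#' Apply post-alignment filters to alignment records
#'
#' Each record is either kept or dropped with the first failing reason, in
#' this order: `unmapped`, `secondary`, `supplementary`, `mapq`,
#' `identity` (`1 - NM/aligned_columns < min_read_identity`), `aln_cov`
#' (aligned read bases / read length `< min_aln_cov`), `proper_pair`,
#' `template_len`. Missing NM tags are recomputed from the MD tag or raise
#' an error, per `params$on_missing_nm`.
#'
#' @param aln alignment data.frame ([parse_sam()] layout).
#' @param params a [filter_params()] object.
#' @return character vector, one element per record: `NA` for kept records,
#'   otherwise the drop reason.
#' @export
filter_alignment <- function(aln, params = filter_params()) {
  stopifnot(inherits(params, "mgt_filter_params"))
  n <- nrow(aln)
  if (n == 0) return(character(0))
  reason <- rep(NA_character_, n)
  fail <- function(cond, why) {
    reason[is.na(reason) & cond] <<- why
  }
  fail(has_flag(aln$flag, FLAG_UNMAPPED), "unmapped")
  fail(has_flag(aln$flag, FLAG_SECONDARY), "secondary")
  fail(has_flag(aln$flag, FLAG_SUPPLEMENTARY), "supplementary")
  fail(aln$mapq < params$min_mapq, "mapq")
  nm <- aln$nm
  need <- is.na(nm) & is.na(reason)
  if (any(need)) {
    if (params$on_missing_nm == "error") {
      stop(sprintf("alignment record %d (%s) lacks an NM tag",
                   which(need)[1L], aln$qname[which(need)[1L]]))
    }
    if (any(need & is.na(aln$md))) {
      i <- which(need & is.na(aln$md))[1L]
      stop(sprintf("alignment record %d (%s) lacks both NM and MD tags",
                   i, aln$qname[i]))
    }
    nm[need] <- md_to_nm(aln$md[need], aln$cigar[need])
  }
  cols <- cigar_aligned_columns(aln$cigar)
  identity <- ifelse(cols > 0, 1 - nm / cols, 0)
  fail(identity < params$min_read_identity, "identity")
  rlen <- cigar_query_length(aln$cigar)
  cov <- ifelse(rlen > 0, cigar_aligned_read_bases(aln$cigar) / rlen, 0)
  fail(cov < params$min_aln_cov, "aln_cov")
  if (params$require_proper_pair) {
    fail(has_flag(aln$flag, FLAG_PAIRED) & !has_flag(aln$flag, FLAG_PROPER),
         "proper_pair")
    fail(abs(aln$tlen) > params$max_template_len, "template_len")
  }
  reason
}
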