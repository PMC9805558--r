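# Pangenome gene copy-number estimation: vertical coverage of pangenome
# centroids, normalized by the species' median marker coverage so that
# single-copy genes sit near 1.

#' Per-centroid coverage from alignments to the centroid catalog
#'
#' Applies the post-alignment filters (by default the SNV defaults minus
#' the proper-pair requirement), deduplicates mate overlaps so a fragment
#' contributes each centroid position at most once, and sums the
#' contributed bases per centroid.
#'
#' @param aln alignment data.frame against the centroid FASTA.
#' @param centroids named character vector of centroid sequences.
#' @param params a [filter_params()] object.
#' @return data.frame: gene_id, mapped_bases, length, vertical_coverage
#'   (mapped_bases / length), one row per centroid (zeros when uncovered),
#'   sorted by gene_id.
#' @export
gene_coverage <- function(aln, centroids,
                          params = filter_params(require_proper_pair = FALSE)) {
  unknown <- setdiff(unique(aln$rname), names(centroids))
  if (length(unknown)) {
    stop(sprintf("alignment to unknown centroid id: %s", unknown[1L]))
  }
  reason <- filter_alignment(aln, params)
  kept <- aln[is.na(reason), , drop = FALSE]
  mapped <- stats::setNames(rep(0, length(centroids)), names(centroids))
  if (nrow(kept)) {
    key <- paste(kept$qname, kept$rname, sep = "\r")
    for (g in split(seq_len(nrow(kept)), key)) {
      rec1 <- kept[g[1L], ]
      clen <- nchar(centroids[[rec1$rname]])
      b1 <- record_bases(rec1$pos, rec1$cigar, rec1$seq, rec1$qual, clen)
      frag <- if (length(g) >= 2L) {
        rec2 <- kept[g[2L], ]
        resolve_mate_overlap(b1, record_bases(rec2$pos, rec2$cigar, rec2$seq,
                                              rec2$qual, clen))
      } else b1
      mapped[rec1$rname] <- mapped[rec1$rname] + length(frag$refpos)
    }
  }
  out <- data.frame(gene_id = names(centroids), mapped_bases = unname(mapped),
                    length = unname(nchar(centroids)), stringsAsFactors = FALSE)
  out$vertical_coverage <- out$mapped_bases / out$length
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate gene copy numbers from centroid coverage
#'
#' Copy number is vertical coverage divided by the species' median marker
#' coverage from the same sample (the screening module's depth estimate),
#' putting genes present once per cell near 1. A gene is called present
#' when its copy number reaches `presence_threshold`.
#'
#' @param coverages data.frame from [gene_coverage()].
#' @param median_marker_coverage the species' median marker coverage in
#'   this sample (x units, must be > 0).
#' @param presence_threshold copy-number presence cutoff.
#' @return `coverages` with added `copy_number` and `present` columns, or
#'   NULL (with a warning) when `median_marker_coverage` is 0 and copy
#'   number is undefined.
#' @export
estimate_copy_number <- function(coverages, median_marker_coverage,
                                 presence_threshold = 0.35) {
  if (median_marker_coverage <= 0) {
    warning("median marker coverage is 0: copy number undefined, species skipped")
    return(NULL)
  }
  coverages$copy_number <- coverages$vertical_coverage / median_marker_coverage
  coverages$present <- coverages$copy_number >= presence_threshold
  coverages
}

#' Gene copy-number estimation for one sample
#'
#' Aligns the sample's reads to the pangenome centroids of the given
#' species, computes per-centroid coverage, and normalizes by the species'
#' median marker coverage from `profile`.
#'
#' @param r1,r2 read data.frames or FASTQ paths.
#' @param db a `midas_db`.
#' @param species character vector of species ids to genotype.
#' @param profile species profile data.frame for this sample
#'   ([profile_species()] output).
#' @param params a [filter_params()] object.
#' @param presence_threshold copy-number presence cutoff.
#' @param out_path optional TSV output (species_id, gene_id,
#'   vertical_coverage, copy_number, present).
#' @return data.frame with one row per centroid of each species.
#' @export
cnv_sample <- function(r1, r2, db, species, profile,
                       params = filter_params(require_proper_pair = FALSE),
                       presence_threshold = 0.35, out_path = NULL) {
  stopifnot(inherits(db, "midas_db"))
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  out <- NULL
  for (sp in sort(species)) {
    cl <- db$pangenomes[[sp]]
    if (is.null(cl) || length(cl) == 0) next
    centroids <- stats::setNames(vapply(cl, `[[`, "", "centroid_sequence"),
                                 vapply(cl, `[[`, "", "centroid_gene_id"))
    aln <- align_to_target(r1, r2, centroids,
                           max_template_len = params$max_template_len)
    cov <- gene_coverage(aln, centroids, params)
    med <- profile$median_marker_coverage[profile$species_id == sp]
    med <- if (length(med)) med[1L] else 0
    cn <- estimate_copy_number(cov, med, presence_threshold)
    if (is.null(cn)) next
    cn <- cbind(data.frame(species_id = sp, stringsAsFactors = FALSE), cn)
    out <- rbind(out, cn)
  }
  if (is.null(out)) {
    out <- data.frame(species_id = character(0), gene_id = character(0),
                      mapped_bases = numeric(0), length = integer(0),
                      vertical_coverage = numeric(0), copy_number = numeric(0),
                      present = logical(0), stringsAsFactors = FALSE)
  }
  if (!is.null(out_path)) {
    tsv <- data.frame(species_id = out$species_id, gene_id = out$gene_id,
                      vertical_coverage = fmt4(out$vertical_coverage),
                      copy_number = fmt4(out$copy_number),
                      present = out$present, stringsAsFactors = FALSE)
    write_tsv(tsv, out_path)
  }
  out
}
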