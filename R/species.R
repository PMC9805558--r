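# Sample-customized species screening: estimate per-species marker-gene
# coverage from the reads, select the species actually present, and build
# the concatenated representative-genome target for SNV alignment.

#' Map reads to the marker-gene catalog
#'
#' Each read (mates treated independently) is assigned to at most one
#' marker gene: the hit with the most identical bases that meets
#' `min_identity` and `min_aln_len`. Ties within one species break
#' lexicographically by marker gene id; reads tying across different
#' species' markers at identical score are discarded (conservative
#' unique-mapping rule).
#'
#' @param r1,r2 read data.frames (`id`, `seq`, `qual`) or FASTQ paths; `r2`
#'   may be NULL for single-end input.
#' @param markers marker data.frame (`gene_id`, `sequence`, `species_id`,
#'   `marker_family`, `length`) as in a `midas_db`, or a `midas_db`.
#' @param min_identity minimum alignment identity.
#' @param min_aln_len minimum aligned length in bases.
#' @return data.frame: read_id, gene_id, species_id, marker_family,
#'   aligned_len, nm, identity.
#' @export
map_to_markers <- function(r1, r2 = NULL, markers, min_identity = 0.94,
                           min_aln_len = 50L) {
  if (inherits(markers, "midas_db")) markers <- markers$markers
  if (nrow(markers) == 0) stop("marker catalog is empty")
  if (is.character(r1)) r1 <- read_fastq(r1)
  if (is.character(r2)) r2 <- read_fastq(r2)
  reads <- r1
  reads$id <- paste0(reads$id, "/1")
  if (!is.null(r2)) {
    r2$id <- paste0(r2$id, "/2")
    reads <- rbind(reads, r2)
  }
  mseqs <- stats::setNames(markers$sequence, markers$gene_id)
  mseqs <- mseqs[order(names(mseqs))] # lexicographic order drives tie-breaks
  idx <- seed_index(mseqs)
  hits <- align_reads(reads, idx, max_mismatch_frac = 1 - min_identity + 0.05)
  if (nrow(hits) == 0) {
    return(data.frame(read_id = character(0), gene_id = character(0),
                      species_id = character(0), marker_family = character(0),
                      aligned_len = integer(0), nm = integer(0),
                      identity = numeric(0), stringsAsFactors = FALSE))
  }
  aln_len <- cigar_aligned_read_bases(hits$cigar)
  identity <- 1 - hits$nm / cigar_aligned_columns(hits$cigar)
  sp_of <- markers$species_id[match(hits$rname, markers$gene_id)]
  tie_sp <- markers$species_id[match(hits$tie_rname, markers$gene_id)]
  cross_tie <- !is.na(tie_sp) & tie_sp != sp_of
  keep <- identity >= min_identity & aln_len >= min_aln_len & !cross_tie
  hits <- hits[keep, , drop = FALSE]
  mrow <- match(hits$rname, markers$gene_id)
  out <- data.frame(read_id = hits$qname, gene_id = hits$rname,
                    species_id = markers$species_id[mrow],
                    marker_family = markers$marker_family[mrow],
                    aligned_len = aln_len[keep], nm = hits$nm,
                    identity = identity[keep], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Profile species from marker hits
#'
#' Marker coverage is mapped bases over marker length; the species depth is
#' the median coverage over the full marker panel, counting panel families
#' without mapped bases (or absent from the database for that species) as
#' zero. Relative abundance normalizes the medians over all species with
#' nonzero median.
#'
#' @param hits data.frame from [map_to_markers()].
#' @param db a `midas_db` (or its `markers` data.frame).
#' @param panel marker family panel over which the median is taken.
#' @return data.frame: species_id, median_marker_coverage,
#'   relative_abundance, n_markers_covered; species with at least one hit
#'   only, sorted by species_id.
#' @export
profile_species <- function(hits, db, panel = marker_panel()) {
  markers <- if (inherits(db, "midas_db")) db$markers else db
  if (nrow(hits) == 0) {
    return(data.frame(species_id = character(0),
                      median_marker_coverage = numeric(0),
                      relative_abundance = numeric(0),
                      n_markers_covered = integer(0), stringsAsFactors = FALSE))
  }
  mapped <- tapply(hits$aligned_len, hits$gene_id, sum)
  out <- NULL
  for (sp in sort(unique(hits$species_id))) {
    mk <- markers[markers$species_id == sp, , drop = FALSE]
    cov <- stats::setNames(rep(0, length(panel)), panel)
    mb <- mapped[mk$gene_id]
    mb[is.na(mb)] <- 0
    cov[mk$marker_family] <- mb / mk$length
    out <- rbind(out, data.frame(
      species_id = sp,
      median_marker_coverage = stats::median(cov),
      n_markers_covered = sum(cov > 0), stringsAsFactors = FALSE))
  }
  tot <- sum(out$median_marker_coverage[out$median_marker_coverage > 0])
  out$relative_abundance <- if (tot > 0) out$median_marker_coverage / tot else 0
  out <- out[, c("species_id", "median_marker_coverage",
                 "relative_abundance", "n_markers_covered")]
  rownames(out) <- NULL
  out
}

#' Select species passing the screening threshold
#'
#' @param profiles data.frame from [profile_species()].
#' @param min_median_coverage minimum median marker coverage (x units);
#'   the default 2x is the screening convention of the MIDAS tool lineage.
#' @return character vector of selected species ids, sorted.
#' @export
select_species <- function(profiles, min_median_coverage = 2.0) {
  stopifnot(min_median_coverage >= 0)
  sort(profiles$species_id[profiles$median_marker_coverage >= min_median_coverage])
}

#' Build the sample-customized alignment target
#'
#' Concatenates the representative genomes of the selected species into one
#' multi-FASTA, rewriting contig ids as `<species_id>|<contig_id>`, in
#' deterministic (lexicographic) order.
#'
#' @param selected character vector of species ids.
#' @param db a `midas_db`.
#' @param out_path optional path to write the FASTA to.
#' @return named character vector of target sequences (invisibly written
#'   to `out_path` when given).
#' @export
build_custom_target <- function(selected, db, out_path = NULL) {
  stopifnot(inherits(db, "midas_db"))
  missing_sp <- setdiff(selected, names(db$representatives))
  if (length(missing_sp)) {
    stop(sprintf("species without representative in database: %s",
                 paste(missing_sp, collapse = ", ")))
  }
  if (length(selected) == 0) {
    warning("empty species selection: alignment target is empty")
    out <- stats::setNames(character(0), character(0))
  } else {
    out <- character(0)
    for (sp in sort(selected)) {
      g <- read_fasta(db$representatives[[sp]])
      names(g) <- paste0(sp, "|", names(g))
      attr(g, "description") <- NULL
      out <- c(out, g)
    }
  }
  if (!is.null(out_path)) {
    if (length(out)) write_fasta(out, out_path) else writeLines(character(0), out_path)
  }
  out
}

#' Screen one sample end-to-end
#'
#' Maps reads to the marker catalog, profiles species, and returns the
#' profile table (optionally written as TSV).
#'
#' @inheritParams map_to_markers
#' @param db a `midas_db`.
#' @param out_path optional TSV output path (columns species_id,
#'   median_marker_coverage, relative_abundance, n_markers_covered).
#' @return the profile data.frame.
#' @export
screen_sample <- function(r1, r2 = NULL, db, min_identity = 0.94,
                          min_aln_len = 50L, out_path = NULL) {
  hits <- map_to_markers(r1, r2, db, min_identity, min_aln_len)
  prof <- profile_species(hits, db)
  if (!is.null(out_path)) {
    tsv <- prof
    tsv$median_marker_coverage <- fmt4(tsv$median_marker_coverage)
    tsv$relative_abundance <- fmt4(tsv$relative_abundance)
    write_tsv(tsv, out_path)
  }
  prof
}
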