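# Reference-database construction: marker genes, representative genomes and
# species pangenomes, built from a genome collection described by a
# table-of-contents (TOC) file. All sort orders are fixed so rebuilding from
# identical inputs yields byte-identical files.

#' Parse a genome-collection table-of-contents file
#'
#' The TOC is a tab-separated file with header columns `genome_id`,
#' `species_id`, `is_representative`, `genome_path`, `genes_path`,
#' assigning genomes to species and designating exactly one representative
#' genome per species.
#'
#' @param toc_path path to the TOC TSV.
#' @return an object of class `genome_collection`: list with `records`
#'   (validated data.frame) and `species` (sorted species ids).
#' @export
parse_toc <- function(toc_path) {
  if (!file.exists(toc_path)) stop_input("TOC file not found: %s", toc_path)
  rec <- read_tsv(toc_path, colClasses = "character")
  need <- c("genome_id", "species_id", "is_representative",
            "genome_path", "genes_path")
  miss <- setdiff(need, names(rec))
  if (length(miss)) {
    stop_input("TOC is missing column(s): %s", paste(miss, collapse = ", "))
  }
  rec$is_representative <- toupper(rec$is_representative) %in% c("TRUE", "T", "1")
  if (anyDuplicated(rec$genome_id)) {
    dup <- rec$genome_id[duplicated(rec$genome_id)][1L]
    stop(sprintf("duplicate genome_id in TOC: %s", dup))
  }
  if (nrow(rec)) {
    nrep <- tapply(rec$is_representative, rec$species_id, sum)
    bad <- names(nrep)[nrep != 1L]
    if (length(bad)) {
      stop(sprintf("species %s has %d representative genomes (exactly 1 required)",
                   bad[1L], nrep[[bad[1L]]]))
    }
    for (p in c(rec$genome_path, rec$genes_path)) {
      if (!file.exists(p)) stop_input("file referenced by TOC not found: %s", p)
    }
  }
  rec <- rec[order(rec$species_id, rec$genome_id), , drop = FALSE]
  rownames(rec) <- NULL
  structure(list(records = rec, species = sort(unique(rec$species_id))),
            class = "genome_collection")
}

#' @export
print.genome_collection <- function(x, ...) {
  cat(sprintf("<genome_collection> %d species, %d genomes\n",
              length(x$species), nrow(x$records)))
  invisible(x)
}

# parse "marker_family=<label>" tags out of gene FASTA descriptions
gene_marker_tags <- function(genes_path) {
  g <- read_fasta(genes_path)
  desc <- attr(g, "description")
  m <- regmatches(desc, regexpr("marker_family=\\S+", desc))
  fam <- rep(NA_character_, length(g))
  hit <- grepl("marker_family=", desc)
  fam[hit] <- sub("marker_family=", "", m)
  data.frame(gene_id = names(g), sequence = unname(g), marker_family = fam,
             stringsAsFactors = FALSE)
}

#' Extract universal single-copy marker genes from representatives
#'
#' For each species, genes of the representative genome whose description
#' carries a `marker_family=<label>` tag in the panel are collected; a
#' representative with two genes tagged with the same family violates the
#' single-copy assumption and raises an error. Species with no tagged
#' genes are permitted (they simply cannot be screened) and reported via a
#' message.
#'
#' @param collection a [parse_toc()] result.
#' @param panel character vector of marker family labels.
#' @return data.frame: species_id, marker_family, gene_id, length,
#'   sequence; sorted by (species_id, marker_family).
#' @export
extract_markers <- function(collection, panel = marker_panel()) {
  stopifnot(inherits(collection, "genome_collection"))
  reps <- collection$records[collection$records$is_representative, , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(reps))) {
    sp <- reps$species_id[i]
    tags <- gene_marker_tags(reps$genes_path[i])
    tags <- tags[!is.na(tags$marker_family) & tags$marker_family %in% panel, ,
                 drop = FALSE]
    if (anyDuplicated(tags$marker_family)) {
      fam <- tags$marker_family[duplicated(tags$marker_family)][1L]
      stop(sprintf("species %s: two genes tagged with marker family %s (single-copy violation)",
                   sp, fam))
    }
    if (nrow(tags) == 0) {
      message(sprintf("species %s has no marker genes; it will be unscreenable", sp))
      next
    }
    out <- rbind(out, data.frame(
      species_id = sp, marker_family = tags$marker_family,
      gene_id = tags$gene_id, length = nchar(tags$sequence),
      sequence = tags$sequence, stringsAsFactors = FALSE))
  }
  if (is.null(out)) {
    out <- data.frame(species_id = character(0), marker_family = character(0),
                      gene_id = character(0), length = integer(0),
                      sequence = character(0), stringsAsFactors = FALSE)
  }
  out <- out[order(out$species_id, out$marker_family), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# global alignment identity = matches / alignment columns
seq_identity <- function(a, b) {
  # cheap upper bound: identity cannot exceed shorter/longer length
  if (min(nchar(a), nchar(b)) / max(nchar(a), nchar(b)) < 0.5) {
    return(min(nchar(a), nchar(b)) / max(nchar(a), nchar(b)))
  }
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global")
  # alignment columns = length of the gapped pattern
  Biostrings::nmatch(aln) / nchar(as.character(Biostrings::alignedPattern(aln)))
}

kmer_set <- function(s, k = 12L) {
  if (nchar(s) < k) return(character(0))
  unique(substring(s, 1:(nchar(s) - k + 1L), k:nchar(s)))
}

#' Greedy centroid clustering of a species' genes
#'
#' Genes are sorted by descending length (ties broken lexicographically by
#' gene id); each gene joins the first existing cluster whose centroid it
#' matches at `>= identity_threshold` global identity (matches over
#' alignment columns), otherwise it founds a new cluster. Clusters
#' partition the input, and the centroid is always the longest member.
#'
#' Gene-versus-centroid comparisons use two shortcuts before the full
#' global alignment: equal-length pairs whose ungapped (Hamming) identity
#' already reaches the threshold are accepted directly (an ungapped global
#' alignment attains that identity), and pairs sharing fewer than 10% of
#' their 12-mers are rejected without alignment (sequences near the
#' threshold share far more; this is the usual word-count prefilter of
#' greedy clustering tools).
#'
#' @param genes data.frame with columns `gene_id`, `sequence`.
#' @param identity_threshold fraction in (0, 1].
#' @return list of clusters, each a list with `centroid_gene_id`,
#'   `centroid_sequence`, `member_gene_ids`, `identity_threshold`.
#' @export
build_pangenome <- function(genes, identity_threshold = 0.95) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1,
            all(nchar(genes$sequence) > 0))
  ord <- order(-nchar(genes$sequence), genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  kmers <- lapply(genes$sequence, kmer_set)
  clusters <- list()
  cluster_kmers <- list()
  for (i in seq_len(nrow(genes))) {
    si <- genes$sequence[i]
    placed <- FALSE
    for (j in seq_along(clusters)) {
      cj <- clusters[[j]]$centroid_sequence
      # length prefilter: identity is at most shorter/longer
      if (nchar(si) / nchar(cj) < identity_threshold) next
      if (nchar(si) == nchar(cj) &&
          1 - hamming(si, cj) / nchar(si) >= identity_threshold) {
        placed <- TRUE
      } else {
        shared <- sum(kmers[[i]] %in% cluster_kmers[[j]])
        lo <- min(length(kmers[[i]]), length(cluster_kmers[[j]]))
        if (lo > 0 && shared / lo < 0.10) next
        placed <- seq_identity(si, cj) >= identity_threshold
      }
      if (placed) {
        clusters[[j]]$member_gene_ids <- c(clusters[[j]]$member_gene_ids,
                                           genes$gene_id[i])
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- list(
        centroid_gene_id = genes$gene_id[i],
        centroid_sequence = si,
        member_gene_ids = genes$gene_id[i],
        identity_threshold = identity_threshold)
      cluster_kmers[[length(clusters)]] <- kmers[[i]]
    }
  }
  clusters
}

#' Build the three-part reference database
#'
#' Writes `markers.fa` (all species' marker genes),
#' `<species_id>/representative.fa`, `<species_id>/centroids.fa` (pangenome
#' cluster centroids from all the species' genomes) and `manifest.tsv` with
#' per-species component counts and MD5 checksums of the written files.
#' Rebuilding from identical inputs reproduces every file byte-for-byte.
#'
#' @param collection a [parse_toc()] result.
#' @param panel marker family panel.
#' @param identity_threshold pangenome clustering identity threshold.
#' @param out_dir output directory (created if needed).
#' @return an object of class `midas_db`: list with `dir`, `markers`
#'   (data.frame), `representatives` (species -> FASTA path),
#'   `pangenomes` (species -> cluster list), `manifest` (data.frame),
#'   `panel`, `identity_threshold`.
#' @export
build_db <- function(collection, panel = marker_panel(),
                     identity_threshold = 0.95, out_dir) {
  stopifnot(inherits(collection, "genome_collection"))
  ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop_input("cannot create output directory: %s", out_dir)
  markers <- extract_markers(collection, panel)
  mseqs <- stats::setNames(markers$sequence, markers$gene_id)
  attr(mseqs, "description") <- sprintf("%s species_id=%s marker_family=%s",
                                        markers$gene_id, markers$species_id,
                                        markers$marker_family)
  markers_path <- file.path(out_dir, "markers.fa")
  write_fasta(mseqs, markers_path)
  rec <- collection$records
  representatives <- character(0)
  pangenomes <- list()
  manifest <- NULL
  for (sp in collection$species) {
    sub <- rec[rec$species_id == sp, , drop = FALSE]
    spdir <- file.path(out_dir, sp)
    dir.create(spdir, showWarnings = FALSE)
    rep_row <- sub[sub$is_representative, , drop = FALSE]
    rep_path <- file.path(spdir, "representative.fa")
    write_fasta(read_fasta(rep_row$genome_path), rep_path)
    genes <- NULL
    for (i in seq_len(nrow(sub))) {
      g <- gene_marker_tags(sub$genes_path[i])
      genes <- rbind(genes, g[, c("gene_id", "sequence")])
    }
    clusters <- if (is.null(genes) || nrow(genes) == 0) list() else
      build_pangenome(genes, identity_threshold)
    cent_path <- file.path(spdir, "centroids.fa")
    cent_ids <- vapply(clusters, `[[`, "", "centroid_gene_id")
    cent_seq <- vapply(clusters, `[[`, "", "centroid_sequence")
    cord <- order(cent_ids)
    write_fasta(stats::setNames(cent_seq[cord], cent_ids[cord]), cent_path)
    representatives[sp] <- rep_path
    pangenomes[[sp]] <- clusters[cord]
    manifest <- rbind(manifest, data.frame(
      species_id = sp, n_genomes = nrow(sub),
      rep_genome_id = rep_row$genome_id,
      n_markers = sum(markers$species_id == sp),
      n_centroids = length(clusters),
      rep_md5 = unname(tools::md5sum(rep_path)),
      centroids_md5 = unname(tools::md5sum(cent_path)),
      markers_md5 = unname(tools::md5sum(markers_path)),
      stringsAsFactors = FALSE))
  }
  if (is.null(manifest)) {
    manifest <- data.frame(species_id = character(0), n_genomes = integer(0),
                           rep_genome_id = character(0), n_markers = integer(0),
                           n_centroids = integer(0), rep_md5 = character(0),
                           centroids_md5 = character(0),
                           markers_md5 = character(0), stringsAsFactors = FALSE)
  }
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  structure(list(dir = out_dir, markers = markers,
                 representatives = representatives,
                 pangenomes = pangenomes, manifest = manifest,
                 panel = panel, identity_threshold = identity_threshold),
            class = "midas_db")
}

#' @export
print.midas_db <- function(x, ...) {
  cat(sprintf("<midas_db> %d species at %s\n", nrow(x$manifest), x$dir))
  cat(sprintf("  markers: %d | pangenome centroids: %d\n",
              nrow(x$markers), sum(x$manifest$n_centroids)))
  invisible(x)
}

#' Load a built database from disk
#'
#' Reads `manifest.tsv` and the component FASTA files back into a
#' `midas_db` object, verifying that the on-disk checksums still match the
#' manifest.
#'
#' @param dir a directory written by [build_db()].
#' @return a `midas_db` object (pangenome clusters carry centroid
#'   information only; member lists are not persisted).
#' @export
load_db <- function(dir) {
  man_path <- file.path(dir, "manifest.tsv")
  if (!file.exists(man_path)) stop_input("no manifest.tsv under %s", dir)
  manifest <- read_tsv(man_path)
  manifest$species_id <- as.character(manifest$species_id)
  markers_path <- file.path(dir, "markers.fa")
  mk <- read_fasta(markers_path)
  desc <- attr(mk, "description")
  markers <- data.frame(
    species_id = sub(".*species_id=(\\S+).*", "\\1", desc),
    marker_family = sub(".*marker_family=(\\S+).*", "\\1", desc),
    gene_id = names(mk), length = nchar(mk), sequence = unname(mk),
    stringsAsFactors = FALSE)
  markers <- markers[order(markers$species_id, markers$marker_family), ,
                     drop = FALSE]
  rownames(markers) <- NULL
  representatives <- character(0)
  pangenomes <- list()
  for (i in seq_len(nrow(manifest))) {
    sp <- manifest$species_id[i]
    rep_path <- file.path(dir, sp, "representative.fa")
    cent_path <- file.path(dir, sp, "centroids.fa")
    for (p in c(rep_path, cent_path)) {
      if (!file.exists(p)) stop_input("database file missing: %s", p)
    }
    if (!identical(unname(tools::md5sum(rep_path)), manifest$rep_md5[i]) ||
        !identical(unname(tools::md5sum(cent_path)), manifest$centroids_md5[i])) {
      stop(sprintf("checksum mismatch for species %s: database files changed since build", sp))
    }
    representatives[sp] <- rep_path
    cent <- read_fasta(cent_path)
    pangenomes[[sp]] <- lapply(names(cent), function(id) {
      list(centroid_gene_id = id, centroid_sequence = cent[[id]],
           member_gene_ids = NA_character_, identity_threshold = NA_real_)
    })
  }
  structure(list(dir = dir, markers = markers,
                 representatives = representatives, pangenomes = pangenomes,
                 manifest = manifest, panel = marker_panel(),
                 identity_threshold = NA_real_),
            class = "midas_db")
}

#' Tag marker genes from an external HMM-search hit table
#'
#' Adapter for collections whose gene files lack `marker_family=` tags:
#' rewrites a gene FASTA adding tags for the (gene_id, marker_family)
#' pairs of a hit table, e.g. one produced by an external profile-HMM
#' search against a universal single-copy family panel.
#'
#' @param genes_path gene FASTA to annotate.
#' @param hits data.frame with columns `gene_id`, `marker_family`.
#' @param out_path annotated FASTA to write.
#' @return `out_path`, invisibly.
#' @export
apply_marker_hits <- function(genes_path, hits, out_path) {
  g <- read_fasta(genes_path)
  fam <- hits$marker_family[match(names(g), hits$gene_id)]
  desc <- ifelse(is.na(fam), names(g),
                 paste0(names(g), " marker_family=", fam))
  attr(g, "description") <- desc
  write_fasta(g, out_path)
  invisible(out_path)
}
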