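# Across-samples population SNV calling.
#
# Per-sample pileups are scanned site-by-site in position chunks. Each
# chunk is a self-contained unit of work (no cross-chunk state), so chunks
# can be processed by any number of workers in any order; the merged
# output is byte-identical for every chunk size and worker count. Sites
# are pooled over the samples in which they are "relevant" (adequately but
# not excessively covered), and a site enters the output when enough
# samples are relevant there.

#' Across-samples site filters
#'
#' @param site_min_depth minimum per-sample depth for a site to count as
#'   relevant in that sample.
#' @param site_max_depth_fold maximum depth as a multiple of the sample's
#'   species-wide mean depth (repeat guard).
#' @param min_sample_prevalence minimum fraction of samples in which the
#'   site must be relevant for the site to be reported.
#' @param allele_min_freq minimum pooled frequency for an allele to count
#'   toward the site's allele class (mono/bi/tri/quad); keeps residual
#'   sequencing error (~1e-3 after base-quality filtering) from promoting
#'   sites to higher allele classes.
#' @return list of class `mgt_site_filters`.
#' @export
site_filters <- function(site_min_depth = 5L, site_max_depth_fold = 3,
                         min_sample_prevalence = 0.8,
                         allele_min_freq = 0.01) {
  stopifnot(site_min_depth >= 0, site_max_depth_fold >= 0,
            min_sample_prevalence >= 0, min_sample_prevalence <= 1,
            allele_min_freq >= 0, allele_min_freq < 1)
  structure(list(site_min_depth = as.integer(site_min_depth),
                 site_max_depth_fold = site_max_depth_fold,
                 min_sample_prevalence = min_sample_prevalence,
                 allele_min_freq = allele_min_freq),
            class = "mgt_site_filters")
}

#' Split contigs into consecutive position chunks
#'
#' @param contigs data.frame with columns species_id, contig_id, length.
#' @param chunk_size chunk width in sites.
#' @return data.frame: chunk_id, species_id, contig_id, start, end with
#'   0-based half-open `[start, end)` intervals that tile each contig
#'   exactly, ordered by (species_id, contig_id, start).
#' @export
make_chunks <- function(contigs, chunk_size = 100000L) {
  stopifnot(chunk_size >= 1)
  contigs <- contigs[order(contigs$species_id, contigs$contig_id), , drop = FALSE]
  out <- NULL
  for (i in seq_len(nrow(contigs))) {
    L <- contigs$length[i]
    start <- seq.int(0L, L - 1L, by = chunk_size)
    out <- rbind(out, data.frame(
      species_id = contigs$species_id[i], contig_id = contigs$contig_id[i],
      start = start, end = pmin(start + chunk_size, L),
      stringsAsFactors = FALSE))
  }
  out$chunk_id <- seq_len(nrow(out))
  out[, c("chunk_id", "species_id", "contig_id", "start", "end")]
}

#' Is a site relevant in a sample?
#'
#' A site counts for a sample when its depth is at least
#' `site_min_depth` and at most `site_max_depth_fold` times the sample's
#' species-wide mean depth.
#'
#' @param depth site depth(s) in the sample (vectorized).
#' @param mean_depth the sample's mean depth over the species genome.
#' @param filters a [site_filters()] object.
#' @return logical vector.
#' @export
site_relevance <- function(depth, mean_depth, filters = site_filters()) {
  mean_depth > 0 & depth >= filters$site_min_depth &
    depth <= filters$site_max_depth_fold * mean_depth
}

# Pooling core over n sites x S samples. cnt: list of 4 (A,C,G,T) n x S
# count matrices; rel: n x S logical. Returns pooled summed counts, the
# pooling statistic, and major/minor allele indices (NA minor when the
# pooled site is monomorphic).
pool_counts_core <- function(cnt, rel, method = c("counts", "prevalence")) {
  method <- match.arg(method)
  n <- nrow(rel)
  relnum <- rel * 1L
  summed <- matrix(0, n, 4L)
  for (b in 1:4) summed[, b] <- rowSums(cnt[[b]] * relnum)
  if (method == "counts") {
    stat <- summed
  } else {
    m <- pmax(cnt[[1L]], cnt[[2L]], cnt[[3L]], cnt[[4L]])
    stat <- matrix(0, n, 4L)
    taken <- matrix(FALSE, n, ncol(rel))
    for (b in 1:4) {
      is_maj <- (cnt[[b]] == m) & !taken & (m > 0)
      stat[, b] <- rowSums(is_maj & rel)
      taken <- taken | is_maj
    }
  }
  maj <- max.col(stat, ties.method = "first")
  s2 <- stat
  s2[cbind(seq_len(n), maj)] <- -1
  minr <- max.col(s2, ties.method = "first")
  support <- s2[cbind(seq_len(n), minr)]
  list(summed = summed, stat = stat, major = maj,
       minor = ifelse(support > 0, minr, NA_integer_))
}

#' Pool allele counts over samples at one site
#'
#' Method `"counts"` takes the argmax of the summed (relevant-sample)
#' counts; method `"prevalence"` takes the allele that is the within-sample
#' major in the most relevant samples. Ties break lexicographically; the
#' pooled minor allele is the runner-up by the same statistic with nonzero
#' support.
#'
#' @param counts S x 4 matrix of per-sample A,C,G,T counts (a vector is
#'   taken as a single sample).
#' @param method pooling statistic.
#' @param relevant logical length-S vector (default: all samples).
#' @return list: pooled_major, pooled_minor (NA if monomorphic),
#'   pooled_counts (named numeric of summed counts),
#'   per_sample_minor_freq (NA for non-relevant samples).
#' @export
pool_site <- function(counts, method = c("counts", "prevalence"),
                      relevant = NULL) {
  if (is.null(dim(counts))) counts <- matrix(counts, nrow = 1L)
  stopifnot(ncol(counts) == 4L)
  S <- nrow(counts)
  relevant <- relevant %||% rep(TRUE, S)
  stopifnot(any(relevant))
  cnt <- lapply(1:4, function(b) matrix(counts[, b], nrow = 1L))
  core <- pool_counts_core(cnt, matrix(relevant, nrow = 1L), method)
  depth <- rowSums(counts)
  minor_freq <- rep(NA_real_, S)
  if (!is.na(core$minor[1L])) {
    minor_freq[relevant] <- ifelse(depth[relevant] > 0,
                                   counts[relevant, core$minor[1L]] / depth[relevant], 0)
  } else {
    minor_freq[relevant] <- 0
  }
  list(pooled_major = BASES[core$major[1L]],
       pooled_minor = if (is.na(core$minor[1L])) NA_character_ else BASES[core$minor[1L]],
       pooled_counts = stats::setNames(core$summed[1L, ], BASES),
       per_sample_minor_freq = minor_freq)
}

# Build dense per-contig count/depth matrices from per-sample pileup
# data.frames (layout of snv_single_sample()$pileup / read_pileup_tsv()).
# Also computes per-species per-sample mean depths and checks sortedness.
build_pileup_mats <- function(pileups, contigs) {
  stopifnot(length(names(pileups)) == length(pileups))
  samples <- names(pileups)
  S <- length(samples)
  contigs <- contigs[order(contigs$species_id, contigs$contig_id), , drop = FALSE]
  mats <- list()
  for (i in seq_len(nrow(contigs))) {
    sp <- contigs$species_id[i]; ct <- contigs$contig_id[i]
    L <- contigs$length[i]
    cnt <- lapply(1:4, function(b) matrix(0L, L, S))
    depth <- matrix(0L, L, S)
    ref <- rep(NA_character_, L)
    for (s in seq_len(S)) {
      pu <- pileups[[s]]
      rows <- which(pu$species_id == sp & pu$contig_id == ct)
      if (!length(rows)) next
      pos <- pu$pos[rows]
      if (is.unsorted(pos, strictly = TRUE)) {
        bad <- rows[which(diff(pos) <= 0)[1L] + 1L]
        stop(sprintf("pileup of sample %s is not position-sorted at %s:%d",
                     samples[s], ct, pu$pos[bad]))
      }
      if (max(pos) > L) {
        stop(sprintf("pileup of sample %s has position %d beyond contig %s length %d",
                     samples[s], max(pos), ct, L))
      }
      for (b in 1:4) cnt[[b]][pos, s] <- pu[[BASES[b]]][rows]
      depth[pos, s] <- pu$depth[rows]
      ref[pos] <- pu$ref[rows]
    }
    mats[[paste(sp, ct, sep = "|")]] <-
      list(species_id = sp, contig_id = ct, length = L,
           cnt = cnt, depth = depth, ref = ref)
  }
  # mean depth over the species genome, per sample
  mean_depth <- list()
  for (sp in unique(contigs$species_id)) {
    tot_len <- sum(contigs$length[contigs$species_id == sp])
    tot <- rep(0, S)
    for (m in mats) {
      if (m$species_id == sp) tot <- tot + colSums(m$depth)
    }
    mean_depth[[sp]] <- stats::setNames(tot / tot_len, samples)
  }
  structure(list(mats = mats, mean_depth = mean_depth, samples = samples),
            class = "mgt_pileup_mats")
}

#' Process one chunk of genomic sites
#'
#' Scans each site of the chunk once across all samples, applies
#' [site_relevance()] per sample and the prevalence filter across samples,
#' and pools the surviving sites. The returned accumulator is
#' self-contained: merging accumulators requires no shared state.
#'
#' @param chunk one row of [make_chunks()] (list or data.frame row).
#' @param pileups named (by sample) list of pileup data.frames, or a
#'   prebuilt matrix store as used internally by [snv_merge()].
#' @param filters a [site_filters()] object.
#' @param method pooling method, `"counts"` or `"prevalence"`.
#' @param contigs contig table (required for the data.frame input path, to
#'   compute mean depths; ignored for the prebuilt store).
#' @return an accumulator list with the chunk coordinates, per-site info
#'   fields and per-sample minor-frequency/depth rows.
#' @export
process_chunk <- function(chunk, pileups, filters = site_filters(),
                          method = "counts", contigs = NULL) {
  if (!inherits(pileups, "mgt_pileup_mats")) {
    stopifnot(!is.null(contigs))
    pileups <- build_pileup_mats(pileups, contigs)
  }
  key <- paste(chunk$species_id, chunk$contig_id, sep = "|")
  m <- pileups$mats[[key]]
  if (is.null(m)) stop(sprintf("unknown chunk target: %s", key))
  S <- length(pileups$samples)
  pos <- (chunk$start + 1L):chunk$end
  w <- length(pos)
  depth <- m$depth[pos, , drop = FALSE]
  md <- pileups$mean_depth[[chunk$species_id]]
  cap <- matrix(filters$site_max_depth_fold * md, w, S, byrow = TRUE)
  ok_mean <- matrix(md > 0, w, S, byrow = TRUE)
  rel <- ok_mean & depth >= filters$site_min_depth & depth <= cap
  n_rel <- rowSums(rel)
  keep <- n_rel >= 1L & (n_rel / S) >= filters$min_sample_prevalence - 1e-12
  acc <- list(chunk_id = chunk$chunk_id, species_id = chunk$species_id,
              contig_id = chunk$contig_id, start = chunk$start,
              end = chunk$end, samples = pileups$samples)
  if (!any(keep)) {
    acc$pos <- integer(0)
    return(acc)
  }
  kk <- which(keep)
  cnt <- lapply(m$cnt, function(x) x[pos[kk], , drop = FALSE])
  relk <- rel[kk, , drop = FALSE]
  core <- pool_counts_core(cnt, relk, method)
  n <- length(kk)
  pooled_depth <- rowSums(core$summed)
  minor_cnt_sample <- matrix(0L, n, S)
  minor_cnt_pooled <- rep(0, n)
  has_min <- !is.na(core$minor)
  for (b in 1:4) {
    rows <- which(has_min & core$minor == b)
    if (length(rows)) {
      minor_cnt_sample[rows, ] <- cnt[[b]][rows, , drop = FALSE]
      minor_cnt_pooled[rows] <- core$summed[cbind(rows, b)]
    }
  }
  depth_k <- depth[kk, , drop = FALSE]
  freq <- ifelse(depth_k > 0, minor_cnt_sample / pmax(depth_k, 1L), 0)
  freq[!relk] <- NA
  depth_out <- depth_k
  depth_out[!relk] <- NA
  n_alleles <- rowSums(core$summed > 0 &
                         core$summed >= filters$allele_min_freq * pooled_depth)
  acc$pos <- pos[kk]
  acc$ref <- m$ref[pos[kk]]
  acc$pooled_major <- BASES[core$major]
  acc$pooled_minor <- ifelse(has_min, BASES[core$minor], NA_character_)
  acc$pooled_counts <- core$summed
  acc$pooled_depth <- pooled_depth
  acc$pooled_minor_freq <- ifelse(pooled_depth > 0, minor_cnt_pooled / pmax(pooled_depth, 1), 0)
  acc$n_relevant <- n_rel[kk]
  acc$allele_class <- c("mono", "bi", "tri", "quad")[pmax(n_alleles, 1L)]
  acc$freq <- freq
  acc$depth <- depth_out
  acc
}

#' Merge chunk accumulators into population-SNV matrices
#'
#' Validates that accumulators cover disjoint chunks, concatenates them and
#' sorts by (species, contig, position). The result is invariant to the
#' accumulators' arrival order and to the chunk size they were produced
#' with.
#'
#' @param accs list of accumulators from [process_chunk()].
#' @return list of class `mgt_popsnv` with data.frames `info`, `freq`,
#'   `depth` (freq/depth: one column per sample, NA where the sample was
#'   not relevant at the site).
#' @export
merge_chunks <- function(accs) {
  if (length(accs) == 0) {
    return(structure(list(info = empty_popsnv_info(),
                          freq = data.frame(), depth = data.frame(),
                          samples = character(0)), class = "mgt_popsnv"))
  }
  samples <- accs[[1L]]$samples
  for (a in accs) stopifnot(identical(a$samples, samples))
  # disjointness per (species, contig)
  meta <- data.frame(
    species = vapply(accs, `[[`, "", "species_id"),
    contig = vapply(accs, `[[`, "", "contig_id"),
    start = vapply(accs, function(a) as.integer(a$start), integer(1)),
    end = vapply(accs, function(a) as.integer(a$end), integer(1)),
    stringsAsFactors = FALSE)
  for (key in unique(paste(meta$species, meta$contig))) {
    sub <- meta[paste(meta$species, meta$contig) == key, , drop = FALSE]
    sub <- sub[order(sub$start), , drop = FALSE]
    if (nrow(sub) > 1 && any(sub$start[-1L] < sub$end[-nrow(sub)])) {
      stop(sprintf("overlapping chunks on %s", key))
    }
  }
  nonempty <- accs[vapply(accs, function(a) length(a$pos) > 0, logical(1))]
  if (length(nonempty) == 0) {
    return(structure(list(info = empty_popsnv_info(),
                          freq = as.data.frame(matrix(numeric(0), 0, length(samples),
                                                      dimnames = list(NULL, samples))),
                          depth = as.data.frame(matrix(numeric(0), 0, length(samples),
                                                       dimnames = list(NULL, samples))),
                          samples = samples), class = "mgt_popsnv"))
  }
  info <- do.call(rbind, lapply(nonempty, function(a) {
    data.frame(species_id = a$species_id, contig_id = a$contig_id,
               position = a$pos, ref_allele = a$ref,
               pooled_major = a$pooled_major, pooled_minor = a$pooled_minor,
               pooled_depth = a$pooled_depth,
               pooled_count_A = a$pooled_counts[, 1L],
               pooled_count_C = a$pooled_counts[, 2L],
               pooled_count_G = a$pooled_counts[, 3L],
               pooled_count_T = a$pooled_counts[, 4L],
               pooled_minor_freq = a$pooled_minor_freq,
               n_relevant_samples = a$n_relevant,
               allele_class = a$allele_class, stringsAsFactors = FALSE)
  }))
  freq <- do.call(rbind, lapply(nonempty, `[[`, "freq"))
  depth <- do.call(rbind, lapply(nonempty, `[[`, "depth"))
  ord <- order(info$species_id, info$contig_id, info$position)
  info <- info[ord, , drop = FALSE]
  rownames(info) <- NULL
  freq <- as.data.frame(freq[ord, , drop = FALSE])
  depth <- as.data.frame(depth[ord, , drop = FALSE])
  colnames(freq) <- samples
  colnames(depth) <- samples
  rownames(freq) <- rownames(depth) <- NULL
  structure(list(info = info, freq = freq, depth = depth, samples = samples),
            class = "mgt_popsnv")
}

empty_popsnv_info <- function() {
  data.frame(species_id = character(0), contig_id = character(0),
             position = integer(0), ref_allele = character(0),
             pooled_major = character(0), pooled_minor = character(0),
             pooled_depth = numeric(0), pooled_count_A = numeric(0),
             pooled_count_C = numeric(0), pooled_count_G = numeric(0),
             pooled_count_T = numeric(0), pooled_minor_freq = numeric(0),
             n_relevant_samples = integer(0), allele_class = character(0),
             stringsAsFactors = FALSE)
}

#' @export
print.mgt_popsnv <- function(x, ...) {
  cat(sprintf("<mgt_popsnv> %d sites x %d samples (%d species)\n",
              nrow(x$info), length(x$samples),
              length(unique(x$info$species_id))))
  invisible(x)
}

#' Across-samples population SNV calling
#'
#' Splits every contig into chunks, processes chunks independently
#' (optionally in a worker pool) and merges the accumulators. Output is
#' byte-identical for any `chunk_size >= 1` and any number of workers.
#'
#' @param pileups named (by sample) list of pileup data.frames as returned
#'   in `snv_single_sample()$pileup` (or read back via
#'   [read_pileup_tsv()]).
#' @param contigs data.frame: species_id, contig_id, length.
#' @param filters a [site_filters()] object.
#' @param method pooling method, `"counts"` (default) or `"prevalence"`.
#' @param chunk_size sites per chunk.
#' @param workers size of the (forked) worker pool.
#' @return an `mgt_popsnv` object (see [merge_chunks()]).
#' @export
snv_merge <- function(pileups, contigs, filters = site_filters(),
                      method = "counts", chunk_size = 100000L,
                      workers = 1L) {
  mats <- build_pileup_mats(pileups, contigs)
  chunks <- make_chunks(contigs, chunk_size)
  rows <- split(chunks, chunks$chunk_id)
  accs <- if (workers > 1L) {
    parallel::mclapply(rows, process_chunk, pileups = mats,
                       filters = filters, method = method,
                       mc.cores = workers, mc.preschedule = TRUE)
  } else {
    lapply(rows, process_chunk, pileups = mats, filters = filters,
           method = method)
  }
  merge_chunks(accs)
}

#' Write population-SNV matrices to TSV files
#'
#' Writes per-species `snps_info.tsv`, `snps_freq.tsv` and
#' `snps_depth.tsv` (sites x samples; missing entries are NA) under
#' `out_dir/<species_id>/`.
#'
#' @param res an `mgt_popsnv` object.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
write_snv_matrices <- function(res, out_dir) {
  stopifnot(inherits(res, "mgt_popsnv"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  species <- unique(res$info$species_id)
  if (length(species) == 0) species <- character(0)
  for (sp in sort(species)) {
    spdir <- file.path(out_dir, sp)
    dir.create(spdir, showWarnings = FALSE)
    sel <- res$info$species_id == sp
    info <- res$info[sel, , drop = FALSE]
    info$pooled_minor_freq <- fmt4(info$pooled_minor_freq)
    write_tsv(info, file.path(spdir, "snps_info.tsv"))
    site_id <- paste0(info$contig_id, "|", info$position)
    fr <- res$freq[sel, , drop = FALSE]
    fr[] <- lapply(fr, fmt4)
    write_tsv(cbind(data.frame(site_id = site_id, stringsAsFactors = FALSE), fr),
              file.path(spdir, "snps_freq.tsv"))
    dp <- res$depth[sel, , drop = FALSE]
    write_tsv(cbind(data.frame(site_id = site_id, stringsAsFactors = FALSE), dp),
              file.path(spdir, "snps_depth.tsv"))
  }
  invisible(out_dir)
}
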