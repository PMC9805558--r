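# Independent brute-force oracles. These re-derive expected results by the
# most literal method available (character-by-character CIGAR walks, full
# identity matrices, explicit loops) and share no code with the package
# implementations they check.

# --- alignment record constructor for hand-built test cases ---------------
rec <- function(qname, rname, pos, seq, qual = strrep("I", nchar(seq)),
                flag = 0L, mapq = 42L, cigar = sprintf("%dM", nchar(seq)),
                nm = 0L, md = NA_character_, rnext = "*", pnext = 0L,
                tlen = 0L) {
  data.frame(qname = qname, flag = as.integer(flag), rname = rname,
             pos = as.integer(pos), mapq = as.integer(mapq), cigar = cigar,
             rnext = rnext, pnext = as.integer(pnext), tlen = as.integer(tlen),
             seq = seq, qual = qual, nm = as.integer(nm), md = md,
             tie_rname = NA_character_, stringsAsFactors = FALSE)
}

# --- brute-force pileup oracle --------------------------------------------
# Assumes every record passes the alignment filters; implements the mate
# overlap and base-quality rules literally, one fragment and one position
# at a time.
oracle_record_bases <- function(r) {
  ops <- character(0)
  num <- ""
  for (ch in strsplit(r$cigar, "")[[1]]) {
    if (ch %in% as.character(0:9)) num <- paste0(num, ch)
    else { ops <- c(ops, strrep(ch, as.integer(num))); num <- "" }
  }
  ops <- strsplit(paste(ops, collapse = ""), "")[[1]]
  refp <- integer(0); base <- character(0); qual <- integer(0)
  rp <- r$pos; qp <- 1L
  for (op in ops) {
    if (op %in% c("M", "=", "X")) {
      refp <- c(refp, rp); base <- c(base, substr(r$seq, qp, qp))
      qual <- c(qual, utf8ToInt(substr(r$qual, qp, qp)) - 33L)
      rp <- rp + 1L; qp <- qp + 1L
    } else if (op %in% c("I", "S")) qp <- qp + 1L
    else if (op %in% c("D", "N")) rp <- rp + 1L
  }
  list(refpos = refp, base = base, qual = qual)
}

oracle_pileup <- function(records, targets, min_baseq = 30L) {
  counts <- lapply(targets, function(s) matrix(0L, nchar(s), 4L))
  frag_key <- paste(records$qname, records$rname)
  for (key in unique(frag_key)) {
    rows <- which(frag_key == key)
    mates <- lapply(rows, function(i) oracle_record_bases(records[i, ]))
    ct <- records$rname[rows[1L]]
    if (length(mates) == 1L) {
      m <- mates[[1L]]
    } else {
      m1 <- mates[[1L]]; m2 <- mates[[2L]]
      m <- list(refpos = integer(0), base = character(0), qual = integer(0))
      for (p in sort(unique(c(m1$refpos, m2$refpos)))) {
        i1 <- match(p, m1$refpos); i2 <- match(p, m2$refpos)
        if (is.na(i2)) {
          m$refpos <- c(m$refpos, p); m$base <- c(m$base, m1$base[i1])
          m$qual <- c(m$qual, m1$qual[i1])
        } else if (is.na(i1)) {
          m$refpos <- c(m$refpos, p); m$base <- c(m$base, m2$base[i2])
          m$qual <- c(m$qual, m2$qual[i2])
        } else if (m1$base[i1] == m2$base[i2]) {
          m$refpos <- c(m$refpos, p); m$base <- c(m$base, m1$base[i1])
          m$qual <- c(m$qual, max(m1$qual[i1], m2$qual[i2]))
        } else if (m1$qual[i1] != m2$qual[i2]) {
          w <- if (m1$qual[i1] > m2$qual[i2]) 1L else 2L
          m$refpos <- c(m$refpos, p)
          m$base <- c(m$base, if (w == 1L) m1$base[i1] else m2$base[i2])
          m$qual <- c(m$qual, max(m1$qual[i1], m2$qual[i2]))
        } # equal quality, disagreeing bases: fragment contributes nothing
      }
    }
    for (j in seq_along(m$refpos)) {
      b <- match(m$base[j], c("A", "C", "G", "T"))
      if (!is.na(b) && m$qual[j] >= min_baseq) {
        counts[[ct]][m$refpos[j], b] <- counts[[ct]][m$refpos[j], b] + 1L
      }
    }
  }
  out <- NULL
  for (ct in sort(names(targets))) {
    cm <- counts[[ct]]
    dep <- rowSums(cm)
    w <- which(dep > 0)
    if (length(w)) {
      out <- rbind(out, data.frame(
        contig = ct, pos = w, ref = substring(targets[[ct]], w, w),
        A = cm[w, 1L], C = cm[w, 2L], G = cm[w, 3L], T = cm[w, 4L],
        depth = as.integer(dep[w]), stringsAsFactors = FALSE))
    }
  }
  out
}

# --- independent greedy clustering from an all-pairs identity matrix ------
oracle_identity <- function(a, b) {
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global")
  Biostrings::nmatch(aln) /
    nchar(as.character(Biostrings::alignedPattern(aln)))
}

oracle_greedy_cluster <- function(genes, threshold) {
  ord <- order(-nchar(genes$sequence), genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  n <- nrow(genes)
  idm <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j) idm[i, j] <- oracle_identity(genes$sequence[i], genes$sequence[j])
  }
  centroid_of <- integer(0) # row index of each cluster's centroid
  assignment <- integer(n)
  for (i in seq_len(n)) {
    hit <- 0L
    for (j in seq_along(centroid_of)) {
      if (idm[i, centroid_of[j]] >= threshold) { hit <- j; break }
    }
    if (hit == 0L) { centroid_of <- c(centroid_of, i); hit <- length(centroid_of) }
    assignment[i] <- hit
  }
  lapply(seq_along(centroid_of), function(j) {
    list(centroid_gene_id = genes$gene_id[centroid_of[j]],
         member_gene_ids = genes$gene_id[assignment == j])
  })
}

# --- explicit single-site pooling oracle ----------------------------------
oracle_pool <- function(counts, method) {
  S <- nrow(counts)
  bases <- c("A", "C", "G", "T")
  if (method == "counts") {
    stat <- colSums(counts)
  } else {
    stat <- c(0, 0, 0, 0)
    for (s in seq_len(S)) {
      if (sum(counts[s, ]) == 0) next
      maj <- which(counts[s, ] == max(counts[s, ]))[1L]
      stat[maj] <- stat[maj] + 1
    }
  }
  maj <- which(stat == max(stat))[1L]
  rest <- stat; rest[maj] <- -1
  minr <- which(rest == max(rest))[1L]
  list(major = bases[maj],
       minor = if (rest[minr] > 0) bases[minr] else NA_character_)
}

# deterministic random DNA string
rand_dna <- function(n, seed) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                               collapse = ""))
}

md5_of_dir <- function(dir) {
  files <- sort(list.files(dir, recursive = TRUE, full.names = TRUE))
  stats::setNames(unname(tools::md5sum(files)),
                  sub(paste0("^", dir, "/?"), "", files))
}
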