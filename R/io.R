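# Shared format readers/writers: FASTA, FASTQ, TSV matrices.
# FASTA goes through Biostrings; FASTQ uses a strict 4-line reader so that
# malformed records can be reported by record number.

#' Read a FASTA file into a named character vector
#'
#' Wraps [Biostrings::readDNAStringSet()]. Sequence names are the first
#' whitespace-delimited token of the header; the full header is kept in the
#' `"description"` attribute. CRLF line endings and any line wrapping are
#' normalized away.
#'
#' @param path path to a FASTA file.
#' @return named character vector of uppercase sequences, with a
#'   `description` attribute (character vector of full header lines).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_input("FASTA file not found: %s", path)
  x <- Biostrings::readDNAStringSet(path)
  desc <- names(x)
  ids <- vapply(strsplit(desc, "[ \t]+"), `[`, "", 1L)
  out <- toupper(as.character(x))
  names(out) <- ids
  attr(out, "description") <- desc
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector; names become headers. An optional
#'   `description` attribute (same length) overrides the headers.
#' @param path output path.
#' @param width line-wrap width in bases.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  x <- Biostrings::DNAStringSet(unname(seqs))
  names(x) <- attr(seqs, "description") %||% names(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' Strict 4-line-per-record reader. A record whose sequence and quality
#' strings differ in length, or a truncated final record, raises an error
#' naming the record number.
#'
#' @param path path to an (uncompressed) FASTQ file.
#' @return data.frame with columns `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop_input("FASTQ file not found: %s", path)
  lines <- readLines(path)
  lines <- sub("\r$", "", lines)
  if (length(lines) == 0) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  if (length(lines) %% 4L != 0L) {
    stop_input("FASTQ record %d in %s is truncated",
               length(lines) %/% 4L + 1L, path)
  }
  n <- length(lines) %/% 4L
  id_lines <- lines[seq(1L, by = 4L, length.out = n)]
  seqs <- lines[seq(2L, by = 4L, length.out = n)]
  quals <- lines[seq(4L, by = 4L, length.out = n)]
  bad_hdr <- which(substr(id_lines, 1L, 1L) != "@")
  if (length(bad_hdr)) {
    stop_input("FASTQ record %d in %s does not start with '@'",
               bad_hdr[1L], path)
  }
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad)) {
    stop_input("FASTQ record %d in %s: sequence and quality lengths differ",
               bad[1L], path)
  }
  ids <- vapply(strsplit(sub("^@", "", id_lines), "[ \t]+"), `[`, "", 1L)
  data.frame(id = ids, seq = toupper(seqs), qual = quals,
             stringsAsFactors = FALSE)
}

#' Write reads to FASTQ
#'
#' @param reads data.frame with columns `id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  stopifnot(all(c("id", "seq", "qual") %in% names(reads)))
  if (any(nchar(reads$seq) != nchar(reads$qual))) {
    stop("sequence/quality length mismatch in reads to be written")
  }
  out <- character(4L * nrow(reads))
  out[seq(1L, by = 4L, length.out = nrow(reads))] <- paste0("@", reads$id)
  out[seq(2L, by = 4L, length.out = nrow(reads))] <- reads$seq
  out[seq(3L, by = 4L, length.out = nrow(reads))] <- "+"
  out[seq(4L, by = 4L, length.out = nrow(reads))] <- reads$qual
  writeLines(out, path)
  invisible(path)
}
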