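# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

BASES <- c("A", "C", "G", "T")

#' Reverse-complement nucleotide strings
#'
#' Vectorized reverse complement over plain character strings (IUPAC bases
#' other than ACGTN are passed through `Biostrings`' rules).
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# reverse a character string (used for reverse-strand quality strings)
str_rev <- function(x) {
  vapply(x, function(s) rawToChar(rev(charToRaw(s))), "", USE.NAMES = FALSE)
}

# deterministic sub-seed derivation; keeps results < 2^31
sub_seed <- function(seed, k) {
  (as.integer(seed) + 7919L * as.integer(k)) %% 2147483647L
}

# write a TSV with fixed conventions so outputs are byte-stable
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

read_tsv <- function(path, colClasses = NA) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    colClasses = colClasses, check.names = FALSE)
}

# fixed-precision number formatting for TSV output (byte-stable)
fmt4 <- function(x) {
  out <- sprintf("%.4f", x)
  out[is.na(x)] <- "NA"
  out
}

stop_input <- function(fmt, ...) {
  stop(structure(class = c("mgt_input_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}
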