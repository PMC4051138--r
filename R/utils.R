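DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors.
#'
#' @param x character vector of DNA sequences (ACGTN).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

comp_base <- function(x) chartr("ACGTN", "TGCAN", x)

reverse_string <- function(x) {
  if (!length(x)) return(character(0))
  as.character(Biostrings::reverse(Biostrings::BStringSet(x)))
}

#' Convert quality strings to integer phred scores
#'
#' @param qual character vector of quality strings.
#' @param offset integer ASCII offset (33 for phred+33).
#' @return list of integer vectors, one per input string.
#' @export
phred_ints <- function(qual, offset = 33L) {
  lapply(qual, function(q) utf8ToInt(q) - offset)
}

phred_chars <- function(scores, offset = 33L) {
  vapply(scores, function(s) intToUtf8(s + offset), character(1))
}

# character class matching quality characters with phred in [lo, hi]
qual_class <- function(lo, hi, offset = 33L) {
  sprintf("[\\x%02x-\\x%02x]", offset + lo, offset + hi)
}

# coerce a reference argument (named character vector, DNAStringSet or FASTA
# path) to a named character vector of uppercase contig sequences
as_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1L &&
      is.null(names(reference)) && file.exists(reference)) {
    return(read_fasta(reference))
  }
  if (methods::is(reference, "DNAStringSet")) {
    out <- toupper(as.character(reference))
    names(out) <- sub("\\s.*$", "", names(reference))
    return(out)
  }
  stopifnot(is.character(reference), !is.null(names(reference)))
  toupper(reference)
}

# validate a reads data.frame (id, seq, qual)
check_reads <- function(reads) {
  stopifnot(is.data.frame(reads), all(c("id", "seq", "qual") %in% names(reads)))
  bad <- which(nchar(reads$seq) != nchar(reads$qual))
  if (length(bad)) {
    stop("base/quality length mismatch for read(s): ",
         paste(utils::head(reads$id[bad], 5L), collapse = ", "))
  }
  invisible(reads)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
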