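#' Trim low-quality read ends
#'
#' Removes bases with phred `<= qual_floor` from both ends of each read,
#' working inwards until a base above the floor is met; interior low-quality
#' bases are retained. Base calls are never altered, only terminal bases
#' removed. Reads may come back empty; they are dropped by
#' [filter_reads()].
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param qual_floor phred threshold; bases at or below it are trimmed.
#' @param offset quality-string ASCII offset (33 for phred+33).
#' @return the reads data.frame with trimmed `seq`/`qual`.
#' @export
trim_reads <- function(reads, qual_floor = 15L, offset = 33L) {
  check_reads(reads)
  if (!nrow(reads)) return(reads)
  cls <- qual_class(0L, qual_floor, offset)
  lead <- attr(regexpr(paste0("^", cls, "+"), reads$qual, perl = TRUE),
               "match.length")
  trail <- attr(regexpr(paste0(cls, "+$"), reads$qual, perl = TRUE),
                "match.length")
  lead[lead < 0L] <- 0L
  trail[trail < 0L] <- 0L
  n <- nchar(reads$qual)
  # fully low-quality reads match both anchors over the whole string
  all_low <- lead == n
  trail[all_low] <- 0L
  from <- lead + 1L
  to <- n - trail
  out <- reads
  out$seq <- substr(reads$seq, from, to)
  out$qual <- substr(reads$qual, from, to)
  out$seq[from > to] <- ""
  out$qual[from > to] <- ""
  out
}

# per-read count of bases passing the quality floor; N bases always fail
count_passing_bases <- function(seq, qual, qual_floor, offset) {
  if (qual_floor <= 0L) {
    n_high <- nchar(qual)
  } else {
    below <- qual_class(0L, qual_floor - 1L, offset)
    n_high <- nchar(gsub(below, "", qual, perl = TRUE))
  }
  has_n <- grepl("N", seq, fixed = TRUE)
  if (any(has_n)) {
    floor_char <- offset + qual_floor
    adj <- vapply(which(has_n), function(i) {
      at <- gregexpr("N", seq[i], fixed = TRUE)[[1]]
      sum(utf8ToInt(qual[i])[at] >= floor_char)
    }, integer(1))
    n_high[has_n] <- n_high[has_n] - adj
  }
  n_high
}

#' Overall-quality read filter
#'
#' Keeps reads that are strictly longer than `min_len` after trimming and in
#' which at least `min_frac` of bases have phred `>= qual_floor`. `N` bases
#' count against the quality fraction regardless of their score.
#'
#' @param reads trimmed reads data.frame.
#' @param min_len reads must be strictly longer than this (default 30 bp).
#' @param min_frac minimum fraction of bases at or above the floor.
#' @param qual_floor phred floor for the fraction rule.
#' @param offset quality-string ASCII offset.
#' @return logical vector, TRUE for kept reads.
#' @export
filter_reads <- function(reads, min_len = 30L, min_frac = 0.8,
                         qual_floor = 15L, offset = 33L) {
  check_reads(reads)
  if (!nrow(reads)) return(logical(0))
  len <- nchar(reads$seq)
  n_high <- count_passing_bases(reads$seq, reads$qual, qual_floor, offset)
  len > min_len & n_high / len >= min_frac
}

#' Trim and filter a read set
#'
#' @inheritParams trim_reads
#' @inheritParams filter_reads
#' @return list with `reads` (kept, trimmed reads) and `report` (a
#'   [qc_report()] row).
#' @export
qc_reads <- function(reads, min_len = 30L, min_frac = 0.8, qual_floor = 15L,
                     offset = 33L) {
  trimmed <- trim_reads(reads, qual_floor = qual_floor, offset = offset)
  keep <- filter_reads(trimmed, min_len = min_len, min_frac = min_frac,
                       qual_floor = qual_floor, offset = offset)
  clean <- trimmed[keep, , drop = FALSE]
  rownames(clean) <- NULL
  list(reads = clean, report = qc_report(reads, clean))
}

#' Retention summary for a QC run
#'
#' @param raw reads before QC.
#' @param clean reads after trimming and filtering.
#' @return one-row data.frame with read/base counts, retained fractions and
#'   mean lengths before/after.
#' @export
qc_report <- function(raw, clean) {
  bases_in <- sum(nchar(raw$seq))
  bases_out <- sum(nchar(clean$seq))
  data.frame(
    reads_in = nrow(raw),
    reads_kept = nrow(clean),
    read_retention = if (nrow(raw)) nrow(clean) / nrow(raw) else NA_real_,
    bases_in = bases_in,
    bases_kept = bases_out,
    base_retention = if (bases_in) bases_out / bases_in else NA_real_,
    mean_len_in = if (nrow(raw)) bases_in / nrow(raw) else NA_real_,
    mean_len_kept = if (nrow(clean)) bases_out / nrow(clean) else NA_real_
  )
}
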