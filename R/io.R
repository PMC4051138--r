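#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file.
#' @return named character vector of uppercase sequences; names are truncated
#'   at the first whitespace.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector.
#' @param path output file.
#' @param width line width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ file (gzip-transparent).
#' @return data.frame with columns `id`, `seq`, `qual` (phred+33 string).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(
    id = sub("\\s.*$", "", names(x)),
    seq = toupper(as.character(x)),
    qual = as.character(S4Vectors::mcols(x)$qualities),
    stringsAsFactors = FALSE
  )
}

#' Write reads to FASTQ (phred+33)
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param path output file.
#' @export
write_fastq <- function(reads, path) {
  check_reads(reads)
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

# ---- SAM ------------------------------------------------------------------
# Rsamtools only reads BAM; the pipeline's interchange format is plain-text
# SAM (ungapped single-end records), so a minimal reader/writer lives here.

#' Write alignments to a SAM file
#'
#' Emits a minimal valid SAM (one `@SQ` line per contig, ungapped `<len>M`
#' CIGARs, `NM` tags). Reverse-strand records carry the reverse-complemented
#' read sequence, as SAM requires.
#'
#' @param alignments alignment data.frame from [map_reads()].
#' @param reads reads data.frame (`id`, `seq`, `qual`) the alignments refer to.
#' @param reference named character vector of contig sequences.
#' @param path output file.
#' @param unmapped optional data.frame (`read_id`, `reason`) to emit as
#'   unmapped (flag 4) records.
#' @export
write_sam <- function(alignments, reads, reference, path, unmapped = NULL) {
  reference <- as_reference(reference)
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", names(reference), nchar(reference)),
           "@PG\tID:aliensnp\tPN:aliensnp")
  body <- character(0)
  if (nrow(alignments)) {
    m <- match(alignments$read_id, reads$id)
    if (anyNA(m)) stop("alignment references unknown read id")
    seq <- reads$seq[m]
    qual <- reads$qual[m]
    neg <- alignments$strand == "-"
    seq[neg] <- revcomp(seq[neg])
    qual[neg] <- reverse_string(qual[neg])
    body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                    alignments$read_id, ifelse(neg, 16L, 0L),
                    alignments$ref_id, alignments$start + 1L,
                    alignments$length, seq, qual, alignments$n_mismatch)
  }
  un <- character(0)
  if (!is.null(unmapped) && nrow(unmapped)) {
    m <- match(unmapped$read_id, reads$id)
    un <- sprintf("%s\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s",
                  unmapped$read_id, reads$seq[m], reads$qual[m])
  }
  writeLines(c(hdr, body, un), path)
  invisible(path)
}

#' Import alignments from a SAM file
#'
#' Unmapped, secondary and supplementary records are skipped. Mismatch counts
#' come from the `NM` tag, then the `MD` tag, and are otherwise recomputed
#' against `reference`. Gapped records (CIGAR other than `<len>M`) and
#' records exceeding `max_mismatch` are dropped with counts reported.
#'
#' @param path SAM file.
#' @param reference optional named character vector; when supplied, reference
#'   names in the SAM must all be present (hard error listing offenders) and
#'   missing mismatch tags are recomputed from it.
#' @param max_mismatch drop alignments with more mismatches than this.
#' @return list with `alignments`, `reads` (forward-orientation sequences)
#'   and `dropped` (named counts).
#' @export
read_sam <- function(path, reference = NULL, max_mismatch = 3L) {
  if (!is.null(reference)) reference <- as_reference(reference)
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  dropped <- c(unmapped_or_secondary = 0L, gapped = 0L, over_mismatch = 0L)
  empty <- data.frame(read_id = character(0), ref_id = character(0),
                      start = integer(0), strand = character(0),
                      n_mismatch = integer(0), length = integer(0),
                      stringsAsFactors = FALSE)
  if (!length(body)) {
    return(list(alignments = empty,
                reads = data.frame(id = character(0), seq = character(0),
                                   qual = character(0)),
                dropped = dropped))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11L)) stop("malformed SAM record (fewer than 11 fields)")
  flag <- as.integer(vapply(f, `[[`, "", 2L))
  keep <- bitwAnd(flag, 4L) == 0L & bitwAnd(flag, 256L) == 0L &
    bitwAnd(flag, 2048L) == 0L
  dropped["unmapped_or_secondary"] <- sum(!keep)
  f <- f[keep]; flag <- flag[keep]
  if (!length(f)) {
    return(list(alignments = empty,
                reads = data.frame(id = character(0), seq = character(0),
                                   qual = character(0)),
                dropped = dropped))
  }
  qname <- vapply(f, `[[`, "", 1L)
  rname <- vapply(f, `[[`, "", 3L)
  pos1 <- as.integer(vapply(f, `[[`, "", 4L))
  cigar <- vapply(f, `[[`, "", 6L)
  seq <- toupper(vapply(f, `[[`, "", 10L))
  qual <- vapply(f, `[[`, "", 11L)
  if (!is.null(reference)) {
    off <- setdiff(unique(rname), names(reference))
    if (length(off)) {
      stop("SAM reference name(s) absent from supplied FASTA: ",
           paste(off, collapse = ", "))
    }
  }
  ungapped <- grepl("^[0-9]+M$", cigar)
  dropped["gapped"] <- sum(!ungapped)
  tag_val <- function(fields, prefix) {
    hit <- fields[startsWith(fields, prefix)]
    if (length(hit)) substring(hit[1L], nchar(prefix) + 1L) else NA_character_
  }
  nm <- vapply(f, function(x) tag_val(x[-(1:11)], "NM:i:"), "")
  md <- vapply(f, function(x) tag_val(x[-(1:11)], "MD:Z:"), "")
  n_mismatch <- suppressWarnings(as.integer(nm))
  use_md <- is.na(n_mismatch) & !is.na(md)
  # substitution count in an MD tag = number of base letters outside deletions
  n_mismatch[use_md] <- vapply(md[use_md], function(m) {
    m <- gsub("\\^[ACGTN]+", "", m)
    sum(strsplit(gsub("[0-9]+", "", m), "")[[1]] %in% c("A", "C", "G", "T", "N"))
  }, integer(1))
  need <- is.na(n_mismatch) & ungapped
  if (any(need)) {
    if (is.null(reference)) {
      stop("records without NM/MD tags require a reference to recompute ",
           "mismatch counts")
    }
    ref_seg <- substr(reference[rname[need]], pos1[need],
                      pos1[need] + nchar(seq[need]) - 1L)
    n_mismatch[need] <- mapply(function(a, b) {
      ra <- charToRaw(a); rb <- charToRaw(b)
      sum(ra != rb | !(rawToChar(ra, multiple = TRUE) %in% DNA_BASES))
    }, seq[need], ref_seg, USE.NAMES = FALSE)
  }
  over <- ungapped & n_mismatch > max_mismatch
  dropped["over_mismatch"] <- sum(over, na.rm = TRUE)
  keep2 <- ungapped & !over
  neg <- bitwAnd(flag, 16L) != 0L
  fwd_seq <- seq
  fwd_qual <- qual
  fwd_seq[neg] <- revcomp(seq[neg])
  fwd_qual[neg] <- reverse_string(qual[neg])
  al <- data.frame(read_id = qname[keep2], ref_id = rname[keep2],
                   start = pos1[keep2] - 1L,
                   strand = ifelse(neg[keep2], "-", "+"),
                   n_mismatch = n_mismatch[keep2],
                   length = nchar(seq[keep2]), stringsAsFactors = FALSE)
  rd <- data.frame(id = qname[keep2], seq = fwd_seq[keep2],
                   qual = fwd_qual[keep2], stringsAsFactors = FALSE)
  rd <- rd[!duplicated(rd$id), , drop = FALSE]
  list(alignments = al, reads = rd, dropped = dropped)
}

# ---- VCF ------------------------------------------------------------------

#' Write variant calls to a minimal VCF 4.2 file
#'
#' Positions are converted to 1-based `POS`; depth and alt read count are
#' stored as `DP` and `AC` INFO fields, call quality as `QUAL` (2 decimals).
#' Heterozygosity and allele-tie flags are emitted as `HET` / `AMB` flags.
#'
#' @param calls variant call data.frame (0-based `pos`).
#' @param reference named character vector of contig sequences.
#' @param path output file.
#' @export
write_vcf <- function(calls, reference, path) {
  reference <- as_reference(reference)
  hdr <- c("##fileformat=VCFv4.2",
           "##source=aliensnp",
           sprintf("##contig=<ID=%s,length=%d>", names(reference),
                   nchar(reference)),
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alt read count\">",
           "##INFO=<ID=HET,Number=0,Type=Flag,Description=\"Second allele above heterozygosity band\">",
           "##INFO=<ID=AMB,Number=0,Type=Flag,Description=\"Alt allele tie broken lexicographically\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- character(0)
  if (nrow(calls)) {
    o <- order(calls$ref_id, calls$pos)
    calls <- calls[o, , drop = FALSE]
    het <- if ("het" %in% names(calls)) calls$het else FALSE
    amb <- if ("ambiguous" %in% names(calls)) calls$ambiguous else FALSE
    info <- sprintf("DP=%d;AC=%d", calls$depth, calls$alt_count)
    info <- paste0(info, ifelse(het, ";HET", ""), ifelse(amb, ";AMB", ""))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%.2f\tPASS\t%s",
                    calls$ref_id, calls$pos + 1L, calls$ref, calls$alt,
                    calls$qual, info)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a VCF written by [write_vcf()]
#'
#' @param path VCF file.
#' @return variant call data.frame with 0-based `pos`.
#' @export
read_vcf <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#")]
  if (!length(body)) {
    return(data.frame(ref_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      depth = integer(0), alt_count = integer(0),
                      qual = numeric(0), het = logical(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  info <- vapply(f, `[[`, "", 8L)
  grab <- function(key) {
    m <- regmatches(info, regexpr(paste0("(?<=", key, "=)[0-9]+"), info,
                                  perl = TRUE))
    out <- rep(NA_integer_, length(info))
    out[grepl(paste0(key, "="), info, fixed = TRUE)] <- as.integer(m)
    out
  }
  data.frame(
    ref_id = vapply(f, `[[`, "", 1L),
    pos = as.integer(vapply(f, `[[`, "", 2L)) - 1L,
    ref = vapply(f, `[[`, "", 4L),
    alt = vapply(f, `[[`, "", 5L),
    depth = grab("DP"),
    alt_count = grab("AC"),
    qual = as.numeric(vapply(f, `[[`, "", 6L)),
    het = grepl("(^|;)HET(;|$)", info),
    ambiguous = grepl("(^|;)AMB(;|$)", info),
    stringsAsFactors = FALSE
  )
}

# ---- BED / TSV ------------------------------------------------------------

#' Write 0-based half-open intervals to BED
#'
#' @param df data.frame with columns `chrom`, `start`, `end` and optionally
#'   `name`.
#' @param path output file.
#' @export
write_bed <- function(df, path) {
  cols <- c("chrom", "start", "end")
  stopifnot(all(cols %in% names(df)))
  out <- df[, c(cols, intersect("name", names(df))), drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a BED file
#'
#' @param path BED file.
#' @return data.frame with `chrom`, `start`, `end` and `name` when present.
#' @export
read_bed <- function(path) {
  x <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  names(x)[1:3] <- c("chrom", "start", "end")
  if (ncol(x) >= 4L) names(x)[4L] <- "name"
  x
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, stringsAsFactors = FALSE, ...)
}
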