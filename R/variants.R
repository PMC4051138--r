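#' Build per-reference pileups
#'
#' Accumulates per-position base counts and quality sums from all reads
#' overlapping each reference position, both strands pooled (reverse-strand
#' reads contribute their reference-oriented sequence). Non-ACGT read bases
#' are excluded from depth.
#'
#' @param alignments alignment data.frame from [map_reads()] or [read_sam()].
#' @param reads reads data.frame (`id`, `seq`, `qual`); every `read_id` in
#'   `alignments` must be present (hard error otherwise).
#' @param reference named character vector / DNAStringSet / FASTA path.
#' @param offset quality-string ASCII offset.
#' @return object of class `pileup`: per-contig `counts` and `qualsum`
#'   4 x N matrices (rows A, C, G, T) plus the reference.
#' @export
build_pileup <- function(alignments, reads, reference, offset = 33L) {
  reference <- as_reference(reference)
  m <- match(alignments$read_id, reads$id)
  if (anyNA(m)) {
    stop("alignment references unknown read id: ",
         paste(utils::head(alignments$read_id[is.na(m)], 5L), collapse = ", "))
  }
  contigs <- lapply(names(reference), function(cn) {
    sel <- alignments$ref_id == cn
    if (!any(sel)) {
      n <- nchar(reference[[cn]])
      return(list(counts = matrix(0L, 4L, n),
                  qualsum = matrix(0, 4L, n)))
    }
    sub <- alignments[sel, , drop = FALSE]
    mi <- m[sel]
    seqs <- reads$seq[mi]
    quals <- reads$qual[mi]
    neg <- sub$strand == "-"
    seqs[neg] <- revcomp(seqs[neg])
    quals[neg] <- reverse_string(quals[neg])
    cpp_pileup(seqs, quals, as.integer(sub$start), nchar(reference[[cn]]),
               as.integer(offset))
  })
  names(contigs) <- names(reference)
  structure(list(contigs = contigs, reference = reference), class = "pileup")
}

#' Pileup columns as a data.frame
#'
#' @param pileup a [build_pileup()] object.
#' @param min_depth only return columns with at least this depth.
#' @return data.frame with `ref_id`, `pos` (0-based), `ref`, per-base counts
#'   `A`,`C`,`G`,`T` and `depth`.
#' @export
pileup_columns <- function(pileup, min_depth = 1L) {
  out <- lapply(names(pileup$contigs), function(cn) {
    cnt <- pileup$contigs[[cn]]$counts
    depth <- colSums(cnt)
    sel <- which(depth >= min_depth)
    if (!length(sel)) return(NULL)
    data.frame(ref_id = cn, pos = sel - 1L,
               ref = substring(pileup$reference[[cn]], sel, sel),
               A = cnt[1L, sel], C = cnt[2L, sel], G = cnt[3L, sel],
               T = cnt[4L, sel], depth = depth[sel],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(ref_id = character(0), pos = integer(0),
                      ref = character(0), A = integer(0), C = integer(0),
                      G = integer(0), T = integer(0), depth = integer(0))
  }
  rownames(out) <- NULL
  out
}

# phred-scaled binomial-tail quality of a haploid non-reference call:
# -10*log10 P(>= alt_count alt reads | site is reference, per-base error eps)
call_quality <- function(alt_count, depth, eps, cap = 1000) {
  lp <- pbinom(alt_count - 1L, depth, pmin(pmax(eps, 0), 1), lower.tail = FALSE,
               log.p = TRUE)
  pmin(cap, -10 / log(10) * lp)
}

#' Call raw variants from a pileup
#'
#' At each column whose majority non-reference base has at least one
#' supporting read, emits a candidate haploid call. Quality is the
#' phred-scaled binomial tail probability of seeing at least `alt_count`
#' non-reference reads under the null that the site matches the reference
#' and bases err independently at rate `eps`, with `eps` derived from the
#' mean phred score of the alt-supporting bases; capped at `qual_cap`.
#' Ties between alt bases are broken by higher quality sum, then
#' lexicographically with an `ambiguous` flag. Columns whose second most
#' common base exceeds `het_frac` of depth are flagged `het` (the sample is
#' modelled as haploid, so heterozygosity is reported, not genotyped).
#'
#' @param pileup a [build_pileup()] object.
#' @param het_frac heterozygosity flag threshold on the second allele.
#' @param qual_cap phred cap avoiding -log of underflow.
#' @return data.frame with `ref_id`, `pos` (0-based), `ref`, `alt`, `depth`,
#'   `alt_count`, `qual`, `het`, `ambiguous`.
#' @export
call_raw_variants <- function(pileup, het_frac = 0.2, qual_cap = 1000) {
  out <- lapply(names(pileup$contigs), function(cn) {
    cnt <- pileup$contigs[[cn]]$counts
    qs <- pileup$contigs[[cn]]$qualsum
    n <- ncol(cnt)
    if (!n) return(NULL)
    refc <- strsplit(pileup$reference[[cn]], "")[[1]]
    re <- match(refc, DNA_BASES)               # NA where reference is N
    depth <- colSums(cnt)
    cnt_alt <- cnt
    valid <- which(!is.na(re))
    cnt_alt[cbind(re[valid], valid)] <- -1L    # mask the reference base row
    M <- pmax(cnt_alt[1L, ], cnt_alt[2L, ], cnt_alt[3L, ], cnt_alt[4L, ])
    cand <- which(!is.na(re) & M >= 1L)
    if (!length(cand)) return(NULL)
    sub <- cnt_alt[, cand, drop = FALSE]
    n_at_max <- colSums(sub == rep(M[cand], each = 4L))
    alt_row <- max.col(t(sub), ties.method = "first")
    ambiguous <- rep(FALSE, length(cand))
    tied <- which(n_at_max > 1L)
    for (k in tied) {
      rows <- which(sub[, k] == M[cand[k]])
      qvals <- qs[rows, cand[k]]
      bestq <- which(qvals == max(qvals))
      alt_row[k] <- rows[bestq[1L]]            # rows ascend = lexicographic
      ambiguous[k] <- length(bestq) > 1L
    }
    alt_count <- M[cand]
    qsum_alt <- qs[cbind(alt_row, cand)]
    eps <- 10^(-(qsum_alt / alt_count) / 10)
    qual <- call_quality(alt_count, depth[cand], eps, qual_cap)
    # second most common base (all four bases considered) for the het flag
    c1 <- cnt[1L, cand]; c2 <- cnt[2L, cand]
    c3 <- cnt[3L, cand]; c4 <- cnt[4L, cand]
    hi1 <- pmax(c1, c2); lo1 <- pmin(c1, c2)
    hi2 <- pmax(c3, c4); lo2 <- pmin(c3, c4)
    second <- pmax(pmin(hi1, hi2), pmax(lo1, lo2))
    data.frame(ref_id = cn, pos = cand - 1L, ref = refc[cand],
               alt = DNA_BASES[alt_row], depth = as.integer(depth[cand]),
               alt_count = as.integer(alt_count), qual = qual,
               het = second > het_frac * depth[cand], ambiguous = ambiguous,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) {
    out <- data.frame(ref_id = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      depth = integer(0), alt_count = integer(0),
                      qual = numeric(0), het = logical(0),
                      ambiguous = logical(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Depth and quality variant filter
#'
#' Keeps calls with `depth >= min_depth` and `qual >= min_qual` (both
#' thresholds inclusive).
#'
#' @param calls raw call data.frame.
#' @param min_depth minimum read depth (default 4).
#' @param min_qual minimum phred-scaled call quality (default 50).
#' @export
filter_variants <- function(calls, min_depth = 4L, min_qual = 50) {
  out <- calls[calls$depth >= min_depth & calls$qual >= min_qual, ,
               drop = FALSE]
  rownames(out) <- NULL
  out
}

#' SNP density per kilobase
#'
#' `density = n_calls / covered_bases * 1000`. The denominator is covered
#' bases (positions with depth >= 1), the closest well-defined analogue of
#' "analyzed bases"; set `denominator = "reference"` to use the full
#' reference length instead.
#'
#' @param calls filtered call data.frame.
#' @param coverage a [coverage_summary()] row for the same reference.
#' @param denominator `"covered"` or `"reference"`.
#' @return SNPs per kb (NA when the denominator is zero).
#' @export
snp_density <- function(calls, coverage, denominator = c("covered",
                                                         "reference")) {
  denominator <- match.arg(denominator)
  den <- if (denominator == "covered") coverage$covered_bases else
    coverage$reference_length
  if (!isTRUE(den > 0)) return(NA_real_)
  nrow(calls) / den * 1000
}

#' Label calls as genic from a precomputed annotation table
#'
#' @param calls call data.frame.
#' @param annotation data.frame with `ref_id`, `start`, `end` (0-based
#'   half-open gene intervals), e.g. from an external homology search.
#' @return `calls` with a logical `genic` column.
#' @export
label_genic <- function(calls, annotation) {
  genic <- rep(FALSE, nrow(calls))
  for (cn in unique(calls$ref_id)) {
    ann <- annotation[annotation$ref_id == cn, , drop = FALSE]
    if (!nrow(ann)) next
    sel <- which(calls$ref_id == cn)
    ir <- IRanges::IRanges(ann$start + 1L, ann$end)
    qp <- IRanges::IRanges(calls$pos[sel] + 1L, width = 1L)
    genic[sel] <- IRanges::overlapsAny(qp, ir)
  }
  calls$genic <- genic
  calls
}

#' Per-reference discovery funnel
#'
#' Mirrors the mapped reads / raw SNPs / filtered SNPs / genic SNPs summary
#' layout used when reporting homoeologue-wise SNP discovery.
#'
#' @param reference_label label for the row.
#' @param mapped_reads mapped read count.
#' @param raw_calls raw call data.frame.
#' @param filtered_calls filtered call data.frame.
#' @param genic_count genic SNP count (NA when no annotation supplied).
#' @export
funnel_row <- function(reference_label, mapped_reads, raw_calls,
                       filtered_calls, genic_count = NA_integer_) {
  data.frame(reference = reference_label, mapped_reads = mapped_reads,
             raw_snps = nrow(raw_calls), filtered_snps = nrow(filtered_calls),
             genic_snps = genic_count, stringsAsFactors = FALSE)
}
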