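#' Map reads to a reference with a strict mismatch budget
#'
#' Ungapped end-to-end placement of each read on both strands of every
#' contig of the reference. A read is reported mapped only when a single
#' placement achieves the minimum mismatch count and that count is at most
#' `max_mismatch`; reads with tied best placements are dropped as ambiguous
#' by default (set `drop_ties = FALSE` to assign one of the tied placements
#' at random, reproducing report-one-best behaviour). All contigs of the
#' reference form a single search space for the uniqueness test.
#'
#' The built-in mapper seeds candidate placements by the pigeonhole
#' principle (a read within the mismatch budget must contain an exactly
#' matching chunk) and verifies every candidate by full comparison, so its
#' results are identical to exhaustive scanning. `N` in read or reference
#' always counts as a mismatch.
#'
#' @param reads data.frame with `id`, `seq`, `qual`.
#' @param reference named character vector of contig sequences, a
#'   DNAStringSet, or a FASTA path.
#' @param max_mismatch maximum allowed mismatches (default 3).
#' @param drop_ties drop reads whose best placement is not unique?
#' @param seed RNG seed used only when `drop_ties = FALSE`.
#' @return list with `alignments` (data.frame `read_id`, `ref_id`, `start`
#'   (0-based), `strand`, `n_mismatch`, `length`) and `unmapped`
#'   (data.frame `read_id`, `reason` in `no_placement` / `ambiguous` /
#'   `read_longer_than_reference`).
#' @export
map_reads <- function(reads, reference, max_mismatch = 3L, drop_ties = TRUE,
                      seed = NULL) {
  check_reads(reads)
  reference <- as_reference(reference)
  n <- nrow(reads)
  empty_al <- data.frame(read_id = character(0), ref_id = character(0),
                         start = integer(0), strand = character(0),
                         n_mismatch = integer(0), length = integer(0),
                         stringsAsFactors = FALSE)
  if (!n) {
    return(list(alignments = empty_al,
                unmapped = data.frame(read_id = character(0),
                                      reason = character(0))))
  }
  lens <- nchar(reads$seq)
  pos_len <- lens[lens > 0L]
  seed_len <- if (length(pos_len)) {
    max(1L, min(31L, as.integer(min(pos_len) %/% (max_mismatch + 1L))))
  } else 1L

  per <- lapply(names(reference), function(cn) {
    cpp_map_to_ref(reads$seq, reference[[cn]], as.integer(max_mismatch),
                   seed_len)
  })
  bm <- vapply(per, function(x) as.integer(x$best_mm), integer(n))
  bm <- matrix(bm, nrow = n)
  gb <- do.call(pmin, c(lapply(seq_len(ncol(bm)), function(j) bm[, j]),
                        list(na.rm = TRUE)))
  nb <- integer(n)
  place <- vector("list", length(per))
  for (j in seq_along(per)) {
    x <- per[[j]]
    contributes <- !is.na(bm[, j]) & !is.na(gb) & bm[, j] == gb
    nb <- nb + ifelse(contributes, as.integer(x$n_best), 0L)
    if (length(x$tie_read)) {
      keep <- contributes[x$tie_read]
      if (any(keep)) {
        place[[j]] <- data.frame(
          ridx = x$tie_read[keep],
          ref_id = names(reference)[j],
          start = x$tie_pos[keep],
          strand = ifelse(x$tie_strand[keep] > 0L, "+", "-"),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  place <- do.call(rbind, place[!vapply(place, is.null, logical(1))])

  mapped <- !is.na(gb) & nb == 1L
  ambiguous <- !is.na(gb) & nb > 1L
  if (!drop_ties && any(ambiguous)) {
    if (!is.null(seed)) set.seed(seed)
    o <- order(place$ridx, place$ref_id, place$start, place$strand)
    place <- place[o, , drop = FALSE]
    pick <- unlist(lapply(split(seq_len(nrow(place)), place$ridx), function(i) {
      if (length(i) == 1L) i else i[sample.int(length(i), 1L)]
    }), use.names = FALSE)
    place <- place[sort(pick), , drop = FALSE]
    mapped <- mapped | ambiguous
    ambiguous <- ambiguous & FALSE
  } else if (!is.null(place)) {
    place <- place[place$ridx %in% which(mapped), , drop = FALSE]
  }

  alignments <- empty_al
  if (!is.null(place) && nrow(place)) {
    place <- place[order(place$ridx), , drop = FALSE]
    alignments <- data.frame(
      read_id = reads$id[place$ridx],
      ref_id = place$ref_id,
      start = as.integer(place$start),
      strand = place$strand,
      n_mismatch = gb[place$ridx],
      length = lens[place$ridx],
      stringsAsFactors = FALSE
    )
    rownames(alignments) <- NULL
  }
  un_idx <- which(!(mapped))
  too_long <- Reduce(`&`, lapply(per, function(x) as.logical(x$too_long)))
  reason <- ifelse(ambiguous[un_idx], "ambiguous",
                   ifelse(too_long[un_idx], "read_longer_than_reference",
                          "no_placement"))
  list(alignments = alignments,
       unmapped = data.frame(read_id = reads$id[un_idx], reason = reason,
                             stringsAsFactors = FALSE))
}

#' Exhaustive-scan reference mapper (oracle)
#'
#' Scores every offset on both strands of every contig; same contract and
#' return shape as [map_reads()] with `drop_ties = TRUE`. Intended as an
#' independent cross-check of the seeded mapper on small references.
#'
#' @inheritParams map_reads
#' @export
map_reads_bruteforce <- function(reads, reference, max_mismatch = 3L) {
  check_reads(reads)
  reference <- as_reference(reference)
  n <- nrow(reads)
  per <- lapply(names(reference), function(cn) {
    cpp_bruteforce_map(reads$seq, reference[[cn]], as.integer(max_mismatch))
  })
  combine_bruteforce(reads, reference, per, max_mismatch)
}

combine_bruteforce <- function(reads, reference, per, max_mismatch) {
  n <- nrow(reads)
  bm <- matrix(vapply(per, function(x) as.integer(x$best_mm), integer(n)),
               nrow = n)
  gb <- do.call(pmin, c(lapply(seq_len(ncol(bm)), function(j) bm[, j]),
                        list(na.rm = TRUE)))
  nb <- integer(n)
  rows <- list()
  for (j in seq_along(per)) {
    x <- per[[j]]
    contributes <- !is.na(bm[, j]) & !is.na(gb) & bm[, j] == gb
    nb <- nb + ifelse(contributes, as.integer(x$n_best), 0L)
    if (length(x$tie_read)) {
      keep <- contributes[x$tie_read]
      rows[[j]] <- data.frame(ridx = x$tie_read[keep],
                              ref_id = names(reference)[j],
                              start = x$tie_pos[keep],
                              strand = ifelse(x$tie_strand[keep] > 0, "+", "-"),
                              stringsAsFactors = FALSE)
    }
  }
  place <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  mapped <- !is.na(gb) & nb == 1L
  alignments <- NULL
  if (!is.null(place)) {
    place <- place[place$ridx %in% which(mapped), , drop = FALSE]
    place <- place[order(place$ridx), , drop = FALSE]
    alignments <- data.frame(
      read_id = reads$id[place$ridx], ref_id = place$ref_id,
      start = as.integer(place$start), strand = place$strand,
      n_mismatch = gb[place$ridx], length = nchar(reads$seq)[place$ridx],
      stringsAsFactors = FALSE)
    rownames(alignments) <- NULL
  }
  too_long <- Reduce(`&`, lapply(per, function(x) as.logical(x$too_long)))
  un_idx <- which(!mapped)
  ambiguous <- !is.na(gb) & nb > 1L
  reason <- ifelse(ambiguous[un_idx], "ambiguous",
                   ifelse(too_long[un_idx], "read_longer_than_reference",
                          "no_placement"))
  list(alignments = alignments %||%
         data.frame(read_id = character(0), ref_id = character(0),
                    start = integer(0), strand = character(0),
                    n_mismatch = integer(0), length = integer(0)),
       unmapped = data.frame(read_id = reads$id[un_idx], reason = reason,
                             stringsAsFactors = FALSE))
}

#' Mapped-read and covered-base summary
#'
#' @param alignments alignment data.frame from [map_reads()].
#' @param reference named character vector (or FASTA path / DNAStringSet).
#' @param n_reads optional total read count for the mapped fraction.
#' @return one-row data.frame: `mapped_read_count`, `covered_bases`
#'   (reference positions with depth >= 1), `reference_length`,
#'   `covered_fraction` and (when `n_reads` given) `mapped_fraction`.
#' @export
coverage_summary <- function(alignments, reference, n_reads = NA_integer_) {
  reference <- as_reference(reference)
  covered <- 0L
  if (nrow(alignments)) {
    for (cn in unique(alignments$ref_id)) {
      sub <- alignments[alignments$ref_id == cn, , drop = FALSE]
      ir <- IRanges::IRanges(start = sub$start + 1L, width = sub$length)
      ir <- IRanges::restrict(ir, start = 1L, end = nchar(reference[[cn]]))
      covered <- covered + sum(IRanges::width(IRanges::reduce(ir)))
    }
  }
  ref_len <- sum(nchar(reference))
  data.frame(
    mapped_read_count = nrow(alignments),
    covered_bases = covered,
    reference_length = ref_len,
    covered_fraction = covered / ref_len,
    mapped_fraction = if (!is.na(n_reads)) nrow(alignments) / n_reads
                      else NA_real_
  )
}
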