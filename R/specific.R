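# exact full-window flank search: find, in `reference`, every placement of a
# (2f+1)-base window whose 2f flanking bases match exactly (center base
# free), on either strand. Left flanks are matched exactly with a PDict,
# right flanks verified by string comparison; equivalent to scanning for the
# full window with the center excluded.
flank_hits <- function(left, right, reference, flank_width) {
  f <- flank_width
  k <- length(left)
  empty <- data.frame(query = integer(0), ref_id = character(0),
                      strand = character(0), center_pos0 = integer(0),
                      center_base = character(0), stringsAsFactors = FALSE)
  if (!k) return(empty)
  pd <- Biostrings::PDict(unname(left))
  res <- list()
  for (cn in names(reference)) {
    s <- reference[[cn]]
    n <- nchar(s)
    for (str in c("+", "-")) {
      subj <- if (str == "+") s else revcomp(s)
      m <- Biostrings::matchPDict(pd, Biostrings::DNAString(subj))
      st <- Biostrings::startIndex(m)
      qi <- rep(seq_len(k), lengths(st))
      ss <- unlist(st)
      if (!length(qi)) next
      keep <- ss + 2L * f <= n
      qi <- qi[keep]; ss <- ss[keep]
      if (!length(qi)) next
      rt <- substring(subj, ss + f + 1L, ss + 2L * f)
      okr <- rt == right[qi]
      qi <- qi[okr]; ss <- ss[okr]
      if (!length(qi)) next
      cb <- substring(subj, ss + f, ss + f)
      pos0 <- if (str == "+") ss + f - 1L else n - (ss + f)
      res[[paste(cn, str)]] <- data.frame(
        query = qi, ref_id = cn, strand = str,
        center_pos0 = as.integer(pos0), center_base = cb,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty)
  do.call(rbind, res)
}

# pick the unique hit per query; returns list(n, hit-data columns)
unique_hits <- function(hits, k) {
  nh <- tabulate(hits$query, nbins = k)
  first <- match(seq_len(k), hits$query)
  list(n = nh,
       ref_id = hits$ref_id[first],
       strand = hits$strand[first],
       pos = hits$center_pos0[first],
       base = hits$center_base[first])
}

#' Find alien-specific SNPs by trio intersection
#'
#' For each filtered call on the anchor homoeologue, the
#' `(2*flank_width+1)`-base window centered on the SNP is located in the
#' other two homoeologues by exact full-length flank search on both strands
#' (the center base is excluded from the identity requirement, and exactly
#' one hit per homoeologue is required). The site is emitted as
#' alien-specific when all three homoeologues carry the same base at the
#' center, the alien alt allele differs, and (by default) a concordant
#' filtered call exists at the corresponding position of each of the other
#' two homoeologues.
#'
#' @param calls_a filtered calls against the anchor homoeologue (A).
#' @param calls_b,calls_d filtered calls of the same alien read set against
#'   the other two homoeologues.
#' @param ref_a,ref_b,ref_d named character vectors (or FASTA paths) of the
#'   three homoeologous assemblies.
#' @param flank_width flank length on each side of the SNP (default 100).
#' @param require_calls_on_all also require concordant filtered calls on B
#'   and D (the strictest reading); set FALSE to rely on reference bases
#'   only.
#' @param emit_rejected also return rejected sites, with a `reason` code
#'   (`edge`, `ambiguous_base`, `flank_mismatch_B/D`, `multi_hit_B/D`,
#'   `trio_discordant`, `no_call_B/D`).
#' @return data.frame of trio-anchored sites; emitted sites have
#'   `reason == ""` and `flank_identical_across_trio == TRUE`.
#' @export
find_alien_specific <- function(calls_a, calls_b, calls_d, ref_a, ref_b,
                                ref_d, flank_width = 100L,
                                require_calls_on_all = TRUE,
                                emit_rejected = FALSE) {
  ref_a <- as_reference(ref_a)
  ref_b <- as_reference(ref_b)
  ref_d <- as_reference(ref_d)
  f <- as.integer(flank_width)
  n <- nrow(calls_a)
  out <- data.frame(
    anchor_ref = calls_a$ref_id, anchor_pos = calls_a$pos,
    wheat_a = calls_a$ref, wheat_b = NA_character_, wheat_d = NA_character_,
    alien_allele = calls_a$alt,
    b_ref = NA_character_, b_pos = NA_integer_, b_strand = NA_character_,
    d_ref = NA_character_, d_pos = NA_integer_, d_strand = NA_character_,
    left_flank = NA_character_, right_flank = NA_character_,
    flank_identical_across_trio = FALSE,
    reason = "", stringsAsFactors = FALSE)
  if (!n) return(out)

  clen <- nchar(ref_a)[calls_a$ref_id]
  edge <- calls_a$pos < f | calls_a$pos + f >= clen
  out$reason[edge] <- "edge"
  idx <- which(!edge)
  if (length(idx)) {
    win <- unname(substr(ref_a[calls_a$ref_id[idx]], calls_a$pos[idx] - f + 1L,
                         calls_a$pos[idx] + f + 1L))
    bad <- grepl("[^ACGT]", win)
    out$reason[idx[bad]] <- "ambiguous_base"
    idx <- idx[!bad]
    win <- win[!bad]
  }
  if (length(idx)) {
    left <- substr(win, 1L, f)
    right <- substr(win, f + 2L, 2L * f + 1L)
    out$left_flank[idx] <- left
    out$right_flank[idx] <- right

    hb <- unique_hits(flank_hits(left, right, ref_b, f), length(idx))
    hd <- unique_hits(flank_hits(left, right, ref_d, f), length(idx))

    set_reason <- function(local_sel, code) {
      sel <- idx[local_sel & out$reason[idx] == ""]
      out$reason[sel] <<- code
      invisible(NULL)
    }
    set_reason(hb$n == 0L, "flank_mismatch_B")
    set_reason(hb$n > 1L, "multi_hit_B")
    set_reason(hd$n == 0L, "flank_mismatch_D")
    set_reason(hd$n > 1L, "multi_hit_D")

    ok <- hb$n == 1L & hd$n == 1L
    out$wheat_b[idx[ok]] <- hb$base[ok]
    out$wheat_d[idx[ok]] <- hd$base[ok]
    out$b_ref[idx[ok]] <- hb$ref_id[ok]
    out$b_pos[idx[ok]] <- hb$pos[ok]
    out$b_strand[idx[ok]] <- hb$strand[ok]
    out$d_ref[idx[ok]] <- hd$ref_id[ok]
    out$d_pos[idx[ok]] <- hd$pos[ok]
    out$d_strand[idx[ok]] <- hd$strand[ok]

    disc <- ok & (hb$base != out$wheat_a[idx] | hd$base != out$wheat_a[idx])
    set_reason(disc, "trio_discordant")

    if (require_calls_on_all) {
      key_b <- paste(calls_b$ref_id, calls_b$pos)
      key_d <- paste(calls_d$ref_id, calls_d$pos)
      mb <- match(paste(hb$ref_id, hb$pos), key_b)
      md <- match(paste(hd$ref_id, hd$pos), key_d)
      exp_b <- ifelse(hb$strand == "+", out$alien_allele[idx],
                      comp_base(out$alien_allele[idx]))
      exp_d <- ifelse(hd$strand == "+", out$alien_allele[idx],
                      comp_base(out$alien_allele[idx]))
      miss_b <- ok & (is.na(mb) | calls_b$alt[mb] != exp_b)
      miss_d <- ok & (is.na(md) | calls_d$alt[md] != exp_d)
      set_reason(miss_b, "no_call_B")
      set_reason(miss_d, "no_call_D")
    }
  }
  out$flank_identical_across_trio <- out$reason == "" & !is.na(out$wheat_b)
  emitted <- out$reason == ""
  if (!emit_rejected) {
    out <- out[emitted, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Promote alien-specific sites to marker candidates
#'
#' A site becomes a marker candidate when (a) no other filtered variant on
#' the anchor homoeologue lies within `flank_width` of the SNP and (b),
#' when alien contigs are supplied, the anchor window with the alien allele
#' substituted at the center has a unique exact full-length match in the
#' contigs (either strand). Without contigs the concordance check is
#' recorded as untested (`flank_clean_vs_alien = NA`). Marker ids are
#' assigned serially in anchor-coordinate order.
#'
#' @param sites emitted sites from [find_alien_specific()].
#' @param calls_a filtered anchor calls (used for the nearby-variant rule).
#' @param alien_contigs optional named character vector of alien assembly
#'   contigs.
#' @param flank_width flank length (must match the discovery step).
#' @param prefix marker id prefix.
#' @return data.frame of marker candidates with `status`
#'   (`candidate`/`specific`), `flank_clean_vs_alien` and `reject_reason`.
#' @export
flank_clean_filter <- function(sites, calls_a, alien_contigs = NULL,
                               flank_width = 100L, prefix = "gsnp_5ms") {
  f <- as.integer(flank_width)
  if ("reason" %in% names(sites)) {
    sites <- sites[sites$reason == "", , drop = FALSE]
  }
  sites <- sites[order(sites$anchor_ref, sites$anchor_pos), , drop = FALSE]
  rownames(sites) <- NULL
  n <- nrow(sites)
  sites$marker_id <- if (n) sprintf("%s%d", prefix, seq_len(n)) else character(0)
  sites$nearby_variants <- integer(n)
  if (n) {
    for (cn in unique(sites$anchor_ref)) {
      pv <- sort(calls_a$pos[calls_a$ref_id == cn])
      sel <- which(sites$anchor_ref == cn)
      p <- sites$anchor_pos[sel]
      cnt <- findInterval(p + f, pv) - findInterval(p - f - 1L, pv)
      own <- p %in% pv
      sites$nearby_variants[sel] <- cnt - as.integer(own)
    }
  }
  clean_a <- sites$nearby_variants == 0L
  clean_alien <- rep(NA, n)
  if (!is.null(alien_contigs) && n) {
    alien_contigs <- as_reference(alien_contigs)
    q <- paste0(sites$left_flank, sites$alien_allele, sites$right_flank)
    pd <- Biostrings::PDict(unname(q))
    subj <- Biostrings::DNAStringSet(alien_contigs)
    hits <- rowSums(Biostrings::vcountPDict(pd, subj)) +
      rowSums(Biostrings::vcountPDict(pd, Biostrings::reverseComplement(subj)))
    clean_alien <- hits == 1L
    sites$alien_contig_hits <- as.integer(hits)
  } else {
    sites$alien_contig_hits <- NA_integer_
  }
  promoted <- clean_a & (is.na(clean_alien) | clean_alien)
  sites$flank_clean_vs_alien <- clean_alien
  sites$status <- ifelse(promoted, "candidate", "specific")
  sites$reject_reason <- ""
  sites$reject_reason[!clean_a] <- "flank_variant"
  no_hit <- !is.na(clean_alien) & !clean_alien & clean_a
  sites$reject_reason[no_hit & sites$alien_contig_hits == 0L] <- "no_contig_hit"
  sites$reject_reason[no_hit & sites$alien_contig_hits > 1L] <- "multi_contig_hit"
  sites
}

#' Export an assay-ready marker sheet
#'
#' Writes the promoted candidates as a TSV with 1-based anchor coordinates,
#' wheat and alien alleles, both flanks and the two allele-variant center
#' sequences (flank + wheat-or-alien base) suitable for allele-specific
#' primer design, plus an optional FASTA of the flanking windows.
#'
#' @param candidates output of [flank_clean_filter()].
#' @param path TSV output path (header-only when no candidates).
#' @param fasta_path optional FASTA of `<marker>_wheat` / `<marker>_alien`
#'   windows.
#' @return the exported data.frame, invisibly.
#' @export
export_marker_sheet <- function(candidates, path, fasta_path = NULL) {
  cand <- candidates[candidates$status == "candidate", , drop = FALSE]
  if (anyDuplicated(cand$marker_id)) {
    stop("duplicate marker ids: ",
         paste(unique(cand$marker_id[duplicated(cand$marker_id)]),
               collapse = ", "))
  }
  sheet <- data.frame(
    marker_id = cand$marker_id,
    chrom = cand$anchor_ref,
    position = cand$anchor_pos + 1L,            # 1-based for assay design
    wheat_allele = cand$wheat_a,
    alien_allele = cand$alien_allele,
    left_flank = cand$left_flank,
    right_flank = cand$right_flank,
    wheat_variant_seq = paste0(cand$left_flank, cand$wheat_a,
                               cand$right_flank),
    alien_variant_seq = paste0(cand$left_flank, cand$alien_allele,
                               cand$right_flank),
    stringsAsFactors = FALSE)
  if (!nrow(sheet)) {
    sheet$wheat_variant_seq <- character(0)
    sheet$alien_variant_seq <- character(0)
  }
  write_tsv(sheet, path)
  if (!is.null(fasta_path)) {
    if (nrow(sheet)) {
      seqs <- c(rbind(sheet$wheat_variant_seq, sheet$alien_variant_seq))
      names(seqs) <- c(rbind(paste0(sheet$marker_id, "_wheat"),
                             paste0(sheet$marker_id, "_alien")))
      write_fasta(seqs, fasta_path)
    } else {
      writeLines(character(0), fasta_path)
    }
  }
  invisible(sheet)
}

#' BED intervals of candidate marker positions
#'
#' @param candidates output of [flank_clean_filter()].
#' @param path BED output path (0-based half-open, one base per marker).
#' @export
write_candidate_bed <- function(candidates, path) {
  cand <- candidates[candidates$status == "candidate", , drop = FALSE]
  write_bed(data.frame(chrom = cand$anchor_ref, start = cand$anchor_pos,
                       end = cand$anchor_pos + 1L, name = cand$marker_id,
                       stringsAsFactors = FALSE), path)
}
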