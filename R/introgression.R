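GENOTYPE_LEVELS <- c("WHEAT_HOM", "HET", "ALIEN_HOM", "MISSING")

#' Genotype calls from allele read counts
#'
#' Stand-in for fluorescence cluster calling: per (line, marker) wheat/alien
#' allele counts are converted to MISSING (total below `min_depth`),
#' WHEAT_HOM (alien fraction at or below the lower band), ALIEN_HOM (at or
#' above the upper band) or HET.
#'
#' @param counts data.frame with `line`, `marker_id`, `wheat_count`,
#'   `alien_count`.
#' @param min_depth minimum total depth for a call.
#' @param het_band numeric length-2: the (lower, upper) alien-fraction band
#'   called HET.
#' @return wide genotype data.frame: first column `line`, one column per
#'   marker (marker order = first appearance in `counts`).
#' @export
genotype_from_counts <- function(counts, min_depth = 4L,
                                 het_band = c(0.2, 0.8)) {
  stopifnot(all(c("line", "marker_id", "wheat_count", "alien_count") %in%
                  names(counts)),
            all(counts$wheat_count >= 0), all(counts$alien_count >= 0))
  total <- counts$wheat_count + counts$alien_count
  frac <- ifelse(total > 0, counts$alien_count / total, NA_real_)
  gt <- ifelse(total < min_depth, "MISSING",
               ifelse(frac <= het_band[1L], "WHEAT_HOM",
                      ifelse(frac >= het_band[2L], "ALIEN_HOM", "HET")))
  lines <- unique(counts$line)
  markers <- unique(counts$marker_id)
  mat <- matrix("MISSING", nrow = length(lines), ncol = length(markers),
                dimnames = list(lines, markers))
  mat[cbind(match(counts$line, lines), match(counts$marker_id, markers))] <- gt
  out <- data.frame(line = lines, mat, stringsAsFactors = FALSE,
                    check.names = FALSE, row.names = NULL)
  out
}

# maximal runs of alien-positive calls along marker order, allowing up to
# `tolerance` interior non-alien (non-missing) calls per run; MISSING calls
# neither extend nor break a run
find_alien_runs <- function(gt, tolerance = 0L) {
  alien <- gt %in% c("HET", "ALIEN_HOM")
  observed <- gt != "MISSING"
  runs <- list()
  cur_start <- NA_integer_
  last <- NA_integer_
  used <- 0L
  pending <- 0L
  for (j in seq_along(gt)) {
    if (!observed[j]) next
    if (alien[j]) {
      if (is.na(cur_start)) {
        cur_start <- j; last <- j; used <- 0L; pending <- 0L
      } else if (used + pending <= tolerance) {
        used <- used + pending; pending <- 0L; last <- j
      } else {
        runs[[length(runs) + 1L]] <- c(cur_start, last)
        cur_start <- j; last <- j; used <- 0L; pending <- 0L
      }
    } else {
      pending <- pending + 1L
    }
  }
  if (!is.na(cur_start)) runs[[length(runs) + 1L]] <- c(cur_start, last)
  runs
}

#' Classify lines and delineate introgressed segments
#'
#' Per line, the alien fraction is the share of non-missing markers called
#' HET or ALIEN_HOM (both are alien-positive: an introgression on a wheat
#' background co-detects wheat and alien alleles, while substitution lines
#' may lack one homoeologous copy and shift dosage). Lines are NO_ALIEN at
#' fraction 0, WHOLE_ARM at or above `whole_arm_min`, PARTIAL otherwise and
#' UNCALLED when every marker is missing. Segments are maximal runs of
#' alien-positive calls along marker order (up to `noise_tolerance` interior
#' non-alien calls per run); each segment's coordinate interval runs from
#' its first marker to the next marker after the run (half-open), or one
#' past the last marker's coordinate at the arm end.
#'
#' @param genotypes wide genotype data.frame (first column `line`).
#' @param marker_pos data.frame with `marker_id`, `pos` (anchor
#'   coordinates), or a named numeric vector; positions must be strictly
#'   increasing in the genotype column order.
#' @param whole_arm_min alien fraction at or above which a line is
#'   WHOLE_ARM.
#' @param noise_tolerance interior non-alien calls tolerated per run.
#' @return object of class `introgression_report`: list with `lines`
#'   (per-line class, alien fraction, counts) and `segments` (per-line
#'   marker-index and coordinate intervals).
#' @export
classify_lines <- function(genotypes, marker_pos, whole_arm_min = 0.9,
                           noise_tolerance = 0L) {
  markers <- names(genotypes)[-1L]
  if (is.data.frame(marker_pos)) {
    pos <- setNames(marker_pos$pos, marker_pos$marker_id)
  } else {
    pos <- marker_pos
  }
  missing_pos <- setdiff(markers, names(pos))
  if (length(missing_pos)) {
    stop("no coordinates for marker(s): ",
         paste(utils::head(missing_pos, 5L), collapse = ", "))
  }
  pos <- as.numeric(pos[markers])
  if (any(diff(pos) <= 0)) {
    stop("marker order must be strictly increasing in anchor coordinate")
  }
  bad <- !as.matrix(genotypes[, -1L, drop = FALSE]) %in% GENOTYPE_LEVELS
  if (any(bad)) stop("invalid genotype call(s); expected one of ",
                     paste(GENOTYPE_LEVELS, collapse = "/"))

  lines_out <- vector("list", nrow(genotypes))
  segs_out <- list()
  for (i in seq_len(nrow(genotypes))) {
    id <- genotypes$line[i]
    gt <- as.character(genotypes[i, -1L])
    observed <- gt != "MISSING"
    n_obs <- sum(observed)
    if (n_obs == 0L) {
      lines_out[[i]] <- data.frame(line = id, class = "UNCALLED",
                                   alien_fraction = NA_real_,
                                   n_markers = length(gt), n_missing = length(gt),
                                   stringsAsFactors = FALSE)
      next
    }
    frac <- sum(gt %in% c("HET", "ALIEN_HOM")) / n_obs
    cls <- if (frac == 0) "NO_ALIEN" else if (frac >= whole_arm_min)
      "WHOLE_ARM" else "PARTIAL"
    lines_out[[i]] <- data.frame(line = id, class = cls,
                                 alien_fraction = frac,
                                 n_markers = length(gt),
                                 n_missing = length(gt) - n_obs,
                                 stringsAsFactors = FALSE)
    runs <- find_alien_runs(gt, noise_tolerance)
    for (r in runs) {
      end_pos <- if (r[2L] < length(pos)) pos[r[2L] + 1L] else pos[r[2L]] + 1
      segs_out[[length(segs_out) + 1L]] <- data.frame(
        line = id,
        start_index = r[1L], end_index = r[2L],
        start_marker = markers[r[1L]], end_marker = markers[r[2L]],
        start_pos = pos[r[1L]], end_pos = end_pos,
        stringsAsFactors = FALSE)
    }
  }
  segments <- if (length(segs_out)) do.call(rbind, segs_out) else
    data.frame(line = character(0), start_index = integer(0),
               end_index = integer(0), start_marker = character(0),
               end_marker = character(0), start_pos = numeric(0),
               end_pos = numeric(0), stringsAsFactors = FALSE)
  structure(list(lines = do.call(rbind, lines_out), segments = segments,
                 markers = data.frame(marker_id = markers, pos = pos,
                                      stringsAsFactors = FALSE)),
            class = "introgression_report")
}

#' @export
print.introgression_report <- function(x, ...) {
  cat("Introgression report:", nrow(x$lines), "lines,",
      nrow(x$segments), "segments over", nrow(x$markers), "markers\n")
  print(x$lines, row.names = FALSE)
  invisible(x)
}

#' Compare an introgression report against truth segments
#'
#' Breakpoint error is measured in marker intervals: the absolute
#' difference between inferred and true run end indices, maximised over
#' both ends of paired segments. Lines whose inferred and true segment
#' counts differ get `Inf`.
#'
#' @param report a [classify_lines()] report.
#' @param truth_segments data.frame with `line`, `start_index`, `end_index`
#'   (1-based marker indices of true alien runs; lines absent here are
#'   treated as having none).
#' @return data.frame with per-line `breakpoint_error` and `exact_match`.
#' @export
compare_panels <- function(report, truth_segments) {
  out <- lapply(report$lines$line, function(id) {
    inf <- report$segments[report$segments$line == id, , drop = FALSE]
    tru <- truth_segments[truth_segments$line == id, , drop = FALSE]
    if (nrow(inf) != nrow(tru)) {
      err <- if (nrow(inf) == 0L && nrow(tru) == 0L) 0 else Inf
    } else if (nrow(inf) == 0L) {
      err <- 0
    } else {
      inf <- inf[order(inf$start_index), , drop = FALSE]
      tru <- tru[order(tru$start_index), , drop = FALSE]
      err <- max(abs(inf$start_index - tru$start_index),
                 abs(inf$end_index - tru$end_index))
    }
    data.frame(line = id, breakpoint_error = err, exact_match = err == 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Simulate a genotype panel with known introgression segments
#'
#' Builds a clean-genotype panel over ordered markers: whole-arm lines
#' (alien-positive at every marker, as in addition/substitution lines),
#' distal translocation lines (alien-positive from a random breakpoint to
#' the arm end) and null lines without alien chromatin.
#'
#' @param markers data.frame with `marker_id`, `pos` (strictly increasing).
#' @param n_whole,n_translocation,n_null line counts per class.
#' @param seed RNG seed.
#' @param max_whole_fraction translocation breakpoints are drawn so the
#'   alien fraction stays below this (keeps them PARTIAL under the default
#'   classifier).
#' @return list with `genotypes` (wide table), `truth_lines` and
#'   `truth_segments` (marker-index intervals).
#' @export
simulate_panel <- function(markers, n_whole = 2L, n_translocation = 8L,
                           n_null = 2L, seed = 1L,
                           max_whole_fraction = 0.85) {
  set.seed(seed)
  M <- nrow(markers)
  stopifnot(M >= 4L)
  min_b <- max(2L, ceiling(M * (1 - max_whole_fraction)) + 1L)
  ids <- c(sprintf("addition_%02d", seq_len(n_whole)),
           sprintf("translocation_%02d", seq_len(n_translocation)),
           sprintf("null_%02d", seq_len(n_null)))
  cls <- rep(c("WHOLE_ARM", "PARTIAL", "NO_ALIEN"),
             times = c(n_whole, n_translocation, n_null))
  gt <- matrix("WHEAT_HOM", nrow = length(ids), ncol = M,
               dimnames = list(ids, markers$marker_id))
  truth_segments <- list()
  for (i in seq_along(ids)) {
    if (cls[i] == "WHOLE_ARM") {
      gt[i, ] <- "HET"
      truth_segments[[length(truth_segments) + 1L]] <-
        data.frame(line = ids[i], start_index = 1L, end_index = M)
    } else if (cls[i] == "PARTIAL") {
      b <- sample(seq.int(min_b, M), 1L)
      gt[i, b:M] <- "HET"
      truth_segments[[length(truth_segments) + 1L]] <-
        data.frame(line = ids[i], start_index = b, end_index = M)
    }
  }
  list(
    genotypes = data.frame(line = ids, gt, stringsAsFactors = FALSE,
                           check.names = FALSE, row.names = NULL),
    truth_lines = data.frame(line = ids, class = cls,
                             stringsAsFactors = FALSE),
    truth_segments = do.call(rbind, truth_segments)
  )
}

#' Read a wide genotype table TSV
#'
#' First column is the line id, remaining columns one per marker. Missing
#' cell tokens `NA`, `.` and the empty string are all mapped to MISSING.
#'
#' @param path TSV file.
#' @export
read_genotypes <- function(path) {
  x <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                  na.strings = c("NA", ".", ""))
  names(x)[1L] <- "line"
  for (j in seq_along(x)[-1L]) x[[j]][is.na(x[[j]])] <- "MISSING"
  x
}

#' Write an introgression report
#'
#' @param report a [classify_lines()] report.
#' @param lines_path per-line classification TSV.
#' @param segments_bed optional BED of segment coordinate intervals
#'   (`chrom` taken from `anchor_ref`).
#' @param anchor_ref contig name used in the BED `chrom` column.
#' @export
write_introgression_report <- function(report, lines_path,
                                       segments_bed = NULL,
                                       anchor_ref = "anchor") {
  write_tsv(report$lines, lines_path)
  if (!is.null(segments_bed)) {
    segs <- report$segments
    write_bed(data.frame(chrom = anchor_ref,
                         start = as.integer(segs$start_pos),
                         end = as.integer(segs$end_pos),
                         name = paste0(segs$line, "_seg"),
                         stringsAsFactors = FALSE), segments_bed)
  }
  invisible(report)
}
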