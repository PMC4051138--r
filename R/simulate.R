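#' Simulation configuration
#'
#' Describes a synthetic homoeologous trio plus alien chromosome arm and the
#' single-end sequencing run over the alien arm. Defaults describe the study
#' conditions used throughout the package's own validation: a 200-kb arm,
#' per-homoeologue branch divergence 0.01, alien branch divergence 0.02,
#' 150 planted alien-specific / 50 homoeologue-discordant / 30
#' flank-contaminated sites, 100-bp reads at 30-fold coverage with per-base
#' error rate 0.001.
#'
#' @param seed integer RNG seed; all simulator outputs are deterministic
#'   functions of it.
#' @param ancestor_length length of the ancestral (and hence every derived)
#'   sequence, in bases. Substitution-only evolution keeps all four sequences
#'   colinear.
#' @param trio_divergence substitutions/site on each of the three wheat
#'   homoeologue branches.
#' @param alien_divergence substitutions/site on the alien branch.
#' @param n_planted_specific number of planted alien-specific sites (trio
#'   shares one allele, alien carries another, flanks kept clean).
#' @param n_planted_discordant number of planted homoeologue-discordant sites
#'   (at least two distinct alleles among the wheat trio).
#' @param n_planted_flank_contaminated number of planted alien-specific sites
#'   carrying a second alien variant within `flank_width`.
#' @param read_length read length in bases.
#' @param coverage expected fold coverage of the alien arm.
#' @param error_rate per-base probability that a read base is flipped to a
#'   uniformly random different base.
#' @param coverage_bias_sd log-scale sd of the per-1-kb lognormal coverage
#'   multiplier emulating amplification bias (0 disables bias).
#' @param flank_width planted sites keep this many bases on each side free of
#'   background substitutions and are pairwise separated by more than
#'   `2 * flank_width`.
#' @param low_tail_frac fraction of reads that receive an appended low-quality
#'   tail (exercises end trimming).
#' @param low_tail_len length of that tail, in bases.
#' @param low_qual_read_frac fraction of reads whose entire quality string is
#'   `low_qual` (these should be discarded by QC).
#' @param high_qual phred score assigned to ordinary bases; by default the
#'   score consistent with `error_rate` (`round(-10*log10(error_rate))`,
#'   capped at 40), so declared error probabilities match the simulation.
#' @param low_qual phred score of low-quality tail/read bases.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       ancestor_length = 200000L,
                       trio_divergence = 0.01,
                       alien_divergence = 0.02,
                       n_planted_specific = 150L,
                       n_planted_discordant = 50L,
                       n_planted_flank_contaminated = 30L,
                       read_length = 100L,
                       coverage = 30,
                       error_rate = 0.001,
                       coverage_bias_sd = 0.3,
                       flank_width = 100L,
                       low_tail_frac = 0.2,
                       low_tail_len = 10L,
                       low_qual_read_frac = 0,
                       high_qual = NULL,
                       low_qual = 2L) {
  rates <- c(trio_divergence = trio_divergence,
             alien_divergence = alien_divergence, error_rate = error_rate,
             low_tail_frac = low_tail_frac,
             low_qual_read_frac = low_qual_read_frac)
  if (any(rates < 0 | rates >= 1)) {
    stop("rates must lie in [0, 1): ",
         paste(names(rates)[rates < 0 | rates >= 1], collapse = ", "))
  }
  stopifnot(ancestor_length > 0, read_length > 0, coverage > 0,
            coverage_bias_sd >= 0, flank_width > 0,
            n_planted_specific >= 0, n_planted_discordant >= 0,
            n_planted_flank_contaminated >= 0, low_qual >= 0)
  if (is.null(high_qual)) {
    high_qual <- if (error_rate > 0) {
      max(2L, min(40L, as.integer(round(-10 * log10(error_rate)))))
    } else 40L
  }
  structure(list(
    seed = as.integer(seed),
    ancestor_length = as.integer(ancestor_length),
    trio_divergence = trio_divergence,
    alien_divergence = alien_divergence,
    n_planted_specific = as.integer(n_planted_specific),
    n_planted_discordant = as.integer(n_planted_discordant),
    n_planted_flank_contaminated = as.integer(n_planted_flank_contaminated),
    read_length = as.integer(read_length),
    coverage = coverage,
    error_rate = error_rate,
    coverage_bias_sd = coverage_bias_sd,
    flank_width = as.integer(flank_width),
    low_tail_frac = low_tail_frac,
    low_tail_len = as.integer(low_tail_len),
    low_qual_read_frac = low_qual_read_frac,
    high_qual = as.integer(high_qual),
    low_qual = as.integer(low_qual)
  ), class = "sim_config")
}

# greedy placement of n planted positions in [f, L-1-f], pairwise separated
# by more than 2*f
plant_positions <- function(L, f, n, max_passes = 50L) {
  if (n == 0L) return(integer(0))
  lo <- f
  hi <- L - 1L - f
  if (hi < lo || n * (2L * f + 1L) > (hi - lo + 1L)) {
    stop("sequence too short to plant ", n, " sites with flank width ", f)
  }
  accepted <- integer(0)
  for (pass in seq_len(max_passes)) {
    cand <- sample(seq.int(lo, hi))
    for (p in cand) {
      if (!length(accepted) || all(abs(accepted - p) > 2L * f)) {
        accepted <- c(accepted, p)
        if (length(accepted) == n) return(accepted)
      }
    }
  }
  stop("could not satisfy planted-site spacing constraints; ",
       "sequence too short for requested counts")
}

# substitute random different bases at idx positions of a base vector
substitute_bases <- function(seqvec, idx) {
  if (!length(idx)) return(seqvec)
  cur <- match(seqvec[idx], DNA_BASES)
  alts <- matrix(c(2L, 3L, 4L,   # alternatives to A
                   1L, 3L, 4L,   # C
                   1L, 2L, 4L,   # G
                   1L, 2L, 3L),  # T
                 nrow = 4L, byrow = TRUE)
  pick <- alts[cbind(cur, sample.int(3L, length(idx), replace = TRUE))]
  seqvec[idx] <- DNA_BASES[pick]
  seqvec
}

random_other_base <- function(base) {
  alts <- matrix(c(2L, 3L, 4L, 1L, 3L, 4L, 1L, 2L, 4L, 1L, 2L, 3L),
                 nrow = 4L, byrow = TRUE)
  cur <- match(base, DNA_BASES)
  DNA_BASES[alts[cbind(cur, sample.int(3L, length(base), replace = TRUE))]]
}

#' Evolve a homoeologous trio and an alien arm from a common ancestor
#'
#' Draws a random ancestor, applies independent substitutions on the three
#' wheat homoeologue branches and on the alien branch, and plants
#' alien-specific, homoeologue-discordant and flank-contaminated sites at
#' positions whose `flank_width` neighbourhoods are protected from background
#' substitutions on every branch. Substitution-only evolution keeps all
#' sequences colinear, so the truth table's anchor positions are valid on all
#' four sequences.
#'
#' @param config a [sim_config()].
#' @return list with `refs` (named character: `5AS`, `5BS`, `5DS`), `alien`
#'   (named character: `5MgS`), `truth` (data.frame `position` (0-based on
#'   the anchor), `class`, `wheat_allele`, `alien_allele`) and `config`. The
#'   truth table records every position at which the four sequences are not
#'   identical: planted sites under their planted class, everything else
#'   (including the companion variants of flank-contaminated sites) as
#'   `background`.
#' @export
evolve_trio <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$ancestor_length
  f <- config$flank_width
  n_spec <- config$n_planted_specific
  n_disc <- config$n_planted_discordant
  n_cont <- config$n_planted_flank_contaminated
  n_all <- n_spec + n_disc + n_cont

  anc <- sample(DNA_BASES, L, replace = TRUE)
  pos <- plant_positions(L, f, n_all)      # 0-based
  class <- rep(c("alien_specific", "homoeologue_discordant",
                 "flank_contaminated"), times = c(n_spec, n_disc, n_cont))

  companion <- integer(0)
  if (n_cont > 0L) {
    main <- pos[class == "flank_contaminated"]
    d <- sample(seq.int(10L, max(11L, f - 10L)), n_cont, replace = TRUE)
    sgn <- sample(c(-1L, 1L), n_cont, replace = TRUE)
    companion <- pmin(pmax(main + sgn * d, 1L), L - 2L)
  }

  protected <- logical(L)
  for (p in c(pos, companion)) {
    protected[max(1L, p + 1L - f):min(L, p + 1L + f)] <- TRUE
  }

  draw_subs <- function(rate) {
    if (rate <= 0) return(integer(0))
    idx <- which(runif(L) < rate)
    idx[!protected[idx]]
  }
  a <- substitute_bases(anc, draw_subs(config$trio_divergence))
  b <- substitute_bases(anc, draw_subs(config$trio_divergence))
  d <- substitute_bases(anc, draw_subs(config$trio_divergence))
  al <- substitute_bases(anc, draw_subs(config$alien_divergence))

  wheat_allele <- anc[pos + 1L]
  alien_allele <- rep(NA_character_, n_all)

  if (n_spec > 0L) {
    i <- which(class == "alien_specific")
    alien_allele[i] <- random_other_base(wheat_allele[i])
    al[pos[i] + 1L] <- alien_allele[i]
  }
  if (n_disc > 0L) {
    i <- which(class == "homoeologue_discordant")
    # one of B/D gets a discordant wheat allele; alien still differs from A
    which_ref <- sample(c("B", "D"), n_disc, replace = TRUE)
    disc_base <- random_other_base(wheat_allele[i])
    bsel <- which_ref == "B"
    b[pos[i][bsel] + 1L] <- disc_base[bsel]
    d[pos[i][!bsel] + 1L] <- disc_base[!bsel]
    alien_allele[i] <- random_other_base(wheat_allele[i])
    al[pos[i] + 1L] <- alien_allele[i]
  }
  if (n_cont > 0L) {
    i <- which(class == "flank_contaminated")
    alien_allele[i] <- random_other_base(wheat_allele[i])
    al[pos[i] + 1L] <- alien_allele[i]
    comp_allele <- random_other_base(anc[companion + 1L])
    al[companion + 1L] <- comp_allele
  }

  planted <- data.frame(position = pos, class = class,
                        wheat_allele = wheat_allele,
                        alien_allele = alien_allele, stringsAsFactors = FALSE)
  diff_sites <- which(!(a == b & b == d & d == al)) - 1L
  bg <- setdiff(diff_sites, pos)
  background <- data.frame(position = bg,
                           class = rep("background", length(bg)),
                           wheat_allele = a[bg + 1L],
                           alien_allele = al[bg + 1L],
                           stringsAsFactors = FALSE)
  truth <- rbind(planted, background)
  truth <- truth[order(truth$position), , drop = FALSE]
  rownames(truth) <- NULL

  list(
    refs = c(`5AS` = paste(a, collapse = ""),
             `5BS` = paste(b, collapse = ""),
             `5DS` = paste(d, collapse = "")),
    alien = c(`5MgS` = paste(al, collapse = "")),
    truth = truth,
    config = config
  )
}

#' Simulate single-end reads over the alien arm
#'
#' Start positions are assigned to 1-kb windows whose expected read counts
#' are `total * weight_w * m_w`, where `total = coverage * arm_length /
#' read_length`, `weight_w` is the window's share of valid start positions
#' and `m_w` is a lognormal multiplier with log-sd `coverage_bias_sd` (mean
#' 1) emulating amplification bias. Realized window counts are
#' `floor(lambda) + Bernoulli(lambda - floor(lambda))`, so the expectation is
#' exact and the bias-free, integer-coverage limit is deterministic. Each
#' base is flipped to a random different base with probability `error_rate`;
#' ordinary bases receive phred `high_qual`, and a `low_tail_frac` fraction
#' of reads get `low_tail_len` appended random bases at phred `low_qual`.
#'
#' @param arm alien arm sequence (character scalar, possibly named).
#' @param config a [sim_config()].
#' @param seed RNG seed; defaults to `config$seed + 1` so the read stream is
#'   decoupled from, but still determined by, the genome seed.
#' @return data.frame with `id`, `seq`, `qual` (phred+33).
#' @export
generate_reads <- function(arm, config, seed = config$seed + 1L) {
  stopifnot(inherits(config, "sim_config"))
  arm <- unname(arm)[1]
  set.seed(seed)
  L <- nchar(arm)
  rl <- config$read_length
  if (rl > L) stop("read_length exceeds arm length")
  n_starts <- L - rl + 1L
  win_of_start <- (seq_len(n_starts) - 1L) %/% 1000L
  starts_per_win <- tabulate(win_of_start + 1L)
  n_win <- length(starts_per_win)
  m <- if (config$coverage_bias_sd > 0) {
    rlnorm(n_win, meanlog = -config$coverage_bias_sd^2 / 2,
           sdlog = config$coverage_bias_sd)
  } else rep(1, n_win)
  total <- config$coverage * L / rl
  lam <- total * (starts_per_win / n_starts) * m
  counts <- floor(lam) + rbinom(n_win, 1L, lam - floor(lam))
  n <- sum(counts)
  if (n == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      qual = character(0), stringsAsFactors = FALSE))
  }
  win_lo <- (seq_len(n_win) - 1L) * 1000L                  # 0-based start range
  widx <- rep(seq_len(n_win), counts)
  starts <- win_lo[widx] +
    floor(runif(n) * pmin(1000L, n_starts - win_lo[widx]))
  starts <- as.integer(starts)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  seqs <- substring(arm, starts + 1L, starts + rl)
  neg <- strand == "-"
  seqs[neg] <- revcomp(seqs[neg])

  if (config$error_rate > 0) {
    n_err <- rbinom(n, rl, config$error_rate)
    for (i in which(n_err > 0L)) {
      at <- sample.int(rl, n_err[i])
      ch <- strsplit(seqs[i], "")[[1]]
      ch[at] <- random_other_base(ch[at])
      seqs[i] <- paste(ch, collapse = "")
    }
  }

  hq <- intToUtf8(33L + config$high_qual)
  lq <- intToUtf8(33L + config$low_qual)
  quals <- rep(strrep(hq, rl), n)
  u <- runif(n)
  all_low <- u < config$low_qual_read_frac
  tail_sel <- !all_low &
    (u < config$low_qual_read_frac + config$low_tail_frac) &
    config$low_tail_len > 0L
  quals[all_low] <- strrep(lq, rl)
  if (any(tail_sel)) {
    k <- sum(tail_sel)
    tails <- vapply(seq_len(k), function(i) {
      paste(sample(DNA_BASES, config$low_tail_len, replace = TRUE),
            collapse = "")
    }, character(1))
    seqs[tail_sel] <- paste0(seqs[tail_sel], tails)
    quals[tail_sel] <- paste0(quals[tail_sel],
                              strrep(lq, config$low_tail_len))
  }
  data.frame(
    id = sprintf("simread_%06d", seq_len(n)),
    seq = seqs,
    qual = quals,
    stringsAsFactors = FALSE
  )
}

#' Slice the alien arm into pseudo-contigs
#'
#' Stands in for a de-novo assembly of the alien reads: the arm is cut into
#' consecutive pieces, optionally overlapping. Sites whose flanks span a
#' piece boundary will (correctly) fail the flank-vs-contig concordance
#' check, mimicking assembly fragmentation.
#'
#' @param arm alien arm sequence.
#' @param contig_length piece length in bases.
#' @param overlap overlap between consecutive pieces.
#' @param prefix contig name prefix.
#' @return named character vector of contig sequences.
#' @export
simulate_contigs <- function(arm, contig_length = 5000L, overlap = 0L,
                             prefix = "alien_contig") {
  arm <- unname(arm)[1]
  L <- nchar(arm)
  stopifnot(contig_length > overlap)
  starts <- seq.int(1L, L, by = contig_length - overlap)
  starts <- starts[starts <= L]
  ends <- pmin(starts + contig_length - 1L, L)
  keep <- ends > starts
  out <- substring(arm, starts[keep], ends[keep])
  names(out) <- sprintf("%s%04d", prefix, seq_along(out))
  out
}

#' Simulate a full dataset and optionally write it to disk
#'
#' @param config a [sim_config()].
#' @param out_dir if non-NULL, writes `homoeologue_trio.fasta`,
#'   `alien_arm.fasta`, `alien_reads.fastq`, `truth.tsv` and (when
#'   `contigs = TRUE`) `alien_contigs.fasta` there.
#' @param contigs also slice the arm into pseudo-contigs?
#' @param ... passed to [simulate_contigs()].
#' @return list with `refs`, `alien`, `truth`, `reads`, `contigs` (or NULL)
#'   and `config`.
#' @export
simulate_dataset <- function(config, out_dir = NULL, contigs = FALSE, ...) {
  trio <- evolve_trio(config)
  reads <- generate_reads(trio$alien, config)
  ctg <- if (contigs) simulate_contigs(trio$alien, ...) else NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_fasta(trio$refs, file.path(out_dir, "homoeologue_trio.fasta"))
    write_fasta(trio$alien, file.path(out_dir, "alien_arm.fasta"))
    write_fastq(reads, file.path(out_dir, "alien_reads.fastq"))
    write_tsv(trio$truth, file.path(out_dir, "truth.tsv"))
    if (!is.null(ctg)) {
      write_fasta(ctg, file.path(out_dir, "alien_contigs.fasta"))
    }
  }
  c(trio[c("refs", "alien", "truth")],
    list(reads = reads, contigs = ctg, config = config))
}
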