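# Independent oracles and small builders used across the test files. These
# deliberately re-derive results by the most literal method available
# (per-base loops, exhaustive scans, direct tail sums) so they share no code
# with the implementation paths they check.

# build a reads data.frame from explicit phred integer vectors
read_df <- function(ids, seqs, qual_ints, offset = 33L) {
  data.frame(
    id = ids,
    seq = seqs,
    qual = vapply(qual_ints, function(q) intToUtf8(q + offset), character(1)),
    stringsAsFactors = FALSE
  )
}

random_quals <- function(len) sample(0:45, len, replace = TRUE)

random_seq <- function(len) paste(sample(c("A", "C", "G", "T"), len,
                                         replace = TRUE), collapse = "")

# literal per-base trim oracle: drop ends with phred <= floor
naive_trim <- function(seq, quals, floor = 15L) {
  above <- which(quals > floor)
  if (!length(above)) return(list(seq = "", quals = integer(0)))
  i <- min(above); j <- max(above)
  list(seq = substr(seq, i, j), quals = quals[i:j])
}

# literal keep/discard oracle on a trimmed read
naive_keep <- function(seq, quals, min_len = 30L, min_frac = 0.8,
                       floor = 15L) {
  len <- nchar(seq)
  if (len <= min_len) return(FALSE)
  bases <- strsplit(seq, "")[[1]]
  pass <- quals >= floor & bases != "N"
  sum(pass) / len >= min_frac
}

# direct log-space binomial tail: P(X >= k), X ~ Binom(n, p), in phred units
binom_tail_phred <- function(k, n, p, cap = 1000) {
  if (k <= 0) return(0)
  lp <- dbinom(k:n, n, p, log = TRUE)
  m <- max(lp)
  lt <- m + log(sum(exp(lp - m)))
  min(cap, -10 / log(10) * lt)
}

# classify every position of an emitted quartet of sequences by direct
# comparison (the round-trip oracle for the simulator's truth table)
scan_sites <- function(a, b, d, alien) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  dv <- strsplit(d, "")[[1]]
  lv <- strsplit(alien, "")[[1]]
  differs <- !(av == bv & bv == dv & dv == lv)
  data.frame(
    position = which(differs) - 1L,
    trio_identical = (av == bv & av == dv)[differs],
    alien_differs = (av != lv)[differs],
    a_base = av[differs],
    alien_base = lv[differs],
    stringsAsFactors = FALSE
  )
}

# depth of alignment coverage at single positions (0-based)
depth_at <- function(alignments, pos) {
  ir <- IRanges::IRanges(alignments$start + 1L, width = alignments$length)
  IRanges::countOverlaps(IRanges::IRanges(pos + 1L, width = 1L), ir)
}

# canonical alignment key for set comparisons
alignment_key <- function(al) {
  paste(al$read_id, al$ref_id, al$start, al$strand, al$n_mismatch, al$length)
}

# inject k mismatches into a sequence at distinct positions
mutate_seq <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  at <- sample(length(ch), k)
  for (i in at) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
  paste(ch, collapse = "")
}
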