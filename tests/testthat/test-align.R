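make_ref <- function(seq, name = "ref1") setNames(seq, name)

test_that("an exact unique substring maps with zero mismatches at its offset", {
  set.seed(11)
  ref <- make_ref(random_seq(2000))
  read <- read_df("r1", substr(ref, 501, 600), list(rep(40, 100)))
  res <- map_reads(read, ref)
  expect_equal(nrow(res$alignments), 1L)
  expect_equal(res$alignments$start, 500L)
  expect_equal(res$alignments$strand, "+")
  expect_equal(res$alignments$n_mismatch, 0L)
})

test_that("reads beyond the mismatch budget or with tied best hits are unmapped", {
  set.seed(12)
  ref_seq <- random_seq(3000)
  # a read whose best placement has 4 mismatches
  bad <- mutate_seq(substr(ref_seq, 1001, 1100), 4)
  # a repeated locus: the same 100-mer at two positions, read at 2 mismatches
  locus <- random_seq(100)
  ref2_seq <- paste0(ref_seq, locus, random_seq(500), locus, random_seq(200))
  ambiguous <- mutate_seq(locus, 2)
  reads <- read_df(c("over_budget", "two_loci"), c(bad, ambiguous),
                   list(rep(40, 100), rep(40, 100)))
  res <- map_reads(reads, make_ref(ref2_seq))
  expect_equal(nrow(res$alignments), 0L)
  expect_setequal(res$unmapped$read_id, c("over_budget", "two_loci"))
  expect_equal(res$unmapped$reason[res$unmapped$read_id == "two_loci"],
               "ambiguous")
  expect_equal(res$unmapped$reason[res$unmapped$read_id == "over_budget"],
               "no_placement")
  # random-best mode assigns one of the tied placements instead
  res2 <- map_reads(reads, make_ref(ref2_seq), drop_ties = FALSE, seed = 1)
  expect_true("two_loci" %in% res2$alignments$read_id)
})

test_that("a read longer than every contig is unmapped with that reason", {
  ref <- make_ref(random_seq(50))
  read <- read_df("long", random_seq(80), list(rep(40, 80)))
  res <- map_reads(read, ref)
  expect_equal(res$unmapped$reason, "read_longer_than_reference")
})

test_that("mapping a read and its reverse complement gives mirrored strands", {
  set.seed(13)
  ref <- make_ref(random_seq(1500))
  fwd <- substr(ref, 301, 400)
  reads <- read_df(c("f", "r"), c(fwd, revcomp(fwd)),
                   list(rep(40, 100), rep(40, 100)))
  res <- map_reads(reads, ref)
  expect_equal(nrow(res$alignments), 2L)
  expect_equal(res$alignments$start, c(300L, 300L))
  expect_setequal(res$alignments$strand, c("+", "-"))
})

test_that("uniqueness is assessed across all contigs of one reference", {
  set.seed(14)
  shared <- random_seq(100)
  ref <- c(c1 = paste0(random_seq(200), shared, random_seq(200)),
           c2 = paste0(random_seq(100), shared, random_seq(300)))
  read <- read_df("dup", shared, list(rep(40, 100)))
  res <- map_reads(read, ref)
  expect_equal(res$unmapped$reason, "ambiguous")
})

test_that("the seeded mapper agrees exactly with the exhaustive-scan oracle", {
  set.seed(15)
  for (rep_i in 1:5) {
    ref <- make_ref(random_seq(sample(1500:3000, 1)),
                    sprintf("ref%02d", rep_i))
    n <- 200
    starts <- sample(nchar(ref) - 60, n, replace = TRUE)
    seqs <- substring(ref, starts, starts + 59)
    mm <- sample(0:5, n, replace = TRUE)
    seqs <- vapply(seq_len(n),
                   function(i) if (mm[i]) mutate_seq(seqs[i], mm[i]) else seqs[i],
                   character(1))
    flip <- runif(n) < 0.5
    seqs[flip] <- revcomp(seqs[flip])
    reads <- read_df(sprintf("r%03d", 1:n), seqs,
                     replicate(n, rep(40, 60), simplify = FALSE))
    got <- map_reads(reads, ref)
    want <- map_reads_bruteforce(reads, ref)
    expect_identical(alignment_key(got$alignments),
                     alignment_key(want$alignments))
    expect_equal(got$unmapped[order(got$unmapped$read_id), ],
                 want$unmapped[order(want$unmapped$read_id), ],
                 ignore_attr = TRUE)
  }
})

test_that("SAM export/import round-trips the alignment set bit-exactly", {
  set.seed(16)
  ref <- make_ref(random_seq(2000))
  n <- 50
  starts <- sample(1900, n, replace = TRUE)
  seqs <- substring(ref, starts, starts + 79)
  seqs[1:10] <- vapply(seqs[1:10], mutate_seq, character(1), k = 2)
  flip <- runif(n) < 0.5
  seqs[flip] <- revcomp(seqs[flip])
  reads <- read_df(sprintf("r%03d", 1:n), seqs,
                   replicate(n, sample(20:40, 80, replace = TRUE),
                             simplify = FALSE))
  res <- map_reads(reads, ref)
  sam <- tempfile(fileext = ".sam")
  write_sam(res$alignments, reads, ref, sam)
  back <- read_sam(sam, reference = ref)
  expect_identical(alignment_key(back$alignments),
                   alignment_key(res$alignments))
  # reads are recovered in forward orientation with original qualities
  m <- match(back$reads$id, reads$id)
  expect_identical(back$reads$seq, reads$seq[m])
  expect_identical(back$reads$qual, reads$qual[m])
  unlink(sam)
})

test_that("SAM import enforces flag, mismatch and reference-name contracts", {
  ref <- c(ref1 = strrep("ACGT", 100))
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6",
    "@SQ\tSN:ref1\tLN:400",
    sprintf("ok\t0\tref1\t1\t255\t8M\t*\t0\t0\t%s\t%s\tNM:i:0",
            "ACGTACGT", "IIIIIIII"),
    sprintf("unmapped\t4\t*\t0\t0\t*\t*\t0\t0\t%s\t%s", "ACGTACGT", "IIIIIIII"),
    sprintf("secondary\t256\tref1\t1\t255\t8M\t*\t0\t0\t%s\t%s\tNM:i:0",
            "ACGTACGT", "IIIIIIII"),
    sprintf("too_div\t0\tref1\t1\t255\t8M\t*\t0\t0\t%s\t%s\tNM:i:5",
            "TTTTTTTT", "IIIIIIII"),
    sprintf("gapped\t0\tref1\t1\t255\t4M1I3M\t*\t0\t0\t%s\t%s\tNM:i:1",
            "ACGTTCGT", "IIIIIIII"),
    # no NM/MD: one real mismatch, recomputed from the reference
    sprintf("recompute\t0\tref1\t5\t255\t8M\t*\t0\t0\t%s\t%s",
            "AGGTACGT", "IIIIIIII")
  ), sam)
  res <- read_sam(sam, reference = ref)
  expect_setequal(res$alignments$read_id, c("ok", "recompute"))
  expect_equal(res$alignments$n_mismatch[res$alignments$read_id == "recompute"],
               1L)
  expect_equal(unname(res$dropped["unmapped_or_secondary"]), 2L)
  expect_equal(unname(res$dropped["over_mismatch"]), 1L)
  expect_equal(unname(res$dropped["gapped"]), 1L)

  writeLines(c("@HD\tVN:1.6",
               sprintf("x\t0\tnot_there\t1\t255\t4M\t*\t0\t0\tACGT\tIIII\tNM:i:0")),
             sam)
  expect_error(read_sam(sam, reference = ref), "not_there")
  unlink(sam)
})

test_that("coverage summary counts covered bases and fractions", {
  ref <- c(ref1 = strrep("A", 1000))
  empty <- data.frame(read_id = character(0), ref_id = character(0),
                      start = integer(0), strand = character(0),
                      n_mismatch = integer(0), length = integer(0))
  expect_equal(coverage_summary(empty, ref)$covered_fraction, 0)
  one <- data.frame(read_id = "r", ref_id = "ref1", start = 0L, strand = "+",
                    n_mismatch = 0L, length = 100L)
  cs <- coverage_summary(one, ref, n_reads = 10L)
  expect_equal(cs$covered_fraction, 0.10)
  expect_equal(cs$mapped_fraction, 0.1)
  # overlapping reads do not double-count covered bases
  two <- rbind(one, transform(one, read_id = "r2", start = 50L))
  expect_equal(coverage_summary(two, ref)$covered_bases, 150L)
})

test_that("deep bias-free coverage leaves almost no uncovered bases", {
  cfg <- sim_config(seed = 21, ancestor_length = 100000, coverage = 10,
                    error_rate = 0, coverage_bias_sd = 0, low_tail_frac = 0,
                    trio_divergence = 0, alien_divergence = 0,
                    n_planted_specific = 0, n_planted_discordant = 0,
                    n_planted_flank_contaminated = 0)
  sim <- evolve_trio(cfg)
  reads <- generate_reads(sim$alien, cfg)
  res <- map_reads(reads, sim$refs["5AS"])
  cs <- coverage_summary(res$alignments, sim$refs["5AS"])
  # Poisson(10) zero-depth probability is ~5e-5 per position
  expect_gte(cs$covered_fraction, 0.999)
})
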