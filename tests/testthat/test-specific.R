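# hand-built trio: B and D equal to A except at controlled positions, so
# flank correspondence is exact and every rejection path can be driven
# explicitly. Coordinates are shared by construction.
make_trio <- function(len = 1200, seed = 41) {
  set.seed(seed)
  a <- random_seq(len)
  list(a = c(A1 = a), b = c(B1 = a), d = c(D1 = a))
}

call_row <- function(ref_id, pos, ref, alt) {
  data.frame(ref_id = ref_id, pos = pos, ref = ref, alt = alt, depth = 10L,
             alt_count = 10L, qual = 300, stringsAsFactors = FALSE)
}

base_at <- function(seq, pos) substr(seq, pos + 1, pos + 1)
other_base <- function(b) setdiff(c("A", "C", "G", "T"), b)[1]

test_that("trio-concordant sites with concordant calls are emitted", {
  tr <- make_trio()
  p <- 600L
  wheat <- base_at(tr$a[[1]], p)
  alien <- other_base(wheat)
  ca <- call_row("A1", p, wheat, alien)
  cb <- call_row("B1", p, wheat, alien)
  cd <- call_row("D1", p, wheat, alien)
  sites <- find_alien_specific(ca, cb, cd, tr$a, tr$b, tr$d)
  expect_equal(nrow(sites), 1L)
  expect_true(sites$flank_identical_across_trio)
  expect_equal(sites$wheat_b, wheat)
  expect_equal(sites$alien_allele, alien)
  expect_equal(sites$b_pos, p)

  # dropping the D call rejects the site under the strict reading but not
  # under the reference-only relaxation
  strict <- find_alien_specific(ca, cb, cd[0, ], tr$a, tr$b, tr$d,
                                emit_rejected = TRUE)
  expect_equal(strict$reason, "no_call_D")
  relaxed <- find_alien_specific(ca, cb, cd[0, ], tr$a, tr$b, tr$d,
                                 require_calls_on_all = FALSE)
  expect_equal(nrow(relaxed), 1L)
})

test_that("homoeologue-discordant and flank-divergent sites are rejected", {
  tr <- make_trio(seed = 42)
  p <- 600L
  wheat <- base_at(tr$a[[1]], p)
  alien <- other_base(wheat)
  # B carries a different center allele -> trio discordant
  b_disc <- tr$b
  substr(b_disc[[1]], p + 1, p + 1) <- other_base(wheat)
  ca <- call_row("A1", p, wheat, alien)
  cb <- call_row("B1", p, wheat, alien)
  cd <- call_row("D1", p, wheat, alien)
  r1 <- find_alien_specific(ca, cb, cd, tr$a, b_disc, tr$d,
                            emit_rejected = TRUE)
  expect_equal(r1$reason, "trio_discordant")

  # one substitution inside the B flank -> no 100%-identical hit
  b_flank <- tr$b
  fp <- p - 40L
  substr(b_flank[[1]], fp + 1, fp + 1) <- other_base(base_at(tr$b[[1]], fp))
  r2 <- find_alien_specific(ca, cb, cd, tr$a, b_flank, tr$d,
                            emit_rejected = TRUE)
  expect_equal(r2$reason, "flank_mismatch_B")

  # window truncated by the contig end -> edge
  r3 <- find_alien_specific(call_row("A1", 50L, wheat, alien), cb, cd,
                            tr$a, tr$b, tr$d, emit_rejected = TRUE)
  expect_equal(r3$reason, "edge")

  # duplicated flank locus in D -> anchoring not unique
  d_dup <- tr$d
  win <- substr(tr$a[[1]], p - 99, p + 101)
  d_dup[[1]] <- paste0(d_dup[[1]], strrep("T", 20), win)
  r4 <- find_alien_specific(ca, cb, cd, tr$a, tr$b, d_dup,
                            emit_rejected = TRUE)
  expect_equal(r4$reason, "multi_hit_D")
})

test_that("reverse-strand flank hits report anchor-forward alleles", {
  tr <- make_trio(seed = 43)
  p <- 600L
  wheat <- base_at(tr$a[[1]], p)
  alien <- other_base(wheat)
  b_rc <- setNames(revcomp(tr$b[[1]]), "B1")
  p_rc <- unname(nchar(b_rc)) - 1L - p
  ca <- call_row("A1", p, wheat, alien)
  cb <- call_row("B1", p_rc, chartr("ACGT", "TGCA", wheat),
                 chartr("ACGT", "TGCA", alien))
  cd <- call_row("D1", p, wheat, alien)
  sites <- find_alien_specific(ca, cb, cd, tr$a, b_rc, tr$d)
  expect_equal(nrow(sites), 1L)
  expect_equal(sites$b_strand, "-")
  expect_equal(sites$b_pos, p_rc)
  expect_equal(sites$wheat_b, wheat)   # reported on the anchor's strand
})

test_that("flank cleanliness gates promotion to marker candidates", {
  tr <- make_trio(seed = 44)
  p1 <- 300L
  p2 <- 800L
  w1 <- base_at(tr$a[[1]], p1); a1 <- other_base(w1)
  w2 <- base_at(tr$a[[1]], p2); a2 <- other_base(w2)
  # second filtered anchor variant 40 bp from p1 contaminates its flank
  near <- call_row("A1", p1 + 40L, base_at(tr$a[[1]], p1 + 40L),
                   other_base(base_at(tr$a[[1]], p1 + 40L)))
  ca <- rbind(call_row("A1", p1, w1, a1), call_row("A1", p2, w2, a2), near)
  cb <- rbind(call_row("B1", p1, w1, a1), call_row("B1", p2, w2, a2))
  cd <- rbind(call_row("D1", p1, w1, a1), call_row("D1", p2, w2, a2))
  sites <- find_alien_specific(ca, cb, cd, tr$a, tr$b, tr$d)
  cand <- flank_clean_filter(sites, ca)
  expect_equal(cand$status[cand$anchor_pos == p1], "specific")
  expect_equal(cand$reject_reason[cand$anchor_pos == p1], "flank_variant")
  expect_equal(cand$status[cand$anchor_pos == p2], "candidate")
  expect_true(is.na(cand$flank_clean_vs_alien[cand$anchor_pos == p2]))

  # with alien contigs supplied: unique alien-allele window -> promoted;
  # flank spanning a contig boundary -> no hit, not promoted
  alien_seq <- tr$a[[1]]
  substr(alien_seq, p1 + 1, p1 + 1) <- a1
  substr(alien_seq, p2 + 1, p2 + 1) <- a2
  whole <- c(contig1 = alien_seq)
  cand2 <- flank_clean_filter(sites, ca, alien_contigs = whole)
  expect_true(cand2$flank_clean_vs_alien[cand2$anchor_pos == p2])
  expect_equal(cand2$status[cand2$anchor_pos == p2], "candidate")
  split_at_p2 <- c(contigA = substr(alien_seq, 1, p2),
                   contigB = substr(alien_seq, p2 + 1, nchar(alien_seq)))
  cand3 <- flank_clean_filter(sites, ca, alien_contigs = split_at_p2)
  expect_equal(cand3$status[cand3$anchor_pos == p2], "specific")
  expect_equal(cand3$reject_reason[cand3$anchor_pos == p2], "no_contig_hit")
})

test_that("marker sheets use 1-based coordinates and reject duplicate ids", {
  tr <- make_trio(seed = 45)
  p <- 999L
  w <- base_at(tr$a[[1]], p); al <- other_base(w)
  ca <- call_row("A1", p, w, al)
  cb <- call_row("B1", p, w, al)
  cd <- call_row("D1", p, w, al)
  sites <- find_alien_specific(ca, cb, cd, tr$a, tr$b, tr$d)
  cand <- flank_clean_filter(sites, ca)
  tsv <- tempfile(fileext = ".tsv")
  fa <- tempfile(fileext = ".fasta")
  sheet <- export_marker_sheet(cand, tsv, fa)
  expect_equal(sheet$position, 1000L)
  expect_equal(nchar(sheet$wheat_variant_seq), 201L)
  expect_equal(substr(sheet$alien_variant_seq, 101, 101), al)
  flanks <- read_fasta(fa)
  expect_equal(length(flanks), 2L)

  dup <- rbind(cand, cand)
  expect_error(export_marker_sheet(dup, tsv), "duplicate")

  # zero candidates produce a header-only sheet
  none <- cand[0, , drop = FALSE]
  sheet0 <- export_marker_sheet(none, tsv)
  expect_equal(nrow(sheet0), 0L)
  expect_match(readLines(tsv)[1], "marker_id")
  unlink(c(tsv, fa))
})

test_that("pipeline funnel keeps candidates within specific within filtered", {
  cfg <- sim_config(seed = 46, ancestor_length = 30000,
                    n_planted_specific = 8, n_planted_discordant = 4,
                    n_planted_flank_contaminated = 2, coverage = 15)
  sim <- simulate_dataset(cfg, contigs = TRUE, contig_length = 8000)
  res <- run_pipeline(sim$refs["5AS"], sim$refs["5BS"], sim$refs["5DS"],
                      sim$reads, alien_contigs = sim$contigs)
  n_cand <- sum(res$candidates$status == "candidate")
  n_spec <- sum(res$sites$reason == "")
  expect_lte(n_cand, n_spec)
  expect_lte(n_spec, nrow(res$filtered_calls$A))
  expect_lte(nrow(res$filtered_calls$A), nrow(res$raw_calls$A))
})

test_that("swapping the anchor preserves planted-site alleles and flanks", {
  cfg <- sim_config(seed = 47, ancestor_length = 40000,
                    n_planted_specific = 12, n_planted_discordant = 4,
                    n_planted_flank_contaminated = 0, coverage = 20,
                    error_rate = 0, coverage_bias_sd = 0)
  sim <- evolve_trio(cfg)
  clean <- qc_reads(generate_reads(sim$alien, cfg))$reads
  flt <- lapply(c(A = "5AS", B = "5BS", D = "5DS"), function(g) {
    mp <- map_reads(clean, sim$refs[g])
    filter_variants(call_raw_variants(
      build_pileup(mp$alignments, clean, sim$refs[g])))
  })
  from_a <- find_alien_specific(flt$A, flt$B, flt$D, sim$refs["5AS"],
                                sim$refs["5BS"], sim$refs["5DS"])
  from_b <- find_alien_specific(flt$B, flt$A, flt$D, sim$refs["5BS"],
                                sim$refs["5AS"], sim$refs["5DS"])
  key <- function(s) paste(s$wheat_a, s$alien_allele, s$left_flank,
                           s$right_flank)
  planted <- sim$truth[sim$truth$class == "alien_specific", ]
  ka <- key(from_a[from_a$anchor_pos %in% planted$position, ])
  kb <- key(from_b[from_b$anchor_pos %in% planted$position, ])
  expect_equal(length(ka), nrow(planted))
  expect_setequal(ka, kb)
})
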