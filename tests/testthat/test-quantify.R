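# Sample-level quantification: the seeded fast path must agree with the
# exhaustive per-read matcher, and counts must be strand-invariant.

small_sample <- function(seed = 11L, n = 1500L, tf = 0.3) {
  simulate_sample(fixture_gene(), fixture_background(),
                  stage_profile("t", target_fraction = tf, skip_fraction = 0.4),
                  simulation_config(library_size = n), sample_seed = seed)
}

test_that("the candidate-seeded path equals the exhaustive matcher", {
  g <- fixture_gene()
  baits <- fixture_baits()[c("E1-11", "J13-14", "J13-15A", "J14-15B")]
  reads <- small_sample()
  filt <- filter_params(); params <- scoring_params()
  fast <- quantify_sample(baits, reads, filt, params)
  n_db <- sum(Biostrings::width(reads))
  for (b in baits) {
    hits <- exact_match_hits(b, reads, seed_len = 12L, params = params,
                             db_size = n_db)
    fh <- filter_hits(hits, filt)
    slow <- if (is.na(b$junction_offset)) {
      length(unique(fh$read_id))
    } else {
      count_junction_reads(fh, b, filt)
    }
    expect_identical(fast$read_count[fast$bait_id == b$bait_id],
                     as.integer(slow), info = b$bait_id)
  }
})

test_that("window soundness: surviving hits lie inside the length window", {
  g <- fixture_gene()
  b <- fixture_baits()[["J13-14"]]
  reads <- small_sample(seed = 12L)
  n_db <- sum(Biostrings::width(reads))
  hits <- exact_match_hits(b, reads, seed_len = 12L, db_size = n_db)
  fh <- filter_hits(hits, filter_params())
  w <- evalue_length_window(scoring_params(), filter_params(),
                            m = nchar(b$sequence), n = n_db)
  if (nrow(fh)) {
    expect_true(all(fh$match_len >= w$L_min & fh$match_len <= w$L_max))
  }
  # and some in-window hits exist at this depth
  expect_gt(nrow(fh), 0L)
})

test_that("reverse-complementing every read leaves all counts unchanged", {
  baits <- fixture_baits()
  reads <- small_sample(seed = 13L, n = 2000L)
  q1 <- quantify_sample(baits, reads)
  flipped <- Biostrings::reverseComplement(reads)
  names(flipped) <- names(reads)
  q2 <- quantify_sample(baits, flipped)
  expect_identical(q1$read_count, q2$read_count)
  expect_identical(q1$rpkm, q2$rpkm)
})

test_that("quantify_samples accepts in-memory samples and sample sheets", {
  baits <- fixture_baits()[c("J13-14", "J10-11")]
  reads <- small_sample(seed = 14L, n = 800L)
  recs <- list(list(sample_id = "s1", stage = "E14", structure = "forebrain",
                    reads = reads))
  t1 <- quantify_samples(baits, recs)
  expect_identical(nrow(t1), 2L)
  expect_identical(t1$total_reads, rep(800L, 2))
  expect_equal(t1$rpkm,
               t1$read_count / ((t1$bait_len / 1000) * (t1$total_reads / 1e6)))
  # sheet-driven: write the reads, point the sheet at them
  fa <- tempfile(fileext = ".fasta")
  write_reads(reads, fa)
  sheet <- data.frame(sample_id = "s1", stage = "E14", structure = "forebrain",
                      reads_path = fa, stringsAsFactors = FALSE)
  t2 <- quantify_samples(baits, sheet)
  expect_identical(t2$read_count, t1$read_count)
})
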