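test_that("fixture gene generation is deterministic in the seed", {
  g1 <- make_gene(11L)
  g2 <- make_gene(11L)
  g3 <- make_gene(12L)
  s1 <- vapply(g1$exons, `[[`, character(1), "sequence")
  expect_identical(s1, vapply(g2$exons, `[[`, character(1), "sequence"))
  expect_false(identical(s1, vapply(g3$exons, `[[`, character(1), "sequence")))
})

test_that("every bait occurs exactly once in the sequence universe (substring scan)", {
  g <- fixture_gene()
  bg <- fixture_background()
  baits <- fixture_baits()
  specs <- enumerate_transcripts(g)
  txs <- vapply(specs, function(sp) splice_transcript(g, sp)$sequence,
                character(1))
  universe <- c(txs, as.character(bg))
  count_occ <- function(pat, subj) {
    m <- gregexpr(pat, subj, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) 0L else length(m)
  }
  for (b in baits) {
    occ <- vapply(universe, count_occ, integer(1), pat = b$sequence)
    expected <- c(vapply(specs, function(sp) {
      if (is.na(b$junction_offset)) 1L
      else as.integer(baitquant:::junction_in_segments(
        splice_transcript(g, sp)$segments, b$donor, b$acceptor, b$site))
    }, integer(1)), integer(length(bg)))
    expect_identical(unname(occ), expected, info = b$bait_id)
  }
})

test_that("read simulation is bit-identical under a fixed seed", {
  g <- fixture_gene(); bg <- fixture_background()
  prof <- stage_profile("E14", target_fraction = 0.05)
  cfg <- simulation_config(library_size = 2000L)
  r1 <- simulate_sample(g, bg, prof, cfg, sample_seed = 7L)
  r2 <- simulate_sample(g, bg, prof, cfg, sample_seed = 7L)
  expect_identical(as.character(r1), as.character(r2))
  r3 <- simulate_sample(g, bg, prof, cfg, sample_seed = 8L)
  expect_false(identical(as.character(r1), as.character(r3)))
})

test_that("impossible junctions never appear in simulated reads", {
  g <- fixture_gene(); bg <- fixture_background()
  baits <- fixture_baits()
  cfg <- simulation_config(library_size = 3000L)
  has_bait <- function(reads, bait) {
    rc <- as.character(reads)
    any(grepl(bait$sequence, rc, fixed = TRUE)) ||
      any(grepl(revcomp(bait$sequence), rc, fixed = TRUE))
  }
  # skip_fraction 0: no 13-15 junction can exist
  never_skip <- stage_profile("x", target_fraction = 0.9, skip_fraction = 0)
  r <- simulate_sample(g, bg, never_skip, cfg, sample_seed = 1L)
  for (s in c("A", "B", "C")) {
    expect_false(has_bait(r, baits[[paste0("J13-15", s)]]))
  }
  expect_true(has_bait(r, baits[["J13-14"]]))
  # skip_fraction 1: no 13-14 junction can exist
  always_skip <- stage_profile("y", target_fraction = 0.9, skip_fraction = 1)
  r2 <- simulate_sample(g, bg, always_skip, cfg, sample_seed = 1L)
  expect_false(has_bait(r2, baits[["J13-14"]]))
  expect_true(has_bait(r2, baits[["J13-15A"]]))
})

test_that("expected junction-read counts follow the position-counting closed form", {
  prof <- stage_profile("z", target_fraction = 1e-3)
  cfg <- simulation_config(read_length = 101L, library_size = 1000L)
  # 101 - 2*10 + 1 = 82 valid start positions per transcript copy
  e <- expected_junction_reads(prof, cfg, "10-11", transcript_len = 1101L,
                               a_min = 10L)
  n_t <- 1000 * 1e-3 * 1
  expect_equal(e, n_t * 82 / 1001)
  # centered-junction boundary: a_min = read_length/2 leaves 0-2 positions
  expect_equal(expected_junction_reads(prof, cfg, "10-11", 1101L, a_min = 50L),
               n_t * 2 / 1001)
  cfg100 <- simulation_config(read_length = 100L, library_size = 1000L)
  expect_equal(expected_junction_reads(prof, cfg100, "10-11", 1101L, a_min = 50L),
               n_t * 1 / 1002)
  # error rate deflates by (1 - e)^R
  cfg_err <- simulation_config(read_length = 101L, library_size = 1000L,
                               error_rate = 0.01)
  expect_equal(expected_junction_reads(prof, cfg_err, "10-11", 1101L),
               n_t * 82 / 1001 * 0.99^101)
  expect_error(expected_junction_reads(prof, cfg, "10-11", 50L), "transcript_len")
})

test_that("default study profiles encode the 13-stage forebrain design", {
  profs <- default_study_profiles()
  expect_length(profs, 13L)
  expect_identical(names(profs)[1], "E14")
  expect_identical(names(profs)[13], "P112")
  expect_equal(profs[["E14"]]$site15_usage[["A"]], 0.40)
  tf <- vapply(profs, `[[`, numeric(1), "target_fraction")
  # monotone decline except the P3 elevation
  expect_true(all(diff(tf[setdiff(names(profs), "P3")]) < 0))
  expect_gt(tf[["P3"]], tf[["P0"]])
  sk <- vapply(profs, `[[`, numeric(1), "skip_fraction")
  expect_true(all(sk[c("E17", "E18", "E19", "E20")] == 0.45))
  expect_true(all(sk[setdiff(names(profs), c("E17", "E18", "E19", "E20"))] == 0.10))
  for (p in profs) {
    expect_equal(sum(p$site15_usage), 1, tolerance = 1e-12)
    expect_equal(sum(p$site17_usage), 1, tolerance = 1e-12)
  }
})

test_that("reads can be written as FASTA and FASTQ and read back", {
  g <- fixture_gene(); bg <- fixture_background()
  r <- simulate_sample(g, bg, stage_profile("w", 0.02),
                       simulation_config(library_size = 50L), sample_seed = 3L)
  fa <- tempfile(fileext = ".fasta"); fq <- tempfile(fileext = ".fastq")
  write_reads(r, fa, "fasta")
  write_reads(r, fq, "fastq")
  expect_identical(as.character(Biostrings::readDNAStringSet(fa)),
                   as.character(r))
  expect_identical(as.character(Biostrings::readDNAStringSet(fq, format = "fastq")),
                   as.character(r))
})
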