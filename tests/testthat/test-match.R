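test_that("containment and strand symmetry of the exact matcher", {
  set.seed(5)
  bait <- random_dna(100)
  read <- paste0(random_dna(1), bait)  # bait padded by 1 nt
  h <- exact_match_hits(bait, c(r1 = read))
  plus <- h[h$strand == "+", ]
  expect_identical(plus$match_len, 100L)
  expect_identical(plus$bait_start, 0L)
  expect_identical(plus$read_start, 1L)
  # the same read on the opposite strand gives the same match length
  h2 <- exact_match_hits(bait, c(r1 = revcomp(read)))
  minus <- h2[h2$strand == "-", ]
  expect_identical(minus$match_len, 100L)
})

test_that("maximal match lengths equal the dynamic-programming oracle", {
  set.seed(42)
  for (i in 1:80) {
    bait <- random_dna(100)
    if (i %% 4 == 0) {
      # implant a shared substring of random length to cover long matches
      core <- random_dna(sample(10:80, 1))
      read <- paste0(random_dna(sample(0:20, 1)), core, random_dna(5))
      bait <- paste0(substr(bait, 1, 100 - nchar(core)), core)
    } else {
      read <- random_dna(101)
    }
    read <- substr(read, 1, 101)
    exp_len <- lcs_oracle(bait, read)
    h <- exact_match_hits(bait, c(r = read), seed_len = 3L,
                          both_strands = FALSE)
    if (nrow(h) == 0L) {
      expect_lt(exp_len, 3L)
    } else {
      expect_identical(h$match_len, as.integer(exp_len))
    }
  }
})

test_that("N bases never match and an ambiguous bait is rejected", {
  expect_error(exact_match_hits("ACGTN", c(r = "ACGTACGT")), "A,C,G,T")
  bait <- strrep("ACGT", 10)
  read <- paste0(substr(bait, 1, 12), "N", substr(bait, 14, 40))
  h <- exact_match_hits(bait, c(r = read), seed_len = 4L, both_strands = FALSE)
  expect_identical(h$match_len, 27L)  # the run right of the N
})

test_that("Karlin-Altschul E-values match direct evaluation and monotonicity", {
  p <- scoring_params()  # lambda 1.28, K 0.46, reward 1
  e100 <- karlin_altschul_evalue(100, m = 100, n = 1e9, params = p)
  expect_equal(e100, 0.46 * 100 * 1e9 * exp(-1.28 * 100))
  expect_equal(e100, 1.18e-45, tolerance = 0.01)
  e40 <- karlin_altschul_evalue(40, m = 100, n = 1e9, params = p)
  expect_equal(e40, 2.7e-12, tolerance = 0.02)
  # strictly decreasing in L, strictly increasing in n
  ls <- karlin_altschul_evalue(1:100, 100, 1e9, p)
  expect_true(all(diff(ls) < 0))
  expect_lt(karlin_altschul_evalue(60, 100, 1e9, p),
            karlin_altschul_evalue(60, 100, 1e10, p))
})

test_that("the E-window inverts to the documented match-length window", {
  p <- scoring_params(); f <- filter_params()
  w <- evalue_length_window(p, f, m = 100, n = 1e9)
  expect_identical(w$L_min, 60L)
  expect_identical(w$L_max, 100L)
  expect_false(w$empty)
  # forward-scan oracle over all lengths
  ev <- karlin_altschul_evalue(1:100, 100, 1e9, p)
  inside <- which(ev >= f$evalue_low & ev <= f$evalue_high)
  expect_identical(w$L_min, min(inside))
  expect_identical(w$L_max, max(inside))
  # a 10x larger database shifts L_min up by ln(10)/lambda (1-2 integer steps)
  w10 <- evalue_length_window(p, f, m = 100, n = 1e10)
  expect_true((w10$L_min - w$L_min) %in% c(1L, 2L))
  # degenerate bounds leave at most one qualifying length
  fd <- filter_params(evalue_low = 1e-40, evalue_high = 1.0000001e-40)
  wd <- evalue_length_window(p, fd, m = 100, n = 1e9)
  if (!wd$empty) expect_lte(wd$L_max - wd$L_min, 0L)
  # an unreachable window is reported empty, not an error
  fe <- filter_params(evalue_low = 1e-300, evalue_high = 2e-300)
  expect_true(evalue_length_window(p, fe, m = 100, n = 1e9)$empty)
})

test_that("hit filtering applies the window and the 20,000-hit retrieval cap", {
  mk_hits <- function(n, evalue) {
    data.frame(read_id = sprintf("r%05d", seq_len(n)),
               bait_id = rep("b", n), match_len = rep(70L, n),
               bait_start = rep(0L, n), read_start = rep(0L, n),
               strand = rep("+", n), evalue = evalue, stringsAsFactors = FALSE)
  }
  f <- filter_params()
  empty <- filter_hits(mk_hits(0, numeric(0)), f)
  expect_identical(nrow(empty), 0L)
  expect_false(attr(empty, "truncated"))
  # out-of-window E-value removed
  out <- filter_hits(mk_hits(3, c(1e-10, 1e-30, 1e-70)), f)
  expect_identical(out$read_id, "r00002")
  # 25,000 qualifying hits: exactly 20,000 kept, smallest E first, flagged
  big <- mk_hits(25000, seq(4e-60, 4e-23, length.out = 25000))
  kept <- filter_hits(big, f)
  expect_identical(nrow(kept), 20000L)
  expect_true(attr(kept, "truncated"))
  expect_identical(kept$read_id, big$read_id[1:20000])
})

test_that("junction counting requires anchors on both sides and dedups reads", {
  g <- fixture_gene()
  b <- build_junction_bait(g, 13L, 14L)
  f <- filter_params()  # a_min = 10
  mk <- function(read_id, bait_start, match_len, strand = "+") {
    data.frame(read_id = read_id, bait_id = b$bait_id, match_len = match_len,
               bait_start = bait_start, read_start = 0L, strand = strand,
               evalue = 1e-40, stringsAsFactors = FALSE)
  }
  # match spanning bait offsets 40..99 (10 nt left, 50 right): counted
  expect_identical(count_junction_reads(mk("r1", 40L, 60L), b, f), 1L)
  # match entirely within the donor side: not counted
  expect_identical(count_junction_reads(mk("r2", 0L, 45L), b, f), 0L)
  # 9-nt anchor on the left: not counted
  expect_identical(count_junction_reads(mk("r3", 41L, 60L), b, f), 0L)
  # the same read hitting on both strands counts once
  two <- rbind(mk("r4", 30L, 70L, "+"), mk("r4", 30L, 70L, "-"))
  expect_identical(count_junction_reads(two, b, f), 1L)
})
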