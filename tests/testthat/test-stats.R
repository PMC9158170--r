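test_that("Kruskal-Wallis matches hand-computed and degenerate cases", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 3.857, tolerance = 1e-3)  # R1 = 6, R2 = 15, N = 6
  expect_identical(kw$df, 1L)
  same <- kruskal_wallis(list(c(2, 2, 2), c(2, 2, 2)))
  expect_identical(same$H, 0)
  expect_identical(same$p, 1)
  k13 <- kruskal_wallis(split(rnorm(52), rep(1:13, each = 4)))
  expect_identical(k13$df, 12L)
})

test_that("Kruskal-Wallis equals the explicit-rank brute-force oracle", {
  set.seed(21)
  for (i in 1:200) {
    k <- sample(2:6, 1)
    groups <- lapply(seq_len(k), function(j) {
      # integer values force ties; mixed sizes 2-6 mirror the study's n
      sample(1:8, sample(2:6, 1), replace = TRUE)
    })
    if (length(unique(unlist(groups))) == 1L) next  # degenerate, tested above
    kw <- kruskal_wallis(groups)
    expect_lt(abs(kw$H - kw_oracle(groups)), 1e-9)
    expect_equal(kw$p, stats::pchisq(kw$H, kw$df, lower.tail = FALSE))
  }
})

test_that("the permutation p-value option agrees with chi-square for clear cases", {
  groups <- list(c(1, 2, 3, 4), c(10, 11, 12, 13), c(20, 21, 22, 23))
  cfg <- stat_config(p_method = "permutation", n_perm = 999L)
  kw <- kruskal_wallis(groups, cfg, perm_seed = 5L)
  expect_lt(kw$p, 0.01)
  flat <- kruskal_wallis(list(c(1, 9, 4, 6), c(2, 8, 5, 3)), cfg, perm_seed = 5L)
  expect_gt(flat$p, 0.05)
})

test_that("Dunn's z statistics are antisymmetric and rank-ordered", {
  groups <- list(lo = c(1, 2, 3), mid = c(4, 5, 6), hi = c(7, 8, 9))
  d <- dunn_posthoc(groups)
  expect_identical(nrow(d), 3L)
  lohi <- d[d$group_i == "lo" & d$group_j == "hi", ]
  expect_identical(max(abs(d$z)), abs(lohi$z))
  # order swap flips the sign, p unchanged
  d2 <- dunn_posthoc(rev(groups))
  swapped <- d2[d2$group_i == "hi" & d2$group_j == "lo", ]
  expect_equal(swapped$z, -lohi$z)
  expect_equal(swapped$p_raw, lohi$p_raw)
  # identical groups: all z = 0, nothing significant
  same <- dunn_posthoc(list(a = c(1, 2), b = c(1, 2), c = c(2, 1)))
  expect_true(all(same$z == 0))
  expect_false(any(same$significant))
  expect_error(dunn_posthoc(list(a = numeric(), b = 1:3)), "empty group")
})

test_that("Dunn adjustment options control the significance flags", {
  set.seed(2)
  groups <- split(c(rnorm(20), rnorm(20, 1.2)), rep(1:10, each = 4))
  raw <- dunn_posthoc(groups, stat_config(posthoc_adjustment = "none"))
  bon <- dunn_posthoc(groups, stat_config(posthoc_adjustment = "bonferroni"))
  expect_equal(bon$p_adj, pmin(1, raw$p_raw * nrow(raw)))
  expect_true(all(bon$p_adj >= raw$p_adj))
})

test_that("stage comparison gates Dunn on the Kruskal-Wallis p-value", {
  mk_table <- function(values) {
    stages <- rep(c("s1", "s2", "s3"), each = 4)
    data.frame(sample_id = paste0(stages, "_", 1:4), stage = stages,
               structure = "forebrain", bait_id = "J13-14",
               read_count = 1L, bait_len = 100L, total_reads = 1000L,
               rpkm = values, stringsAsFactors = FALSE)
  }
  sep <- compare_stages(mk_table(c(1:4, 11:14, 21:24)), "J13-14")
  expect_lt(sep$kw$p, 0.05)
  expect_s3_class(sep$dunn, "dunn_result")
  set.seed(4)
  flat <- compare_stages(mk_table(rep(c(3, 4, 5, 6), 3)), "J13-14")
  expect_gte(flat$kw$p, 0.05)
  expect_null(flat$dunn)
  expect_error(compare_stages(mk_table(1:12)[1:4, ], "J13-14"), "2 stages")
  two_struct <- mk_table(1:12); two_struct$structure[1] <- "cerebellum"
  expect_error(compare_stages(two_struct, "J13-14"), "single structure")
})

test_that("outlier detection flags multi-bait elevation and is order-invariant", {
  # deterministic table: per bait, samples s1..s4 sit at 100..103 RPKM
  # (median 101.5, MAD about 2.2, threshold about 112.6 at c = 5)
  mk_table <- function() {
    grid <- expand.grid(sample_id = paste0("s", 1:4),
                        bait_id = paste0("b", 1:5),
                        stringsAsFactors = FALSE)
    grid$stage <- "E14"; grid$structure <- "forebrain"
    grid$rpkm <- 100 + (match(grid$sample_id, paste0("s", 1:4)) - 1)
    grid
  }
  cfg <- stat_config(outlier_c = 5, outlier_min_baits = 3L)
  clean <- mk_table()
  expect_length(detect_outliers(clean, cfg)$excluded, 0L)
  # one sample at 10x the group level on every bait: flagged
  hot <- mk_table()
  hot$rpkm[hot$sample_id == "s2"] <- hot$rpkm[hot$sample_id == "s2"] * 10
  expect_identical(detect_outliers(hot, cfg)$excluded, "s2")
  # elevated on exactly outlier_min_baits - 1 baits: not flagged
  warm <- mk_table()
  idx <- which(warm$sample_id == "s3" & warm$bait_id %in% c("b1", "b2"))
  warm$rpkm[idx] <- warm$rpkm[idx] * 10
  res <- detect_outliers(warm, cfg)
  expect_length(res$excluded, 0L)
  expect_identical(res$report$n_elevated_baits[res$report$sample_id == "s3"], 2L)
  # permutation invariance in row order
  set.seed(9)
  shuf <- hot[sample(nrow(hot)), ]
  expect_identical(detect_outliers(shuf, cfg)$excluded, "s2")
  # undersized groups are skipped with a warning
  expect_warning(detect_outliers(hot[hot$sample_id %in% c("s1", "s2"), ], cfg),
                 "fewer than 3")
})
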