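# Stage statistics: robust outlier exclusion, tie-corrected Kruskal-Wallis,
# Dunn's post-hoc pairwise comparisons, and per-bait stage-comparison reports.

#' Statistical configuration for stage comparisons
#'
#' @param alpha significance level for the Kruskal-Wallis gate and Dunn pairs
#'   (default 0.05).
#' @param posthoc_adjustment p-value adjustment for Dunn pairs: `"none"`
#'   (classical Dunn at alpha per pair, the default), `"bonferroni"` or
#'   `"holm"`.
#' @param outlier_c robust-deviation multiplier: a sample's RPKM is elevated
#'   on a bait when it exceeds the group median plus `outlier_c` times the MAD
#'   (default 5).
#' @param outlier_min_baits minimum number of baits on which a sample must be
#'   elevated to be flagged as an outlier (default 3).
#' @param p_method `"chisq"` for the chi-square approximation (default) or
#'   `"permutation"` for a seeded Monte-Carlo permutation p-value (small
#'   groups).
#' @param n_perm permutation count when `p_method = "permutation"`.
#' @return object of class `stat_config`.
#' @export
stat_config <- function(alpha = 0.05,
                        posthoc_adjustment = c("none", "bonferroni", "holm"),
                        outlier_c = 5, outlier_min_baits = 3L,
                        p_method = c("chisq", "permutation"),
                        n_perm = 2000L) {
  stopifnot(alpha > 0, alpha < 1, outlier_c > 0, outlier_min_baits >= 1L)
  structure(
    list(alpha = alpha, posthoc_adjustment = match.arg(posthoc_adjustment),
         outlier_c = outlier_c, outlier_min_baits = as.integer(outlier_min_baits),
         p_method = match.arg(p_method), n_perm = as.integer(n_perm)),
    class = "stat_config"
  )
}

#' Flag outlier samples from an RPKM table
#'
#' A sample is flagged when its RPKM exceeds its (structure, stage) group
#' median plus `outlier_c` * MAD for at least `outlier_min_baits` distinct
#' baits — a reproducible operationalization of removing samples that retrieve
#' anomalously many reads across several target sequences. Groups with fewer
#' than 3 samples are skipped with a warning. Deterministic and invariant to
#' sample order.
#'
#' @param table RPKM table from [quantify_samples()].
#' @param cfg a [stat_config()].
#' @return list with `excluded` (character sample ids) and `report`
#'   (data.frame sample_id, n_elevated_baits, flagged).
#' @export
detect_outliers <- function(table, cfg = stat_config()) {
  table$group <- paste(table$structure, table$stage, sep = "|")
  elevated <- integer()
  for (g in sort(unique(table$group))) {
    sub <- table[table$group == g, , drop = FALSE]
    if (length(unique(sub$sample_id)) < 3L) {
      warning("group ", g, " has fewer than 3 samples; outlier check skipped")
      next
    }
    for (b in unique(sub$bait_id)) {
      v <- sub[sub$bait_id == b, , drop = FALSE]
      med <- stats::median(v$rpkm)
      dev <- stats::mad(v$rpkm)
      thr <- if (dev > 0) med + cfg$outlier_c * dev else med
      up <- v$sample_id[v$rpkm > thr]
      for (s in up) elevated[s] <- (if (s %in% names(elevated)) elevated[[s]] else 0L) + 1L
    }
  }
  ids <- sort(unique(table$sample_id))
  n_elev <- vapply(ids, function(s) {
    if (s %in% names(elevated)) elevated[[s]] else 0L
  }, integer(1))
  flagged <- n_elev >= cfg$outlier_min_baits
  list(excluded = ids[flagged],
       report = data.frame(sample_id = ids, n_elevated_baits = unname(n_elev),
                           flagged = unname(flagged), stringsAsFactors = FALSE,
                           row.names = NULL))
}

#' Tie-corrected Kruskal-Wallis test over k groups
#'
#' Midranks for ties; `H = [12/(N(N+1)) * sum R_i^2/n_i - 3(N+1)] / C` where
#' `C = 1 - sum(t^3 - t)/(N^3 - N)` is the tie correction; p from chi-square
#' with `k - 1` degrees of freedom (computed via [stats::kruskal.test()]),
#' or from a seeded Monte-Carlo permutation null when requested.
#'
#' @param groups list of numeric vectors, one per group (>= 2 non-empty
#'   groups).
#' @param cfg a [stat_config()] (controls the p-value method).
#' @param perm_seed seed for the permutation null.
#' @return object of class `kw_result`: list with `H`, `df`, `p`,
#'   `tie_correction`.
#' @export
kruskal_wallis <- function(groups, cfg = stat_config(), perm_seed = 1L) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) > 0L))
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  n <- length(x)
  ties <- table(x)
  tie_correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_correction == 0) {
    # every observation identical: no evidence against the null
    res <- structure(list(H = 0, df = length(groups) - 1L, p = 1,
                          tie_correction = 0), class = "kw_result")
    return(res)
  }
  kt <- stats::kruskal.test(x, g)
  h <- unname(kt$statistic)
  p <- unname(kt$p.value)
  if (cfg$p_method == "permutation") {
    # permuting the data permutes the midranks, so the null H can be computed
    # directly from rank sums (the tie pattern, hence C, is invariant)
    r <- rank(x)
    ni <- lengths(groups)
    with_seed(perm_seed, {
      null_h <- vapply(seq_len(cfg$n_perm), function(i) {
        rs <- rowsum(r[sample.int(n)], g)
        (12 / (n * (n + 1)) * sum(rs^2 / ni) - 3 * (n + 1)) / tie_correction
      }, numeric(1))
    })
    p <- (1 + sum(null_h >= h - 1e-12)) / (cfg$n_perm + 1)
  }
  structure(list(H = h, df = unname(kt$parameter), p = p,
                 tie_correction = tie_correction),
            class = "kw_result")
}

#' @export
print.kw_result <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H (chi-square) = %.4g, df = %d, P = %.4g\n",
              x$H, x$df, x$p))
  invisible(x)
}

#' Dunn's post-hoc pairwise comparisons on ranks
#'
#' For each group pair (i, j), `z = (Rbar_i - Rbar_j) / sqrt((N(N+1)/12 -
#' T) * (1/n_i + 1/n_j))` where `T = sum(t^3 - t) / (12 (N - 1))` is the tie
#' term on the pooled midranks; two-sided p from the standard normal, with the
#' configured adjustment across all k(k-1)/2 pairs.
#'
#' @param groups list of named numeric vectors (names become group labels;
#'   unnamed lists get `group1`, `group2`, ...).
#' @param cfg a [stat_config()].
#' @return data.frame of class `dunn_result`: `group_i`, `group_j`,
#'   `mean_rank_diff`, `z`, `p_raw`, `p_adj`, `significant`.
#' @export
dunn_posthoc <- function(groups, cfg = stat_config()) {
  k <- length(groups)
  stopifnot(k >= 2L)
  if (any(lengths(groups) == 0L)) stop("empty group in Dunn test", call. = FALSE)
  labs <- names(groups) %||% paste0("group", seq_len(k))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_len(k), lengths(groups))
  n <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  ni <- lengths(groups)
  ties <- table(x)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(k, 2L)
  diff <- rbar[pairs[1L, ]] - rbar[pairs[2L, ]]
  v <- (n * (n + 1) / 12 - tie_term) *
    (1 / ni[pairs[1L, ]] + 1 / ni[pairs[2L, ]])
  z <- ifelse(v > 0, diff / sqrt(v), 0)
  p_raw <- 2 * stats::pnorm(-abs(z))
  p_adj <- stats::p.adjust(p_raw, method = cfg$posthoc_adjustment)
  out <- data.frame(
    group_i = labs[pairs[1L, ]], group_j = labs[pairs[2L, ]],
    mean_rank_diff = unname(diff), z = unname(z), p_raw = unname(p_raw),
    p_adj = unname(p_adj), significant = unname(p_adj < cfg$alpha),
    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("dunn_result", class(out))
  out
}

#' Kruskal-Wallis plus gated Dunn post-hoc for one bait across stages
#'
#' Runs the Kruskal-Wallis test over the stage groups of `bait_id`'s RPKM
#' values (one structure at a time; outliers are assumed already excluded) and
#' runs Dunn's post-hoc only when the Kruskal-Wallis null is rejected at
#' `cfg$alpha` — mirroring the gatekeeping procedure of the original analysis.
#'
#' @param table RPKM table restricted to one structure.
#' @param bait_id bait to test.
#' @param cfg a [stat_config()].
#' @return list with `bait_id`, `kw` (a `kw_result`) and `dunn` (a
#'   `dunn_result`, or `NULL` when the gate stays closed).
#' @export
compare_stages <- function(table, bait_id, cfg = stat_config()) {
  if (length(unique(table$structure)) > 1L) {
    stop("table must be restricted to a single structure", call. = FALSE)
  }
  sub <- table[table$bait_id == bait_id, , drop = FALSE]
  stages <- unique(sub$stage)
  if (length(stages) < 2L) stop("fewer than 2 stages present", call. = FALSE)
  groups <- stats::setNames(
    lapply(stages, function(s) sub$rpkm[sub$stage == s]), stages)
  kw <- kruskal_wallis(groups, cfg)
  dunn <- if (kw$p < cfg$alpha) dunn_posthoc(groups, cfg) else NULL
  list(bait_id = bait_id, kw = kw, dunn = dunn)
}
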