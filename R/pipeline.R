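# End-to-end orchestration: simulate -> quantify -> stats from one config,
# with seed control, deterministic outputs and a summary object.

#' Assemble a full run configuration
#'
#' @param seed global integer seed; per-sample seeds are derived by stable
#'   hashing of the sample id (see [derive_seed()]), so adding a sample never
#'   perturbs the reads of the others.
#' @param profiles list of [stage_profile()] (default
#'   [default_study_profiles()]).
#' @param sim a [simulation_config()].
#' @param filt a [filter_params()].
#' @param scoring a [scoring_params()].
#' @param stats a [stat_config()].
#' @param bait_len junction bait length.
#' @param out_dir optional output directory; when given, [run_pipeline()]
#'   writes the RPKM table, stats tables, outlier report, reads (optional) and
#'   a JSON metadata sidecar there.
#' @param write_reads also write per-sample FASTA read files under `out_dir`.
#' @return object of class `run_config`.
#' @export
run_config <- function(seed = 1L, profiles = default_study_profiles(),
                       sim = simulation_config(seed = seed),
                       filt = filter_params(), scoring = scoring_params(),
                       stats = stat_config(), bait_len = 100L,
                       out_dir = NULL, write_reads = FALSE) {
  structure(
    list(seed = as.integer(seed), profiles = profiles, sim = sim, filt = filt,
         scoring = scoring, stats = stats, bait_len = as.integer(bait_len),
         out_dir = out_dir, write_reads = isTRUE(write_reads)),
    class = "run_config"
  )
}

#' Read a run configuration from YAML or JSON
#'
#' Recognized top-level keys: `seed`, `bait_len`, `out_dir`, `write_reads`,
#' `sim` (fields of [simulation_config()]), `filter` ([filter_params()]),
#' `scoring` ([scoring_params()]), `stats` ([stat_config()]), and `profiles`
#' (list of [stage_profile()] fields). Missing keys take the package defaults.
#'
#' @param path YAML (`.yml`/`.yaml`) or JSON config file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  obj <- if (grepl("\\.ya?ml$", path)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  seed <- obj$seed %||% 1L
  sim <- do.call(simulation_config, c(obj$sim %||% list(),
                                      if (is.null(obj$sim$seed)) list(seed = seed)))
  profiles <- if (is.null(obj$profiles)) {
    default_study_profiles()
  } else {
    profs <- lapply(obj$profiles, function(p) do.call(stage_profile, p))
    stats::setNames(profs, vapply(profs, `[[`, character(1), "stage_label"))
  }
  run_config(
    seed = seed, profiles = profiles, sim = sim,
    filt = do.call(filter_params, obj$filter %||% list()),
    scoring = do.call(scoring_params, obj$scoring %||% list()),
    stats = do.call(stat_config, obj$stats %||% list()),
    bait_len = obj$bait_len %||% 100L,
    out_dir = obj$out_dir, write_reads = isTRUE(obj$write_reads))
}

sibling_ids <- function(baits, donor, acceptor) {
  ids <- names(baits)
  ids[grepl(sprintf("^J%d-%d", donor, acceptor), ids)]
}

#' Run the full simulate - quantify - test pipeline
#'
#' Builds the seeded fixture gene and background transcriptome, simulates
#' every sample of the study design (one per stage and replicate), quantifies
#' the default bait set, excludes outlier samples, runs the gated
#' Kruskal-Wallis/Dunn stage comparisons per bait, and assembles usage
#' fractions and junction-ratio series. Identical config and seed give
#' byte-identical output tables.
#'
#' @param config a [run_config()].
#' @return object of class `bait_run`: list with `gene`, `baits`, `sheet`,
#'   `rpkm` (the RPKM table), `outliers`, `stats` (per-bait Kruskal-Wallis +
#'   Dunn), `stage_means`, `usage` (per-stage 14-15 site-usage fractions),
#'   `ratios` (per-sample 13-15X / 10-11 RPKM ratios), `skip_estimates`
#'   (per-stage exon-14 skip fraction estimated as 13-15*/(13-14 + 13-15*)),
#'   `config`, `config_hash`, and `excluded`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config[setdiff(names(config), "out_dir")])
  background <- make_background(config$seed + 1L, config$sim$background_n,
                                config$sim$background_len)
  gene <- make_gene(config$seed, background = background,
                    bait_len = config$bait_len)
  baits <- default_bait_set(gene, bait_len = config$bait_len)

  sheet <- do.call(rbind, lapply(config$profiles, function(p) {
    data.frame(
      sample_id = sprintf("%s_%s_rep%d", substr(p$structure, 1, 2), p$stage_label,
                          seq_len(config$sim$replicates)),
      stage = p$stage_label, structure = p$structure,
      replicate = seq_len(config$sim$replicates), stringsAsFactors = FALSE)
  }))
  rownames(sheet) <- NULL

  out_dir <- config$out_dir
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  # simulate and quantify one sample at a time (reads are transient)
  per_sample <- vector("list", nrow(sheet))
  trunc <- list()
  for (i in seq_len(nrow(sheet))) {
    p <- config$profiles[[sheet$stage[i]]]
    reads <- simulate_sample(gene, background, p, config$sim,
                             sample_seed = derive_seed(config$seed,
                                                       sheet$sample_id[i]),
                             read_prefix = paste0(sheet$sample_id[i], "_r"))
    if (!is.null(out_dir) && config$write_reads) {
      write_reads(reads, file.path(out_dir,
                                   paste0(sheet$sample_id[i], ".fasta")))
    }
    q <- quantify_sample(baits, reads, filt = config$filt,
                         params = config$scoring)
    tr <- attr(q, "truncated")
    if (any(tr)) trunc[[sheet$sample_id[i]]] <- names(tr)[tr]
    per_sample[[i]] <- cbind(
      data.frame(sample_id = sheet$sample_id[i], stage = sheet$stage[i],
                 structure = sheet$structure[i], stringsAsFactors = FALSE), q)
  }
  sheet$total_reads <- config$sim$library_size
  rpkm <- do.call(rbind, per_sample)
  rownames(rpkm) <- NULL

  outl <- detect_outliers(rpkm, config$stats)
  kept <- rpkm[!(rpkm$sample_id %in% outl$excluded), , drop = FALSE]

  stage_order <- vapply(config$profiles, `[[`, character(1), "stage_label")
  kept$stage <- factor(kept$stage, levels = stage_order)
  kept <- kept[order(kept$stage, kept$sample_id, kept$bait_id), , drop = FALSE]
  kept$stage <- as.character(kept$stage)
  rownames(kept) <- NULL

  stats_res <- lapply(names(baits), function(b) {
    compare_stages(kept, b, config$stats)
  })
  names(stats_res) <- names(baits)

  stage_means <- stats::aggregate(rpkm ~ stage + bait_id, data = kept, FUN = mean)
  stage_means <- stage_means[order(match(stage_means$stage, stage_order),
                                   stage_means$bait_id), , drop = FALSE]
  rownames(stage_means) <- NULL

  # per-stage 14-15 acceptor-site usage from summed junction counts
  sib1415 <- sibling_ids(baits, 14L, 15L)
  usage <- do.call(rbind, lapply(stage_order, function(st) {
    v <- vapply(sib1415, function(b) {
      sum(kept$read_count[kept$stage == st & kept$bait_id == b])
    }, numeric(1))
    u <- usage_fractions(v)
    data.frame(stage = st, site = sub("^J14-15", "", sib1415),
               fraction = as.numeric(u), stringsAsFactors = FALSE)
  }))
  rownames(usage) <- NULL

  # per-sample ratio series: each 13-15 site junction over the 10-11 junction
  sib1315 <- sibling_ids(baits, 13L, 15L)
  den <- kept[kept$bait_id == "J10-11", c("sample_id", "stage", "rpkm")]
  ratios <- do.call(rbind, lapply(sib1315, function(b) {
    num <- kept[kept$bait_id == b, c("sample_id", "rpkm")]
    mg <- merge(den, num, by = "sample_id", suffixes = c("_den", "_num"))
    data.frame(sample_id = mg$sample_id, stage = mg$stage, bait_id = b,
               ratio = as.numeric(junction_ratio(mg$rpkm_num, mg$rpkm_den)),
               stringsAsFactors = FALSE)
  }))
  rownames(ratios) <- NULL

  # per-stage exon-14 skip estimate: 13-15* / (13-14 + 13-15*) on counts
  skip_estimates <- do.call(rbind, lapply(stage_order, function(st) {
    skip_n <- sum(kept$read_count[kept$stage == st & kept$bait_id %in% sib1315])
    incl_n <- sum(kept$read_count[kept$stage == st & kept$bait_id == "J13-14"])
    data.frame(stage = st,
               skip_fraction_true = config$profiles[[st]]$skip_fraction,
               skip_fraction_est = if (skip_n + incl_n > 0) {
                 skip_n / (skip_n + incl_n)
               } else NA_real_,
               stringsAsFactors = FALSE)
  }))
  rownames(skip_estimates) <- NULL

  run <- structure(
    list(gene = gene, baits = baits, sheet = sheet, rpkm = kept,
         rpkm_all = rpkm, outliers = outl, stats = stats_res,
         stage_means = stage_means, usage = usage, ratios = ratios,
         skip_estimates = skip_estimates, config = config,
         config_hash = hash, excluded = outl$excluded,
         truncated = trunc),
    class = "bait_run"
  )
  if (!is.null(out_dir)) write_run_outputs(run, out_dir)
  run
}

write_tsv <- function(df, path, hash) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# config_hash=%s", hash), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Flatten the per-bait stats into the two exported tables.
stats_tables <- function(stats_res) {
  kw <- do.call(rbind, lapply(names(stats_res), function(b) {
    k <- stats_res[[b]]$kw
    data.frame(bait_id = b, H = k$H, df = k$df, p = k$p,
               tie_correction = k$tie_correction, stringsAsFactors = FALSE)
  }))
  dunn <- do.call(rbind, lapply(names(stats_res), function(b) {
    d <- stats_res[[b]]$dunn
    if (is.null(d)) return(NULL)
    cbind(data.frame(bait_id = b, stringsAsFactors = FALSE),
          as.data.frame(d))
  }))
  list(kw = kw, dunn = dunn)
}

write_run_outputs <- function(run, out_dir) {
  h <- run$config_hash
  write_tsv(run$rpkm, file.path(out_dir, "rpkm.tsv"), h)
  st <- stats_tables(run$stats)
  write_tsv(st$kw, file.path(out_dir, "stats_kw.tsv"), h)
  if (!is.null(st$dunn)) {
    write_tsv(st$dunn, file.path(out_dir, "stats_dunn.tsv"), h)
  }
  write_tsv(run$outliers$report, file.path(out_dir, "outliers.tsv"), h)
  write_tsv(run$sheet, file.path(out_dir, "samples.tsv"), h)
  meta <- list(
    config_hash = h, seed = run$config$seed,
    filter = unclass(run$config$filt), scoring = unclass(run$config$scoring),
    read_length = run$config$sim$read_length,
    library_size = run$config$sim$library_size,
    replicates = run$config$sim$replicates,
    truncated = run$truncated, excluded = run$excluded,
    package_version = as.character(utils::packageVersion("baitquant")))
  jsonlite::write_json(meta, file.path(out_dir, "run_metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.bait_run <- function(x, ...) {
  cat(sprintf("<bait_run> %d samples x %d baits | config %s\n",
              length(unique(x$rpkm_all$sample_id)), length(x$baits),
              x$config_hash))
  if (length(x$excluded)) {
    cat("  outliers excluded:", paste(x$excluded, collapse = ", "), "\n")
  }
  sig <- names(Filter(function(s) s$kw$p < x$config$stats$alpha, x$stats))
  cat("  stage-significant baits:",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' @export
summary.bait_run <- function(object, ...) {
  st <- stats_tables(object$stats)
  cat("Per-bait Kruskal-Wallis across stages:\n")
  print(st$kw, digits = 4)
  cat("\nPer-stage exon-14 skip-fraction estimates:\n")
  print(object$skip_estimates, digits = 3)
  cat("\n14-15 acceptor-site usage (pooled over stages):\n")
  pooled <- tapply(object$usage$fraction, object$usage$site, mean, na.rm = TRUE)
  print(round(pooled, 3))
  invisible(object)
}

#' Plot a pipeline run
#'
#' Box plots of per-stage RPKM for selected baits (one panel per bait).
#'
#' @param x a `bait_run`.
#' @param baits bait ids to plot (default: all).
#' @param ... passed to [graphics::boxplot()].
#' @export
plot.bait_run <- function(x, baits = names(x$baits), ...) {
  stage_order <- unique(vapply(x$config$profiles, `[[`, character(1),
                               "stage_label"))
  n <- length(baits)
  nc <- ceiling(sqrt(n))
  old <- graphics::par(mfrow = c(ceiling(n / nc), nc),
                       mar = c(4, 4, 2, 0.5))
  on.exit(graphics::par(old))
  for (b in baits) {
    sub <- x$rpkm[x$rpkm$bait_id == b, , drop = FALSE]
    graphics::boxplot(rpkm ~ factor(stage, levels = stage_order), data = sub,
                      main = b, xlab = "stage", ylab = "RPKM", las = 2, ...)
  }
  invisible(x)
}

#' Render a human-readable report for a pipeline run
#'
#' Writes static figures (per-bait RPKM box plots, the 13-15X / 10-11 ratio
#' series, stacked 14-15 site-usage bars) and a text digest of the
#' Kruskal-Wallis/Dunn results.
#'
#' @param run a `bait_run` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
render_summary <- function(run, dir) {
  stopifnot(inherits(run, "bait_run"))
  if (!nrow(run$rpkm)) stop("empty run summary", call. = FALSE)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  stage_order <- vapply(run$config$profiles, `[[`, character(1), "stage_label")

  grDevices::png(file.path(dir, "rpkm_boxplots.png"), width = 1600,
                 height = 1200, res = 120)
  plot(run)
  grDevices::dev.off()

  grDevices::png(file.path(dir, "junction_ratios.png"), width = 1000,
                 height = 700, res = 120)
  sib <- unique(run$ratios$bait_id)
  means <- sapply(sib, function(b) {
    sub <- run$ratios[run$ratios$bait_id == b, ]
    vapply(stage_order, function(st) {
      mean(sub$ratio[sub$stage == st], na.rm = TRUE)
    }, numeric(1))
  })
  graphics::matplot(seq_along(stage_order), means, type = "b", pch = 1:3,
                    lty = 1, xaxt = "n", xlab = "stage",
                    ylab = "RPKM ratio to J10-11")
  graphics::axis(1, at = seq_along(stage_order), labels = stage_order, las = 2)
  graphics::legend("topright", legend = sib, pch = 1:3, lty = 1, col = 1:6)
  grDevices::dev.off()

  grDevices::png(file.path(dir, "site_usage.png"), width = 1000, height = 700,
                 res = 120)
  um <- t(sapply(stage_order, function(st) {
    sub <- run$usage[run$usage$stage == st, ]
    stats::setNames(sub$fraction, sub$site)
  }))
  graphics::barplot(t(um), col = grDevices::gray.colors(ncol(um)), las = 2,
                    ylab = "14-15 site usage fraction",
                    legend.text = colnames(um))
  grDevices::dev.off()

  st <- stats_tables(run$stats)
  digest <- file.path(dir, "digest.txt")
  con <- file(digest, "wt")
  writeLines(sprintf("run %s | seed %d", run$config_hash, run$config$seed), con)
  writeLines("\nKruskal-Wallis per bait:", con)
  utils::write.table(format(st$kw, digits = 4), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(st$dunn)) {
    writeLines("\nSignificant Dunn pairs:", con)
    utils::write.table(format(st$dunn[st$dunn$significant, ], digits = 4),
                       con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  close(con)
  invisible(dir)
}
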