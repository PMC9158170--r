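# Independent oracles and shared fixtures for the test suite.

# Brute-force longest-common-substring oracle: O(n*m) dynamic programming over
# the suffix-match table. Returns the length of the longest exact common
# substring of a and b.
lcs_oracle <- function(a, b) {
  av <- strsplit(a, "", fixed = TRUE)[[1L]]
  bv <- strsplit(b, "", fixed = TRUE)[[1L]]
  n <- length(av); m <- length(bv)
  prev <- integer(m)
  best <- 0L
  for (i in seq_len(n)) {
    cur <- integer(m)
    eq <- av[i] == bv
    cur[eq] <- c(0L, prev)[seq_len(m)][eq] + 1L
    best <- max(best, cur)
    prev <- cur
  }
  best
}

# Brute-force tie-corrected Kruskal-Wallis H: explicit midrank table, no
# shortcuts, independent of stats::kruskal.test.
kw_oracle <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  n <- length(x)
  # midranks by explicit sort
  ord <- order(x)
  r <- numeric(n)
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && x[ord[j + 1L]] == x[ord[i]]) j <- j + 1L
    r[ord[i:j]] <- mean(i:j)
    i <- j + 1L
  }
  g <- rep(seq_along(groups), lengths(groups))
  rs <- tapply(r, g, sum)
  ni <- lengths(groups)
  h <- 12 / (n * (n + 1)) * sum(rs^2 / ni) - 3 * (n + 1)
  tie_counts <- table(x)
  corr <- 1 - sum(tie_counts^3 - tie_counts) / (n^3 - n)
  h / corr
}

# A tiny hand-written 5-exon gene for coordinate arithmetic tests:
# exon lengths 60, 40, 66, 55, 90; exon 3 optional; exon 4 has sites A/B/C.
toy_gene <- function() {
  set.seed(99)
  seqs <- vapply(c(60L, 40L, 66L, 55L, 90L), function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
  }, character(1))
  gene_model(
    "toy",
    list(exon_model(1L, seqs[1L]),
         exon_model(2L, seqs[2L]),
         exon_model(3L, seqs[3L]),
         exon_model(4L, seqs[4L], c(A = 0L, B = 21L, C = 33L)),
         exon_model(5L, seqs[5L])),
    optional_exons = 3L,
    start_codon = c(1L, 0L)
  )
}

# The seeded Fmr1-like fixture gene and its background, built once per suite.
.fixture_env <- new.env(parent = emptyenv())

fixture_background <- function() {
  if (is.null(.fixture_env$bg)) {
    .fixture_env$bg <- make_background(2L, n = 50L, len = 2000L)
  }
  .fixture_env$bg
}

fixture_gene <- function() {
  if (is.null(.fixture_env$gene)) {
    .fixture_env$gene <- make_gene(1L, background = fixture_background())
  }
  .fixture_env$gene
}

fixture_baits <- function() {
  if (is.null(.fixture_env$baits)) {
    .fixture_env$baits <- default_bait_set(fixture_gene())
  }
  .fixture_env$baits
}

# A transcript spec for the fixture gene.
fx_spec <- function(e12 = TRUE, e14 = TRUE, s15 = "A", s17 = "B") {
  transcript_spec(c(`12` = e12, `14` = e14), c(`15` = s15, `17` = s17))
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
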