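# Full-identity matching of baits against reads, Karlin-Altschul E-values,
# the E-value window filter, retrieval cap, and junction-read counting.

#' Karlin-Altschul scoring parameters
#'
#' Defaults approximate ungapped nucleotide BLAST with +1/-2 match/mismatch
#' scoring (lambda = 1.28 nats per score unit, K = 0.46, reward 1 per matched
#' base).
#'
#' @param lambda_ Karlin-Altschul lambda (nats per score unit).
#' @param K Karlin-Altschul K (dimensionless).
#' @param reward score per matched base.
#' @return object of class `scoring_params`.
#' @export
scoring_params <- function(lambda_ = 1.28, K = 0.46, reward = 1) {
  stopifnot(lambda_ > 0, K > 0, reward > 0)
  structure(list(lambda_ = lambda_, K = K, reward = reward),
            class = "scoring_params")
}

#' Hit-filtering parameters
#'
#' @param evalue_low,evalue_high E-value window bounds (defaults 4e-60 and
#'   4e-23); hits are kept when their E-value falls inside the window.
#' @param max_hits per-bait retrieval cap (default 20,000); when more hits
#'   qualify, the smallest-E hits are retained and truncation is flagged.
#' @param a_min minimum matched nt on each side of the junction for a read to
#'   count as junction-spanning (default 10).
#' @param min_identity identity fraction over the reported match; fixed at 1
#'   (full identity) in this matcher.
#' @return object of class `filter_params`.
#' @export
filter_params <- function(evalue_low = 4e-60, evalue_high = 4e-23,
                          max_hits = 20000L, a_min = 10L, min_identity = 1) {
  stopifnot(evalue_low < evalue_high, max_hits > 0, a_min >= 1L,
            min_identity == 1)
  structure(list(min_identity = min_identity, evalue_low = evalue_low,
                 evalue_high = evalue_high, max_hits = as.integer(max_hits),
                 a_min = as.integer(a_min)),
            class = "filter_params")
}

#' Karlin-Altschul E-value for an ungapped full-identity match
#'
#' `E = K * m * n * exp(-lambda * reward * match_len)`: the expected number of
#' chance matches of at least this score between a bait of length `m` and a
#' read database of `n` total nucleotides.
#'
#' @param match_len matched length in nt (vectorized).
#' @param m bait length (nt).
#' @param n database size (total nt across reads).
#' @param params a [scoring_params()].
#' @return E-value(s).
#' @export
karlin_altschul_evalue <- function(match_len, m, n, params = scoring_params()) {
  stopifnot(all(match_len > 0), m > 0, n > 0)
  params$K * m * n * exp(-params$lambda_ * params$reward * match_len)
}

#' Invert the E-value window into a match-length window
#'
#' Solves `E(L) = K m n exp(-lambda reward L)` for the smallest and largest
#' integer `L` with `E(L)` inside `[evalue_low, evalue_high]`; `L_max` is
#' capped at the bait length `m`.
#'
#' @inheritParams karlin_altschul_evalue
#' @param filt a [filter_params()].
#' @return list with integer `L_min`, `L_max` and logical `empty`; when no
#'   integer length qualifies, `L_min`/`L_max` are `NA` and `empty` is `TRUE`
#'   (callers should warn).
#' @export
evalue_length_window <- function(params = scoring_params(),
                                 filt = filter_params(), m, n) {
  stopifnot(m > 0, n > 0)
  lr <- params$lambda_ * params$reward
  lkmn <- log(params$K) + log(m) + log(n)
  eps <- 1e-9
  l_min <- max(1L, as.integer(ceiling((lkmn - log(filt$evalue_high)) / lr - eps)))
  l_max <- min(as.integer(m),
               as.integer(floor((lkmn - log(filt$evalue_low)) / lr + eps)))
  if (l_min > l_max) {
    return(list(L_min = NA_integer_, L_max = NA_integer_, empty = TRUE))
  }
  list(L_min = l_min, L_max = l_max, empty = FALSE)
}

bait_sequence <- function(bait) {
  if (inherits(bait, "junction_bait")) bait$sequence
  else if (methods::is(bait, "DNAString")) as.character(bait)
  else as.character(bait)
}

bait_id_of <- function(bait) {
  if (inherits(bait, "junction_bait")) bait$bait_id else "bait"
}

reads_as_character <- function(reads) {
  x <- as.character(reads)
  if (is.null(names(x))) names(x) <- sprintf("read%06d", seq_along(x))
  x
}

empty_hits <- function() {
  data.frame(read_id = character(), bait_id = character(),
             match_len = integer(), bait_start = integer(),
             read_start = integer(), strand = character(),
             evalue = numeric(), stringsAsFactors = FALSE)
}

# Maximal exact common substring of one read (as utf8 ints) against the bait,
# via k-mer seed + ungapped extension along each seeded diagonal. Exact for
# all common substrings of length >= seed_len. Returns NULL or
# c(match_len, bait_start, read_start) (0-based starts).
best_run <- function(rv, bait_env, bv, k) {
  nr <- length(rv)
  if (nr < k) return(NULL)
  rk <- substring(intToUtf8(rv), seq_len(nr - k + 1L), k:nr)
  hit_list <- lapply(seq_along(rk), function(i) {
    j <- bait_env[[rk[i]]]
    if (is.null(j)) NULL else cbind(i, j)
  })
  hits <- do.call(rbind, hit_list)
  if (is.null(hits)) return(NULL)
  diags <- unique(hits[, 1L] - hits[, 2L])
  best <- NULL
  nb <- length(bv)
  acgt <- utf8ToInt("ACGT")
  for (d in diags) {
    ri <- max(1L, 1L + d):min(nr, nb + d)
    bi <- ri - d
    eq <- (rv[ri] == bv[bi]) & (rv[ri] %in% acgt)
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    for (q in runs) {
      len <- r$lengths[q]
      cand <- c(len, bi[starts[q]] - 1L, ri[starts[q]] - 1L)
      if (is.null(best) ||
          cand[1L] > best[1L] ||
          (cand[1L] == best[1L] &&
           (cand[2L] < best[2L] ||
            (cand[2L] == best[2L] && cand[3L] < best[3L])))) {
        best <- cand
      }
    }
  }
  if (!is.null(best) && best[1L] < k) best <- NULL
  best
}

# Hash of all k-mers of the bait: k-mer string -> 1-based bait positions.
bait_kmer_index <- function(bait_seq, k) {
  m <- nchar(bait_seq)
  env <- new.env(hash = TRUE, parent = emptyenv(), size = max(2L * m, 29L))
  if (m < k) return(env)
  kmers <- substring(bait_seq, seq_len(m - k + 1L), k:m)
  for (i in seq_along(kmers)) {
    env[[kmers[i]]] <- c(env[[kmers[i]]], i)
  }
  env
}

#' Maximal full-identity matches between a bait and reads
#'
#' For each read and strand, reports the maximal-length exact common substring
#' with the bait, found by k-mer seeding plus ungapped extension along each
#' seeded diagonal; common substrings shorter than `seed_len` are not
#' reported. One hit per (read, strand): the longest, ties broken by smallest
#' bait start, then smallest read start. Minus-strand coordinates refer to the
#' reverse-complemented read. Ambiguous bases (`N`) in the bait are an error;
#' `N` in reads never matches.
#'
#' @param bait a `junction_bait`, `DNAString`, or character sequence.
#' @param reads `DNAStringSet` or named character vector.
#' @param seed_len k-mer seed length (default 12); exactness floor of the
#'   search.
#' @param params a [scoring_params()] used to attach E-values to hits.
#' @param db_size database size in nt for the E-value (default: total length
#'   of `reads`).
#' @param both_strands also search the reverse complement of each read.
#' @return data.frame of hits: `read_id`, `bait_id`, `match_len`,
#'   `bait_start`, `read_start` (0-based), `strand`, `evalue`.
#' @export
exact_match_hits <- function(bait, reads, seed_len = 12L,
                             params = scoring_params(), db_size = NULL,
                             both_strands = TRUE) {
  bseq <- bait_sequence(bait)
  assert_dna(bseq, "bait")
  rc <- reads_as_character(reads)
  if (!length(rc)) stop("reads must be non-empty", call. = FALSE)
  if (is.null(db_size)) db_size <- sum(nchar(rc))
  m <- nchar(bseq)
  k <- as.integer(seed_len)
  env <- bait_kmer_index(bseq, k)
  bv <- utf8ToInt(bseq)
  strands <- if (both_strands) c("+", "-") else "+"
  rc_rev <- if (both_strands) revcomp(unname(rc)) else NULL
  n_out <- length(rc) * length(strands)
  ids <- character(n_out); lens <- integer(n_out)
  bst <- integer(n_out); rst <- integer(n_out); std <- character(n_out)
  pos <- 0L
  for (i in seq_along(rc)) {
    for (s in strands) {
      rseq <- if (s == "+") rc[[i]] else rc_rev[[i]]
      run <- best_run(utf8ToInt(rseq), env, bv, k)
      if (!is.null(run)) {
        pos <- pos + 1L
        ids[pos] <- names(rc)[i]; lens[pos] <- run[1L]
        bst[pos] <- run[2L]; rst[pos] <- run[3L]; std[pos] <- s
      }
    }
  }
  if (pos == 0L) return(empty_hits())
  idx <- seq_len(pos)
  hits <- data.frame(read_id = ids[idx], bait_id = bait_id_of(bait),
                     match_len = lens[idx], bait_start = bst[idx],
                     read_start = rst[idx], strand = std[idx],
                     stringsAsFactors = FALSE)
  hits$evalue <- karlin_altschul_evalue(hits$match_len, m, db_size, params)
  hits
}

#' Filter hits by the E-value window and the retrieval cap
#'
#' Keeps hits whose E-value lies inside `[evalue_low, evalue_high]`. When more
#' than `max_hits` qualify, the `max_hits` hits with smallest E-value are kept
#' (ties by input order) and the result carries `attr(, "truncated") = TRUE`.
#'
#' @param hits data.frame from [exact_match_hits()].
#' @param filt a [filter_params()].
#' @return filtered hits data.frame with a `truncated` attribute.
#' @export
filter_hits <- function(hits, filt = filter_params()) {
  keep <- hits$evalue >= filt$evalue_low & hits$evalue <= filt$evalue_high
  res <- hits[keep, , drop = FALSE]
  truncated <- FALSE
  if (nrow(res) > filt$max_hits) {
    ord <- order(res$evalue, seq_len(nrow(res)))
    res <- res[ord[seq_len(filt$max_hits)], , drop = FALSE]
    truncated <- TRUE
  }
  rownames(res) <- NULL
  attr(res, "truncated") <- truncated
  res
}

#' Count junction-spanning reads among filtered hits
#'
#' A read counts when its match covers the bait's junction offset with at
#' least `a_min` matched nt on each side; each read is counted at most once
#' (across strands and positions).
#'
#' @param hits filtered hits for this bait (see [filter_hits()]).
#' @param bait the `junction_bait` the hits refer to.
#' @param filt a [filter_params()] supplying `a_min`.
#' @return integer count of junction-spanning reads.
#' @export
count_junction_reads <- function(hits, bait, filt = filter_params()) {
  if (!nrow(hits)) return(0L)
  j <- bait$junction_offset
  if (is.na(j)) stop("bait has no junction (constitutive bait)", call. = FALSE)
  left <- j - hits$bait_start
  right <- hits$bait_start + hits$match_len - j
  ok <- left >= filt$a_min & right >= filt$a_min
  length(unique(hits$read_id[ok]))
}

#' Convert read counts to RPKM
#'
#' `rpkm = count / ((bait_len / 1000) * (total_reads / 1e6))` — reads per
#' kilobase of bait per million sequenced reads.
#'
#' @param counts integer vector of per-bait read counts.
#' @param bait_lens bait lengths in nt (recycled against `counts`).
#' @param total_reads total reads in the sample (scalar, > 0).
#' @return numeric RPKM vector.
#' @export
compute_rpkm <- function(counts, bait_lens, total_reads) {
  if (length(total_reads) != 1L || total_reads <= 0) {
    stop("total_reads must be a single positive count", call. = FALSE)
  }
  stopifnot(all(counts >= 0), all(bait_lens > 0))
  counts / ((bait_lens / 1000) * (total_reads / 1e6))
}

#' Usage fractions among sibling junctions
#'
#' Divides each sibling's value (count or RPKM) by the sibling sum, e.g. the
#' share of each 14-15 acceptor site among all 14-15 junction reads. An
#' all-zero input yields `NA` values flagged with `attr(, "undefined") = TRUE`
#' rather than NaN propagation.
#'
#' @param values non-negative numeric vector (one per sibling bait).
#' @return numeric vector summing to 1, or all-`NA` flagged `undefined`.
#' @export
usage_fractions <- function(values) {
  stopifnot(length(values) >= 1L, all(values >= 0))
  s <- sum(values)
  if (s == 0) {
    out <- rep(NA_real_, length(values))
    names(out) <- names(values)
    attr(out, "undefined") <- TRUE
    return(out)
  }
  out <- values / s
  attr(out, "undefined") <- FALSE
  out
}

#' Ratio of one bait's RPKM to another's
#'
#' Plain ratio (e.g. 13-15C / 10-11). Zero denominators yield `NA`, flagged
#' per element via `attr(, "undefined_at")`.
#'
#' @param rpkm_numerator,rpkm_denominator numeric vectors (recycled).
#' @return numeric ratio vector.
#' @export
junction_ratio <- function(rpkm_numerator, rpkm_denominator) {
  bad <- rpkm_denominator == 0
  out <- ifelse(bad, NA_real_, rpkm_numerator / rpkm_denominator)
  attr(out, "undefined_at") <- which(bad)
  out
}
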