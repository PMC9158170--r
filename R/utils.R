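# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of character DNA sequences
#'
#' Thin wrapper over [Biostrings::reverseComplement()] operating on plain
#' character vectors, used wherever reads or baits are handled as strings.
#'
#' @param x character vector of DNA sequences (A/C/G/T, N allowed).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

assert_dna <- function(x, what = "sequence", allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]+$" else "^[ACGT]+$"
  if (length(x) != 1L || is.na(x) || !nzchar(x) || !grepl(pat, x)) {
    stop(what, " must be a non-empty string over {A,C,G,T", if (allow_n) ",N", "}",
         call. = FALSE)
  }
  invisible(x)
}

# Evaluate expr under a fixed RNG state, restoring the caller's stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Exact 32-bit modular multiply (doubles hold 53 bits; split one factor).
mulmod32 <- function(a, b) {
  # split a into 16-bit halves to stay within double precision
  lo <- a %% 65536
  hi <- (a - lo) / 65536
  ((hi * b %% 4294967296) * 65536 + lo * b) %% 4294967296
}

# XOR of two doubles holding 32-bit unsigned values (bitwXor is int-only).
xor32 <- function(a, b) {
  alo <- a %% 65536; ahi <- (a - alo) / 65536
  blo <- b %% 65536; bhi <- (b - blo) / 65536
  bitwXor(ahi, bhi) * 65536 + bitwXor(alo, blo)
}

# 32-bit FNV-1a hash of a character scalar; stable across platforms.
hash32 <- function(x) {
  bytes <- utf8ToInt(x)
  h <- 2166136261
  for (b in bytes) {
    h <- xor32(h, b)
    h <- mulmod32(h, 16777619)
  }
  h
}

#' Derive a reproducible per-sample seed from a global seed
#'
#' Hashes the sample identifier (FNV-1a, 32-bit) and combines it with the
#' global seed, so that adding or removing a sample never perturbs the reads
#' simulated for the others.
#'
#' @param seed integer global seed.
#' @param sample_id character scalar.
#' @return integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, sample_id) {
  as.integer((hash32(sample_id) + as.numeric(seed)) %% 2147483647)
}

# Fingerprint an R object (config provenance in output headers).
config_hash <- function(x) {
  raw <- serialize(x, connection = NULL, version = 2)
  h <- 2166136261
  ints <- as.integer(raw)
  for (b in ints) {
    h <- xor32(h, b)
    h <- mulmod32(h, 16777619)
  }
  # h is a double holding a 32-bit value; format as hex in two halves
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
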