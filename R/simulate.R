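# Synthetic data: seeded fixture genes, background transcripts, and
# stage-profiled single-end read sets emulating a developmental RNA-Seq design
# (13 forebrain stages, ~4 replicates, unpaired 101-nt reads).

NONSTOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all64 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all64, c("TAA", "TAG", "TGA"))
})

rand_nonstop_codons <- function(n) {
  sample(NONSTOP_CODONS, n, replace = TRUE)
}

# Generate an exon that must be stop-free in the codon-aligned frame
# (local positions 0,3,6,...). Length must be a multiple of 3.
frame0_exon <- function(len, first_codon = NULL) {
  stopifnot(len %% 3L == 0L)
  codons <- rand_nonstop_codons(len %/% 3L)
  if (!is.null(first_codon)) codons[1L] <- first_codon
  paste(codons, collapse = "")
}

# Generate an exon constrained in two reading frames:
#  - frame 0 (codon starts at local positions = 0 mod 3): stop-free except
#    where `f0_stops` implants a stop codon;
#  - frame 1 (codon starts at local positions = 2 mod 3, the frame produced by
#    an upstream exon of length = 1 mod 3): stop-free except at `f1_stops`.
# `last_c` forces the final base to C so that codons straddling the downstream
# junction can never spell a stop.
dual_frame_exon <- function(len, f0_stops = integer(), f1_stops = integer(),
                            last_c = FALSE, max_iter = 1000L) {
  stopifnot(len %% 3L == 0L, all(f0_stops %% 3L == 0L),
            all(f1_stops %% 3L == 2L), all(c(f0_stops, f1_stops) <= len - 3L))
  chars <- strsplit(paste(rand_nonstop_codons(len %/% 3L), collapse = ""),
                    "", fixed = TRUE)[[1L]]
  locked <- logical(len)
  implant <- function(pos0, codon) {
    chars[(pos0 + 1L):(pos0 + 3L)] <<- strsplit(codon, "", fixed = TRUE)[[1L]]
    locked[(pos0 + 1L):(pos0 + 3L)] <<- TRUE
  }
  for (p in f0_stops) implant(p, "TAA")
  for (p in f1_stops) implant(p, "TAA")
  if (last_c) { chars[len] <- "C"; locked[len] <- TRUE }
  f1_starts <- seq.int(2L, len - 3L, by = 3L)
  f0_starts <- seq.int(0L, len - 3L, by = 3L)
  codon_at <- function(p) paste(chars[(p + 1L):(p + 3L)], collapse = "")
  for (iter in seq_len(max_iter)) {
    bad_f1 <- f1_starts[vapply(f1_starts, function(p) {
      codon_at(p) %in% STOP_CODONS && !(p %in% f1_stops)
    }, logical(1))]
    bad_f0 <- f0_starts[vapply(f0_starts, function(p) {
      codon_at(p) %in% STOP_CODONS && !(p %in% f0_stops)
    }, logical(1))]
    bad <- c(bad_f1, bad_f0)
    if (!length(bad)) return(paste(chars, collapse = ""))
    p <- bad[1L]
    # resample a fully unlocked frame-0 codon overlapping the offending codon
    cand <- unique((p:(p + 2L)) %/% 3L)
    free <- cand[vapply(cand, function(ci) {
      !any(locked[(3L * ci + 1L):(3L * ci + 3L)])
    }, logical(1))]
    if (!length(free)) {
      stop("cannot repair exon frame constraints near a locked region",
           call. = FALSE)
    }
    ci <- free[1L]
    chars[(3L * ci + 1L):(3L * ci + 3L)] <-
      strsplit(rand_nonstop_codons(1L), "", fixed = TRUE)[[1L]]
  }
  stop("frame-constraint repair did not converge", call. = FALSE)
}

# Largest multiple of `m` in [lo, hi), or NA.
mult_in <- function(m, lo, hi) {
  x <- (ceiling(lo / m):max(ceiling(lo / m), floor((hi - 1) / m))) * m
  x <- x[x >= lo & x < hi]
  if (!length(x)) NA_integer_ else as.integer(x[length(x)])
}

#' Generate a deterministic Fmr1-like fixture gene
#'
#' Builds a 17-exon gene model whose structural facts mirror the biology this
#' package targets: exons 12 and 14 are optional, exon 15 has three acceptor
#' sites and exon 17 two, the constitutive exon 1-11 block is 1,122 nt, exon 14
#' has length not divisible by 3 (so skipping it shifts the reading frame), and
#' stop codons are placed so that skipping exon 14 with acceptor site 15A or
#' 15B terminates translation in exon 15 (a premature termination codon under
#' the exon-junction rule) while site 15C reads through to a stop on exon 17.
#' Exon sequences are rejection-sampled until every junction bait of
#' [default_bait_set()] occurs exactly once in each transcript carrying that
#' junction and nowhere else (including reverse complements and the background
#' transcriptome, when supplied).
#'
#' @param seed integer seed; the result is a deterministic function of the
#'   seed and the structural arguments.
#' @param exon_lengths integer vector of 17 exon lengths. Defaults give
#'   102 nt for exons 1-11, 105 (exon 12), 120 (exon 13), 52 (exon 14),
#'   300 (exon 15), 150 (exon 16), 201 (exon 17).
#' @param site_offsets list with elements `"15"` and `"17"`: named acceptor
#'   offsets (multiples of 3), defaults `c(A = 0, B = 21, C = 33)` and
#'   `c(A = 0, B = 12)`.
#' @param background optional `DNAStringSet` (or character vector) of decoy
#'   transcripts the baits must not collide with.
#' @param bait_len junction bait length used for the uniqueness check.
#' @param max_tries rejection-sampling cap.
#' @return a [gene_model()].
#' @export
make_gene <- function(seed, exon_lengths = NULL, site_offsets = NULL,
                      background = NULL, bait_len = 100L, max_tries = 50L) {
  if (is.null(exon_lengths)) {
    exon_lengths <- c(rep(102L, 11L), 105L, 120L, 52L, 300L, 150L, 201L)
  }
  exon_lengths <- as.integer(exon_lengths)
  stopifnot(length(exon_lengths) == 17L)
  if (is.null(site_offsets)) {
    site_offsets <- list(`15` = c(A = 0L, B = 21L, C = 33L),
                         `17` = c(A = 0L, B = 12L))
  }
  off15 <- site_offsets[["15"]]; off17 <- site_offsets[["17"]]
  half <- bait_len %/% 2L
  if (any(exon_lengths[-c(12L, 14L)] %% 3L != 0L)) {
    stop("exons other than 12 and 14 must have lengths divisible by 3",
         call. = FALSE)
  }
  if (exon_lengths[14L] %% 3L == 0L) {
    stop("exon 14 length must not be divisible by 3 (frame shift on skip)",
         call. = FALSE)
  }
  if (exon_lengths[12L] %% 3L != 0L) {
    stop("exon 12 length must be divisible by 3 (its skipping is in-frame)",
         call. = FALSE)
  }
  if (any(c(off15, off17) %% 3L != 0L)) {
    stop("acceptor offsets must be multiples of 3", call. = FALSE)
  }
  if (exon_lengths[14L] < half || exon_lengths[13L] < half ||
      exon_lengths[15L] - max(off15) < half ||
      exon_lengths[17L] - max(off17) < half || exon_lengths[16L] < half ||
      exon_lengths[10L] < half || exon_lengths[11L] < half) {
    stop("exon lengths too short to supply ", half, " nt bait anchors",
         call. = FALSE)
  }
  # stop-codon placement (local 0-based offsets, frame-0 multiples of 3):
  # a stop reachable only from site A, one reachable from A and B but not C,
  # and exon-17 stops for the shifted (frame-0) and canonical (frame-1) frames.
  sA <- mult_in(3L, off15[1L], off15[2L])
  sB <- mult_in(3L, off15[2L], off15[3L])
  if (is.na(sA) || is.na(sB)) {
    stop("acceptor offsets too close together to place distinguishing stops",
         call. = FALSE)
  }
  s17_f0 <- mult_in(3L, max(off17) + 3L, max(off17) + 24L)
  s17_f1 <- s17_f0 + 14L  # = 2 (mod 3): the exon-14-containing frame
  stopifnot(s17_f1 <= exon_lengths[17L] - 3L)

  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      exons <- vector("list", 17L)
      for (i in 1:13) {
        exons[[i]] <- exon_model(i, frame0_exon(
          exon_lengths[i], first_codon = if (i == 1L) "ATG" else NULL))
      }
      # exon 14: 3k+1 frame-0 codons then a final C so the codon straddling
      # the 14-15 junction can never be a stop
      n14 <- exon_lengths[14L]
      tail_len <- n14 %% 3L
      tail14 <- paste(rep("C", tail_len), collapse = "")
      exons[[14L]] <- exon_model(14L, paste0(
        frame0_exon(n14 - tail_len), tail14))
      exons[[15L]] <- exon_model(15L, dual_frame_exon(
        exon_lengths[15L], f0_stops = c(sA, sB), last_c = TRUE), off15)
      exons[[16L]] <- exon_model(16L, dual_frame_exon(
        exon_lengths[16L], last_c = TRUE))
      exons[[17L]] <- exon_model(17L, dual_frame_exon(
        exon_lengths[17L], f0_stops = s17_f0, f1_stops = s17_f1), off17)
      gene <- gene_model("synthetic-fmr1-like", exons,
                         optional_exons = c(12L, 14L),
                         start_codon = c(1L, 0L))
      if (verify_gene(gene, background = background, bait_len = bait_len)) {
        return(gene)
      }
    }
  })
  stop("could not satisfy fixture constraints in ", max_tries,
       " attempts; consider longer exons", call. = FALSE)
}

# Does a spliced transcript (by its segments) contain this bait's junction?
junction_in_segments <- function(seg, donor, acceptor, site = "") {
  rd <- match(donor, seg$exon); ra <- match(acceptor, seg$exon)
  !is.na(rd) && !is.na(ra) && ra == rd + 1L &&
    (!nzchar(site) || seg$site[ra] == site)
}

# Structural verification: ORF/PTC pattern over all transcripts plus exact
# single-occurrence of every bait in the transcript/background universe.
verify_gene <- function(gene, background = NULL, bait_len = 100L) {
  specs <- enumerate_transcripts(gene)
  anns <- lapply(specs, function(sp) annotate_orf(gene, sp))
  last15 <- names(exon_sites(get_exon(gene, 15L)))
  last15 <- last15[length(last15)]
  ok <- vapply(seq_along(specs), function(i) {
    sp <- specs[[i]]; a <- anns[[i]]
    if (!a$has_stop) return(FALSE)
    if (sp$include[["14"]]) {
      a$stop_exon == 17L && !a$is_ptc && !a$frame_shifted
    } else if (sp$site_choice[["15"]] == last15) {
      a$stop_exon == 17L && a$frame_shifted
    } else {
      a$stop_exon == 15L && a$is_ptc && a$frame_shifted
    }
  }, logical(1))
  if (!all(ok)) return(FALSE)

  baits <- default_bait_set(gene, bait_len = bait_len)
  txs <- lapply(specs, function(sp) splice_transcript(gene, sp))
  seqs <- Biostrings::DNAStringSet(vapply(txs, `[[`, character(1), "sequence"))
  bg <- if (is.null(background)) NULL else Biostrings::DNAStringSet(background)
  for (b in baits) {
    pat <- Biostrings::DNAString(b$sequence)
    fwd <- Biostrings::vcountPattern(pat, seqs)
    rev <- Biostrings::vcountPattern(Biostrings::reverseComplement(pat), seqs)
    expected <- if (is.na(b$junction_offset)) {
      rep(1L, length(txs))
    } else {
      vapply(txs, function(tx) {
        as.integer(junction_in_segments(tx$segments, b$donor, b$acceptor, b$site))
      }, integer(1))
    }
    if (any(fwd != expected) || any(rev != 0L)) return(FALSE)
    if (!is.null(bg)) {
      if (any(Biostrings::vcountPattern(pat, bg) > 0L) ||
          any(Biostrings::vcountPattern(
            Biostrings::reverseComplement(pat), bg) > 0L)) return(FALSE)
    }
  }
  TRUE
}

#' Generate a seeded background transcriptome of decoy sequences
#'
#' Random uniform sequence; only its total read mass (the RPKM denominator)
#' and non-collision with the bait set matter downstream.
#'
#' @param seed integer seed.
#' @param n number of decoy transcripts.
#' @param len length of each decoy in nt.
#' @return a named `DNAStringSet` (`bg001`, `bg002`, ...).
#' @export
make_background <- function(seed, n = 50L, len = 2000L) {
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i) {
      paste(sample(DNA_BASES, len, replace = TRUE), collapse = "")
    }, character(1))
  })
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- sprintf("bg%03d", seq_len(n))
  out
}

#' Construct a per-stage ground-truth profile for the simulator
#'
#' @param stage_label stage name, e.g. `"E14"` or `"P112"`.
#' @param target_fraction fraction of library reads drawn from the focal gene.
#' @param skip_fraction probability that a focal transcript skips exon 14.
#' @param site15_usage probability vector over acceptor sites A/B/C of exon 15.
#' @param site17_usage probability vector over acceptor sites A/B of exon 17.
#' @param exon12_fraction inclusion probability for optional exon 12.
#' @param structure tissue label (`"forebrain"`, `"cerebellum"`, `"whole brain"`).
#' @return object of class `stage_profile`.
#' @export
stage_profile <- function(stage_label, target_fraction, skip_fraction = 0.10,
                          site15_usage = c(A = 0.40, B = 0.35, C = 0.25),
                          site17_usage = c(A = 0, B = 1),
                          exon12_fraction = 0.25,
                          structure = "forebrain") {
  stopifnot(target_fraction >= 0, target_fraction < 1,
            skip_fraction >= 0, skip_fraction <= 1,
            exon12_fraction >= 0, exon12_fraction <= 1,
            abs(sum(site15_usage) - 1) < 1e-12,
            abs(sum(site17_usage) - 1) < 1e-12,
            all(site15_usage >= 0), all(site17_usage >= 0))
  structure(
    list(stage_label = stage_label, structure = structure,
         target_fraction = target_fraction, skip_fraction = skip_fraction,
         site15_usage = site15_usage, site17_usage = site17_usage,
         exon12_fraction = exon12_fraction),
    class = "stage_profile"
  )
}

#' Default 13-stage forebrain study profiles
#'
#' Encodes the study conditions the simulator emulates: 13 forebrain stages
#' E14..P112 with total focal-gene abundance declining monotonically from E14
#' to P112 except for an elevation at P3; exon-14 skipping elevated (0.45) in
#' the late embryonic window E17-E20 against a 0.10 baseline; and exon-15
#' acceptor-site usage (A, B, C) = (0.40, 0.35, 0.25), putting site A at about
#' 40\% of 14-15 junctions.
#'
#' @param base_fraction focal-gene read fraction at the E14 stage; later
#'   stages scale it down (P3 excepted). The default (0.04) is a depth choice:
#'   at 2e5 reads per sample and 4 replicates it yields roughly 1,000-1,400
#'   exon-13 junction reads per stage, putting the binomial standard error of
#'   recovered skip and site-usage fractions near 0.013 - small against the
#'   0.35/0.10 contrasts the design encodes. The decoy background is a
#'   denominator, not a realistic transcriptome, so the focal fraction acts as
#'   a sequencing-depth knob rather than a biological abundance.
#' @param skip_elevated,skip_baseline exon-14 skip fractions inside and
#'   outside the E17-E20 window.
#' @return named list of [stage_profile()], one per stage.
#' @export
default_study_profiles <- function(base_fraction = 0.04,
                                   skip_elevated = 0.45,
                                   skip_baseline = 0.10) {
  stages <- c("E14", "E15", "E16", "E17", "E18", "E19", "E20",
              "P0", "P3", "P7", "P14", "P42", "P112")
  rel <- c(1.00, 0.95, 0.90, 0.85, 0.80, 0.76, 0.72,
           0.68, 0.80, 0.62, 0.58, 0.55, 0.53)
  elevated <- c("E17", "E18", "E19", "E20")
  profs <- lapply(seq_along(stages), function(i) {
    stage_profile(
      stage_label = stages[i],
      target_fraction = base_fraction * rel[i],
      skip_fraction = if (stages[i] %in% elevated) skip_elevated else skip_baseline
    )
  })
  stats::setNames(profs, stages)
}

#' Simulation configuration
#'
#' @param read_length read length in nt (default 101, unpaired).
#' @param library_size reads per sample.
#' @param error_rate per-base substitution probability (default 0; under the
#'   full-identity filter errors act as a pure count deflation).
#' @param replicates samples per stage (default 4).
#' @param seed global integer seed.
#' @param background_n,background_len decoy transcriptome dimensions.
#' @return object of class `simulation_config`.
#' @export
simulation_config <- function(read_length = 101L, library_size = 200000L,
                              error_rate = 0, replicates = 4L, seed = 1L,
                              background_n = 50L, background_len = 2000L) {
  stopifnot(read_length >= 20L, library_size > 0, error_rate >= 0,
            error_rate < 1, replicates >= 1L, background_n >= 1L,
            background_len >= read_length)
  structure(
    list(read_length = as.integer(read_length),
         library_size = as.integer(library_size), error_rate = error_rate,
         replicates = as.integer(replicates), seed = as.integer(seed),
         background_n = as.integer(background_n),
         background_len = as.integer(background_len)),
    class = "simulation_config"
  )
}

# Probability that a sampled focal transcript follows this spec.
spec_probability <- function(profile, spec) {
  p <- 1
  inc <- spec$include
  if ("12" %in% names(inc)) {
    p <- p * if (inc[["12"]]) profile$exon12_fraction else 1 - profile$exon12_fraction
  }
  if ("14" %in% names(inc)) {
    p <- p * if (inc[["14"]]) 1 - profile$skip_fraction else profile$skip_fraction
  }
  sc <- spec$site_choice
  if ("15" %in% names(sc)) p <- p * profile$site15_usage[[sc[["15"]]]]
  if ("17" %in% names(sc)) p <- p * profile$site17_usage[[sc[["17"]]]]
  unname(p)
}

#' Simulate one single-end read sample
#'
#' Each read independently comes from the focal gene with probability
#' `profile$target_fraction` (transcript class sampled from the profile's
#' event probabilities) or from a uniformly chosen background decoy; the start
#' position is uniform over valid positions, the strand uniform, and
#' substitution errors are applied at `config$error_rate`. Fixed seed gives
#' bit-identical output.
#'
#' @param gene a [gene_model()] (see [make_gene()]).
#' @param background `DNAStringSet` of decoy transcripts.
#' @param profile a [stage_profile()].
#' @param config a [simulation_config()].
#' @param sample_seed integer seed for this sample (see [derive_seed()]).
#' @param read_prefix prefix for read names.
#' @return named `DNAStringSet` of `config$library_size` reads.
#' @export
simulate_sample <- function(gene, background, profile, config, sample_seed,
                            read_prefix = "read") {
  specs <- enumerate_transcripts(gene)
  txs <- vapply(specs, function(sp) splice_transcript(gene, sp)$sequence,
                character(1))
  probs <- vapply(specs, spec_probability, numeric(1), profile = profile)
  bg <- as.character(background)
  class_seq <- c(txs, bg)
  class_prob <- c(profile$target_fraction * probs,
                  rep((1 - profile$target_fraction) / length(bg), length(bg)))
  R <- config$read_length
  short <- nchar(class_seq) < R
  if (any(short & class_prob > 0)) {
    warning(sum(short), " transcript(s) shorter than the read length excluded")
    class_prob[short] <- 0
  }
  N <- config$library_size
  with_seed(sample_seed, {
    cls <- sample.int(length(class_seq), N, replace = TRUE, prob = class_prob)
    span <- nchar(class_seq)[cls] - R + 1L
    st <- 1L + as.integer(floor(stats::runif(N) * span))
    st <- pmin(st, span)
    reads <- substring(class_seq[cls], st, st + R - 1L)
    if (config$error_rate > 0) {
      nmut <- stats::rbinom(N, R, config$error_rate)
      for (i in which(nmut > 0L)) {
        pos <- sample.int(R, nmut[i])
        ch <- strsplit(reads[i], "", fixed = TRUE)[[1L]]
        for (p in pos) ch[p] <- sample(setdiff(DNA_BASES, ch[p]), 1L)
        reads[i] <- paste(ch, collapse = "")
      }
    }
    minus <- stats::runif(N) < 0.5
    if (any(minus)) reads[minus] <- revcomp(reads[minus])
  })
  out <- Biostrings::DNAStringSet(reads)
  names(out) <- sprintf("%s%06d", read_prefix, seq_len(N))
  out
}

#' Write simulated reads to FASTA or FASTQ
#'
#' FASTQ output uses a constant quality string (`I`), since the downstream
#' matcher is quality-blind.
#'
#' @param reads named `DNAStringSet`.
#' @param path output file.
#' @param format `"fasta"` or `"fastq"`.
#' @export
write_reads <- function(reads, path, format = c("fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "fasta") {
    Biostrings::writeXStringSet(reads, path)
  } else {
    quals <- Biostrings::BStringSet(vapply(
      Biostrings::width(reads), function(w) strrep("I", w), character(1)))
    Biostrings::writeXStringSet(reads, path, format = "fastq", qualities = quals)
  }
  invisible(path)
}

parse_junction_id <- function(junction) {
  m <- regmatches(junction, regexec("^J?(\\d+)-(\\d+)([A-Za-z]*)$", junction))[[1L]]
  if (!length(m)) stop("cannot parse junction id '", junction, "'", call. = FALSE)
  list(donor = as.integer(m[2L]), acceptor = as.integer(m[3L]), site = m[4L])
}

# Probability that a focal transcript carries the named junction, under the
# profile's event probabilities (Fmr1-like event semantics).
junction_probability <- function(profile, junction) {
  j <- parse_junction_id(junction)
  d <- j$donor; a <- j$acceptor; s <- j$site
  if (d == 13L && a == 14L) return(1 - profile$skip_fraction)
  if (d == 14L && a == 15L) {
    return((1 - profile$skip_fraction) * profile$site15_usage[[s]])
  }
  if (d == 13L && a == 15L) {
    return(profile$skip_fraction * profile$site15_usage[[s]])
  }
  if (d == 16L && a == 17L) return(profile$site17_usage[[s]])
  if (d == 11L && a == 12L) return(profile$exon12_fraction)
  if (d == 12L && a == 13L) return(profile$exon12_fraction)
  if (d == 11L && a == 13L) return(1 - profile$exon12_fraction)
  if (a == d + 1L) return(1)  # constitutive junction
  stop("unsupported junction '", junction, "' for this profile", call. = FALSE)
}

#' Closed-form expected junction-read count
#'
#' For a transcript class of length `transcript_len` carrying the junction,
#' the number of read start positions whose read covers the junction with at
#' least `a_min` nt on each side is `read_length - 2 a_min + 1`, out of
#' `transcript_len - read_length + 1` equally likely positions. The expected
#' count is that fraction times the expected number of reads from the class,
#' `library_size * target_fraction * P(class carries the junction)`. A
#' positive error rate multiplies by `(1 - error_rate)^read_length`, an
#' upper-bound correction (any substitution can break the full-identity match).
#'
#' @param profile a [stage_profile()].
#' @param config a [simulation_config()].
#' @param junction junction id, e.g. `"13-14"` or `"J14-15A"`.
#' @param transcript_len length (nt) of the transcript class carrying the
#'   junction.
#' @param a_min minimum matched anchor on each side of the junction.
#' @return expected read count (real).
#' @export
expected_junction_reads <- function(profile, config, junction, transcript_len,
                                    a_min = 10L) {
  R <- config$read_length
  stopifnot(R >= 2L * a_min, transcript_len >= R)
  n_t <- config$library_size * profile$target_fraction *
    junction_probability(profile, junction)
  e <- n_t * (R - 2L * a_min + 1L) / (transcript_len - R + 1L)
  if (config$error_rate > 0) e <- e * (1 - config$error_rate)^R
  e
}

#' Exact expected junction-read count over all transcript classes of a gene
#'
#' Enumerates every transcript spec of `gene`, and sums the closed form of
#' [expected_junction_reads()] over the classes that carry the junction,
#' using each class's exact spliced length and profile probability.
#'
#' @inheritParams expected_junction_reads
#' @param gene a [gene_model()].
#' @return expected read count (real).
#' @export
expected_junction_reads_gene <- function(gene, profile, config, junction,
                                         a_min = 10L) {
  j <- parse_junction_id(junction)
  R <- config$read_length
  specs <- enumerate_transcripts(gene)
  total <- 0
  for (sp in specs) {
    tx <- splice_transcript(gene, sp)
    if (!junction_in_segments(tx$segments, j$donor, j$acceptor, j$site)) next
    len <- nchar(tx$sequence)
    if (len < R) next
    total <- total + config$library_size * profile$target_fraction *
      spec_probability(profile, sp) * (R - 2L * a_min + 1L) / (len - R + 1L)
  }
  if (config$error_rate > 0) total <- total * (1 - config$error_rate)^R
  total
}
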