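# Junction and constitutive bait construction.
#
# A junction bait is a fixed-length sequence spanning one exon-exon junction,
# drawn equally from the two exons (50:50 by default), used downstream to
# retrieve junction-spanning reads by full-identity matching.

#' Build a junction bait spanning one exon-exon junction
#'
#' The bait takes the last `bait_len/2` nt of the donor exon and the first
#' `bait_len/2` nt of the acceptor exon measured from the chosen acceptor-site
#' offset, so the junction sits at offset `bait_len/2` within the bait.
#'
#' @param model a [gene_model()].
#' @param donor,acceptor exon indices; donor must be upstream of acceptor.
#' @param site acceptor-site label for a multi-acceptor exon (e.g. `"A"`);
#'   `NULL` for a constitutive acceptor.
#' @param bait_len total bait length in nt (even; default 100).
#' @return object of class `junction_bait`: list with `bait_id`, `sequence`,
#'   `donor`, `acceptor`, `site`, `junction_offset`, `length`.
#' @export
build_junction_bait <- function(model, donor, acceptor, site = NULL,
                                bait_len = 100L) {
  stopifnot(bait_len >= 2L, bait_len %% 2L == 0L)
  half <- bait_len %/% 2L
  if (!(donor < acceptor)) {
    stop("donor exon must be upstream of the acceptor exon", call. = FALSE)
  }
  dex <- get_exon(model, donor)
  aex <- get_exon(model, acceptor)
  off <- site_offset(model, acceptor, site)
  dlen <- nchar(dex$sequence)
  arem <- nchar(aex$sequence) - off
  if (dlen < half) {
    stop(sprintf("donor exon %d too short: %d nt available, %d required",
                 donor, dlen, half), call. = FALSE)
  }
  if (arem < half) {
    stop(sprintf(
      "acceptor exon %d too short after site offset: %d nt available, %d required",
      acceptor, arem, half), call. = FALSE)
  }
  site_lab <- if (is.null(site)) "" else site
  seq <- paste0(substring(dex$sequence, dlen - half + 1L, dlen),
                substring(aex$sequence, off + 1L, off + half))
  structure(
    list(bait_id = sprintf("J%d-%d%s", donor, acceptor, site_lab),
         sequence = seq, donor = as.integer(donor),
         acceptor = as.integer(acceptor), site = site_lab,
         junction_offset = half, length = bait_len),
    class = "junction_bait"
  )
}

#' @export
print.junction_bait <- function(x, ...) {
  cat(sprintf("<junction_bait> %s: %d nt, junction at offset %d\n",
              x$bait_id, x$length, x$junction_offset))
  invisible(x)
}

#' Build a constitutive bait from a run of consecutive exons
#'
#' Concatenates the sequences of exons `first..last`; the range must not
#' contain any optional exon (the bait must be present in every transcript).
#'
#' @inheritParams build_junction_bait
#' @param first,last exon indices bounding the range (inclusive).
#' @return the concatenated nucleotide string.
#' @export
build_constitutive_bait <- function(model, first, last) {
  stopifnot(first <= last)
  idx <- exon_indices(model)
  range_idx <- idx[idx >= first & idx <= last]
  if (!(first %in% idx) || !(last %in% idx)) {
    stop("exon range outside the model", call. = FALSE)
  }
  bad <- intersect(range_idx, model$optional_exons)
  if (length(bad)) {
    stop("range contains optional exon(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  paste(vapply(range_idx, function(i) get_exon(model, i)$sequence,
               character(1)), collapse = "")
}

# Wrap a constitutive bait in the common bait interface (no junction).
constitutive_bait <- function(model, first, last) {
  seq <- build_constitutive_bait(model, first, last)
  structure(
    list(bait_id = sprintf("E%d-%d", first, last), sequence = seq,
         donor = NA_integer_, acceptor = NA_integer_, site = "",
         junction_offset = NA_integer_, length = nchar(seq)),
    class = "junction_bait"
  )
}

#' Default bait set for an Fmr1-like gene model
#'
#' Mirrors the bait panel used for developmental Fmr1 profiling: the
#' constitutive exon 1-11 coding bait, the constitutive 10-11 junction, the
#' exon-14 inclusion junctions (13-14 and 14-15A/B/C), the exon-14 skipping
#' junctions (13-15A/B/C), and the exon-17 acceptor junctions (16-17A/B).
#'
#' @param model a [gene_model()] containing exons 1..17 with optional exons 12
#'   and 14 and multi-acceptor exons 15 and 17.
#' @param bait_len junction bait length (default 100).
#' @return named list of bait objects keyed by `bait_id`.
#' @export
default_bait_set <- function(model, bait_len = 100L) {
  b15 <- names(exon_sites(get_exon(model, 15L)))
  b17 <- names(exon_sites(get_exon(model, 17L)))
  baits <- c(
    list(constitutive_bait(model, 1L, 11L),
         build_junction_bait(model, 10L, 11L, bait_len = bait_len),
         build_junction_bait(model, 13L, 14L, bait_len = bait_len)),
    lapply(b15, function(s) build_junction_bait(model, 14L, 15L, s, bait_len)),
    lapply(b15, function(s) build_junction_bait(model, 13L, 15L, s, bait_len)),
    lapply(b17, function(s) build_junction_bait(model, 16L, 17L, s, bait_len))
  )
  stats::setNames(baits, vapply(baits, `[[`, character(1), "bait_id"))
}

#' Export a bait set as FASTA
#'
#' Headers encode donor, acceptor, site and junction offset, e.g.
#' `J13-15A|off=50`.
#'
#' @param baits list of bait objects (see [default_bait_set()]).
#' @param path output FASTA path.
#' @export
baits_to_fasta <- function(baits, path) {
  seqs <- Biostrings::DNAStringSet(vapply(baits, `[[`, character(1), "sequence"))
  names(seqs) <- vapply(baits, function(b) {
    if (is.na(b$junction_offset)) b$bait_id
    else sprintf("%s|off=%d", b$bait_id, b$junction_offset)
  }, character(1))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
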