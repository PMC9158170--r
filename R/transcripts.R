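# Transcript enumeration, splicing and ORF/PTC annotation.

#' Construct a transcript specification
#'
#' A transcript spec fixes the outcome of every alternative event: an
#' inclusion flag for each optional exon and one chosen acceptor site for each
#' multi-acceptor exon.
#'
#' @param include named logical vector keyed by exon index (as character),
#'   e.g. `c("12" = TRUE, "14" = FALSE)`.
#' @param site_choice named character vector keyed by exon index,
#'   e.g. `c("15" = "A", "17" = "B")`.
#' @return an object of class `transcript_spec`.
#' @export
transcript_spec <- function(include = logical(), site_choice = character()) {
  if (length(include)) {
    stopifnot(is.logical(include), !is.null(names(include)), !anyNA(include))
  }
  if (length(site_choice)) {
    stopifnot(is.character(site_choice), !is.null(names(site_choice)),
              !anyNA(site_choice))
  }
  structure(list(include = include, site_choice = site_choice),
            class = "transcript_spec")
}

#' @export
print.transcript_spec <- function(x, ...) {
  cat("<transcript_spec>", spec_label(x), "\n")
  invisible(x)
}

spec_label <- function(spec) {
  parts <- character()
  if (length(spec$include)) {
    parts <- c(parts, paste0("exon", names(spec$include),
                             ifelse(spec$include, "+", "-")))
  }
  if (length(spec$site_choice)) {
    parts <- c(parts, paste0("site", names(spec$site_choice), "=",
                             spec$site_choice))
  }
  if (!length(parts)) "constitutive" else paste(parts, collapse = " ")
}

validate_spec <- function(model, spec) {
  idx <- exon_indices(model)
  inc_idx <- as.integer(names(spec$include))
  if (length(inc_idx) && !all(inc_idx %in% model$optional_exons)) {
    stop("inclusion flags refer to exons that are not optional in this model",
         call. = FALSE)
  }
  missing_opt <- setdiff(model$optional_exons, inc_idx)
  if (length(missing_opt)) {
    stop("spec lacks an inclusion flag for optional exon(s) ",
         paste(missing_opt, collapse = ", "), call. = FALSE)
  }
  sc_idx <- as.integer(names(spec$site_choice))
  if (length(sc_idx) && !all(sc_idx %in% idx)) {
    stop("site choices refer to exon(s) absent from the model", call. = FALSE)
  }
  multi <- multi_acceptor_exons(model)
  missing_site <- setdiff(multi, sc_idx)
  if (length(missing_site)) {
    stop("spec lacks a site choice for multi-acceptor exon(s) ",
         paste(missing_site, collapse = ", "), call. = FALSE)
  }
  for (i in sc_idx) site_offset(model, i, spec$site_choice[[as.character(i)]])
  invisible(spec)
}

#' Enumerate all transcript specifications for a set of alternative events
#'
#' Takes the Cartesian product of event outcomes: each skip event contributes
#' \{included, excluded\} and each acceptor-site event contributes its site
#' labels. With the four Fmr1-like events (exon 12 in/out, exon 14 in/out,
#' site 15 in \{A,B,C\}) this yields the 12 variable transcripts; adding the
#' exon-17 site doubles it to 24.
#'
#' @param model a [gene_model()].
#' @param events list with elements `skip` (integer indices of optional exons)
#'   and `site` (integer indices of multi-acceptor exons). `NULL` (default)
#'   uses every alternative event the model defines.
#' @return list of [transcript_spec()] in deterministic order (lexicographic
#'   on event labels, later events varying fastest).
#' @export
enumerate_transcripts <- function(model, events = NULL) {
  if (is.null(events)) {
    events <- list(skip = model$optional_exons,
                   site = multi_acceptor_exons(model))
  }
  skip <- sort(as.integer(events$skip %||% integer()))
  site <- sort(as.integer(events$site %||% integer()))
  if (length(skip) && !all(skip %in% model$optional_exons)) {
    stop("skip events must name optional exons of the model; offending: ",
         paste(setdiff(skip, model$optional_exons), collapse = ", "),
         call. = FALSE)
  }
  if (length(site) && !all(site %in% multi_acceptor_exons(model))) {
    stop("site events must name multi-acceptor exons of the model; offending: ",
         paste(setdiff(site, multi_acceptor_exons(model)), collapse = ", "),
         call. = FALSE)
  }
  outcomes <- c(
    stats::setNames(lapply(skip, function(i) c(TRUE, FALSE)),
                    paste0("skip", skip, recycle0 = TRUE)),
    stats::setNames(lapply(site, function(i) {
      names(exon_sites(get_exon(model, i)))
    }), paste0("site", site, recycle0 = TRUE))
  )
  # order event labels lexicographically for a deterministic product
  if (length(outcomes)) outcomes <- outcomes[order(names(outcomes))]
  if (!length(outcomes)) {
    grid <- data.frame(row.names = 1L)  # empty product: one constitutive spec
  } else {
    grid <- unique(rev(expand.grid(rev(outcomes), stringsAsFactors = FALSE,
                                   KEEP.OUT.ATTRS = FALSE)))
  }
  specs <- lapply(seq_len(nrow(grid)), function(r) {
    include <- logical(); site_choice <- character()
    for (nm in names(grid)) {
      i <- sub("^(skip|site)", "", nm)
      if (startsWith(nm, "skip")) {
        include[i] <- as.logical(grid[r, nm])
      } else {
        site_choice[i] <- as.character(grid[r, nm])
      }
    }
    # default flags for model events not enumerated: optional exons included,
    # multi-acceptor exons at their first site
    for (i in setdiff(model$optional_exons, as.integer(names(include)))) {
      include[as.character(i)] <- TRUE
    }
    for (i in setdiff(multi_acceptor_exons(model),
                      as.integer(names(site_choice)))) {
      site_choice[as.character(i)] <-
        names(exon_sites(get_exon(model, i)))[1L]
    }
    transcript_spec(include, site_choice)
  })
  specs
}

# Exons retained by a spec, with the chosen site offset for each.
spec_segments <- function(model, spec) {
  validate_spec(model, spec)
  idx <- exon_indices(model)
  keep <- vapply(idx, function(i) {
    key <- as.character(i)
    if (i %in% model$optional_exons) spec$include[[key]] else TRUE
  }, logical(1))
  used <- idx[keep]
  data.frame(
    exon = used,
    site = vapply(used, function(i) {
      key <- as.character(i)
      if (key %in% names(spec$site_choice)) spec$site_choice[[key]] else ""
    }, character(1)),
    offset = vapply(used, function(i) {
      key <- as.character(i)
      s <- if (key %in% names(spec$site_choice)) spec$site_choice[[key]] else NULL
      site_offset(model, i, s)
    }, integer(1)),
    stringsAsFactors = FALSE
  )
}

#' Splice a transcript from a gene model and a transcript spec
#'
#' Concatenates the retained exon sequences, trimming each multi-acceptor exon
#' to start at its chosen acceptor offset, and records the 0-based transcript
#' coordinate of every exon-exon junction (the first base of the downstream
#' exon's retained part).
#'
#' @inheritParams enumerate_transcripts
#' @param spec a [transcript_spec()] valid for `model`.
#' @return object of class `spliced_transcript`: list with `sequence`
#'   (character), `junctions` (integer, 0-based), and `segments` (data.frame
#'   exon/site/offset/start/length describing each retained exon).
#' @export
splice_transcript <- function(model, spec) {
  seg <- spec_segments(model, spec)
  pieces <- vapply(seq_len(nrow(seg)), function(r) {
    e <- get_exon(model, seg$exon[r])
    substring(e$sequence, seg$offset[r] + 1L)
  }, character(1))
  len <- nchar(pieces)
  starts <- cumsum(c(0L, len[-length(len)]))
  seg$start <- as.integer(starts)
  seg$length <- as.integer(len)
  structure(
    list(sequence = paste(pieces, collapse = ""),
         junctions = as.integer(starts[-1L]),
         segments = seg),
    class = "spliced_transcript"
  )
}

#' @export
print.spliced_transcript <- function(x, ...) {
  cat(sprintf("<spliced_transcript> %d nt, exons %s, %d junction(s)\n",
              nchar(x$sequence),
              paste(paste0(x$segments$exon, x$segments$site), collapse = "-"),
              length(x$junctions)))
  invisible(x)
}

#' Annotate the open reading frame of a spliced transcript
#'
#' Scans codons from the start codon to the first in-frame stop and classifies
#' it under the exon-junction-complex rule for nonsense-mediated decay: the
#' stop is a premature termination codon (PTC) when it lies more than
#' `ejc_rule_nt` nucleotides upstream of the last exon-exon junction.
#' `frame_shifted` reports whether the cumulative length of coding sequence
#' skipped or trimmed upstream of the stop (relative to the full-length
#' transcript) is not a multiple of 3.
#'
#' @inheritParams splice_transcript
#' @param ejc_rule_nt the NMD distance rule in nucleotides (default 50).
#' @return object of class `orf_annotation`: list with `has_stop`, `stop_exon`,
#'   `stop_offset` (0-based transcript coordinate of the stop codon's first
#'   base), `is_ptc`, `frame_shifted`.
#' @export
annotate_orf <- function(model, spec, ejc_rule_nt = 50) {
  tx <- splice_transcript(model, spec)
  seg <- tx$segments
  # transcript coordinate of the start codon
  sc_exon <- model$start_codon[1L]; sc_off <- model$start_codon[2L]
  r <- match(sc_exon, seg$exon)
  if (is.na(r)) stop("spliced transcript does not contain the start-codon exon",
                     call. = FALSE)
  if (sc_off < seg$offset[r]) {
    stop("start codon removed by the chosen acceptor site", call. = FALSE)
  }
  start <- seg$start[r] + (sc_off - seg$offset[r])
  n <- nchar(tx$sequence)
  if (n - start < 3L) stop("transcript too short to translate", call. = FALSE)
  if (substr(tx$sequence, start + 1L, start + 3L) != "ATG") {
    warning("sequence at the annotated start is not ATG; scanning anyway")
  }
  codon_starts <- seq.int(start, n - 3L, by = 3L)
  codons <- substring(tx$sequence, codon_starts + 1L, codon_starts + 3L)
  hit <- which(codons %in% STOP_CODONS)
  last_junction <- if (length(tx$junctions)) tx$junctions[length(tx$junctions)] else 0L
  if (!length(hit)) {
    return(structure(list(has_stop = FALSE, stop_exon = NA_integer_,
                          stop_offset = NA_integer_, is_ptc = NA,
                          frame_shifted = frame_shift(model, seg, Inf)),
                     class = "orf_annotation"))
  }
  stop_offset <- codon_starts[hit[1L]]
  stop_row <- findInterval(stop_offset, seg$start)
  stop_exon <- seg$exon[stop_row]
  stop_end <- stop_offset + 3L
  is_ptc <- (last_junction - stop_end) > ejc_rule_nt
  structure(
    list(has_stop = TRUE, stop_exon = as.integer(stop_exon),
         stop_offset = as.integer(stop_offset), is_ptc = is_ptc,
         frame_shifted = frame_shift(model, seg, stop_exon)),
    class = "orf_annotation"
  )
}

# Net frame displacement at exons up to `upto_exon` (skipped optional exons
# and acceptor-site trims), relative to the full-length transcript.
frame_shift <- function(model, seg, upto_exon) {
  idx <- exon_indices(model)
  shift <- 0L
  for (i in idx) {
    if (i > upto_exon) break
    if (i %in% model$optional_exons && !(i %in% seg$exon)) {
      shift <- shift + nchar(get_exon(model, i)$sequence)
    } else if (i %in% seg$exon) {
      shift <- shift + seg$offset[match(i, seg$exon)]
    }
  }
  (shift %% 3L) != 0L
}

#' @export
print.orf_annotation <- function(x, ...) {
  if (!x$has_stop) {
    cat("<orf_annotation> no in-frame stop before transcript end\n")
  } else {
    cat(sprintf("<orf_annotation> stop in exon %d @ %d | PTC: %s | frame shift: %s\n",
                x$stop_exon, x$stop_offset, x$is_ptc, x$frame_shifted))
  }
  invisible(x)
}
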