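# Gene model: exon structure with optional exons and multi-acceptor exons.
#
# Coordinates are 0-based, half-open everywhere internally; exon numbering
# keeps the conventional 1-based labels (exon 1, exon 12, ...) for display.

#' Construct a single exon of a gene model
#'
#' An exon carries its nucleotide sequence and, for exons with alternative 3'
#' splice-acceptor sites, a map from site label to the 0-based offset within
#' the exon where that acceptor variant begins. Constitutive exons carry no
#' explicit map (the single implicit site starts at offset 0).
#'
#' @param index integer exon number (1-based display label).
#' @param sequence nucleotide string over `{A,C,G,T}`.
#' @param acceptor_offsets named integer vector, e.g. `c(A = 0, B = 21, C = 33)`;
#'   offsets must be strictly increasing in label order and all `< nchar(sequence)`.
#' @return an object of class `exon_model`.
#' @export
exon_model <- function(index, sequence, acceptor_offsets = NULL) {
  stopifnot(length(index) == 1L, index == as.integer(index), index >= 1L)
  assert_dna(sequence, sprintf("exon %d sequence", index))
  if (!is.null(acceptor_offsets) && length(acceptor_offsets)) {
    labs <- names(acceptor_offsets)
    if (is.null(labs) || anyNA(labs) || any(!nzchar(labs)) || anyDuplicated(labs)) {
      stop("acceptor_offsets must have unique non-empty labels", call. = FALSE)
    }
    if (is.unsorted(labs, strictly = TRUE)) {
      stop("acceptor site labels must be in increasing order", call. = FALSE)
    }
    off <- as.integer(acceptor_offsets)
    if (is.unsorted(off, strictly = TRUE) || any(off < 0L) ||
        any(off >= nchar(sequence))) {
      stop("acceptor offsets must be strictly increasing, >= 0 and < exon length",
           call. = FALSE)
    }
    acceptor_offsets <- stats::setNames(off, labs)
  } else {
    acceptor_offsets <- NULL
  }
  structure(
    list(index = as.integer(index), sequence = sequence,
         acceptor_offsets = acceptor_offsets),
    class = "exon_model"
  )
}

#' Construct a gene model
#'
#' @param name gene name (display only).
#' @param exons list of [exon_model()] objects with unique, ascending indices.
#' @param optional_exons integer vector of exon indices that may be skipped.
#' @param start_codon integer pair `c(exon, offset)`: exon index and 0-based
#'   offset within that exon of the translation start.
#' @return an object of class `gene_model`.
#' @export
gene_model <- function(name, exons, optional_exons = integer(),
                       start_codon = c(1L, 0L)) {
  stopifnot(is.list(exons), length(exons) >= 1L,
            all(vapply(exons, inherits, logical(1), "exon_model")))
  idx <- vapply(exons, `[[`, integer(1), "index")
  if (anyDuplicated(idx) || is.unsorted(idx, strictly = TRUE)) {
    stop("exon indices must be unique and ascending", call. = FALSE)
  }
  optional_exons <- as.integer(optional_exons)
  if (!all(optional_exons %in% idx)) {
    stop("optional_exons must be a subset of the model's exon indices", call. = FALSE)
  }
  start_codon <- as.integer(start_codon)
  stopifnot(length(start_codon) == 2L)
  se <- match(start_codon[1L], idx)
  if (is.na(se)) stop("start codon exon not present in model", call. = FALSE)
  if (start_codon[2L] < 0L ||
      start_codon[2L] > nchar(exons[[se]]$sequence) - 3L) {
    stop("start codon offset outside its exon", call. = FALSE)
  }
  structure(
    list(name = name, exons = stats::setNames(exons, paste0("exon", idx)),
         optional_exons = optional_exons, start_codon = start_codon),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  lens <- vapply(x$exons, function(e) nchar(e$sequence), integer(1))
  cat(sprintf("<gene_model> %s: %d exons, %s nt total\n", x$name,
              length(x$exons), format(sum(lens), big.mark = ",")))
  multi <- Filter(function(e) length(e$acceptor_offsets) > 1L, x$exons)
  if (length(x$optional_exons)) {
    cat("  optional exons:", paste(x$optional_exons, collapse = ", "), "\n")
  }
  for (e in multi) {
    cat(sprintf("  exon %d acceptor sites: %s\n", e$index,
                paste(sprintf("%s@%d", names(e$acceptor_offsets),
                              e$acceptor_offsets), collapse = " ")))
  }
  invisible(x)
}

exon_indices <- function(model) {
  vapply(model$exons, `[[`, integer(1), "index")
}

get_exon <- function(model, index) {
  i <- match(index, exon_indices(model))
  if (is.na(i)) stop("exon ", index, " not present in gene model", call. = FALSE)
  model$exons[[i]]
}

# Named offset map of an exon's acceptor sites; constitutive exons expose the
# single implicit site with empty label "" at offset 0.
exon_sites <- function(exon) {
  if (is.null(exon$acceptor_offsets)) stats::setNames(0L, "") else exon$acceptor_offsets
}

is_multi_acceptor <- function(exon) length(exon$acceptor_offsets %||% integer()) > 1L

multi_acceptor_exons <- function(model) {
  idx <- exon_indices(model)
  idx[vapply(model$exons, is_multi_acceptor, logical(1))]
}

site_offset <- function(model, index, site) {
  exon <- get_exon(model, index)
  sites <- exon_sites(exon)
  if (is.null(site) || !nzchar(site)) {
    if (length(sites) > 1L) {
      stop("exon ", index, " has multiple acceptor sites; specify one of ",
           paste(names(sites), collapse = "/"), call. = FALSE)
    }
    return(unname(sites[1L]))
  }
  if (!site %in% names(sites)) {
    stop("exon ", index, " has no acceptor site '", site, "'", call. = FALSE)
  }
  unname(sites[[site]])
}

#' Write / read a gene model as JSON
#'
#' The on-disk form records name, exons (index, sequence, acceptor offsets),
#' optional exons and the start codon.
#'
#' @param model a [gene_model()].
#' @param path file path.
#' @return `read_gene_model` returns a `gene_model`; `write_gene_model`
#'   returns `path` invisibly.
#' @export
write_gene_model <- function(model, path) {
  obj <- list(
    name = model$name,
    exons = lapply(model$exons, function(e) {
      x <- list(index = e$index, sequence = e$sequence)
      if (!is.null(e$acceptor_offsets)) {
        x$acceptor_offsets <- as.list(e$acceptor_offsets)
      }
      x
    }),
    optional_exons = model$optional_exons,
    start_codon = model$start_codon
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_gene_model
#' @export
read_gene_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  exons <- lapply(obj$exons, function(e) {
    ao <- if (!is.null(e$acceptor_offsets)) unlist(e$acceptor_offsets) else NULL
    exon_model(e$index, e$sequence, ao)
  })
  gene_model(obj$name, exons,
             optional_exons = unlist(obj$optional_exons) %||% integer(),
             start_codon = unlist(obj$start_codon))
}

#' Export exon sequences as FASTA
#'
#' One record per exon, headers `exon<N>`.
#'
#' @inheritParams write_gene_model
#' @export
gene_to_fasta <- function(model, path) {
  seqs <- Biostrings::DNAStringSet(
    vapply(model$exons, `[[`, character(1), "sequence"))
  names(seqs) <- paste0("exon", exon_indices(model))
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}
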