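#' Construct a typing locus
#'
#' A locus is one housekeeping-gene fragment of an MLST scheme: a name, the
#' PCR/sequencing primer pair that delimits the amplicon, and the expected
#' amplicon size. An optional reference genome span can be recorded for
#' documentation; it is never used in computation.
#'
#' @param name Short locus name (e.g. \code{"recA"}); unique within a scheme.
#' @param forward_primer,reverse_primer Primer sequences, uppercase IUPAC DNA.
#'   The reverse primer is given 5'->3' on the opposite strand, as printed in
#'   primer tables.
#' @param amplicon_length Expected amplicon size in bp (> 0), primers included.
#' @param reference_span Optional integer pair, 1-based inclusive genome
#'   coordinates of the source gene (documentation only).
#' @return An object of class \code{mlst_locus}.
#' @export
locus <- function(name, forward_primer, reverse_primer, amplicon_length,
                  reference_span = NULL) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    mlst_stop("locus name must be a non-empty string", "mlst_format_error")
  }
  for (p in list(forward = forward_primer, reverse = reverse_primer)) {
    if (!is.character(p) || length(p) != 1L || !nzchar(p) || !is_iupac(p)) {
      mlst_stop(sprintf("locus '%s': primer is empty or contains non-IUPAC characters",
                        name), "mlst_format_error")
    }
  }
  amplicon_length <- as.integer(amplicon_length)
  if (is.na(amplicon_length) || amplicon_length <= 0L) {
    mlst_stop(sprintf("locus '%s': amplicon_length must be a positive integer", name),
              "mlst_format_error")
  }
  if (!is.null(reference_span)) {
    reference_span <- as.integer(reference_span)
    stopifnot(length(reference_span) == 2L, all(reference_span >= 1L))
  }
  structure(list(name = name,
                 forward_primer = forward_primer,
                 reverse_primer = reverse_primer,
                 amplicon_length = amplicon_length,
                 reference_span = reference_span),
            class = "mlst_locus")
}

#' Construct an MLST scheme
#'
#' A scheme is an ordered set of loci; the order fixes the column order of
#' allelic profiles and of every table the toolkit writes.
#'
#' @param loci List of \code{\link{locus}} objects (at least 2, distinct names).
#' @param name Scheme name.
#' @return An object of class \code{mlst_scheme}.
#' @export
scheme <- function(loci, name = "unnamed") {
  if (length(loci) < 2L) {
    mlst_stop("a scheme needs at least 2 loci", "mlst_format_error")
  }
  stopifnot(all(vapply(loci, inherits, logical(1), "mlst_locus")))
  nms <- vapply(loci, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    mlst_stop(sprintf("duplicate locus name '%s' in scheme",
                      nms[duplicated(nms)][1]), "mlst_format_error")
  }
  names(loci) <- nms
  structure(list(name = name, loci = loci), class = "mlst_scheme")
}

#' @export
print.mlst_scheme <- function(x, ...) {
  cat(sprintf("MLST scheme '%s': %d loci\n", x$name, length(x$loci)))
  for (l in x$loci) {
    cat(sprintf("  %-6s amplicon %4d bp  F:%s R:%s\n",
                l$name, l$amplicon_length, l$forward_primer, l$reverse_primer))
  }
  invisible(x)
}

#' Locus names of a scheme, in profile column order
#' @param s An \code{mlst_scheme}.
#' @return Character vector of locus names.
#' @export
locus_names <- function(s) {
  stopifnot(inherits(s, "mlst_scheme"))
  names(s$loci)
}

#' Read a scheme definition file
#'
#' The on-disk format is a small key/value text file: top-level
#' \code{name: ...}, then one block per locus started by \code{locus: <name>}
#' with indented \code{forward_primer}, \code{reverse_primer},
#' \code{amplicon_length} and optional \code{reference_span: a-b} keys.
#' Loci appear in profile column order.
#'
#' @param path Path to the scheme file.
#' @return An \code{mlst_scheme}.
#' @seealso \code{\link{write_scheme}}, \code{\link{default_scheme}}
#' @export
read_scheme <- function(path) {
  if (!file.exists(path)) {
    mlst_stop(sprintf("scheme file '%s' does not exist", path), "mlst_format_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  scheme_name <- "unnamed"
  blocks <- list()
  current <- NULL
  flush <- function(cur, blocks) {
    if (is.null(cur)) return(blocks)
    blocks[[length(blocks) + 1L]] <- cur
    blocks
  }
  for (ln in lines) {
    m <- regmatches(ln, regexec("^\\s*([A-Za-z_]+)\\s*:\\s*(.*\\S)\\s*$", ln))[[1]]
    if (length(m) == 0L) {
      mlst_stop(sprintf("cannot parse scheme line: '%s'", ln), "mlst_format_error")
    }
    key <- m[2]; val <- m[3]
    if (key == "name") {
      scheme_name <- val
    } else if (key == "locus") {
      blocks <- flush(current, blocks)
      current <- list(name = val)
    } else {
      if (is.null(current)) {
        mlst_stop(sprintf("key '%s' appears before any locus block", key),
                  "mlst_format_error")
      }
      current[[key]] <- val
    }
  }
  blocks <- flush(current, blocks)
  loci <- lapply(blocks, function(b) {
    for (req in c("forward_primer", "reverse_primer", "amplicon_length")) {
      if (is.null(b[[req]])) {
        mlst_stop(sprintf("locus '%s': missing field '%s'", b$name, req),
                  "mlst_format_error")
      }
    }
    span <- NULL
    if (!is.null(b$reference_span)) {
      span <- as.integer(strsplit(b$reference_span, "-", fixed = TRUE)[[1]])
    }
    locus(b$name, toupper(b$forward_primer), toupper(b$reverse_primer),
          as.integer(b$amplicon_length), span)
  })
  scheme(loci, name = scheme_name)
}

#' Write a scheme definition file
#' @param s An \code{mlst_scheme}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_scheme <- function(s, path) {
  stopifnot(inherits(s, "mlst_scheme"))
  out <- c(sprintf("name: %s", s$name))
  for (l in s$loci) {
    out <- c(out,
             sprintf("locus: %s", l$name),
             sprintf("  forward_primer: %s", l$forward_primer),
             sprintf("  reverse_primer: %s", l$reverse_primer),
             sprintf("  amplicon_length: %d", l$amplicon_length),
             if (!is.null(l$reference_span)) {
               sprintf("  reference_span: %d-%d",
                       l$reference_span[1], l$reference_span[2])
             })
  }
  writeLines(out, path)
  invisible(path)
}

#' The bundled Leuconostoc lactis eight-locus scheme
#'
#' Eight housekeeping-gene fragments (carB, groEL, murC, pheS, pyrG, recA,
#' rpoB, uvrC) with their published primer pairs and amplicon sizes, loci in
#' alphabetical order. The amplicon sizes sum to 5,325 bp.
#'
#' @return An \code{mlst_scheme} with 8 loci.
#' @export
default_scheme <- function() {
  path <- system.file("extdata", "leuconostoc_lactis.scheme",
                      package = "mlstkit", mustWork = TRUE)
  read_scheme(path)
}
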