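#' Trim a raw sequence to a scheme locus fragment
#'
#' In-silico analogue of the PCR + sequencing step: locate the forward primer
#' and the reverse complement of the reverse primer within a finished
#' sequence, and return the fragment between them in the scheme's forward
#' orientation. If the primers are not found in the given orientation the
#' reverse complement of the input is searched. By default the primer sites
#' themselves are removed (sequencing-primer regions are unreliable);
#' \code{keep_primers = TRUE} retains them.
#'
#' @param sequence A/C/G/T (or IUPAC) string, at least as long as the expected
#'   fragment.
#' @param locus An \code{mlst_locus}.
#' @param max_primer_mismatches Mismatch budget per primer (default 1).
#' @param length_tolerance Maximum relative deviation of the trimmed fragment
#'   from \code{amplicon_length - len(fwd) - len(rev)} (default 0.10); beyond
#'   it an error of class \code{mlst_length_error} ("fragment length anomaly")
#'   is raised. \code{Inf} disables the check.
#' @param keep_primers Retain the primer sites in the returned fragment.
#' @return The trimmed fragment (character scalar).
#' @export
trim_to_locus <- function(sequence, locus, max_primer_mismatches = 1L,
                          length_tolerance = 0.10, keep_primers = FALSE) {
  stopifnot(inherits(locus, "mlst_locus"))
  sequence <- toupper(sequence)
  fwd <- locus$forward_primer
  rev_rc <- revcomp(locus$reverse_primer)
  hit <- locate_fragment(sequence, fwd, rev_rc, max_primer_mismatches, keep_primers)
  if (is.null(hit)) {
    hit <- locate_fragment(revcomp(sequence), fwd, rev_rc,
                           max_primer_mismatches, keep_primers)
  }
  if (is.null(hit)) {
    mlst_stop(sprintf("locus '%s': primer not located within %d mismatch(es) in either orientation",
                      locus$name, max_primer_mismatches), "mlst_primer_error")
  }
  primer_bp <- if (keep_primers) 0L else nchar(fwd) + nchar(locus$reverse_primer)
  expected <- locus$amplicon_length - primer_bp
  if (is.finite(length_tolerance) &&
      abs(nchar(hit) - expected) > length_tolerance * expected) {
    mlst_stop(sprintf("locus '%s': fragment length anomaly (%d bp vs expected %d)",
                      locus$name, nchar(hit), expected), "mlst_length_error")
  }
  hit
}

# Find fwd ... rev_rc in `x` and return the enclosed fragment, or NULL.
locate_fragment <- function(x, fwd, rev_rc, max_mm, keep_primers) {
  subj <- Biostrings::DNAString(x)
  f <- Biostrings::matchPattern(fwd, subj, max.mismatch = max_mm, fixed = FALSE)
  if (length(f) == 0L) return(NULL)
  r <- Biostrings::matchPattern(rev_rc, subj, max.mismatch = max_mm, fixed = FALSE)
  if (length(r) == 0L) return(NULL)
  f_start <- Biostrings::start(f)[1]
  f_end <- Biostrings::end(f)[1]
  r_ok <- Biostrings::start(r) > f_end
  if (!any(r_ok)) return(NULL)
  i <- which(r_ok)[sum(r_ok)]  # right-most hit after the forward primer
  r_start <- Biostrings::start(r)[i]
  r_end <- Biostrings::end(r)[i]
  if (keep_primers) {
    as.character(subj[f_start:r_end])
  } else if (r_start - f_end >= 2L) {
    as.character(subj[(f_end + 1L):(r_start - 1L)])
  } else {
    NULL
  }
}

#' Assign an allele number to a locus fragment
#'
#' Exact sequence identity against the database. In open mode a novel
#' fragment is appended as the next free allele number; in closed mode it is
#' signalled without touching the database. IUPAC ambiguity codes in the
#' fragment are a hard error: alleles are exact-sequence identities.
#'
#' @param fragment Trimmed A/C/G/T fragment.
#' @param locus_name Locus name in \code{db}.
#' @param db An \code{mlst_allele_db}.
#' @param mode \code{"closed"} or \code{"open"}.
#' @return List with \code{allele} (integer; \code{NA} for a novel fragment in
#'   closed mode), \code{novel} (logical) and \code{db} (possibly extended).
#' @export
assign_allele <- function(fragment, locus_name, db, mode = c("closed", "open")) {
  mode <- match.arg(mode)
  stopifnot(inherits(db, "mlst_allele_db"))
  if (!is_acgt(fragment)) {
    mlst_stop(sprintf("locus '%s': fragment contains ambiguity codes or non-ACGT characters",
                      locus_name), "mlst_ambiguity_error")
  }
  known <- db$alleles[[locus_name]] %||% character(0)
  if (length(known) && nchar(fragment) != nchar(known[1])) {
    mlst_stop(sprintf("locus '%s': fragment length %d conflicts with allele length %d (indels are out of model)",
                      locus_name, nchar(fragment), nchar(known[1])),
              "mlst_length_error")
  }
  hit <- match(fragment, known)
  if (!is.na(hit)) {
    return(list(allele = as.integer(hit), novel = FALSE, db = db))
  }
  if (mode == "closed") {
    return(list(allele = NA_integer_, novel = TRUE, db = db))
  }
  db$alleles[[locus_name]] <- c(known, fragment)
  list(allele = length(known) + 1L, novel = TRUE, db = db)
}

#' Type a batch of isolates from per-locus FASTA files
#'
#' End-to-end in-silico MLST: per locus, read the FASTA, trim each isolate's
#' sequence to the scheme fragment (unless \code{trim = FALSE}, for inputs
#' that are already exact fragments), assign allele numbers, then assign STs.
#' Isolates that fail at any locus (primer not located, ambiguity code,
#' length conflict, missing record, novel allele in closed mode) are excluded
#' from the profile table and listed in the report.
#'
#' @param fasta_dir Directory containing \code{<locus>.fasta} per scheme locus
#'   (isolate ids in the headers), or a named list of such paths.
#' @param s An \code{mlst_scheme}.
#' @param db An \code{mlst_allele_db} (may be empty).
#' @param st_definitions Optional data.frame of known ST definitions.
#' @param mode \code{"open"} (novel alleles/STs are numbered) or
#'   \code{"closed"}.
#' @param max_primer_mismatches,length_tolerance,trim Passed to
#'   \code{\link{trim_to_locus}}; \code{trim = FALSE} skips primer trimming.
#' @param metadata Optional data.frame with columns \code{isolate} and any of
#'   \code{region}, \code{source}.
#' @param sequences Optional named list (locus -> named character vector of
#'   sequences) used instead of reading \code{fasta_dir}.
#' @return List with \code{profiles} (an \code{mlst_profiles} of successfully
#'   typed isolates), \code{report} (data.frame: isolate, locus, status,
#'   allele), \code{failed} (character vector of excluded isolates) and
#'   \code{db} (the possibly extended allele database).
#' @export
type_batch <- function(fasta_dir = NULL, s, db = allele_database(),
                       st_definitions = NULL, mode = c("open", "closed"),
                       max_primer_mismatches = 1L, length_tolerance = 0.10,
                       trim = TRUE, metadata = NULL, sequences = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(s, "mlst_scheme"))
  loci <- locus_names(s)
  seqs <- list()
  isolates <- character(0)
  if (is.null(sequences)) {
    paths <- if (is.list(fasta_dir)) {
      fasta_dir
    } else {
      stats::setNames(file.path(fasta_dir, paste0(loci, ".fasta")), loci)
    }
    for (loc in loci) {
      if (is.null(paths[[loc]]) || !file.exists(paths[[loc]])) {
        mlst_stop(sprintf("no FASTA for locus '%s'", loc), "mlst_format_error")
      }
      seqs[[loc]] <- suppressWarnings(read_locus_fasta(paths[[loc]], s$loci[[loc]]))
      isolates <- union(isolates, names(seqs[[loc]]))
    }
  } else {
    if (!all(loci %in% names(sequences))) {
      mlst_stop("'sequences' must cover every scheme locus", "mlst_format_error")
    }
    seqs <- sequences[loci]
    isolates <- Reduce(union, lapply(seqs, names))
  }
  calls <- matrix(NA_integer_, nrow = length(isolates), ncol = length(loci),
                  dimnames = list(isolates, loci))
  report <- vector("list", length(isolates) * length(loci))
  k <- 0L
  for (loc in loci) {
    for (iso in isolates) {
      k <- k + 1L
      status <- "matched"; allele <- NA_integer_
      raw <- seqs[[loc]][iso]
      if (is.na(raw)) {
        status <- "missing"
      } else {
        res <- tryCatch({
          frag <- if (trim) {
            trim_to_locus(raw, s$loci[[loc]], max_primer_mismatches,
                          length_tolerance)
          } else toupper(raw)
          assign_allele(frag, loc, db, mode)
        }, mlst_error = function(e) e)
        if (inherits(res, "error")) {
          status <- if (inherits(res, "mlst_primer_error")) "primer_not_located"
                    else if (inherits(res, "mlst_ambiguity_error")) "ambiguous"
                    else if (inherits(res, "mlst_length_error")) "length_conflict"
                    else "failed"
        } else if (is.na(res$allele)) {
          status <- "novel"
        } else {
          db <- res$db
          allele <- res$allele
          if (res$novel) status <- "novel_assigned"
          calls[iso, loc] <- allele
        }
      }
      report[[k]] <- data.frame(isolate = iso, locus = loc,
                                status = status, allele = allele)
    }
  }
  report <- do.call(rbind, report)
  ok <- rownames(calls)[stats::complete.cases(calls)]
  failed <- setdiff(isolates, ok)
  prof <- data.frame(isolate = ok)
  for (loc in loci) prof[[loc]] <- calls[ok, loc]
  if (!is.null(metadata)) {
    m <- metadata[match(ok, metadata$isolate), , drop = FALSE]
    if ("region" %in% names(m)) prof$region <- m$region
    if ("source" %in% names(m)) prof$source <- m$source
  }
  pt <- profile_table(prof, loci, st_definitions = st_definitions)
  if (nrow(prof)) pt <- assign_sts(pt, mode = mode)
  list(profiles = pt, report = report, failed = failed, db = db)
}
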