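#' Read per-isolate sequences for one locus from FASTA
#'
#' Headers carry the isolate identifier as the first whitespace-delimited
#' token. Sequences are uppercased and U is mapped to T. IUPAC ambiguity
#' codes are accepted with a warning (they are rejected later, at allele
#' assignment); any other character is an error naming the record.
#'
#' @param path FASTA file.
#' @param locus Optional \code{mlst_locus}, used only to label messages.
#' @return Named character vector of sequences (names = isolate ids), in file
#'   order.
#' @export
read_locus_fasta <- function(path, locus = NULL) {
  if (!file.exists(path)) {
    mlst_stop(sprintf("FASTA file '%s' does not exist", path), "mlst_format_error")
  }
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) {
    mlst_stop(sprintf("FASTA file '%s' contains no records", path),
              "mlst_format_error")
  }
  ids <- vapply(strsplit(names(set), "\\s+"), `[[`, character(1), 1L)
  seqs <- chartr("u", "t", toupper(as.character(set)))
  seqs <- chartr("U", "T", seqs)
  bad <- !is_iupac(seqs)
  if (any(bad)) {
    mlst_stop(sprintf("record '%s'%s contains non-nucleotide characters",
                      ids[bad][1],
                      if (is.null(locus)) "" else sprintf(" (locus %s)", locus$name)),
              "mlst_format_error")
  }
  ambig <- !is_acgt(seqs)
  if (any(ambig)) {
    mlst_warn(sprintf("%d record(s) contain IUPAC ambiguity codes (first: '%s'); they will be rejected at allele assignment",
                      sum(ambig), ids[ambig][1]))
  }
  names(seqs) <- ids
  seqs
}

write_fasta <- function(seqs, path, width = 70L) {
  set <- Biostrings::BStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Create an allele database
#'
#' Per locus, a vector of unique equal-length A/C/G/T sequences; position i is
#' allele number i. Numbers are authoritative: reading a database never
#' renumbers.
#'
#' @param alleles Named list (names = locus names) of character vectors of
#'   sequences; element i of a vector is allele i.
#' @return An object of class \code{mlst_allele_db}.
#' @export
allele_database <- function(alleles = list()) {
  for (loc in names(alleles)) {
    seqs <- alleles[[loc]]
    if (length(seqs) == 0L) next
    if (!all(is_acgt(seqs))) {
      mlst_stop(sprintf("locus '%s': allele sequences must be A/C/G/T only", loc),
                "mlst_format_error")
    }
    if (length(unique(nchar(seqs))) != 1L) {
      mlst_stop(sprintf("locus '%s': alleles differ in length (indels are out of model)",
                        loc), "mlst_length_error")
    }
    if (anyDuplicated(seqs)) {
      mlst_stop(sprintf("locus '%s': duplicate allele sequences", loc),
                "mlst_format_error")
    }
  }
  structure(list(alleles = lapply(alleles, unname)), class = "mlst_allele_db")
}

#' @export
print.mlst_allele_db <- function(x, ...) {
  cat("Allele database:\n")
  if (length(x$alleles) == 0L) cat("  (empty)\n")
  for (loc in names(x$alleles)) {
    s <- x$alleles[[loc]]
    cat(sprintf("  %-8s %3d allele(s), %d bp\n", loc, length(s),
                if (length(s)) nchar(s[1]) else 0L))
  }
  invisible(x)
}

#' Read / write an allele database as per-locus FASTA files
#'
#' Files are named \code{<locus>.fasta} in \code{dir}; records are named
#' \code{<locus>_<number>} (PubMLST convention). Allele numbers are taken from
#' the headers and must form 1..k without gaps.
#'
#' @param dir Directory of per-locus FASTA files.
#' @param s An \code{mlst_scheme}; only its loci are read.
#' @return \code{read_allele_db}: an \code{mlst_allele_db}.
#' @export
read_allele_db <- function(dir, s) {
  stopifnot(inherits(s, "mlst_scheme"))
  alleles <- list()
  for (loc in locus_names(s)) {
    path <- file.path(dir, paste0(loc, ".fasta"))
    if (!file.exists(path)) next
    seqs <- read_locus_fasta(path)
    m <- regmatches(names(seqs),
                    regexec(sprintf("^%s_([0-9]+)$", loc), names(seqs)))
    nums <- vapply(m, function(x) {
      if (length(x) < 2L) NA_integer_ else as.integer(x[2])
    }, integer(1))
    if (anyNA(nums)) {
      mlst_stop(sprintf("locus '%s': allele header '%s' is not of the form %s_<number>",
                        loc, names(seqs)[is.na(nums)][1], loc), "mlst_format_error")
    }
    if (!setequal(nums, seq_along(nums))) {
      mlst_stop(sprintf("locus '%s': allele numbers must form 1..%d without gaps",
                        loc, length(nums)), "mlst_format_error")
    }
    alleles[[loc]] <- unname(seqs[order(nums)])
  }
  allele_database(alleles)
}

#' @rdname read_allele_db
#' @param db An \code{mlst_allele_db} to write.
#' @return \code{write_allele_db}: \code{dir}, invisibly.
#' @export
write_allele_db <- function(db, dir) {
  stopifnot(inherits(db, "mlst_allele_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (loc in names(db$alleles)) {
    seqs <- db$alleles[[loc]]
    names(seqs) <- sprintf("%s_%d", loc, seq_along(seqs))
    write_fasta(seqs, file.path(dir, paste0(loc, ".fasta")))
  }
  invisible(dir)
}
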