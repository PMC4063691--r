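#' Construct an allelic-profile table
#'
#' The central container for typed isolates: one row per isolate with an
#' allele number per scheme locus, an optional sequence type (ST), and
#' optional region/source metadata, plus the ST definitions (unique allele
#' vector -> ST number) in force.
#'
#' @param profiles data.frame with columns \code{isolate}, one integer column
#'   per locus (in scheme order), and optionally \code{ST}, \code{region},
#'   \code{source}.
#' @param loci Character vector of locus names, in scheme column order.
#' @param st_definitions Optional data.frame with columns \code{ST} and the
#'   loci; defaults to the definitions implied by the profiles' ST column.
#' @return An object of class \code{mlst_profiles}.
#' @export
profile_table <- function(profiles, loci, st_definitions = NULL) {
  stopifnot(is.data.frame(profiles), is.character(loci), length(loci) >= 2L)
  if (!"isolate" %in% names(profiles)) {
    mlst_stop("profiles need an 'isolate' column", "mlst_format_error")
  }
  missing <- setdiff(loci, names(profiles))
  if (length(missing)) {
    mlst_stop(sprintf("profiles are missing locus column(s): %s",
                      paste(missing, collapse = ", ")), "mlst_format_error")
  }
  for (loc in loci) {
    v <- profiles[[loc]]
    if (nrow(profiles) && (anyNA(suppressWarnings(as.integer(v))) ||
                           any(as.integer(v) < 1L))) {
      mlst_stop(sprintf("locus '%s': allele numbers must be integers >= 1", loc),
                "mlst_format_error")
    }
    profiles[[loc]] <- as.integer(v)
  }
  for (opt in c("ST", "region", "source")) {
    if (!opt %in% names(profiles)) {
      profiles[[opt]] <- rep(if (opt == "ST") NA_integer_ else NA_character_,
                             nrow(profiles))
    }
  }
  profiles$ST <- as.integer(profiles$ST)
  profiles <- profiles[, c("isolate", loci, "ST", "region", "source")]
  if (is.null(st_definitions)) {
    st_definitions <- derive_st_definitions(profiles, loci)
  } else {
    stopifnot(all(c("ST", loci) %in% names(st_definitions)))
    st_definitions <- st_definitions[, c("ST", loci)]
    st_definitions$ST <- as.integer(st_definitions$ST)
    rownames(st_definitions) <- NULL
  }
  validate_st_consistency(profiles, st_definitions, loci)
  structure(list(loci = loci, profiles = profiles,
                 st_definitions = st_definitions),
            class = "mlst_profiles")
}

profile_key <- function(mat) {
  apply(mat, 1L, paste, collapse = "-")
}

derive_st_definitions <- function(profiles, loci) {
  typed <- profiles[!is.na(profiles$ST), , drop = FALSE]
  if (nrow(typed) == 0L) {
    out <- as.data.frame(c(list(ST = integer(0)),
                           stats::setNames(rep(list(integer(0)), length(loci)), loci)))
    return(out)
  }
  defs <- unique(typed[, c("ST", loci)])
  defs <- defs[order(defs$ST), , drop = FALSE]
  rownames(defs) <- NULL
  defs
}

validate_st_consistency <- function(profiles, defs, loci) {
  if (nrow(defs)) {
    if (anyDuplicated(defs$ST)) {
      mlst_stop("an ST number maps to more than one allele vector", "mlst_format_error")
    }
    if (anyDuplicated(profile_key(as.matrix(defs[, loci])))) {
      mlst_stop("identical allele vectors map to different STs", "mlst_format_error")
    }
    if (!setequal(defs$ST, seq_len(max(defs$ST)))) {
      mlst_stop("ST numbers must form 1..m without gaps", "mlst_format_error")
    }
  }
  typed <- profiles[!is.na(profiles$ST), , drop = FALSE]
  if (nrow(typed)) {
    key <- profile_key(as.matrix(typed[, loci]))
    dkey <- profile_key(as.matrix(defs[, loci]))
    st_of <- defs$ST[match(key, dkey)]
    if (anyNA(st_of) || any(st_of != typed$ST)) {
      mlst_stop("a profile's ST disagrees with the ST definitions",
                "mlst_format_error")
    }
  }
}

#' @export
print.mlst_profiles <- function(x, ...) {
  n_st <- sum(!is.na(unique(x$profiles$ST)))
  cat(sprintf("Allelic profiles: %d isolate(s), %d loci, %d defined ST(s)\n",
              nrow(x$profiles), length(x$loci), nrow(x$st_definitions)))
  print(utils::head(x$profiles, 10L), row.names = FALSE)
  if (nrow(x$profiles) > 10L) cat(sprintf("  ... %d more\n", nrow(x$profiles) - 10L))
  invisible(x)
}

#' Allele-number matrix of a profile table
#' @param pt An \code{mlst_profiles}.
#' @param by \code{"isolate"} (one row per isolate) or \code{"st"} (one row
#'   per distinct ST, rownames \code{"ST<k>"}).
#' @return Integer matrix, columns = loci.
#' @export
profile_matrix <- function(pt, by = c("isolate", "st")) {
  by <- match.arg(by)
  stopifnot(inherits(pt, "mlst_profiles"))
  if (by == "isolate") {
    m <- as.matrix(pt$profiles[, pt$loci])
    rownames(m) <- pt$profiles$isolate
  } else {
    defs <- pt$st_definitions
    if (nrow(defs) == 0L) {
      mlst_stop("no STs defined; run assign_sts() first", "mlst_format_error")
    }
    m <- as.matrix(defs[, pt$loci])
    rownames(m) <- paste0("ST", defs$ST)
  }
  storage.mode(m) <- "integer"
  m
}

#' Isolate counts per ST
#' @param pt An \code{mlst_profiles}.
#' @return Named integer vector (names \code{"ST<k>"}).
#' @export
st_frequencies <- function(pt) {
  st <- pt$profiles$ST
  st <- st[!is.na(st)]
  tab <- table(factor(st, levels = sort(unique(st))))
  stats::setNames(as.integer(tab), paste0("ST", names(tab)))
}

#' Read / write allelic profiles as tab-separated text
#'
#' PubMLST-style isolate dialect: header \code{isolate<TAB>locus1..locusL}
#' followed by optional \code{ST}, \code{region}, \code{source} columns.
#' The locus columns must match the scheme's order exactly. Writing then
#' reading a table reproduces it.
#'
#' @param path TSV file.
#' @param s An \code{mlst_scheme} (fixes the expected locus columns).
#' @return \code{read_profiles_tsv}: an \code{mlst_profiles}.
#' @export
read_profiles_tsv <- function(path, s) {
  stopifnot(inherits(s, "mlst_scheme"))
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", check.names = FALSE)
  loci <- locus_names(s)
  hdr <- names(df)
  if (hdr[1] != "isolate") {
    mlst_stop("profiles TSV must start with an 'isolate' column", "mlst_format_error")
  }
  got <- hdr[seq_along(loci) + 1L]
  if (length(got) < length(loci) || !identical(got, loci)) {
    mlst_stop(sprintf("locus columns (%s) do not match the scheme order (%s)",
                      paste(got, collapse = ","), paste(loci, collapse = ",")),
              "mlst_format_error")
  }
  for (loc in loci) {
    v <- suppressWarnings(as.integer(df[[loc]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      mlst_stop(sprintf("line %d: non-integer allele '%s' at locus %s",
                        bad + 1L, df[[loc]][bad], loc), "mlst_format_error")
    }
    df[[loc]] <- v
  }
  if ("ST" %in% names(df)) df$ST <- suppressWarnings(as.integer(df$ST))
  profile_table(df, loci)
}

#' @rdname read_profiles_tsv
#' @param pt An \code{mlst_profiles} to write.
#' @return \code{write_profiles_tsv}: \code{path}, invisibly.
#' @export
write_profiles_tsv <- function(pt, path) {
  stopifnot(inherits(pt, "mlst_profiles"))
  df <- pt$profiles
  keep <- c("isolate", pt$loci,
            if (!all(is.na(df$ST))) "ST",
            if (!all(is.na(df$region))) "region",
            if (!all(is.na(df$source))) "source")
  utils::write.table(df[, keep, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read / write ST definitions (profiles dialect)
#'
#' PubMLST profiles dialect: header \code{ST<TAB>locus1..locusL}, one row per
#' defined sequence type.
#'
#' @param path TSV file.
#' @param s An \code{mlst_scheme}.
#' @return \code{read_st_definitions_tsv}: data.frame of definitions.
#' @export
read_st_definitions_tsv <- function(path, s) {
  loci <- locus_names(s)
  df <- utils::read.delim(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (names(df)[1] != "ST" || !identical(names(df)[seq_along(loci) + 1L], loci)) {
    mlst_stop("ST definitions header must be ST followed by the scheme loci in order",
              "mlst_format_error")
  }
  df$ST <- as.integer(df$ST)
  df[, c("ST", loci)]
}

#' @rdname read_st_definitions_tsv
#' @param defs data.frame of ST definitions (\code{ST} + locus columns).
#' @export
write_st_definitions_tsv <- function(defs, path) {
  utils::write.table(defs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assign sequence types to allelic profiles
#'
#' Identical allele vectors always share an ST. In open mode, vectors absent
#' from the definitions receive the next free ST number in first-encounter
#' (input) order; in closed mode an unknown vector is an error of class
#' \code{mlst_novel_st}.
#'
#' @param pt An \code{mlst_profiles} (STs may be missing).
#' @param mode \code{"open"} or \code{"closed"}.
#' @return An \code{mlst_profiles} with every ST filled in and the
#'   definitions extended (open mode).
#' @export
assign_sts <- function(pt, mode = c("open", "closed")) {
  mode <- match.arg(mode)
  stopifnot(inherits(pt, "mlst_profiles"))
  loci <- pt$loci
  defs <- pt$st_definitions
  dkey <- profile_key(as.matrix(defs[, loci, drop = FALSE]))
  dst <- defs$ST
  key <- profile_key(as.matrix(pt$profiles[, loci, drop = FALSE]))
  st <- integer(nrow(pt$profiles))
  for (i in seq_along(key)) {
    hit <- match(key[i], dkey)
    if (!is.na(hit)) {
      st[i] <- dst[hit]
    } else if (mode == "closed") {
      mlst_stop(sprintf("isolate '%s': allele vector %s matches no defined ST",
                        pt$profiles$isolate[i], key[i]), "mlst_novel_st")
    } else {
      new_st <- if (length(dst)) max(dst) + 1L else 1L
      dkey <- c(dkey, key[i])
      dst <- c(dst, new_st)
      row <- as.data.frame(c(list(ST = new_st),
                             as.list(as.integer(pt$profiles[i, loci]))))
      names(row) <- c("ST", loci)
      defs <- rbind(defs, row)
      st[i] <- new_st
    }
  }
  pt$profiles$ST <- st
  pt$st_definitions <- defs[order(defs$ST), , drop = FALSE]
  rownames(pt$st_definitions) <- NULL
  validate_st_consistency(pt$profiles, pt$st_definitions, loci)
  pt
}
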