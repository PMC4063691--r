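#' Count polymorphic (segregating) sites
#'
#' Number of alignment columns carrying at least two distinct residues, over
#' an ungapped equal-length set of sequences.
#'
#' @param seqs Character vector of equal-length A/C/G/T sequences (>= 1; a
#'   single sequence has 0 polymorphic sites).
#' @return Integer count.
#' @export
count_polymorphic_sites <- function(seqs) {
  if (length(seqs) == 0L) mlst_stop("no sequences", "mlst_format_error")
  if (!all(is_acgt(seqs))) {
    mlst_stop("sequences must be A/C/G/T only", "mlst_format_error")
  }
  if (length(seqs) == 1L) return(0L)
  m <- seq_matrix(seqs)
  sum(apply(m, 2L, function(col) length(unique(col)) > 1L))
}

#' Total SNPs across loci
#' @param stats A data.frame from \code{\link{summarize_loci}} (or anything
#'   with a \code{polymorphic_sites} column).
#' @return Integer: sum of per-locus polymorphic sites.
#' @export
total_snps <- function(stats) {
  as.integer(sum(stats$polymorphic_sites))
}

#' Pooled G+C content
#'
#' Percentage of G or C bases pooled over all input sequences (so isolates
#' weigh in proportion to their representation).
#'
#' @param seqs Character vector of A/C/G/T sequences (>= 1).
#' @return Percentage in [0, 100].
#' @export
gc_content <- function(seqs) {
  if (length(seqs) == 0L) mlst_stop("no sequences", "mlst_format_error")
  chars <- strsplit(paste(seqs, collapse = ""), "", fixed = TRUE)[[1]]
  100 * sum(chars %in% c("G", "C")) / length(chars)
}

# --- Nei-Gojobori (1986) pathway-counting dN/dS ------------------------------

# Per-codon synonymous/nonsynonymous site counts under the standard genetic
# code. Mutations creating stop codons are excluded from the possible-change
# count at a position, keeping 3 sites per codon (s + n = 3).
codon_site_table <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- Biostrings::GENETIC_CODE
    codons <- names(gc)
    s <- stats::setNames(numeric(length(codons)), codons)
    for (cod in codons) {
      if (gc[[cod]] == "*") { s[cod] <- NA_real_; next }
      total <- 0
      for (p in 1:3) {
        alts <- DNA_BASES[DNA_BASES != substr(cod, p, p)]
        muts <- vapply(alts, function(b) {
          x <- cod; substr(x, p, p) <- b; x
        }, character(1))
        aa <- gc[muts]
        valid <- aa != "*"
        if (any(valid)) total <- total + sum(aa[valid] == gc[[cod]]) / sum(valid)
      }
      s[cod] <- total
    }
    cache <<- s
    s
  }
})

split_codons <- function(x) {
  n <- nchar(x)
  substring(x, seq(1L, n, 3L), seq(3L, n, 3L))
}

# Average synonymous/nonsynonymous difference counts between two codons over
# all minimal mutational pathways; pathways through stop codons are discarded
# (all pathways are used if every one hits a stop).
codon_path_differences <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  k <- length(diffs)
  if (k == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- permutations_of(diffs)
  counts <- matrix(NA_real_, nrow = nrow(perms), ncol = 2L)
  valid <- logical(nrow(perms))
  for (r in seq_len(nrow(perms))) {
    cur <- a
    sy <- 0; ns <- 0; ok <- TRUE
    for (step in seq_len(k)) {
      p <- perms[r, step]
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      # a pathway is discarded if it passes through a stop codon
      if (gc[[nxt]] == "*" && step != k) ok <- FALSE
      if (gc[[nxt]] == gc[[cur]]) sy <- sy + 1 else ns <- ns + 1
      cur <- nxt
    }
    counts[r, ] <- c(sy, ns)
    valid[r] <- ok
  }
  use <- if (any(valid)) counts[valid, , drop = FALSE] else counts
  c(syn = mean(use[, 1]), nonsyn = mean(use[, 2]))
}

permutations_of <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1L))
  out <- NULL
  for (i in seq_len(n)) {
    rest <- permutations_of(x[-i])
    out <- rbind(out, cbind(x[i], rest))
  }
  out
}

#' Nei-Gojobori (1986) pairwise dN and dS
#'
#' Pathway-counting method: per-codon synonymous site counts are the expected
#' fraction of synonymous single-base changes (stop-codon mutations excluded
#' from the possibilities), averaged over the two sequences; differences in
#' multi-hit codons are averaged over all minimal mutational pathways; the
#' Jukes-Cantor correction \eqn{d = -3/4 \log(1 - 4p/3)} converts the
#' proportions pN and pS into distances. Codons that are stops in either
#' sequence are dropped with a warning.
#'
#' @param a,b Equal-length A/C/G/T coding sequences, length divisible by 3,
#'   read in frame from position 1.
#' @param correction \code{"jc"} (default) or \code{"none"} (return the raw
#'   proportions as dN/dS).
#' @return List with \code{dN}, \code{dS}, the uncorrected \code{pN},
#'   \code{pS}, site counts \code{N}, \code{S} and difference counts
#'   \code{Nd}, \code{Sd}.
#' @export
nei_gojobori_pair <- function(a, b, correction = c("jc", "none")) {
  correction <- match.arg(correction)
  a <- toupper(a); b <- toupper(b)
  if (nchar(a) != nchar(b)) {
    mlst_stop("sequences differ in length", "mlst_length_error")
  }
  if (nchar(a) %% 3L != 0L) {
    mlst_stop("sequence length is not a multiple of 3", "mlst_format_error")
  }
  if (!is_acgt(a) || !is_acgt(b)) {
    mlst_stop("sequences must be A/C/G/T only", "mlst_format_error")
  }
  st <- codon_site_table()
  ca <- split_codons(a); cb <- split_codons(b)
  stop_mask <- is.na(st[ca]) | is.na(st[cb])
  if (any(stop_mask)) {
    mlst_warn(sprintf("%d in-frame stop codon(s) dropped from dN/dS", sum(stop_mask)))
    ca <- ca[!stop_mask]; cb <- cb[!stop_mask]
  }
  n_codons <- length(ca)
  if (n_codons == 0L) mlst_stop("no usable codons", "mlst_format_error")
  S <- (sum(st[ca]) + sum(st[cb])) / 2
  N <- 3 * n_codons - S
  if (S <= 0) mlst_stop("zero synonymous sites", "mlst_format_error")
  Sd <- 0; Nd <- 0
  for (i in which(ca != cb)) {
    d <- codon_path_differences(ca[i], cb[i])
    Sd <- Sd + d[["syn"]]
    Nd <- Nd + d[["nonsyn"]]
  }
  pS <- Sd / S
  pN <- Nd / N
  if (correction == "none") {
    return(list(dN = pN, dS = pS, pN = pN, pS = pS, N = N, S = S, Nd = Nd, Sd = Sd))
  }
  jc <- function(p) {
    if (p >= 0.75) {
      mlst_stop(sprintf("substitution proportion %.3f >= 3/4: Jukes-Cantor correction is undefined (saturation)",
                        p), "mlst_saturation_error")
    }
    -0.75 * log(1 - 4 * p / 3)
  }
  list(dN = jc(pN), dS = jc(pS), pN = pN, pS = pS, N = N, S = S, Nd = Nd, Sd = Sd)
}

#' Mean dN, dS and dN/dS for a locus
#'
#' Average of \code{\link{nei_gojobori_pair}} over all unordered pairs of
#' distinct alleles (default) or of isolate sequences. Following the usual
#' typing-table convention, the ratio is reported as 0 when dN = 0 and as
#' \code{NA} (undefined) when dS = 0 with dN > 0.
#'
#' @param seqs Character vector of equal-length in-frame sequences. For
#'   \code{weighting = "by_allele"} duplicates are collapsed first.
#' @param weighting \code{"by_allele"} or \code{"by_isolate"}.
#' @param correction Passed to \code{\link{nei_gojobori_pair}}.
#' @return List with \code{dN}, \code{dS}, \code{ratio}.
#' @export
locus_dn_ds <- function(seqs, weighting = c("by_allele", "by_isolate"),
                        correction = "jc") {
  weighting <- match.arg(weighting)
  u <- if (weighting == "by_allele") unique(seqs) else seqs
  if (length(u) < 2L || length(unique(u)) < 2L) {
    return(list(dN = 0, dS = 0, ratio = 0))
  }
  dn <- 0; ds <- 0; np <- 0L
  for (i in seq_len(length(u) - 1L)) {
    for (j in seq((i + 1L), length(u))) {
      p <- nei_gojobori_pair(u[i], u[j], correction)
      dn <- dn + p$dN; ds <- ds + p$dS; np <- np + 1L
    }
  }
  dn <- dn / np; ds <- ds / np
  ratio <- if (dn == 0) 0 else if (ds > 0) dn / ds else NA_real_
  list(dN = dn, dS = ds, ratio = ratio)
}

#' Per-locus diversity and selection summary
#'
#' One row per locus: number of sequences and alleles, fragment length,
#' polymorphic sites, pooled GC percentage, and Nei-Gojobori dN, dS and
#' dN/dS. The companion \code{\link{write_locus_stats_tsv}} emits the table
#' as TSV.
#'
#' @param seqs_by_locus Named list (locus -> character vector of per-isolate
#'   fragments, or of alleles).
#' @param weighting Passed to \code{\link{locus_dn_ds}}.
#' @param frame_offset Named integer vector of 0-based reading-frame offsets
#'   per locus (default 0: the fragment starts in frame).
#' @return data.frame with columns \code{locus}, \code{n_sequences},
#'   \code{n_alleles}, \code{fragment_length}, \code{polymorphic_sites},
#'   \code{gc_percent}, \code{dN}, \code{dS}, \code{dn_ds}.
#' @export
summarize_loci <- function(seqs_by_locus, weighting = "by_allele",
                           frame_offset = NULL) {
  rows <- lapply(names(seqs_by_locus), function(loc) {
    seqs <- seqs_by_locus[[loc]]
    off <- (frame_offset[[loc]] %||% 0L)
    len <- nchar(seqs[1])
    coding_len <- len - off
    coding_len <- coding_len - coding_len %% 3L
    coding <- substr(seqs, off + 1L, off + coding_len)
    dd <- locus_dn_ds(coding, weighting)
    data.frame(locus = loc,
               n_sequences = length(seqs),
               n_alleles = length(unique(seqs)),
               fragment_length = len,
               polymorphic_sites = count_polymorphic_sites(seqs),
               gc_percent = gc_content(seqs),
               dN = dd$dN, dS = dd$dS, dn_ds = dd$ratio)
  })
  do.call(rbind, rows)
}

#' @rdname summarize_loci
#' @param stats A data.frame from \code{summarize_loci}.
#' @param path Output TSV path (GC to 2 d.p., distances to 4 d.p.).
#' @export
write_locus_stats_tsv <- function(stats, path) {
  out <- stats
  out$gc_percent <- sprintf("%.2f", out$gc_percent)
  for (col in c("dN", "dS", "dn_ds")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "undefined", sprintf("%.4f", out[[col]]))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
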