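# Bandelt-Dress split decomposition: decompose a distance matrix into
# weighted bipartitions (splits). Incompatible split pairs are the
# "parallelograms" of a split network and indicate reticulate signal
# (recombination); an additive (tree) metric decomposes exactly into its
# tree edges with residual 0.

#' Isolation index of a split
#'
#' \deqn{\alpha_{A|B} = \tfrac12 \min_{i,j \in A;\; k,l \in B}
#'   \big[\max(d_{ik}+d_{jl},\; d_{il}+d_{jk},\; d_{ij}+d_{kl})
#'        - d_{ij} - d_{kl}\big]}
#' with \eqn{i = j} and \eqn{k = l} allowed. Splits with \eqn{\alpha > 0}
#' are the d-splits of the metric.
#'
#' @param side Logical vector (or vector of taxon labels/indices) giving side
#'   A of the bipartition; the rest of the taxa form side B.
#' @param dm A \code{dist} or symmetric matrix.
#' @return The isolation index (>= 0).
#' @export
isolation_index <- function(side, dm) {
  D <- as.matrix(dm)
  n <- nrow(D)
  A <- side_to_indices(side, D)
  B <- setdiff(seq_len(n), A)
  if (length(A) == 0L || length(B) == 0L) {
    mlst_stop("both sides of a split must be non-empty", "mlst_parameter_error")
  }
  alpha_idx(A, B, D)
}

side_to_indices <- function(side, D) {
  n <- nrow(D)
  if (is.logical(side)) {
    stopifnot(length(side) == n)
    which(side)
  } else if (is.character(side)) {
    idx <- match(side, rownames(D))
    if (anyNA(idx)) mlst_stop("unknown taxon in split side", "mlst_parameter_error")
    idx
  } else {
    as.integer(side)
  }
}

# core computation on index sets; pairs with repetition on each side
alpha_idx <- function(A, B, D) {
  pa <- pairs_with_rep(A)
  pb <- pairs_with_rep(B)
  dkl <- D[cbind(pb[, 1], pb[, 2])]
  best <- Inf
  for (r in seq_len(nrow(pa))) {
    i <- pa[r, 1]; j <- pa[r, 2]
    dij <- D[i, j]
    beta <- pmax(D[i, pb[, 1]] + D[j, pb[, 2]],
                 D[i, pb[, 2]] + D[j, pb[, 1]],
                 dij + dkl) - dij - dkl
    m <- min(beta)
    if (m < best) best <- m
    if (best <= 0) return(0)
  }
  best / 2
}

pairs_with_rep <- function(x) {
  k <- length(x)
  idx <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  cbind(x[idx[, 1]], x[idx[, 2]])
}

#' Split decomposition of a distance matrix
#'
#' Enumerates all splits with positive isolation index: exhaustively for
#' small taxon sets, and by the incremental construction (add one taxon at a
#' time, extend each surviving split both ways plus the new trivial split,
#' discard splits whose index drops to 0) above \code{brute_limit} taxa. The
#' two routes agree wherever both apply, because the restriction of a d-split
#' keeps a positive index.
#'
#' @param dm A \code{dist} or labelled symmetric matrix (2..\code{max_taxa}
#'   taxa).
#' @param method \code{"auto"} (default), \code{"bruteforce"} or
#'   \code{"incremental"}.
#' @param brute_limit Taxon count up to which brute force is used under
#'   \code{"auto"} (default 12).
#' @param max_taxa Complexity guard (default 60); collapse isolates to
#'   distinct STs or alleles before calling.
#' @return An object of class \code{mlst_splits}: \code{taxa}, \code{splits}
#'   (list of logical membership vectors, side A = side containing the first
#'   taxon), \code{alpha} (isolation indices, descending), \code{residual}
#'   (fraction of the total distance not represented by the split metric).
#' @export
split_decomposition <- function(dm, method = c("auto", "bruteforce", "incremental"),
                                brute_limit = 12L, max_taxa = 60L) {
  method <- match.arg(method)
  D <- as.matrix(dm)
  n <- nrow(D)
  taxa <- rownames(D) %||% as.character(seq_len(n))
  if (n < 2L) mlst_stop("need at least 2 taxa", "mlst_format_error")
  if (n > max_taxa) {
    mlst_stop(sprintf("%d taxa exceeds the cap of %d; collapse to distinct STs or alleles first",
                      n, max_taxa), "mlst_parameter_error")
  }
  if (method == "auto") {
    method <- if (n <= brute_limit) "bruteforce" else "incremental"
  }
  tol <- 1e-12
  if (method == "bruteforce") {
    sides <- list(); alphas <- numeric(0)
    # a split is identified by its side not containing taxon 1
    for (code in seq_len(2^(n - 1L) - 1L)) {
      B <- which(as.logical(intToBits(code)[seq_len(n - 1L)])) + 1L
      a <- alpha_idx(setdiff(seq_len(n), B), B, D)
      if (a > tol) {
        sides[[length(sides) + 1L]] <- !(seq_len(n) %in% B)
        alphas <- c(alphas, a)
      }
    }
  } else {
    # incremental Bandelt-Dress construction over taxa in input order
    sides <- list(c(TRUE, FALSE))          # {1} | {2}
    for (k in 3:n) {
      cand <- list()
      for (s in sides) {
        cand[[length(cand) + 1L]] <- c(s, FALSE)
        cand[[length(cand) + 1L]] <- c(s, TRUE)
      }
      cand[[length(cand) + 1L]] <- c(rep(FALSE, k - 1L), TRUE)
      Dk <- D[1:k, 1:k]
      keep <- vapply(cand, function(s) {
        alpha_idx(which(s), which(!s), Dk) > tol
      }, logical(1))
      sides <- cand[keep]
    }
    alphas <- vapply(sides, function(s) alpha_idx(which(s), which(!s), D),
                     numeric(1))
    # canonicalize: side A contains taxon 1
    sides <- lapply(sides, function(s) if (s[1]) s else !s)
  }
  ord <- order(-alphas)
  sides <- sides[ord]; alphas <- alphas[ord]
  # residual: 1 - (split-metric distance sum) / (input distance sum)
  ut <- upper.tri(D)
  dsplit <- matrix(0, n, n)
  for (i in seq_along(sides)) {
    sep <- outer(sides[[i]], sides[[i]], "!=")
    dsplit <- dsplit + alphas[i] * sep
  }
  total <- sum(D[ut])
  residual <- if (total > 0) 1 - sum(dsplit[ut]) / total else 0
  structure(list(taxa = taxa, splits = sides, alpha = alphas,
                 residual = residual, method = method),
            class = "mlst_splits")
}

#' @export
print.mlst_splits <- function(x, ...) {
  cat(sprintf("Split system: %d taxa, %d split(s), residual %.4f (%s)\n",
              length(x$taxa), length(x$splits), x$residual, x$method))
  for (i in seq_along(x$splits)) {
    s <- x$splits[[i]]
    cat(sprintf("  %8.5f  {%s} | {%s}\n", x$alpha[i],
                paste(x$taxa[s], collapse = ","),
                paste(x$taxa[!s], collapse = ",")))
  }
  invisible(x)
}

is_trivial_split <- function(s) min(sum(s), sum(!s)) <= 1L

#' Detect reticulate (recombination) signal in a split system
#'
#' Two splits are incompatible when all four intersections of their sides are
#' non-empty; incompatible pairs are the parallelogram-shaped structures of a
#' drawn split network. Only non-trivial splits (both sides >= 2 taxa) can be
#' incompatible.
#'
#' @param ss An \code{mlst_splits}.
#' @return List with \code{reticulate} (logical) and \code{pairs} (two-column
#'   matrix of indices into \code{ss$splits}).
#' @export
has_reticulation <- function(ss) {
  stopifnot(inherits(ss, "mlst_splits"))
  nontriv <- which(!vapply(ss$splits, is_trivial_split, logical(1)))
  pairs <- matrix(integer(0), ncol = 2L,
                  dimnames = list(NULL, c("split1", "split2")))
  if (length(nontriv) >= 2L) {
    for (ii in seq_len(length(nontriv) - 1L)) {
      for (jj in seq((ii + 1L), length(nontriv))) {
        a <- ss$splits[[nontriv[ii]]]
        b <- ss$splits[[nontriv[jj]]]
        if (any(a & b) && any(a & !b) && any(!a & b) && any(!a & !b)) {
          pairs <- rbind(pairs, c(nontriv[ii], nontriv[jj]))
        }
      }
    }
  }
  list(reticulate = nrow(pairs) > 0L, pairs = pairs)
}

#' Per-locus and combined split graphs
#'
#' Per locus, the taxa are the distinct alleles (uncorrected p-distance
#' between allele sequences); the summary row records whether the locus's
#' split system contains an incompatible pair, i.e. recombination signal.
#'
#' @param seqs_by_locus Named list: locus -> character vector of per-isolate
#'   (or per-allele) sequences.
#' @return data.frame: locus, n_alleles, n_splits, n_incompatible_pairs,
#'   reticulate; the split systems are attached as attribute
#'   \code{"split_systems"} (a named list).
#' @export
locus_split_graphs <- function(seqs_by_locus) {
  systems <- list()
  rows <- lapply(names(seqs_by_locus), function(loc) {
    alleles <- unique(seqs_by_locus[[loc]])
    if (length(alleles) < 2L) {
      systems[[loc]] <<- NULL
      return(data.frame(locus = loc, n_alleles = length(alleles),
                        n_splits = 0L, n_incompatible_pairs = 0L,
                        reticulate = FALSE))
    }
    m <- seq_matrix(alleles)
    n <- length(alleles)
    D <- matrix(0, n, n,
                dimnames = list(as.character(seq_len(n)), as.character(seq_len(n))))
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        D[i, j] <- D[j, i] <- sum(m[i, ] != m[j, ]) / ncol(m)
      }
    }
    ss <- split_decomposition(stats::as.dist(D))
    ret <- has_reticulation(ss)
    systems[[loc]] <<- ss
    data.frame(locus = loc, n_alleles = n, n_splits = length(ss$splits),
               n_incompatible_pairs = nrow(ret$pairs), reticulate = ret$reticulate)
  })
  out <- do.call(rbind, rows)
  attr(out, "split_systems") <- systems
  out
}

#' Write a split system as a SplitsTree-readable Nexus file
#'
#' Emits Taxa and Splits blocks; each split is written as the taxon ids of
#' the side containing the first taxon, weighted by its isolation index.
#'
#' @param ss An \code{mlst_splits}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_nexus_splits <- function(ss, path) {
  stopifnot(inherits(ss, "mlst_splits"))
  n <- length(ss$taxa)
  lines <- c("#NEXUS", "",
             "BEGIN Taxa;",
             sprintf("DIMENSIONS ntax=%d;", n),
             "TAXLABELS",
             sprintf("[%d] '%s'", seq_len(n), ss$taxa),
             ";", "END;", "",
             "BEGIN Splits;",
             sprintf("DIMENSIONS ntax=%d nsplits=%d;", n, length(ss$splits)),
             "FORMAT labels=no weights=yes;",
             "MATRIX")
  for (i in seq_along(ss$splits)) {
    ids <- which(ss$splits[[i]])
    lines <- c(lines, sprintf("[%d, size=%d] \t%.10f \t%s,", i, length(ids),
                              ss$alpha[i], paste(ids, collapse = " ")))
  }
  writeLines(c(lines, ";", "END;"), path)
  invisible(path)
}
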