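# Clonality testing via the index of association over allelic profiles.
#
# K (for one pair of isolates) = number of loci at which the two differ.
# V_O = population variance of K over all unordered pairs; V_E = sum over
# loci of h_j (1 - h_j) with h_j the per-locus allelic diversity, the
# expected variance under free recombination. I_A = V_O/V_E - 1;
# I_A^S = I_A / (l - 1).

# number of unordered pairs with equal values
npairs_equal <- function(v) {
  t <- tabulate(match(v, unique(v)))
  sum(t * (t - 1) / 2)
}

npairs_equal_joint <- function(x, y) {
  npairs_equal(as.numeric(x) * (max(y) + 1) + y)
}

# Population variance of the pairwise mismatch count, computed from per-locus
# and per-locus-pair match tallies in O(n l^2) without enumerating pairs.
vo_from_matrix <- function(mat) {
  n <- nrow(mat)
  l <- ncol(mat)
  P <- n * (n - 1) / 2
  match1 <- vapply(seq_len(l), function(j) npairs_equal(mat[, j]), numeric(1))
  mis <- 1 - match1 / P
  EK <- sum(mis)
  EK2 <- sum(mis)                      # E[X_j^2] = E[X_j]
  if (l >= 2L) {
    for (j in seq_len(l - 1L)) {
      for (k in seq((j + 1L), l)) {
        mjk <- npairs_equal_joint(mat[, j], mat[, k])
        pjk <- (P - match1[j] - match1[k] + mjk) / P
        EK2 <- EK2 + 2 * pjk
      }
    }
  }
  EK2 - EK^2
}

ve_from_matrix <- function(mat, ve_method = c("unbiased", "biased")) {
  ve_method <- match.arg(ve_method)
  n <- nrow(mat)
  h <- apply(mat, 2L, function(v) {
    p <- tabulate(match(v, unique(v))) / n
    h0 <- 1 - sum(p^2)
    if (ve_method == "unbiased") n / (n - 1) * h0 else h0
  })
  sum(h * (1 - h))
}

#' Distribution of pairwise allelic mismatch counts
#'
#' For every unordered pair of isolates, K = the number of loci at which
#' their profiles differ. The histogram over K is the substrate of the
#' index-of-association statistic.
#'
#' @param pt An \code{mlst_profiles} (>= 2 isolates).
#' @return Named integer vector of counts for K = 0..l; sums to
#'   \code{n(n-1)/2}.
#' @export
mismatch_distribution <- function(pt) {
  mat <- profile_matrix(pt)
  n <- nrow(mat)
  if (n < 2L) mlst_stop("need at least 2 isolates", "mlst_format_error")
  l <- ncol(mat)
  D <- matrix(0L, n, n)
  for (j in seq_len(l)) {
    D <- D + outer(mat[, j], mat[, j], "!=")
  }
  K <- D[upper.tri(D)]
  counts <- tabulate(K + 1L, nbins = l + 1L)
  stats::setNames(as.integer(counts), 0:l)
}

#' Index of association over allelic profiles
#'
#' Computes the observed variance V_O of the pairwise mismatch count, the
#' expected variance V_E under linkage equilibrium, I_A = V_O/V_E - 1 and the
#' standardized I_A^S = I_A/(l - 1). I_A has expectation 0 when alleles at
#' different loci associate at random (free recombination) and grows positive
#' under clonality.
#'
#' @param pt An \code{mlst_profiles} (>= 3 isolates, >= 2 loci, at least one
#'   polymorphic locus).
#' @param ve_method Per-locus diversity estimator used in V_E:
#'   \code{"unbiased"} applies the n/(n-1) small-sample correction (default);
#'   \code{"biased"} omits it. Different MLST programs differ here, which
#'   moves I_A without changing its sign.
#' @return An object of class \code{mlst_linkage} with fields
#'   \code{n_isolates}, \code{n_loci}, \code{V_O}, \code{V_E}, \code{I_A},
#'   \code{I_A_S}, and (after \code{\link{permutation_test}})
#'   \code{p_value}, \code{n_permutations}, \code{seed}.
#' @export
index_of_association <- function(pt, ve_method = c("unbiased", "biased")) {
  ve_method <- match.arg(ve_method)
  mat <- profile_matrix(pt)
  if (nrow(mat) < 3L) mlst_stop("need at least 3 isolates", "mlst_format_error")
  if (ncol(mat) < 2L) mlst_stop("needs >= 2 loci", "mlst_format_error")
  V_E <- ve_from_matrix(mat, ve_method)
  if (V_E <= 0) {
    mlst_stop("no variation: every locus is monomorphic", "mlst_novariation_error")
  }
  V_O <- vo_from_matrix(mat)
  I_A <- V_O / V_E - 1
  structure(list(n_isolates = nrow(mat), n_loci = ncol(mat),
                 V_O = V_O, V_E = V_E, I_A = I_A,
                 I_A_S = I_A / (ncol(mat) - 1L),
                 ve_method = ve_method,
                 p_value = NA_real_, n_permutations = NA_integer_,
                 seed = NA_integer_),
            class = "mlst_linkage")
}

#' @export
print.mlst_linkage <- function(x, ...) {
  cat(sprintf("Index of association (%d isolates, %d loci)\n",
              x$n_isolates, x$n_loci))
  cat(sprintf("  V_O = %.6f  V_E = %.6f (%s h)\n", x$V_O, x$V_E, x$ve_method))
  cat(sprintf("  I_A = %.4f  I_A^S = %.4f\n", x$I_A, x$I_A_S))
  if (!is.na(x$p_value)) {
    cat(sprintf("  permutation p = %.4g (%d permutations, seed %d)\n",
                x$p_value, x$n_permutations, x$seed))
  }
  invisible(x)
}

#' Monte-Carlo permutation test for linkage disequilibrium
#'
#' Each permutation independently shuffles the allele column at every locus
#' across isolates, destroying between-locus association while preserving
#' allele frequencies, and recomputes V_O. The tail probability uses the +1
#' correction, \eqn{p = (1 + \#\{V_O^{perm} \ge V_O\}) / (1 + n)}, so a
#' finite run never reports 0.
#'
#' @param pt An \code{mlst_profiles}.
#' @param n_permutations Number of permutations (default 1000).
#' @param seed Integer seed (required, for reproducibility).
#' @param ve_method Passed to \code{\link{index_of_association}}.
#' @return An \code{mlst_linkage} with \code{p_value} filled in.
#' @export
permutation_test <- function(pt, n_permutations = 1000L, seed,
                             ve_method = "unbiased") {
  res <- index_of_association(pt, ve_method)
  mat <- profile_matrix(pt)
  n <- nrow(mat)
  exceed <- with_seed(seed, {
    cnt <- 0L
    for (r in seq_len(n_permutations)) {
      perm <- mat
      for (j in seq_len(ncol(mat))) perm[, j] <- mat[sample.int(n), j]
      if (vo_from_matrix(perm) >= res$V_O) cnt <- cnt + 1L
    }
    cnt
  })
  res$p_value <- (1 + exceed) / (1 + n_permutations)
  res$n_permutations <- as.integer(n_permutations)
  res$seed <- as.integer(seed)
  res
}
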