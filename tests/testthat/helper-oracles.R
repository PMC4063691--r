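# Independent oracles and fixture builders used across the test files.
# These deliberately use the most naive formulation of each quantity.

# --- tiny fixture builders ---------------------------------------------------

toy_profiles <- function(mat, loci = NULL, ids = NULL) {
  loci <- loci %||% paste0("L", seq_len(ncol(mat)))
  ids <- ids %||% sprintf("iso%03d", seq_len(nrow(mat)))
  df <- data.frame(isolate = ids)
  for (j in seq_along(loci)) df[[loci[j]]] <- as.integer(mat[, j])
  assign_sts(profile_table(df, loci))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

with_seed_helper <- function(seed, expr) {
  set.seed(seed)
  force(expr)
}

seq_matrix_test <- function(seqs) {
  matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
         nrow = length(seqs), byrow = TRUE)
}

random_codon_seq <- function(n_codons) {
  gc <- Biostrings::GENETIC_CODE
  codons <- names(gc)[gc != "*"]
  paste(sample(codons, n_codons, replace = TRUE), collapse = "")
}

# additive (tree) metric from a random topology with positive branch lengths
random_tree_metric <- function(n_taxa) {
  tr <- ape::rtree(n_taxa, br = function(k) stats::runif(k, 0.1, 1))
  tr$tip.label <- paste0("t", seq_len(n_taxa))
  list(tree = tr, dm = stats::as.dist(ape::cophenetic.phylo(tr)))
}

# --- Nei-Gojobori brute-force oracle -----------------------------------------
# Straight-line reimplementation: per-position synonymous fractions by
# enumerating the single-base changes of every codon (stop targets excluded
# from the possibilities), pathway averaging by explicit recursion.

oracle_codon_s <- function(codon) {
  gc <- Biostrings::GENETIC_CODE
  bases <- c("A", "C", "G", "T")
  s <- 0
  for (p in 1:3) {
    syn <- 0; valid <- 0
    for (b in setdiff(bases, substr(codon, p, p))) {
      mut <- codon
      substr(mut, p, p) <- b
      if (gc[[mut]] == "*") next
      valid <- valid + 1
      if (gc[[mut]] == gc[[codon]]) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  s
}

oracle_paths <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  diffs <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  walk <- function(cur, remaining) {
    if (!length(remaining)) {
      return(list(list(syn = 0, nonsyn = 0, ok = TRUE)))
    }
    out <- list()
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(b, p, p)
      step_syn <- gc[[nxt]] == gc[[cur]]
      hits_stop <- gc[[nxt]] == "*" && length(remaining) > 1L
      for (tail in walk(nxt, setdiff(remaining, p))) {
        out[[length(out) + 1L]] <- list(
          syn = tail$syn + as.integer(step_syn),
          nonsyn = tail$nonsyn + as.integer(!step_syn),
          ok = tail$ok && !hits_stop)
      }
    }
    out
  }
  paths <- walk(a, diffs)
  ok <- vapply(paths, `[[`, logical(1), "ok")
  use <- if (any(ok)) paths[ok] else paths
  c(syn = mean(vapply(use, `[[`, numeric(1), "syn")),
    nonsyn = mean(vapply(use, `[[`, numeric(1), "nonsyn")))
}

oracle_ng86 <- function(a, b) {
  gc <- Biostrings::GENETIC_CODE
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  keep <- gc[ca] != "*" & gc[cb] != "*"
  ca <- ca[keep]; cb <- cb[keep]
  S <- (sum(vapply(ca, oracle_codon_s, numeric(1))) +
        sum(vapply(cb, oracle_codon_s, numeric(1)))) / 2
  N <- 3 * length(ca) - S
  Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    if (ca[i] == cb[i]) next
    d <- oracle_paths(ca[i], cb[i])
    Sd <- Sd + d[["syn"]]; Nd <- Nd + d[["nonsyn"]]
  }
  list(pN = Nd / N, pS = Sd / S, N = N, S = S, Nd = Nd, Sd = Sd)
}

# --- linkage: pair-enumeration variance oracle -------------------------------

oracle_vo <- function(mat) {
  n <- nrow(mat)
  K <- apply(utils::combn(n, 2), 2L, function(p) {
    sum(mat[p[1], ] != mat[p[2], ])
  })
  mean(K^2) - mean(K)^2      # population variance over pairs
}

oracle_ve <- function(mat) {
  n <- nrow(mat)
  h <- apply(mat, 2L, function(v) {
    p <- table(v) / n
    (n / (n - 1)) * (1 - sum(p^2))
  })
  sum(h * (1 - h))
}

# --- MST: exhaustive spanning-tree enumeration via Pruefer sequences ---------

prufer_to_edges <- function(seq, n) {
  degree <- rep(1L, n)
  for (x in seq) degree[x] <- degree[x] + 1L
  edges <- matrix(0L, n - 1L, 2L)
  k <- 0L
  for (x in seq) {
    leaf <- min(which(degree == 1L))
    k <- k + 1L
    edges[k, ] <- c(leaf, x)
    degree[leaf] <- degree[leaf] - 1L
    degree[x] <- degree[x] - 1L
  }
  edges[n - 1L, ] <- which(degree == 1L)
  edges
}

oracle_mst_weight <- function(D) {
  n <- nrow(D)
  if (n == 2L) return(D[1, 2])
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  best <- Inf
  for (r in seq_len(nrow(seqs))) {
    e <- prufer_to_edges(seqs[r, ], n)
    w <- sum(D[e])
    if (w < best) best <- w
  }
  best
}

st_dist_for_test <- function(pt) {
  m <- profile_matrix(pt, by = "st")
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) D[i, j] <- sum(m[i, ] != m[j, ])
  D
}

# --- splits: weak-compatibility check ----------------------------------------
# Splits S1..S3 are weakly incompatible iff there exist taxa y, x1, x2, x3
# with S_i putting {y, x_i} on one side and {x_j, x_k} on the other.

is_weakly_compatible <- function(splits) {
  n <- if (length(splits)) length(splits[[1]]) else 0L
  if (length(splits) < 3L) return(TRUE)
  combos <- utils::combn(length(splits), 3L)
  for (c_i in seq_len(ncol(combos))) {
    s <- splits[combos[, c_i]]
    for (y in seq_len(n)) {
      others <- setdiff(seq_len(n), y)
      for (x1 in others) for (x2 in setdiff(others, x1)) {
        for (x3 in setdiff(others, c(x1, x2))) {
          xs <- c(x1, x2, x3)
          bad <- all(vapply(1:3, function(i) {
            side_y <- s[[i]][y]
            s[[i]][xs[i]] == side_y && all(s[[i]][xs[-i]] != side_y)
          }, logical(1)))
          if (bad) return(FALSE)
        }
      }
    }
  }
  TRUE
}
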