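#' Distance matrix from allelic profiles
#'
#' Entry (i, j) is the proportion of mismatched loci between the two
#' profiles (Hamming distance / number of loci).
#'
#' @param pt An \code{mlst_profiles}.
#' @param by \code{"st"} (default; taxa are distinct STs, labelled
#'   \code{"ST<k>"}) or \code{"isolate"}.
#' @return A \code{dist} object.
#' @export
distance_from_profiles <- function(pt, by = c("st", "isolate")) {
  by <- match.arg(by)
  mat <- profile_matrix(pt, by = by)
  D <- st_distance_matrix(mat) / ncol(mat)
  stats::as.dist(D)
}

#' Distance matrix from concatenated locus sequences
#'
#' Concatenates each taxon's per-locus sequences in the given locus order and
#' returns the uncorrected p-distance (proportion of differing sites) between
#' taxa.
#'
#' @param seqs_by_locus Named list: locus -> named character vector of
#'   equal-length sequences; every taxon must appear at every locus.
#' @param s Optional \code{mlst_scheme}; if given, loci are concatenated in
#'   scheme order and must all be present.
#' @return A \code{dist} object over the taxa.
#' @export
distance_from_concatenates <- function(seqs_by_locus, s = NULL) {
  loci <- if (is.null(s)) names(seqs_by_locus) else locus_names(s)
  if (!all(loci %in% names(seqs_by_locus))) {
    mlst_stop("missing loci in sequence list", "mlst_format_error")
  }
  taxa <- names(seqs_by_locus[[loci[1]]])
  concat <- rep("", length(taxa))
  for (loc in loci) {
    v <- seqs_by_locus[[loc]]
    if (!all(taxa %in% names(v))) {
      mlst_stop(sprintf("locus '%s': missing taxa", loc), "mlst_format_error")
    }
    if (length(unique(nchar(v))) != 1L) {
      mlst_stop(sprintf("locus '%s': unequal sequence lengths", loc),
                "mlst_length_error")
    }
    concat <- paste0(concat, v[taxa])
  }
  m <- seq_matrix(concat)
  n <- length(taxa)
  D <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      D[i, j] <- D[j, i] <- sum(m[i, ] != m[j, ]) / ncol(m)
    }
  }
  stats::as.dist(D)
}

#' UPGMA dendrogram
#'
#' Average-linkage agglomeration: at each step the closest pair of clusters
#' is merged at height = distance/2 (so the tree is ultrametric), and
#' distances to the merged cluster are size-weighted arithmetic averages.
#' Ties are broken by the lexicographically smallest pair of cluster labels
#' (a cluster is labelled by its smallest leaf label), making the result
#' independent of input order up to leaf rotation.
#'
#' @param dm A \code{dist} or symmetric matrix with labels.
#' @return An object of class \code{mlst_upgma} with components \code{phylo}
#'   (rooted ultrametric \code{ape::phylo}) and \code{hclust} (the merge
#'   history; heights are the merge distances, i.e. twice the node heights).
#' @export
upgma <- function(dm) {
  D <- as.matrix(dm)
  labels <- rownames(D)
  n <- nrow(D)
  if (n < 2L) mlst_stop("need at least 2 taxa", "mlst_format_error")
  if (is.null(labels)) labels <- as.character(seq_len(n))
  active <- seq_len(n)                       # current cluster ids
  id_of <- -seq_len(n)                       # hclust code: -leaf or +merge row
  size <- rep(1L, n)
  minlab <- labels                           # smallest leaf label per cluster
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    k <- length(active)
    sub <- D[active, active, drop = FALSE]
    best <- Inf; bi <- bj <- NA_integer_
    for (i in seq_len(k - 1L)) {
      for (j in seq((i + 1L), k)) {
        d <- sub[i, j]
        lab <- sort(c(minlab[active[i]], minlab[active[j]]))
        if (d < best - 1e-12 ||
            (abs(d - best) <= 1e-12 && !is.na(bi) &&
             lexico_less(lab, sort(c(minlab[active[bi]], minlab[active[bj]]))))) {
          best <- d; bi <- i; bj <- j
        }
      }
    }
    ci <- active[bi]; cj <- active[bj]
    merge[step, ] <- sort(c(id_of[ci], id_of[cj]))
    height[step] <- best
    # size-weighted average linkage update
    new_id <- length(size) + 1L
    newd <- (size[ci] * D[ci, ] + size[cj] * D[cj, ]) / (size[ci] + size[cj])
    D <- rbind(cbind(D, newd), c(newd, 0))
    size <- c(size, size[ci] + size[cj])
    id_of <- c(id_of, step)
    minlab <- c(minlab, min(minlab[ci], minlab[cj]))
    active <- c(setdiff(active, c(ci, cj)), new_id)
  }
  hc <- structure(list(merge = merge, height = height,
                       order = hclust_order(merge), labels = labels,
                       method = "average", call = match.call(),
                       dist.method = "allelic"),
                  class = "hclust")
  structure(list(phylo = ape::as.phylo(hc), hclust = hc), class = "mlst_upgma")
}

lexico_less <- function(a, b) {
  if (a[1] != b[1]) return(a[1] < b[1])
  a[2] < b[2]
}

# Leaf ordering compatible with the merge matrix (left-to-right traversal).
hclust_order <- function(merge) {
  expand <- function(i) {
    if (i < 0L) return(-i)
    c(expand(merge[i, 1]), expand(merge[i, 2]))
  }
  expand(nrow(merge))
}

#' @export
print.mlst_upgma <- function(x, ...) {
  cat("UPGMA dendrogram\n")
  print(x$phylo)
  invisible(x)
}

#' Neighbour-joining tree
#'
#' Saitou-Nei neighbour joining (via \code{ape::nj}); negative branch lengths
#' (which NJ can produce on non-additive input) are clamped to 0 with a
#' warning.
#'
#' @param dm A \code{dist} or symmetric matrix with labels.
#' @return An unrooted \code{ape::phylo}.
#' @export
neighbor_joining <- function(dm) {
  D <- as.matrix(dm)
  if (nrow(D) < 3L) mlst_stop("NJ needs at least 3 taxa", "mlst_format_error")
  tree <- ape::nj(stats::as.dist(D))
  if (any(tree$edge.length < 0)) {
    mlst_warn(sprintf("%d negative NJ branch length(s) clamped to 0",
                      sum(tree$edge.length < 0)))
    tree$edge.length <- pmax(tree$edge.length, 0)
  }
  tree
}

#' Cut an UPGMA dendrogram into k groups
#'
#' Removes the k-1 highest internal nodes, i.e. cuts the tree at a height
#' between the (k-1)-th and k-th highest merges.
#'
#' @param tree An \code{mlst_upgma}.
#' @param k Number of groups (1..n).
#' @return Named integer vector: group index per leaf label.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "mlst_upgma"))
  n <- length(tree$hclust$labels)
  if (k < 1L || k > n) mlst_stop("k must be in 1..n", "mlst_parameter_error")
  stats::cutree(tree$hclust, k = k)
}

#' Write a tree in Newick format
#'
#' Branch lengths are written with 6 decimal places.
#'
#' @param tree An \code{mlst_upgma} or an \code{ape::phylo}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  phy <- if (inherits(tree, "mlst_upgma")) tree$phylo else tree
  stopifnot(inherits(phy, "phylo"))
  phy$edge.length <- round(phy$edge.length, 6L)
  ape::write.tree(phy, file = path)
  invisible(path)
}
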