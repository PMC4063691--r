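#' Hamming distance between two allelic profiles
#'
#' Number of loci at which two profiles carry different allele numbers; the
#' locus-variant count (distance 1 = single-locus variant, SLV; 2 = DLV).
#'
#' @param a,b Integer allele vectors of equal length.
#' @return Integer in 0..l.
#' @export
profile_distance <- function(a, b) {
  if (length(a) != length(b)) {
    mlst_stop("profiles come from different schemes", "mlst_format_error")
  }
  as.integer(sum(a != b))
}

# Pairwise Hamming distances between the rows of an ST-by-locus matrix.
st_distance_matrix <- function(mat) {
  n <- nrow(mat)
  D <- matrix(0L, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (j in seq_len(ncol(mat))) {
    D <- D + outer(mat[, j], mat[, j], "!=")
  }
  D
}

# SLV/DLV counts per ST within the given ST set (rows of D).
variant_counts <- function(D) {
  list(slv = rowSums(D == 1L), dlv = rowSums(D == 2L))
}

#' Group sequence types into clonal complexes
#'
#' Implements the shared-allele rule: a candidate central genotype (the
#' unassigned ST with the most single-locus variants, ties broken by DLV
#' count, isolate frequency, then lowest ST number) seeds a group containing
#' every unassigned ST that shares at least \code{threshold} alleles with it;
#' groups whose centers themselves share \code{threshold} alleles are merged.
#' STs joining no multi-ST group are singletons. \code{rule = "slv"} instead
#' forms groups as connected components of the graph linking STs that share
#' \code{threshold} alleles with at least one member (classic eBURST-style
#' single linkage).
#'
#' @param pt An \code{mlst_profiles} with STs assigned.
#' @param threshold Minimum number of identical alleles shared with the
#'   central genotype (default 5, of 8 loci).
#' @param rule \code{"shared"} (default) or \code{"slv"}.
#' @return An object of class \code{mlst_ccs}: \code{groups} (list of integer
#'   ST vectors, multi-ST groups first, then singletons), \code{founders}
#'   (predicted founder per group), \code{slv}, \code{dlv} (per-ST counts over
#'   the whole ST set), \code{frequencies} (isolates per ST),
#'   \code{n_complexes} (multi-ST groups), \code{n_singletons}, and
#'   \code{n_groups_total} (their sum).
#' @export
group_sts <- function(pt, threshold = 5L, rule = c("shared", "slv")) {
  rule <- match.arg(rule)
  mat <- profile_matrix(pt, by = "st")
  l <- ncol(mat)
  if (threshold < 1L || threshold > l) {
    mlst_stop(sprintf("threshold must be in 1..%d", l), "mlst_parameter_error")
  }
  sts <- as.integer(sub("^ST", "", rownames(mat)))
  freq <- st_frequencies(pt)[rownames(mat)]
  D <- st_distance_matrix(mat)
  vc <- variant_counts(D)
  max_dist <- l - threshold
  if (rule == "slv") {
    adj <- D <= max_dist
    comp <- connected_components(adj)
    groups <- split(seq_along(sts), comp)
  } else {
    assigned <- rep(FALSE, length(sts))
    groups <- list()
    centers <- integer(0)
    while (!all(assigned)) {
      un <- which(!assigned)
      Dun <- D[un, un, drop = FALSE]
      slv_un <- rowSums(Dun == 1L)
      dlv_un <- rowSums(Dun == 2L)
      ord <- order(-slv_un, -dlv_un, -freq[un], sts[un])
      center <- un[ord[1]]
      members <- un[D[center, un] <= max_dist]
      groups[[length(groups) + 1L]] <- members
      centers <- c(centers, center)
      assigned[members] <- TRUE
    }
    # merge groups whose centers share >= threshold alleles
    k <- length(groups)
    if (k > 1L) {
      parent <- seq_len(k)
      find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
      for (i in seq_len(k - 1L)) {
        for (j in seq((i + 1L), k)) {
          if (D[centers[i], centers[j]] <= max_dist) {
            parent[find(j)] <- find(i)
          }
        }
      }
      root <- vapply(seq_len(k), find, integer(1))
      groups <- lapply(split(seq_len(k), root),
                       function(gs) sort(unique(unlist(groups[gs]))))
    }
  }
  groups <- lapply(groups, function(g) sort(sts[g]))
  multi <- vapply(groups, length, integer(1)) > 1L
  groups <- c(groups[multi][order(-vapply(groups[multi], function(g)
                sum(freq[paste0("ST", g)]), numeric(1)))],
              groups[!multi][order(vapply(groups[!multi], `[[`, integer(1), 1L))])
  founders <- vapply(groups, function(g)
    predict_founder(g, pt), integer(1))
  structure(list(groups = unname(groups), founders = unname(founders),
                 slv = stats::setNames(as.integer(vc$slv), rownames(mat)),
                 dlv = stats::setNames(as.integer(vc$dlv), rownames(mat)),
                 frequencies = freq,
                 threshold = as.integer(threshold), rule = rule,
                 n_complexes = sum(multi), n_singletons = sum(!multi),
                 n_groups_total = length(groups)),
            class = "mlst_ccs")
}

connected_components <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cur <- cur + 1L
    queue <- i
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      if (!is.na(comp[v])) next
      comp[v] <- cur
      queue <- c(queue, which(adj[v, ] & is.na(comp)))
    }
  }
  comp
}

#' @export
print.mlst_ccs <- function(x, ...) {
  cat(sprintf("Clonal complexes (shared-allele threshold %d, rule '%s')\n",
              x$threshold, x$rule))
  cat(sprintf("  %d multi-ST complex(es) + %d singleton(s) = %d group(s)\n",
              x$n_complexes, x$n_singletons, x$n_groups_total))
  for (i in seq_along(x$groups)) {
    g <- x$groups[[i]]
    iso <- sum(x$frequencies[paste0("ST", g)])
    cat(sprintf("  group %d (%d isolates, founder ST%d): %s\n", i, iso,
                x$founders[i], paste0("ST", g, collapse = " ")))
  }
  invisible(x)
}

#' Predict the founder of a clonal complex
#'
#' The founder is the member ST with the most single-locus variants within
#' the group; ties are broken by double-locus variant count, then isolate
#' frequency, then lowest ST number (fully deterministic).
#'
#' @param group Integer vector of ST numbers.
#' @param pt The \code{mlst_profiles} the group came from.
#' @return The founder's ST number.
#' @export
predict_founder <- function(group, pt) {
  if (length(group) == 0L) mlst_stop("empty group", "mlst_parameter_error")
  if (length(group) == 1L) return(as.integer(group))
  mat <- profile_matrix(pt, by = "st")[paste0("ST", group), , drop = FALSE]
  freq <- st_frequencies(pt)[paste0("ST", group)]
  D <- st_distance_matrix(mat)
  slv <- rowSums(D == 1L)
  dlv <- rowSums(D == 2L)
  ord <- order(-slv, -dlv, -freq, group)
  as.integer(group[ord[1]])
}

#' Minimum spanning tree over sequence types
#'
#' Prim's algorithm on the complete graph of distinct STs weighted by
#' profile Hamming distance. Ties are broken deterministically: smallest
#' weight, then the candidate endpoint with the higher isolate frequency,
#' then the lower candidate ST number, then the lower tree-side ST number.
#' Edges are classed by weight for display: 1..\code{breaks[1]} strong,
#' ..\code{breaks[2]} intermediate, above that weak.
#'
#' @param pt An \code{mlst_profiles} with STs assigned.
#' @param breaks Two increasing integers; default \code{c(2, 5)}.
#' @return An object of class \code{mlst_mst}: \code{nodes} (data.frame: st,
#'   n_isolates, regions, sources), \code{edges} (data.frame: from, to,
#'   weight, class), \code{total_weight}.
#' @export
minimum_spanning_tree <- function(pt, breaks = c(2L, 5L)) {
  stopifnot(length(breaks) == 2L, breaks[1] < breaks[2])
  mat <- profile_matrix(pt, by = "st")
  sts <- as.integer(sub("^ST", "", rownames(mat)))
  n <- length(sts)
  freq <- st_frequencies(pt)[rownames(mat)]
  D <- st_distance_matrix(mat)
  nodes <- data.frame(st = sts, n_isolates = as.integer(freq),
                      regions = meta_tally(pt, sts, "region"),
                      sources = meta_tally(pt, sts, "source"))
  if (n == 1L) {
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = integer(0), to = integer(0),
                                             weight = integer(0),
                                             class = character(0)),
                          total_weight = 0L, breaks = breaks),
                     class = "mlst_mst"))
  }
  start <- order(-freq, sts)[1]
  in_tree <- rep(FALSE, n)
  in_tree[start] <- TRUE
  edges <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    ins <- which(in_tree); outs <- which(!in_tree)
    W <- D[ins, outs, drop = FALSE]
    w <- min(W)
    idx <- which(W == w, arr.ind = TRUE)
    cand <- data.frame(from = ins[idx[, 1]], to = outs[idx[, 2]])
    ord <- order(-freq[cand$to], sts[cand$to], sts[cand$from])
    pick <- cand[ord[1], ]
    edges[[step]] <- data.frame(from = sts[pick$from], to = sts[pick$to],
                                weight = as.integer(w))
    in_tree[pick$to] <- TRUE
  }
  edges <- do.call(rbind, edges)
  edges$class <- ifelse(edges$weight <= breaks[1], "strong",
                        ifelse(edges$weight <= breaks[2], "intermediate", "weak"))
  structure(list(nodes = nodes, edges = edges,
                 total_weight = sum(edges$weight), breaks = breaks),
            class = "mlst_mst")
}

meta_tally <- function(pt, sts, col) {
  vapply(sts, function(s) {
    v <- pt$profiles[[col]][pt$profiles$ST == s]
    v <- v[!is.na(v)]
    if (!length(v)) return("")
    t <- sort(table(v), decreasing = TRUE)
    paste(sprintf("%s:%d", names(t), as.integer(t)), collapse = ";")
  }, character(1))
}

#' @export
print.mlst_mst <- function(x, ...) {
  cat(sprintf("Minimum spanning tree: %d ST(s), total weight %d\n",
              nrow(x$nodes), x$total_weight))
  print(x$edges, row.names = FALSE)
  invisible(x)
}

#' Write a minimum spanning tree as Graphviz DOT or as a TSV edge list
#'
#' Node attributes carry isolate counts and region/source tallies; edge
#' attributes carry the locus-distance weight and the strong/intermediate/
#' weak class.
#'
#' @param mst An \code{mlst_mst}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_mst_dot <- function(mst, path) {
  style <- c(strong = "solid", intermediate = "dashed", weak = "dotted")
  lines <- c("graph mst {",
             sprintf('  ST%d [label="ST%d (n=%d)" isolates=%d regions="%s" sources="%s"];',
                     mst$nodes$st, mst$nodes$st, mst$nodes$n_isolates,
                     mst$nodes$n_isolates, mst$nodes$regions, mst$nodes$sources))
  if (nrow(mst$edges)) {
    lines <- c(lines,
               sprintf('  ST%d -- ST%d [label=%d weight=%d class="%s" style=%s];',
                       mst$edges$from, mst$edges$to, mst$edges$weight,
                       mst$edges$weight, mst$edges$class,
                       style[mst$edges$class]))
  }
  writeLines(c(lines, "}"), path)
  invisible(path)
}

#' @rdname write_mst_dot
#' @export
write_mst_edges_tsv <- function(mst, path) {
  utils::write.table(mst$edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
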