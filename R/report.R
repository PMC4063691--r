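#' One-shot dataset report
#'
#' Runs the whole downstream analysis on a typed dataset: per-locus diversity
#' and selection statistics (when sequences are given), ST counts, clonal
#' complexes with founders, minimum spanning tree, linkage disequilibrium
#' with a permutation p-value, and UPGMA groups. Writes a locus-stats TSV and
#' a JSON summary when \code{out_dir} is given.
#'
#' @param pt An \code{mlst_profiles} with STs assigned (>= 3 isolates).
#' @param seqs_by_locus Optional named list of per-isolate fragments per locus
#'   (enables the locus-stats table).
#' @param n_permutations,seed For \code{\link{permutation_test}}.
#' @param threshold Shared-allele threshold for \code{\link{group_sts}};
#'   default \code{NULL} uses l - 3 (5 for an eight-locus scheme), floored
#'   at 1.
#' @param k_groups Number of UPGMA groups to cut (default 2).
#' @param out_dir Optional output directory.
#' @return List with \code{st_counts}, \code{locus_stats} (or NULL),
#'   \code{ccs}, \code{mst}, \code{linkage}, \code{upgma_groups} and
#'   \code{summary} (the JSON-ready list).
#' @export
mlst_report <- function(pt, seqs_by_locus = NULL, n_permutations = 1000L,
                        seed = 1L, threshold = NULL, k_groups = 2L,
                        out_dir = NULL) {
  stopifnot(inherits(pt, "mlst_profiles"))
  threshold <- threshold %||% max(1L, length(pt$loci) - 3L)
  freq <- st_frequencies(pt)
  stats <- if (!is.null(seqs_by_locus)) summarize_loci(seqs_by_locus) else NULL
  ccs <- group_sts(pt, threshold = threshold)
  mst <- minimum_spanning_tree(pt)
  lk <- permutation_test(pt, n_permutations = n_permutations, seed = seed)
  up <- upgma(distance_from_profiles(pt, by = "st"))
  k <- min(k_groups, nrow(pt$st_definitions))
  grp <- cut_tree(up, k)
  # isolates per UPGMA group, weighting each ST by its frequency
  grp_iso <- vapply(seq_len(k), function(g) {
    sum(freq[names(grp)[grp == g]])
  }, numeric(1))
  summary <- list(
    n_isolates = nrow(pt$profiles),
    n_sts = nrow(pt$st_definitions),
    st_counts = as.list(freq),
    n_clonal_complexes = ccs$n_complexes,
    n_singletons = ccs$n_singletons,
    groups = lapply(seq_along(ccs$groups), function(i) list(
      sts = ccs$groups[[i]],
      founder = ccs$founders[i],
      isolates = as.integer(sum(freq[paste0("ST", ccs$groups[[i]])])))),
    mst_total_weight = mst$total_weight,
    linkage = list(V_O = lk$V_O, V_E = lk$V_E, I_A = lk$I_A, I_A_S = lk$I_A_S,
                   p_value = lk$p_value, n_permutations = lk$n_permutations,
                   seed = lk$seed),
    upgma_group_sizes = as.integer(sort(grp_iso, decreasing = TRUE)),
    total_snps = if (!is.null(stats)) total_snps(stats) else NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(stats)) {
      write_locus_stats_tsv(stats, file.path(out_dir, "locus_stats.tsv"))
    }
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    write_tree_newick(up, file.path(out_dir, "upgma.nwk"))
    write_mst_dot(mst, file.path(out_dir, "mst.dot"))
  }
  list(st_counts = freq, locus_stats = stats, ccs = ccs, mst = mst,
       linkage = lk, upgma = up, upgma_groups = grp, summary = summary)
}
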