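# Synthetic scheme / allele / population generator. Provides ground truth
# for every analysis module: planted segregating sites with known
# synonymous/nonsynonymous effects, and populations that are clonal
# (founder + single-locus-variant descendants) or panmictic (independent
# allele draws per locus, i.e. linkage equilibrium by construction).

random_coding_fragment <- function(length_bp, gc_target) {
  if (length_bp %% 3L != 0L) {
    mlst_stop("fragment length must be divisible by 3 (in-frame coding fragment)",
              "mlst_parameter_error")
  }
  gc <- Biostrings::GENETIC_CODE
  probs <- c(A = (1 - gc_target) / 2, C = gc_target / 2,
             G = gc_target / 2, T = (1 - gc_target) / 2)
  n_codons <- length_bp / 3L
  codons <- character(n_codons)
  for (i in seq_len(n_codons)) {
    repeat {
      cod <- paste(sample(DNA_BASES, 3L, replace = TRUE, prob = probs),
                   collapse = "")
      if (gc[[cod]] != "*") break
    }
    codons[i] <- cod
  }
  paste(codons, collapse = "")
}

random_primer <- function() {
  paste(sample(DNA_BASES, sample(18:22, 1L), replace = TRUE), collapse = "")
}

#' Generate a synthetic MLST scheme
#'
#' Random in-frame coding fragments (no internal stop codons) at a requested
#' GC content, flanked by synthesized 18-22 bp primers, so that
#' \code{\link{trim_to_locus}} applied to the amplicon returns the fragment
#' exactly.
#'
#' @param n_loci Number of loci (>= 2).
#' @param fragment_lengths Integer vector (recycled) of fragment lengths in
#'   bp, each divisible by 3.
#' @param gc_target Target GC fraction of the fragments (default 0.45).
#' @param seed Integer seed.
#' @return List with \code{scheme} (an \code{mlst_scheme}), \code{fragments}
#'   (named character vector of reference alleles, one per locus) and
#'   \code{amplicons} (fwd primer + fragment + revcomp(rev primer)).
#' @export
gen_scheme <- function(n_loci = 8L, fragment_lengths = 498L, gc_target = 0.45,
                       seed = 1L) {
  stopifnot(n_loci >= 2L)
  lens <- rep_len(as.integer(fragment_lengths), n_loci)
  with_seed(seed, {
    nms <- sprintf("loc%02d", seq_len(n_loci))
    frags <- character(n_loci)
    loci <- vector("list", n_loci)
    amps <- character(n_loci)
    for (i in seq_len(n_loci)) {
      frags[i] <- random_coding_fragment(lens[i], gc_target)
      fwd <- random_primer()
      rev <- random_primer()
      amps[i] <- paste0(fwd, frags[i], revcomp(rev))
      loci[[i]] <- locus(nms[i], fwd, rev,
                         nchar(fwd) + lens[i] + nchar(rev))
    }
    names(frags) <- nms
    names(amps) <- nms
    list(scheme = scheme(loci, name = "synthetic"),
         fragments = frags, amplicons = amps)
  })
}

#' Embed a locus fragment in its primers plus random flanks
#'
#' Builds a finished-sequence read (the in-silico analogue of a sequenced
#' amplicon): random flank + forward primer + fragment + revcomp(reverse
#' primer) + random flank.
#'
#' @param fragment The allele sequence.
#' @param loc An \code{mlst_locus} (synthetic, so the primers match exactly).
#' @param flank Flank length on each side (default 15).
#' @return Character scalar.
#' @export
embed_fragment <- function(fragment, loc, flank = 15L) {
  f5 <- paste(sample(DNA_BASES, flank, replace = TRUE), collapse = "")
  f3 <- paste(sample(DNA_BASES, flank, replace = TRUE), collapse = "")
  paste0(f5, loc$forward_primer, fragment, revcomp(loc$reverse_primer), f3)
}

# classify the effect of substituting `alt` at fragment position `pos`
substitution_effect <- function(reference, pos, alt) {
  gc <- Biostrings::GENETIC_CODE
  ci <- (pos - 1L) %/% 3L + 1L
  cod <- substr(reference, 3L * ci - 2L, 3L * ci)
  mut <- cod
  substr(mut, (pos - 1L) %% 3L + 1L, (pos - 1L) %% 3L + 1L) <- alt
  if (gc[[mut]] == "*") return("stop")
  if (gc[[mut]] == gc[[cod]]) "synonymous" else "nonsynonymous"
}

#' Generate an allele set with planted polymorphic sites
#'
#' Plants exactly \code{n_sites} segregating sites in distinct codons of the
#' reference fragment; each site's substitution is drawn synonymous or
#' nonsynonymous according to \code{synonymous_fraction} (rejection sampling
#' on the codon effect; stop-creating changes are never used). Alleles are
#' distinct subsets of the planted substitutions, with every site carried by
#' at least one allele, so the realized segregating-site count equals
#' \code{n_sites} exactly.
#'
#' @param reference In-frame A/C/G/T fragment (allele 1).
#' @param n_alleles Number of distinct alleles (>= 2; <= 2^n_sites).
#' @param n_sites Number of segregating sites (<= number of codons).
#' @param synonymous_fraction Probability a planted site is synonymous.
#' @param seed Integer seed.
#' @return List with \code{alleles} (character vector, element i = allele i,
#'   allele 1 = reference) and \code{truth} (data.frame: site, codon,
#'   ref_base, alt_base, effect).
#' @export
gen_alleles <- function(reference, n_alleles, n_sites,
                        synonymous_fraction = 0.8, seed = 1L) {
  if (n_alleles < 2L) {
    if (n_sites > 0L) {
      mlst_stop("cannot plant segregating sites in a single allele",
                "mlst_parameter_error")
    }
    return(list(alleles = reference, truth = data.frame()))
  }
  n_codons <- nchar(reference) %/% 3L
  if (n_sites > n_codons) {
    mlst_stop("more sites requested than codons available", "mlst_parameter_error")
  }
  if (n_alleles > 2^n_sites) {
    mlst_stop(sprintf("%d distinct alleles need at least %d sites",
                      n_alleles, ceiling(log2(n_alleles))), "mlst_parameter_error")
  }
  with_seed(seed, {
    codon_pool <- sample(seq_len(n_codons), n_sites)
    truth <- vector("list", n_sites)
    for (j in seq_len(n_sites)) {
      want <- if (stats::runif(1) < synonymous_fraction) "synonymous" else "nonsynonymous"
      placed <- FALSE
      for (attempt in seq_len(500L)) {
        pos <- 3L * (codon_pool[j] - 1L) + sample.int(3L, 1L)
        ref_base <- substr(reference, pos, pos)
        alt <- sample(setdiff(DNA_BASES, ref_base), 1L)
        eff <- substitution_effect(reference, pos, alt)
        if (eff == want) {
          truth[[j]] <- data.frame(site = pos, codon = codon_pool[j],
                                   ref_base = ref_base, alt_base = alt,
                                   effect = eff)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        # this codon cannot yield the requested effect; swap it for another
        remaining <- setdiff(seq_len(n_codons), codon_pool)
        if (!length(remaining)) {
          mlst_stop("could not place a site with the requested codon effect",
                    "mlst_parameter_error")
        }
        codon_pool[j] <- sample(remaining, 1L)
        j_truth <- scan_codon_for_effect(reference, codon_pool[j], want)
        if (is.null(j_truth)) {
          mlst_stop("could not place a site with the requested codon effect",
                    "mlst_parameter_error")
        }
        truth[[j]] <- j_truth
      }
    }
    truth <- do.call(rbind, truth)
    # membership of each planted substitution in alleles 2..n_alleles
    n_rows <- n_alleles - 1L
    for (attempt in seq_len(1000L)) {
      M <- matrix(stats::runif(n_rows * n_sites) < 0.5, n_rows, n_sites)
      for (j in seq_len(n_sites)) {
        M[(j - 1L) %% n_rows + 1L, j] <- TRUE
      }
      keys <- apply(M, 1L, paste, collapse = "")
      if (!anyDuplicated(keys) && !any(keys == paste(rep("FALSE", n_sites),
                                                     collapse = ""))) break
      M <- NULL
    }
    if (is.null(M)) {
      mlst_stop("could not construct distinct alleles; increase n_sites",
                "mlst_parameter_error")
    }
    alleles <- character(n_alleles)
    alleles[1] <- reference
    for (i in seq_len(n_rows)) {
      a <- reference
      for (j in which(M[i, ])) {
        substr(a, truth$site[j], truth$site[j]) <- truth$alt_base[j]
      }
      alleles[i + 1L] <- a
    }
    list(alleles = alleles, truth = truth)
  })
}

# try every position/alt in a codon for the wanted effect (deterministic scan)
scan_codon_for_effect <- function(reference, codon, want) {
  for (off in sample.int(3L)) {
    pos <- 3L * (codon - 1L) + off
    ref_base <- substr(reference, pos, pos)
    for (alt in sample(setdiff(DNA_BASES, ref_base))) {
      if (substitution_effect(reference, pos, alt) == want) {
        return(data.frame(site = pos, codon = codon, ref_base = ref_base,
                          alt_base = alt, effect = want))
      }
    }
  }
  NULL
}

#' Generate a synthetic population of allelic profiles
#'
#' Clonal mode draws founder profiles (pairwise far apart), then descends
#' each isolate from a random founder by a geometric number of single-locus
#' allele changes, producing the founder-plus-SLV star pattern of clonal
#' populations. Panmictic mode draws every locus's allele independently
#' (uniformly over the locus's alleles by default), i.e. linkage equilibrium
#' by construction.
#'
#' @param mode \code{"clonal"} or \code{"panmictic"}.
#' @param n_isolates Number of isolates (0 gives an empty table).
#' @param allele_counts Named integer vector: alleles available per locus.
#' @param n_founders Clonal mode: number of founders (default 2).
#' @param founder_min_distance Clonal mode: minimum pairwise profile distance
#'   between founders (default: all loci differ).
#' @param p_change Clonal mode: geometric parameter for the number of
#'   single-locus changes per descendant (default 0.5; expected depth 1).
#' @param seed Integer seed.
#' @return List with \code{profiles} (an \code{mlst_profiles}, STs assigned
#'   in input order) and \code{truth} (mode, founder profiles, per-isolate
#'   founder index and mutation depth).
#' @export
gen_population <- function(mode = c("clonal", "panmictic"), n_isolates,
                           allele_counts, n_founders = 2L,
                           founder_min_distance = NULL, p_change = 0.5,
                           seed = 1L) {
  mode <- match.arg(mode)
  loci <- names(allele_counts)
  if (is.null(loci)) {
    loci <- sprintf("loc%02d", seq_along(allele_counts))
    names(allele_counts) <- loci
  }
  l <- length(allele_counts)
  ids <- sprintf("iso%04d", seq_len(n_isolates))
  empty <- function() {
    df <- as.data.frame(c(list(isolate = character(0)),
                          stats::setNames(rep(list(integer(0)), l), loci)))
    profile_table(df, loci)
  }
  if (n_isolates == 0L) {
    return(list(profiles = empty(),
                truth = list(mode = mode, founders = NULL,
                             founder_of = integer(0), depth = integer(0))))
  }
  with_seed(seed, {
    if (mode == "panmictic") {
      mat <- vapply(loci, function(loc) {
        sample.int(allele_counts[[loc]], n_isolates, replace = TRUE)
      }, integer(n_isolates))
      mat <- matrix(mat, nrow = n_isolates,
                    dimnames = list(NULL, loci))
      truth <- list(mode = mode, founders = NULL,
                    founder_of = integer(0), depth = integer(0))
    } else {
      if (any(allele_counts < 2L)) {
        mlst_stop("clonal mode needs >= 2 alleles at every locus",
                  "mlst_parameter_error")
      }
      min_d <- founder_min_distance %||% l
      founders <- matrix(0L, n_founders, l, dimnames = list(NULL, loci))
      for (attempt in seq_len(1000L)) {
        for (f in seq_len(n_founders)) {
          founders[f, ] <- vapply(loci, function(loc)
            sample.int(allele_counts[[loc]], 1L), integer(1))
        }
        ok <- TRUE
        if (n_founders > 1L) {
          for (i in seq_len(n_founders - 1L)) {
            for (j in seq((i + 1L), n_founders)) {
              if (profile_distance(founders[i, ], founders[j, ]) < min_d) ok <- FALSE
            }
          }
        }
        if (ok) break
      }
      if (!ok) {
        mlst_stop("could not draw founders at the requested distance",
                  "mlst_parameter_error")
      }
      founder_of <- sample.int(n_founders, n_isolates, replace = TRUE)
      depth <- stats::rgeom(n_isolates, p_change)
      mat <- founders[founder_of, , drop = FALSE]
      for (i in seq_len(n_isolates)) {
        if (depth[i] == 0L) next
        for (m in seq_len(depth[i])) {
          j <- sample.int(l, 1L)
          mat[i, j] <- sample(setdiff(seq_len(allele_counts[[j]]), mat[i, j]), 1L)
        }
      }
      truth <- list(mode = mode, founders = founders,
                    founder_of = founder_of, depth = depth)
    }
    df <- data.frame(isolate = ids)
    for (j in seq_len(l)) df[[loci[j]]] <- mat[, j]
    pt <- assign_sts(profile_table(df, loci), mode = "open")
    list(profiles = pt, truth = truth)
  })
}

#' Generate and write a complete synthetic MLST dataset
#'
#' Composes \code{\link{gen_scheme}}, \code{\link{gen_alleles}} and
#' \code{\link{gen_population}} and writes a scheme config, an allele
#' database, per-locus isolate FASTAs (fragments embedded in primers with
#' random flanks), a profiles TSV and a truth JSON to \code{out_dir}. All
#' randomness derives from \code{seed}; identical calls are bit-identical.
#'
#' @param out_dir Output directory (created).
#' @param mode,n_isolates,n_founders,p_change Passed to
#'   \code{\link{gen_population}}.
#' @param n_loci,fragment_lengths,gc_target Passed to \code{\link{gen_scheme}}.
#' @param n_alleles,n_sites Integer vectors (recycled over loci) for
#'   \code{\link{gen_alleles}}.
#' @param synonymous_fraction Passed to \code{\link{gen_alleles}}.
#' @param seed Integer master seed (sub-seeds are derived from it).
#' @return Invisibly, a list: scheme, db, profiles, truth, and the file paths.
#' @export
simulate_dataset <- function(out_dir, mode = "clonal", n_isolates = 50L,
                             n_loci = 8L, fragment_lengths = 498L,
                             gc_target = 0.45, n_alleles = 4L, n_sites = 6L,
                             synonymous_fraction = 0.8, n_founders = 2L,
                             p_change = 0.5, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  gs <- gen_scheme(n_loci, fragment_lengths, gc_target, seed = seed)
  s <- gs$scheme
  loci <- locus_names(s)
  n_alleles <- rep_len(as.integer(n_alleles), n_loci)
  n_sites <- rep_len(as.integer(n_sites), n_loci)
  alleles <- list()
  site_truth <- list()
  for (i in seq_len(n_loci)) {
    ga <- gen_alleles(gs$fragments[[i]], n_alleles[i], n_sites[i],
                      synonymous_fraction, seed = seed + i)
    alleles[[loci[i]]] <- ga$alleles
    site_truth[[loci[i]]] <- ga$truth
  }
  db <- allele_database(alleles)
  pop <- gen_population(mode, n_isolates,
                        stats::setNames(n_alleles, loci),
                        n_founders = n_founders, p_change = p_change,
                        seed = seed + n_loci + 1L)
  pt <- pop$profiles
  scheme_path <- file.path(out_dir, "scheme.txt")
  write_scheme(s, scheme_path)
  db_dir <- file.path(out_dir, "alleles")
  write_allele_db(db, db_dir)
  fasta_dir <- file.path(out_dir, "sequences")
  dir.create(fasta_dir, showWarnings = FALSE)
  mat <- if (nrow(pt$profiles)) profile_matrix(pt) else NULL
  with_seed(seed + n_loci + 2L, {
    for (loc in loci) {
      seqs <- character(0)
      if (!is.null(mat)) {
        seqs <- vapply(seq_len(nrow(mat)), function(i) {
          embed_fragment(alleles[[loc]][mat[i, loc]], s$loci[[loc]])
        }, character(1))
        names(seqs) <- rownames(mat)
      }
      if (length(seqs)) write_fasta(seqs, file.path(fasta_dir, paste0(loc, ".fasta")))
    }
  })
  profiles_path <- file.path(out_dir, "profiles.tsv")
  write_profiles_tsv(pt, profiles_path)
  truth <- list(mode = mode, seed = seed,
                n_isolates = n_isolates,
                n_sts = nrow(pt$st_definitions),
                allele_counts = stats::setNames(as.list(n_alleles), loci),
                planted_sites = lapply(site_truth, function(t)
                  if (nrow(t)) t$site else integer(0)),
                site_effects = lapply(site_truth, function(t)
                  if (nrow(t)) t$effect else character(0)),
                founders = if (!is.null(pop$truth$founders))
                  apply(pop$truth$founders, 1L, paste, collapse = "-") else NULL,
                founder_of = pop$truth$founder_of,
                depth = pop$truth$depth)
  truth_path <- file.path(out_dir, "truth.json")
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(scheme = s, db = db, profiles = pt, truth = truth,
                 site_truth = site_truth,
                 paths = list(scheme = scheme_path, alleles = db_dir,
                              sequences = fasta_dir, profiles = profiles_path,
                              truth = truth_path)))
}
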