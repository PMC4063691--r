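box_metric <- function() {
  D <- matrix(c(0, 1, 2, 1,
                1, 0, 1, 2,
                2, 1, 0, 1,
                1, 2, 1, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  stats::as.dist(D)
}

test_that("isolation index specializes to the trivial-split formula", {
  tm <- with_seed_helper(3, random_tree_metric(5L))
  D <- as.matrix(tm$dm)
  n <- nrow(D)
  for (x in seq_len(n)) {
    side <- seq_len(n) == x
    rest <- which(!side)
    pr <- pairs_rest <- expand.grid(k = rest, l = rest)
    want <- min((D[x, pr$k] + D[x, pr$l] - D[cbind(pr$k, pr$l)]) / 2)
    expect_equal(isolation_index(side, D), want, tolerance = 1e-12)
    expect_gte(isolation_index(side, D), 0)
  }
})

test_that("the 4-point box metric carries two incompatible splits of index 1", {
  ss <- split_decomposition(box_metric())
  nontriv <- ss$splits[vapply(ss$splits, function(s) min(sum(s), sum(!s)) > 1L,
                              logical(1))]
  expect_length(nontriv, 2L)
  expect_equal(ss$alpha[1:2], c(1, 1))
  ret <- has_reticulation(ss)
  expect_true(ret$reticulate)
  expect_identical(nrow(ret$pairs), 1L)
  expect_equal(ss$residual, 0, tolerance = 1e-12)
})

test_that("tree metrics decompose exactly into their edge splits", {
  set.seed(77)
  for (n in 5:7) {
    for (rep in 1:5) {
      tm <- random_tree_metric(n)
      ss <- split_decomposition(tm$dm)
      expect_equal(ss$residual, 0, tolerance = 1e-10)
      # every split of an additive metric corresponds to a tree edge:
      # count must equal the number of edges of the unrooted tree with
      # distinct splits (internal + terminal)
      un <- ape::unroot(tm$tree)
      expect_identical(length(ss$splits), nrow(un$edge))
      # and its weights reconstruct the distances exactly (residual 0 means
      # sum matches; check pointwise too)
      D <- as.matrix(tm$dm)
      taxa <- ss$taxa
      dsplit <- matrix(0, n, n, dimnames = list(taxa, taxa))
      for (i in seq_along(ss$splits)) {
        sep <- outer(ss$splits[[i]], ss$splits[[i]], "!=")
        dsplit <- dsplit + ss$alpha[i] * sep
      }
      expect_equal(dsplit[rownames(D), colnames(D)], D, tolerance = 1e-10)
      expect_false(has_reticulation(ss)$reticulate)
    }
  }
})

test_that("a split not matching a tree edge has isolation index 0", {
  set.seed(41)
  for (rep in 1:10) {
    tm <- random_tree_metric(6L)
    D <- as.matrix(tm$dm)
    ss <- split_decomposition(tm$dm)
    edge_sides <- lapply(ss$splits, which)
    # random bipartitions that are not tree splits
    tried <- 0L
    while (tried < 5L) {
      side <- sample(c(TRUE, FALSE), 6L, replace = TRUE)
      if (sum(side) %in% c(0L, 6L)) next
      canon <- if (side[1]) which(side) else which(!side)
      if (any(vapply(edge_sides, identical, logical(1), canon))) next
      expect_equal(isolation_index(side, D), 0, tolerance = 1e-12)
      tried <- tried + 1L
    }
  }
})

test_that("incremental construction agrees with brute force", {
  set.seed(2040)
  for (rep in 1:8) {
    n <- sample(5:9, 1L)
    # mix of tree metric and noise keeps systems non-trivial
    tm <- random_tree_metric(n)
    D <- as.matrix(tm$dm)
    noise <- matrix(stats::runif(n * n, 0, 0.3), n)
    D <- D + (noise + t(noise)) / 2
    diag(D) <- 0
    bf <- split_decomposition(stats::as.dist(D), method = "bruteforce")
    inc <- split_decomposition(stats::as.dist(D), method = "incremental")
    canon <- function(ss) {
      sides <- lapply(ss$splits, function(s) paste(which(s), collapse = ","))
      ord <- order(unlist(sides))
      list(sides = unlist(sides)[ord], alpha = ss$alpha[ord])
    }
    cb <- canon(bf); ci <- canon(inc)
    expect_identical(cb$sides, ci$sides)
    expect_equal(cb$alpha, ci$alpha, tolerance = 1e-10)
  }
})

test_that("emitted split systems are weakly compatible", {
  set.seed(555)
  for (rep in 1:10) {
    n <- sample(5:7, 1L)
    M <- matrix(stats::runif(n * n), n)
    D <- (M + t(M)) / 2
    diag(D) <- 0
    dimnames(D) <- list(paste0("t", 1:n), paste0("t", 1:n))
    ss <- split_decomposition(stats::as.dist(D))
    expect_true(is_weakly_compatible(ss$splits))
    expect_gte(ss$residual, -1e-12)
    expect_lte(ss$residual, 1)
  }
})

test_that("isolation indices never increase as taxa are added", {
  set.seed(808)
  tm <- random_tree_metric(7L)
  D <- as.matrix(tm$dm)
  noise <- matrix(stats::runif(49, 0, 0.2), 7)
  D <- D + (noise + t(noise)) / 2
  diag(D) <- 0
  for (k in 4:6) {
    Dk <- D[1:k, 1:k]
    ssk <- split_decomposition(stats::as.dist(Dk))
    for (i in seq_along(ssk$splits)) {
      # adding taxon k+1 to either side cannot raise the index above alpha_k
      s_a <- c(ssk$splits[[i]], TRUE)
      s_b <- c(ssk$splits[[i]], FALSE)
      expect_lte(isolation_index(s_a, D[1:(k + 1), 1:(k + 1)]),
                 ssk$alpha[i] + 1e-12)
      expect_lte(isolation_index(s_b, D[1:(k + 1), 1:(k + 1)]),
                 ssk$alpha[i] + 1e-12)
    }
  }
})

test_that("per-locus split graphs flag recombinant loci only", {
  # recombinant locus: alleles forming a box metric in sequence space
  recomb <- c("AAA", "AAT", "ATT", "ATA")
  # tree-like locus: nested mutations
  clonal <- c("AAAAAA", "AAAAAT", "AAAATT", "AAATTT")
  res <- locus_split_graphs(list(locR = recomb, locC = clonal,
                                 locMono = rep("AAA", 3L)))
  expect_identical(res$reticulate, c(TRUE, FALSE, FALSE))
  expect_identical(res$n_alleles, c(4L, 4L, 1L))
  systems <- attr(res, "split_systems")
  expect_identical(nrow(has_reticulation(systems$locR)$pairs), 1L)
})

test_that("the taxon cap and Nexus output behave", {
  big <- matrix(1, 61, 61)
  diag(big) <- 0
  expect_error(split_decomposition(stats::as.dist(big)),
               class = "mlst_parameter_error")
  ss <- split_decomposition(box_metric())
  path <- withr::local_tempfile(fileext = ".nex")
  write_nexus_splits(ss, path)
  lines <- readLines(path)
  expect_identical(lines[1], "#NEXUS")
  expect_true(any(grepl("BEGIN Splits;", lines)))
  # the square metric is exactly the two box splits; its trivial splits all
  # have isolation index 0 (no pendant edges), so nsplits = 2
  expect_true(any(grepl("nsplits=2", lines)))
})
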