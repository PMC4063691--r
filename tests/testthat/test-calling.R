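make_locus <- function() {
  fwd <- "GGAGTCGTTTCTGGGTTAC"
  rev <- "GTTGCTTTAGGCGTTGGTG"
  frag <- "ACGTACGT"
  locus("recA", fwd, rev, nchar(fwd) + nchar(frag) + nchar(rev))
}

rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))

test_that("trim_to_locus extracts the fragment in either orientation", {
  loc <- make_locus()
  amplicon <- paste0(loc$forward_primer, "ACGTACGT", rc(loc$reverse_primer))
  read <- paste0("TTTTT", amplicon, "AAAAA")
  expect_identical(trim_to_locus(read, loc), "ACGTACGT")
  expect_identical(trim_to_locus(rc(read), loc), "ACGTACGT")
  expect_identical(trim_to_locus(amplicon, loc, keep_primers = TRUE), amplicon)
})

test_that("trim_to_locus enforces the primer mismatch budget", {
  loc <- make_locus()
  fwd_bad <- loc$forward_primer
  substr(fwd_bad, 3, 5) <- "CCC"   # 3 mismatches vs a budget of 1
  stopifnot(sum(strsplit(fwd_bad, "")[[1]] != strsplit(loc$forward_primer, "")[[1]]) == 3L)
  read <- paste0(fwd_bad, "ACGTACGT", rc(loc$reverse_primer))
  expect_error(trim_to_locus(read, loc, max_primer_mismatches = 1L),
               class = "mlst_primer_error")
  expect_identical(trim_to_locus(read, loc, max_primer_mismatches = 3L),
                   "ACGTACGT")
})

test_that("trim_to_locus flags fragment length anomalies", {
  loc <- make_locus()
  long <- paste0(loc$forward_primer, strrep("ACGT", 20), rc(loc$reverse_primer))
  expect_error(trim_to_locus(long, loc), "length anomaly",
               class = "mlst_length_error")
  expect_identical(trim_to_locus(long, loc, length_tolerance = Inf),
                   strrep("ACGT", 20))
})

test_that("assign_allele matches exactly, extends in open mode, signals in closed", {
  db <- allele_database(list(recA = c("AAAA", "AAAT", "AATA", "ATTA")))
  hit <- assign_allele("AATA", "recA", db, mode = "closed")
  expect_identical(hit$allele, 3L)
  expect_false(hit$novel)
  expect_identical(hit$db$alleles, db$alleles)

  open <- assign_allele("TTTT", "recA", db, mode = "open")
  expect_identical(open$allele, 5L)
  expect_true(open$novel)
  expect_identical(open$db$alleles$recA[5], "TTTT")

  closed <- assign_allele("TTTT", "recA", db, mode = "closed")
  expect_identical(closed$allele, NA_integer_)
  expect_true(closed$novel)

  expect_error(assign_allele("TTTTT", "recA", db), class = "mlst_length_error")
  expect_error(assign_allele("TTNT", "recA", db), class = "mlst_ambiguity_error")
})

test_that("assign_sts numbers novel vectors in first-encounter order", {
  df <- data.frame(isolate = "solo", L1 = 4L, L2 = 9L)
  pt <- assign_sts(profile_table(df, c("L1", "L2")))
  expect_identical(pt$profiles$ST, 1L)

  mat <- rbind(c(1, 1), c(2, 2), c(1, 1))
  pt3 <- toy_profiles(mat)
  expect_identical(pt3$profiles$ST, c(1L, 2L, 1L))
  expect_identical(sort(as.integer(table(pt3$profiles$ST)), decreasing = TRUE),
                   c(2L, 1L))

  closed_pt <- profile_table(data.frame(isolate = "x", L1 = 9L, L2 = 9L),
                             c("L1", "L2"),
                             st_definitions = data.frame(ST = 1L, L1 = 1L, L2 = 1L))
  expect_error(assign_sts(closed_pt, mode = "closed"), class = "mlst_novel_st")
})

test_that("type_batch types a synthetic batch end-to-end and recovers planted STs", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(dir, mode = "clonal", n_isolates = 20L, n_loci = 4L,
                          fragment_lengths = 300L, n_alleles = 4L, n_sites = 5L,
                          n_founders = 2L, seed = 301L)
  res <- type_batch(file.path(dir, "sequences"), sim$scheme,
                    db = sim$db, mode = "open")
  expect_identical(res$failed, character(0))
  expect_identical(nrow(res$profiles$st_definitions), sim$truth$n_sts)
  expect_true(all(res$report$status == "matched"))
  # allele calls agree with the generator's truth profiles
  expect_identical(profile_matrix(res$profiles)[sim$profiles$profiles$isolate, ],
                   profile_matrix(sim$profiles))
})

test_that("type_batch excludes isolates missing at a locus without failing the batch", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(dir, mode = "panmictic", n_isolates = 5L, n_loci = 3L,
                          fragment_lengths = 150L, n_alleles = 3L, n_sites = 4L,
                          seed = 77L)
  # drop one isolate from one locus file
  loc1 <- locus_names(sim$scheme)[1]
  f <- file.path(dir, "sequences", paste0(loc1, ".fasta"))
  seqs <- read_locus_fasta(f)
  write_tmp <- seqs[-3]
  writeLines(unlist(lapply(names(write_tmp), function(id)
    c(paste0(">", id), write_tmp[[id]]))), f)
  res <- type_batch(file.path(dir, "sequences"), sim$scheme, db = sim$db)
  expect_identical(res$failed, names(seqs)[3])
  expect_identical(nrow(res$profiles$profiles), 4L)
  expect_identical(res$report$status[res$report$isolate == names(seqs)[3] &
                                     res$report$locus == loc1], "missing")
})

test_that("typing is deterministic and input order only permutes novel labels", {
  dir <- withr::local_tempdir()
  sim <- simulate_dataset(dir, mode = "clonal", n_isolates = 12L, n_loci = 3L,
                          fragment_lengths = 150L, n_alleles = 4L, n_sites = 5L,
                          seed = 9L)
  paths <- setNames(file.path(dir, "sequences",
                              paste0(locus_names(sim$scheme), ".fasta")),
                    locus_names(sim$scheme))
  res1 <- type_batch(as.list(paths), sim$scheme, mode = "open")
  res2 <- type_batch(as.list(paths), sim$scheme, mode = "open")
  expect_identical(res1$profiles$profiles, res2$profiles$profiles)

  # reverse the record order in every FASTA: the partition of isolates into
  # STs must be unchanged even though novel numbering may differ
  dir2 <- withr::local_tempdir()
  for (loc in locus_names(sim$scheme)) {
    seqs <- rev(read_locus_fasta(paths[[loc]]))
    writeLines(unlist(lapply(names(seqs), function(id)
      c(paste0(">", id), seqs[[id]]))), file.path(dir2, paste0(loc, ".fasta")))
  }
  res3 <- type_batch(dir2, sim$scheme, mode = "open")
  st1 <- res1$profiles$profiles$ST[order(res1$profiles$profiles$isolate)]
  st3 <- res3$profiles$profiles$ST[order(res3$profiles$profiles$isolate)]
  part1 <- unname(split(seq_along(st1), st1))
  part3 <- unname(split(seq_along(st3), st3))
  expect_setequal(part1, part3)
})
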