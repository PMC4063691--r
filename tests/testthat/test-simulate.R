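test_that("gen_scheme hits the GC target and stays in frame", {
  gs <- gen_scheme(n_loci = 3L, fragment_lengths = 600L, gc_target = 0.5,
                   seed = 100L)
  for (frag in gs$fragments) {
    expect_identical(nchar(frag), 600L)
    expect_lt(abs(gc_content(frag) / 100 - 0.5), 0.03)
    cods <- substring(frag, seq(1, 600, 3), seq(3, 600, 3))
    expect_false(any(Biostrings::GENETIC_CODE[cods] == "*"))
  }
  expect_error(gen_scheme(2L, fragment_lengths = 400L, seed = 1L),
               class = "mlst_parameter_error")
})

test_that("trim_to_locus inverts embed_fragment for every generated locus", {
  gs <- gen_scheme(n_loci = 4L, fragment_lengths = 300L, seed = 42L)
  set.seed(9)
  for (loc_name in locus_names(gs$scheme)) {
    loc <- gs$scheme$loci[[loc_name]]
    frag <- gs$fragments[[loc_name]]
    read <- embed_fragment(frag, loc)
    expect_identical(trim_to_locus(read, loc), frag)
    expect_identical(trim_to_locus(gs$amplicons[[loc_name]], loc), frag)
  }
})

test_that("gen_alleles plants exactly the requested sites and effects", {
  ref <- with_seed_helper(1, random_codon_seq(100L))
  ga <- gen_alleles(ref, n_alleles = 6L, n_sites = 9L,
                    synonymous_fraction = 0.5, seed = 5L)
  expect_length(ga$alleles, 6L)
  expect_identical(count_polymorphic_sites(ga$alleles), 9L)
  expect_identical(sort(ga$truth$site),
                   sort(which(apply(seq_matrix_test(ga$alleles), 2L,
                                    function(col) length(unique(col)) > 1L))))
  # effects recorded in truth match direct codon translation
  for (r in seq_len(nrow(ga$truth))) {
    ci <- ga$truth$codon[r]
    ref_cod <- substr(ref, 3 * ci - 2, 3 * ci)
    mut_cod <- ref_cod
    substr(mut_cod, (ga$truth$site[r] - 1) %% 3 + 1,
           (ga$truth$site[r] - 1) %% 3 + 1) <- ga$truth$alt_base[r]
    same_aa <- Biostrings::GENETIC_CODE[[ref_cod]] ==
      Biostrings::GENETIC_CODE[[mut_cod]]
    expect_identical(ga$truth$effect[r],
                     if (same_aa) "synonymous" else "nonsynonymous")
  }
})

test_that("all-synonymous allele sets give dN exactly 0", {
  ref <- with_seed_helper(2, random_codon_seq(120L))
  ga <- gen_alleles(ref, n_alleles = 5L, n_sites = 8L,
                    synonymous_fraction = 1, seed = 6L)
  res <- locus_dn_ds(ga$alleles)
  expect_identical(res$dN, 0)
  expect_identical(res$ratio, 0)
})

test_that("inconsistent allele requests are refused", {
  ref <- with_seed_helper(3, random_codon_seq(30L))
  expect_error(gen_alleles(ref, n_alleles = 1L, n_sites = 3L, seed = 1L),
               class = "mlst_parameter_error")
  expect_error(gen_alleles(ref, n_alleles = 9L, n_sites = 3L, seed = 1L),
               class = "mlst_parameter_error")
  expect_error(gen_alleles(ref, n_alleles = 2L, n_sites = 31L, seed = 1L),
               class = "mlst_parameter_error")
})

test_that("panmictic populations are near linkage equilibrium", {
  pop <- gen_population("panmictic", 500L,
                        setNames(rep(4L, 8L), paste0("L", 1:8)), seed = 2024L)
  expect_identical(nrow(pop$profiles$profiles), 500L)
  expect_lt(abs(index_of_association(pop$profiles)$I_A), 0.1)
})

test_that("clonal populations recover founders and groups", {
  pop <- gen_population("clonal", 60L, setNames(rep(5L, 8L), paste0("L", 1:8)),
                        n_founders = 2L, p_change = 0.5, seed = 33L)
  expect_identical(pop$truth$mode, "clonal")
  expect_identical(profile_distance(pop$truth$founders[1, ],
                                    pop$truth$founders[2, ]), 8L)
  ccs <- group_sts(pop$profiles, threshold = 5L)
  # the two founder profiles must sit in different groups
  key <- apply(pop$truth$founders, 1L, paste, collapse = "-")
  dkey <- apply(profile_matrix(pop$profiles, by = "st"), 1L, paste, collapse = "-")
  f_st <- as.integer(sub("ST", "", rownames(profile_matrix(pop$profiles, by = "st"))[match(key, dkey)]))
  grp_of <- integer(nrow(pop$profiles$st_definitions))
  for (i in seq_along(ccs$groups)) grp_of[ccs$groups[[i]]] <- i
  expect_false(grp_of[f_st[1]] == grp_of[f_st[2]])
})

test_that("an empty population is an empty table, not an error", {
  pop <- gen_population("panmictic", 0L, setNames(rep(3L, 4L), paste0("L", 1:4)),
                        seed = 1L)
  expect_identical(nrow(pop$profiles$profiles), 0L)
})

test_that("generators are bit-reproducible and do not disturb the caller's RNG", {
  a <- gen_population("clonal", 20L, setNames(rep(4L, 6L), paste0("L", 1:6)),
                      seed = 7L)
  set.seed(1234)
  before <- .Random.seed
  b <- gen_population("clonal", 20L, setNames(rep(4L, 6L), paste0("L", 1:6)),
                      seed = 7L)
  expect_identical(.Random.seed, before)
  expect_identical(a$profiles$profiles, b$profiles$profiles)
  expect_identical(a$truth, b$truth)
})

test_that("simulate_dataset writes a complete, reproducible dataset", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  s1 <- simulate_dataset(d1, mode = "clonal", n_isolates = 15L, n_loci = 4L,
                         fragment_lengths = 240L, n_alleles = 4L, n_sites = 5L,
                         seed = 55L)
  simulate_dataset(d2, mode = "clonal", n_isolates = 15L, n_loci = 4L,
                   fragment_lengths = 240L, n_alleles = 4L, n_sites = 5L,
                   seed = 55L)
  for (f in c("scheme.txt", "profiles.tsv", "truth.json",
              file.path("sequences", paste0(locus_names(s1$scheme), ".fasta")),
              file.path("alleles", paste0(locus_names(s1$scheme), ".fasta")))) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  # the written profile table re-reads to the generated one
  pt <- read_profiles_tsv(file.path(d1, "profiles.tsv"), s1$scheme)
  expect_identical(profile_matrix(pt), profile_matrix(s1$profiles))
})
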