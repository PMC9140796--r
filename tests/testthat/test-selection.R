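test_that("codon pair counts match hand-derived values", {
  # TTT/TTC: one synonymous difference; syn sites 1/3 each
  cnt <- ng_codon_pair_counts("TTT", "TTC")
  expect_equal(cnt$Sd, 1)
  expect_equal(cnt$Nd, 0)
  expect_equal(cnt$s1, 1 / 3)
  expect_equal(cnt$s2, 1 / 3)
  expect_equal(ng_codon_pair_counts("GGG", "GGG")$s1, 1)
  expect_error(ng_codon_pair_counts("TAA", "TTT"), "Stop")
})

test_that("potential sites sum to 3 and match enumeration for all sense codons", {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  for (cod in sense) {
    s <- ng_codon_pair_counts(cod, cod)$s1
    expect_equal(s, oracle_syn_sites(cod), info = cod)
    expect_true(s >= 0 && s <= 3)
  }
})

test_that("pathway averaging agrees with exhaustive enumeration on random pairs", {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  withr::with_seed(8, {
    pairs <- cbind(sample(sense, 120, replace = TRUE),
                   sample(sense, 120, replace = TRUE))
  })
  for (r in seq_len(nrow(pairs))) {
    got <- ng_codon_pair_counts(pairs[r, 1], pairs[r, 2])
    want <- oracle_ng_counts(pairs[r, 1], pairs[r, 2])
    expect_equal(got$Sd, unname(want["Sd"]),
                 info = paste(pairs[r, ], collapse = "/"))
    expect_equal(got$Nd, unname(want["Nd"]),
                 info = paste(pairs[r, ], collapse = "/"))
    # conservation: averaged changes sum to the positional differences
    n_diff <- sum(strsplit(pairs[r, 1], "")[[1]] !=
                    strsplit(pairs[r, 2], "")[[1]])
    expect_equal(got$Sd + got$Nd, n_diff)
  }
})

test_that("dN/dS on the worked single-difference pair matches closed form", {
  aln <- make_aln(c(a = "TTTGGGAAA", b = "TTCGGGAAA"))
  res <- ng_dn_ds(aln, bootstrap_reps = 200, seed = 1)
  expect_equal(res$dS, -0.75 * log(1 - 4 / 3 * 0.6), tolerance = 1e-12)
  expect_equal(res$dN, 0)
  expect_equal(res$omega, 0)
  raw <- ng_dn_ds(aln, correction = "none", bootstrap_reps = 50, seed = 1)
  expect_equal(raw$dS, 0.6)  # pS = 1 / (5/3)
  expect_equal(raw$dN, 0)
})

test_that("identical sequences give null rates and a flat test", {
  aln <- make_aln(rep(strrep("ATGAAG", 5), 3))
  res <- ng_dn_ds(aln, bootstrap_reps = 50, seed = 1)
  expect_equal(res$dN, 0)
  expect_equal(res$dS, 0)
  expect_equal(res$Z_neq, 0)
  expect_equal(res$p_neq, 1)
})

test_that("uncorrected rates reduce to proportions on single-difference pairs", {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  withr::with_seed(13, picks <- sample(sense, 10))
  for (cod in picks) {
    ch <- strsplit(cod, "")[[1]]
    repeat {
      p <- sample(1:3, 1)
      mut <- ch
      mut[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      mut_cod <- paste(mut, collapse = "")
      if (code[mut_cod] != "*") break
    }
    aln <- make_aln(c(a = cod, b = mut_cod))
    raw <- ng_dn_ds(aln, correction = "none", bootstrap_reps = 10, seed = 1)
    cnt <- ng_codon_pair_counts(cod, mut_cod)
    sbar <- (cnt$s1 + cnt$s2) / 2
    expect_equal(raw$dS, if (sbar > 0) cnt$Sd / sbar else 0)
    expect_equal(raw$dN, cnt$Nd / (3 - sbar))
  }
})

test_that("the selection Z-test matches normal-theory p-values", {
  flat <- z_test_selection(0.1, 0.1, 0.001, 0.001, "neq")
  expect_equal(flat$Z, 0)
  expect_equal(flat$p, 1)
  expect_equal(z_test_selection(0.1, 0.1, 0.001, 0.001, "pos")$p, 0.5)

  res <- z_test_selection(1.96, 0, 0.5, 0.5, "neq")
  expect_equal(res$p, 0.05, tolerance = 1e-3)
  expect_error(z_test_selection(0.1, 0.2, 0, 0), "zero")
})

test_that("Wu-Kabat scores follow N * k / n with X excluded", {
  # invariant site -> 1; all-distinct site with N = 4 -> 16
  wk <- wu_kabat_profile(c("AR", "AK", "AQ", "AE"))
  expect_equal(wk$profile$W, c(1, 16))
  # N = 10, residues 5/3/2 -> W = 10 * 3 / 5 = 6
  col <- c(rep("A", 5), rep("S", 3), rep("T", 2))
  wk2 <- wu_kabat_profile(paste0(col, "G"))
  expect_equal(wk2$profile$W[1], 6)
  # X is excluded from both k and the modal count
  wk3 <- wu_kabat_profile(c("AX", "AA", "AA"))
  expect_equal(wk3$profile$W[2], 3 * 1 / 2)
  expect_error(wu_kabat_profile("AA"), "At least 2")
})

test_that("Wu-Kabat profile is permutation-invariant and monotone in k", {
  withr::with_seed(31, {
    peps <- translate_codons(make_aln(replicate(6, random_codon_seq(12))))
  })
  w1 <- wu_kabat_profile(peps)
  w2 <- wu_kabat_profile(peps[sample.int(6), ])
  expect_equal(w1$profile, w2$profile)
  # adding a novel residue at a site cannot decrease k there
  extra <- peps$aa[1]
  substr(extra, 1, 1) <- if (substr(extra, 1, 1) == "W") "M" else "W"
  w3 <- wu_kabat_profile(c(peps$aa, extra))
  expect_gte(w3$profile$n_residues[1], w1$profile$n_residues[1])
})

test_that("conserved fragments are maximal invariant runs", {
  # 12 codons: sites 1-6 invariant, 7 variable, 8-12 invariant
  a <- "AAAAAAKAAAAA"
  b <- "AAAAAARAAAAA"
  wk <- wu_kabat_profile(c(a, b), min_run = 5)
  expect_equal(wk$conserved_runs$start, c(1L, 8L))
  expect_equal(wk$conserved_runs$end, c(6L, 12L))
  wk6 <- wu_kabat_profile(c(a, b), min_run = 6)
  expect_equal(nrow(wk6$conserved_runs), 1L)
})

test_that("elevated PBS polymorphism surfaces in partitioned dN/dS", {
  sim <- simulate_clone_library(n_individuals = 24, seed = 17,
                                pbs_nonsyn_multiplier = 8)
  pool <- sim$truth$allele_pool
  kept <- pool[!is.na(pool$class) & pool$class != "pseudogene", ]
  aln <- as_codon_alignment(tibble::tibble(id = kept$haplotype_id,
                                           seq = kept$seq))
  part <- site_partition(pbs_default())
  pbs <- ng_dn_ds(aln, part, bootstrap_reps = 100, seed = 1)
  expect_gt(pbs$dN, 0)
  expect_gte(pbs$dN, pbs$dS)  # nonsynonymous change concentrated at PBS
})
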