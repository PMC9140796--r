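test_that("segregating sites are counted per partition column", {
  expect_equal(segregating_sites(make_aln(rep("AAA", 3))), 0)
  aln <- make_aln(c("AAAAAA", "AATAAA", "AACAAA"))  # A/T/C at site 3
  expect_equal(segregating_sites(aln), 1)
  expect_equal(segregating_sites(aln, partition = 1), 1)
  expect_equal(segregating_sites(aln, partition = 2), 0)
  expect_error(segregating_sites(make_aln("AAA")), "At least 2")
})

test_that("columns containing N are excluded from segregating sites", {
  aln <- make_aln(c("ANA", "ANA", "ATA"))
  expect_equal(segregating_sites(aln), 0)
})

test_that("pairwise diversity matches direct enumeration", {
  two <- make_aln(c("AAATTT", "ATTTAT"))
  pd <- pairwise_diversity(two)
  expect_equal(pd$K, 3)
  expect_equal(pd$pi, 0.5)

  three <- pairwise_diversity(make_aln(c("AAA", "AAT", "ATT")))
  expect_equal(three$K, 4 / 3)
  expect_equal(three$pi, 4 / 9, tolerance = 1e-12)

  # brute-force oracle on random alignments with n <= 6
  withr::with_seed(100, {
    for (r in 1:10) {
      aln <- random_polymorphic_alignment(n = sample(3:6, 1))
      expect_equal(pairwise_diversity(aln)$K, oracle_mean_pairwise(aln$seq))
    }
  })
})

test_that("frequency weighting equals expanding duplicated haplotypes", {
  withr::with_seed(42, aln <- random_polymorphic_alignment(n = 4))
  freqs <- c(3, 1, 2, 4)
  expanded <- make_aln(rep(aln$seq, freqs))
  expect_equal(pairwise_diversity(aln, freqs = freqs)$K,
               pairwise_diversity(expanded)$K)
})

test_that("haplotype diversity follows the unbiased formula", {
  expect_equal(haplotype_diversity(c(1, 1)), 1)
  expect_equal(haplotype_diversity(c(5)), 0)  # one haplotype, 5 carriers
  expect_equal(haplotype_diversity(c(4, 4, 2)), 0.7111, tolerance = 1e-4)
  expect_equal(haplotype_diversity(c("a", "a", "b")),
               haplotype_diversity(c(2, 1)))
  expect_error(haplotype_diversity(c(1)), "At least 2")
})

test_that("mean p-distance has closed-form mean and sensible bootstrap se", {
  ident <- make_aln(rep(strrep("ACG", 8), 3))
  res <- mean_p_distance(ident, "nt", bootstrap_reps = 50, seed = 1)
  expect_equal(res$d, 0)
  expect_equal(res$se, 0)

  # 10 codons, 6 differing sites in distinct codons -> d = 0.2; the
  # bootstrap se should match the analytic codon-resampling se
  base <- strrep("AAA", 10)
  mut <- base
  for (p in c(1, 4, 7, 10, 13, 16)) substr(mut, p, p) <- "T"
  two <- make_aln(c(base, mut))
  res2 <- mean_p_distance(two, "nt", bootstrap_reps = 2000, seed = 2)
  expect_equal(res2$d, 0.2)
  p_c <- c(rep(1 / 3, 6), rep(0, 4))  # per-codon difference proportions
  se_analytic <- sqrt(mean((p_c - mean(p_c))^2) / 10)
  expect_lt(abs(res2$se - se_analytic) / se_analytic, 0.15)

  expect_error(mean_p_distance(two, "nt", partition = integer()),
               "artition")
})

test_that("nt p-distance equals pi for distinct-haplotype input", {
  withr::with_seed(12, aln <- random_polymorphic_alignment(n = 5))
  d <- mean_p_distance(aln, "nt", bootstrap_reps = 10, seed = 1)$d
  expect_equal(d, pairwise_diversity(aln)$pi, tolerance = 1e-12)
})

test_that("pi over all sites is the site-weighted mean of partition pis", {
  withr::with_seed(77, aln <- random_polymorphic_alignment(n = 5,
                                                           n_codons = 12))
  part <- site_partition(c(2, 5, 9), codon_count = 12)
  pi_all <- pairwise_diversity(aln)$pi
  pbs <- pairwise_diversity(aln, part)
  non <- pairwise_diversity(aln, part$non_pbs_codons)
  expect_equal(pi_all,
               (pbs$pi * pbs$sites + non$pi * non$sites) /
                 (pbs$sites + non$sites),
               tolerance = 1e-12)
})

test_that("site partitions validate their codon indices", {
  p <- site_partition(pbs_default())
  expect_length(p$pbs_codons, 20)
  expect_length(p$non_pbs_codons, 46)
  expect_equal(sort(c(p$pbs_codons, p$non_pbs_codons)), 1:66)
  expect_error(site_partition(c(1, 70)), "1..66")
  expect_error(site_partition(integer()), "Empty")
})

test_that("diversity summary assembles the table row", {
  withr::with_seed(3, aln <- random_polymorphic_alignment(n = 6,
                                                          n_codons = 20))
  row <- diversity_summary(aln, bootstrap_reps = 20, seed = 1)
  expect_equal(row$sites, 60)
  expect_equal(row$K / row$sites, row$pi)
  expect_gte(row$S, 1)
  expect_true(is.na(row$Hd))
  row2 <- diversity_summary(aln, freqs = rep(2, 6), bootstrap_reps = 5,
                            seed = 1)
  expect_true(row2$Hd > 0 && row2$Hd <= 1)
})
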