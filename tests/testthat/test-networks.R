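test_that("minimum spanning networks handle degenerate and tied cases", {
  single <- minimum_spanning_network(make_aln(c(A = "AAA")))
  expect_equal(nrow(single$nodes), 1)
  expect_equal(nrow(single$edges), 0)

  # chain A-B-C: the distance-2 A-C edge is excluded entirely
  net <- minimum_spanning_network(make_aln(c(A = "AAA", B = "AAT",
                                             C = "ATT")))
  expect_equal(nrow(net$edges), 2)
  expect_true(all(net$edges$in_mst))
  expect_setequal(paste(net$edges$from, net$edges$to),
                  c("A B", "B C"))

  # four haplotypes all at distance 1 (one four-state column):
  # 3 spanning edges + 3 co-minimal alternatives
  tie <- minimum_spanning_network(make_aln(c(A = "AAA", B = "CAA",
                                             C = "GAA", D = "TAA")))
  expect_equal(nrow(tie$edges), 6)
  expect_equal(sum(tie$edges$in_mst), 3)
  expect_equal(sum(!tie$edges$in_mst), 3)
})

test_that("identical haplotypes are collapsed with summed frequencies", {
  net <- minimum_spanning_network(make_aln(c(A = "AAA", B = "AAA",
                                             C = "AAT")),
                                  freqs = c(2, 3, 1))
  expect_equal(nrow(net$nodes), 2)
  expect_equal(net$nodes$frequency[net$nodes$id == "A"], 5)
})

test_that("spanning-edge weight equals the independent MST oracle", {
  withr::with_seed(23, {
    for (r in 1:8) {
      aln <- random_polymorphic_alignment(n = sample(4:7, 1))
      aln <- make_aln(unique(aln$seq))
      if (nrow(aln) < 3) next
      net <- minimum_spanning_network(aln)
      m <- do.call(rbind, strsplit(aln$seq, ""))
      d <- as.matrix(stats::dist(apply(m, 2, function(c) match(c, c("A","C","G","T"))),
                                 method = "manhattan"))
      # Hamming for single-character states: count of differing columns
      d2 <- matrix(0, nrow(m), nrow(m))
      for (i in seq_len(nrow(m))) {
        for (j in seq_len(nrow(m))) d2[i, j] <- sum(m[i, ] != m[j, ])
      }
      adj <- ape::mst(stats::as.dist(d2))
      oracle_weight <- sum(d2[adj == 1]) / 2
      expect_equal(sum(net$edges$distance[net$edges$in_mst]), oracle_weight)
      expect_equal(sum(net$edges$in_mst), nrow(aln) - 1)
    }
  })
})

test_that("hamming distances form a metric", {
  withr::with_seed(61, aln <- random_polymorphic_alignment(n = 6))
  d <- mhc2popkit:::hamming_matrix(mhc2popkit:::aln_matrix(aln))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  n <- nrow(d)
  for (i in 1:n) for (j in 1:n) for (k in 1:n) {
    expect_lte(d[i, j], d[i, k] + d[k, j])
  }
})

test_that("locus clustering recovers well-separated synthetic pools", {
  sim <- simulate_clone_library(n_individuals = 20, seed = 77,
                                inter_locus_diffs = 25)
  pool <- sim$truth$allele_pool
  kept <- pool[!is.na(pool$class), ]
  aln <- as_codon_alignment(tibble::tibble(id = kept$haplotype_id,
                                           seq = kept$seq))
  cl <- locus_clusters(aln, k = 2, bootstrap_reps = 50, seed = 3)
  joined <- dplyr::left_join(cl$assignments,
                             kept[, c("haplotype_id", "locus")],
                             by = c(id = "haplotype_id"))
  tab <- table(joined$cluster, joined$locus)
  # each cluster maps to exactly one simulated locus
  expect_equal(sum(apply(tab, 1, function(x) sum(x > 0))), 2)
  expect_true(all(cl$support$support >= 0.9))
})

test_that("cluster assignment is invariant under reordering and renaming", {
  sim <- simulate_clone_library(n_individuals = 12, seed = 41)
  pool <- sim$truth$allele_pool
  kept <- pool[!is.na(pool$class), ]
  aln <- as_codon_alignment(tibble::tibble(id = kept$haplotype_id,
                                           seq = kept$seq))
  cl1 <- locus_clusters(aln, seed = 1, bootstrap_reps = 10)
  perm <- withr::with_seed(2, sample.int(nrow(aln)))
  renamed <- as_codon_alignment(tibble::tibble(
    id = paste0("x", seq_len(nrow(aln))), seq = aln$seq[perm]
  ))
  cl2 <- locus_clusters(renamed, seed = 1, bootstrap_reps = 10)
  # compare the partitions as sets of original row indices
  part1 <- unname(lapply(split(seq_len(nrow(aln)),
                               cl1$assignments$cluster), sort))
  part2 <- unname(lapply(split(perm, cl2$assignments$cluster), sort))
  expect_true(all(vapply(part1, function(s) {
    any(vapply(part2, identical, logical(1), y = s))
  }, logical(1))))
})

test_that("degenerate clustering input errors", {
  expect_error(locus_clusters(make_aln(rep("AAA", 4)), k = 2),
               "identical")
})
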