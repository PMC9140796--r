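clone_row <- function(ind, pcr, clone, seq) {
  tibble::tibble(individual_id = ind, pcr_id = pcr, clone_id = clone,
                 sequence = seq)
}

test_that("classification follows the shared-carrier and clone-count rules", {
  withr::with_seed(21, {
    s_true <- random_codon_seq(6)
    s_uni <- random_codon_seq(6)
    s_art <- random_codon_seq(6)
  })
  s_pseudo <- paste0("TAA", substr(random_codon_seq(5), 1, 15))

  clones <- dplyr::bind_rows(
    # two carriers, two PCR runs -> putative_true
    clone_row("A", "p1", "c1", s_true), clone_row("B", "p2", "c1", s_true),
    # one carrier, three identical clones over two PCRs -> unique
    clone_row("A", "p1", "c2", s_uni), clone_row("A", "p1", "c3", s_uni),
    clone_row("A", "p2", "c4", s_uni),
    # stop codon, two carriers -> pseudogene despite meeting the true rule
    clone_row("A", "p1", "c5", s_pseudo), clone_row("A", "p2", "c6", s_pseudo),
    clone_row("B", "p1", "c2", s_pseudo), clone_row("B", "p2", "c2b", s_pseudo),
    # one carrier, two clones, one PCR -> artifact
    clone_row("C", "p1", "c1", s_art), clone_row("C", "p1", "c2", s_art)
  )
  cat <- classify_haplotypes(clones)
  cls <- setNames(as.character(cat$class), cat$seq)
  expect_equal(unname(cls[s_true]), "putative_true")
  expect_equal(unname(cls[s_uni]), "unique")
  expect_equal(unname(cls[s_pseudo]), "pseudogene")
  expect_equal(unname(cls[s_art]), "artifact")
  # clone counts are conserved
  expect_equal(sum(cat$clone_count), nrow(clones))
})

test_that("a stop-codon haplotype failing both count rules is an artifact", {
  s <- paste0("ATG", "TGA", "AAA")
  cat <- classify_haplotypes(clone_row("A", "p1", "c1", s))
  expect_equal(as.character(cat$class), "artifact")
})

test_that("classification and IDs are invariant under clone row order", {
  sim <- simulate_clone_library(n_individuals = 12, pcr_error_rate = 0.001,
                                seed = 303)
  cat1 <- classify_haplotypes(sim$clones)
  shuffled <- withr::with_seed(7, sim$clones[sample.int(nrow(sim$clones)), ])
  cat2 <- classify_haplotypes(shuffled)
  expect_equal(cat1, cat2)
})

test_that("artifacts fail both count rules on noisy synthetic libraries", {
  sim <- simulate_clone_library(n_individuals = 15, pcr_error_rate = 0.002,
                                seed = 99)
  cat <- classify_haplotypes(sim$clones)
  art <- cat[cat$class == "artifact", ]
  expect_gt(nrow(art), 0)  # at this error rate some artifacts must appear
  fails_true <- art$n_carriers < 2 | art$pcr_replicates < 2
  fails_unique <- art$n_carriers != 1 | art$clone_count < 3 |
    art$pcr_replicates < 2
  expect_true(all(fails_true & fails_unique))
  # every artifact differs from some non-artifact haplotype
  expect_true(all(!art$seq %in% cat$seq[cat$class != "artifact"]))
})

test_that("catalog summaries count classes and per-individual haplotypes", {
  withr::with_seed(5, {
    s1 <- random_codon_seq(4); s2 <- random_codon_seq(4)
  })
  clones <- dplyr::bind_rows(
    clone_row("A", "p1", "c1", s1), clone_row("B", "p2", "c1", s1),
    clone_row("A", "p1", "c2", s2), clone_row("B", "p1", "c3", s2)
  )
  sm <- summarize_catalog(classify_haplotypes(clones))
  counts <- setNames(sm$class_counts$n, sm$class_counts$class)
  expect_equal(unname(counts[c("putative_true", "unique", "pseudogene",
                               "artifact")]),
               c(2L, 0L, 0L, 0L))
  expect_equal(sort(sm$per_individual$n_haplotypes), c(2L, 2L))

  empty <- summarize_catalog(classify_haplotypes(clones[0, ]))
  expect_equal(sum(empty$class_counts$n), 0L)
  expect_equal(nrow(empty$per_individual), 0L)
})
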