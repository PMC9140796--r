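test_that("clone-library simulation is deterministic and frame-safe", {
  a <- simulate_clone_library(n_individuals = 10, seed = 5)
  b <- simulate_clone_library(n_individuals = 10, seed = 5)
  expect_identical(a, b)
  expect_true(all(nchar(a$clones$sequence) == 198))
  expect_true(all(grepl("^[ACGT]+$", a$clones$sequence)))
  # every clone derives from an assigned haplotype at zero error
  expect_true(all(a$clones$sequence %in% a$truth$allele_pool$seq))
})

test_that("pseudogene_fraction = 0 leaves the library stop-free", {
  sim <- simulate_clone_library(n_individuals = 10,
                                pseudogene_fraction = 0, seed = 8)
  pep <- translate_codons(tibble::tibble(
    id = as.character(seq_len(nrow(sim$clones))),
    seq = sim$clones$sequence
  ))
  expect_false(any(pep$has_internal_stop))
})

test_that("error-free libraries are recovered exactly by classification", {
  for (s in c(1, 2, 3, 104, 105)) {
    sim <- simulate_clone_library(n_individuals = 16, seed = s)
    cat <- classify_haplotypes(sim$clones)
    truth <- sim$truth$allele_pool
    truth <- truth[!is.na(truth$class), ]
    expect_equal(nrow(cat), nrow(truth), info = paste("seed", s))
    merged <- dplyr::inner_join(truth, cat[, c("seq", "class")], by = "seq",
                                suffix = c("_truth", "_found"))
    expect_equal(nrow(merged), nrow(truth), info = paste("seed", s))
    expect_equal(as.character(merged$class_found),
                 as.character(merged$class_truth), info = paste("seed", s))
  }
})

test_that("per-individual haplotype and clone counts respect the ranges", {
  sim <- simulate_clone_library(n_individuals = 25, seed = 12)
  per_ind <- table(sim$truth$assignments$individual_id)
  expect_true(all(per_ind >= 1 & per_ind <= 6))
  clone_counts <- table(sim$clones$individual_id)
  expect_true(all(clone_counts >= 8 & clone_counts <= 24))
  expect_setequal(unique(sim$clones$pcr_id), c("pcr1", "pcr2"))
})

test_that("coalescent samples are deterministic with matching moments", {
  a <- simulate_coalescent_sample(8, L = 300, theta0 = 2, seed = 3)
  b <- simulate_coalescent_sample(8, L = 300, theta0 = 2, seed = 3)
  expect_identical(a, b)
  expect_true(all(nchar(a$seq) == 300))

  # tau = 0 reduces to constant size theta0: E[K] = theta0 for n = 2
  withr::with_seed(30, {
    K <- replicate(200, {
      aln <- simulate_coalescent_sample(2, L = 999, theta0 = 3)
      pairwise_diversity(aln)$K
    })
  })
  expect_lt(abs(mean(K) - 3) / 3, 0.05 + 3 * sd(K) / sqrt(200) / 3)

  # piecewise model: E[K] = theta1 + exp(-tau/theta1) (theta0 - theta1)
  withr::with_seed(31, {
    K2 <- replicate(150, {
      aln <- simulate_coalescent_sample(2, L = 2001, theta0 = 1,
                                        theta1 = 50, tau = 5)
      pairwise_diversity(aln)$K
    })
  })
  expected <- 50 + exp(-5 / 50) * (1 - 50)
  expect_lt(abs(mean(K2) - expected), 3 * sd(K2) / sqrt(150))
})

test_that("infinite-sites overflow is caught with advice", {
  expect_error(simulate_coalescent_sample(10, L = 3, theta0 = 50, seed = 1),
               "Increase L")
})

test_that("large samples converge to the expected mismatch distribution", {
  # single samples keep genealogical correlation, so the empirical
  # distribution averaged over replicates is compared to the expectation
  tau <- 5; th0 <- 1; th1 <- 20
  reps <- 40
  d_max <- 120
  acc <- numeric(d_max + 1)
  for (s in seq_len(reps)) {
    aln <- simulate_coalescent_sample(200, L = 1500, theta0 = th0,
                                      theta1 = th1, tau = tau,
                                      seed = 700 + s)
    obs <- mismatch_observed(aln)
    acc[obs$differences + 1] <- acc[obs$differences + 1] +
      obs$frequency / reps
  }
  f_exp <- mismatch_expected(tau, th0, th1, d_max)
  tv <- sum(abs(acc - f_exp)) / 2 + (1 - sum(f_exp)) / 2
  expect_lt(tv, 0.05)
})
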