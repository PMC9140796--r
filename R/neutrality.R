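#' Tajima's D
#'
#' Tajima's D contrasts the mean pairwise difference estimator of theta
#' (K) with the segregating-sites estimator (S / a1): negative values
#' indicate an excess of low-frequency variants, as after a population
#' expansion or under purifying selection.
#'
#' @param n Number of sampled sequences (>= 4).
#' @param S Number of segregating sites.
#' @param K Mean pairwise nucleotide differences.
#' @return Tajima's D, or `NA` when `S = 0` (statistic undefined).
#' @export
tajima_d <- function(n, S, K) {
  if (n < 4) abort("Tajima's D requires at least 4 sequences.")
  if (S == 0) return(NA_real_)
  cst <- tajima_constants(n)
  (K - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Ewens sampling distribution of the number of alleles
#'
#' P(K = k | theta, n) = |s(n, k)| theta^k / (theta (theta+1) ...
#' (theta+n-1)) for k = 1..n, with unsigned Stirling numbers of the first
#' kind computed by a log-space recurrence (stable up to large n).
#'
#' @param n Sample size.
#' @param theta Scaled mutation rate (> 0).
#' @return Numeric vector of probabilities for k = 1..n (sums to 1).
#' @export
ewens_allele_probs <- function(n, theta) {
  if (theta <= 0) abort("theta must be positive.")
  ls <- log_stirling1_row(n)
  logp <- ls + seq_len(n) * log(theta) - sum(log(theta + 0:(n - 1)))
  exp(logp)
}

# log |s(n, k)| for k = 1..n via |s(n+1,k)| = n |s(n,k)| + |s(n,k-1)|
log_stirling1_row <- function(n) {
  row <- 0  # n = 1: |s(1,1)| = 1
  if (n == 1) return(row)
  for (m in 1:(n - 1)) {
    new <- numeric(m + 1)
    new[1] <- log(m) + row[1]
    if (m > 1) {
      for (k in 2:m) new[k] <- logsumexp(c(log(m) + row[k], row[k - 1]))
    }
    new[m + 1] <- row[m]
    row <- new
  }
  row
}

#' Fu's Fs
#'
#' Fu's Fs asks whether the observed number of distinct haplotypes is
#' larger than expected given the pairwise-difference estimate of theta:
#' with S' = P(number of alleles >= k_obs | theta = K, n) under the Ewens
#' sampling formula, Fs = ln(S' / (1 - S')). Strongly negative values
#' signal an excess of haplotypes, typical of recent expansion.
#'
#' @param n Number of sampled sequences.
#' @param K Mean pairwise differences (used as the theta estimate).
#' @param k_obs Observed number of distinct haplotypes.
#' @return Fu's Fs, or `NA` when undefined (e.g. `K = 0` with a single
#'   haplotype, where S' = 1).
#' @export
fu_fs <- function(n, K, k_obs) {
  if (n < 2) abort("Fu's Fs requires at least 2 sequences.")
  if (k_obs < 1 || k_obs > n) abort("`k_obs` must lie in 1..n.")
  if (K <= 0) return(NA_real_)
  probs <- ewens_allele_probs(n, K)
  s_prime <- sum(probs[k_obs:n])
  if (s_prime >= 1 - 1e-15 || s_prime <= 0) return(NA_real_)
  log(s_prime / (1 - s_prime))
}

# Observed S, K, singleton counts U, and haplotype count from a
# per-individual alignment (sites containing N ignored for S and U,
# pairwise-deleted for K).
alignment_sfs_stats <- function(aln) {
  aln <- as_codon_alignment(aln, expected_length = NULL)
  m <- aln_matrix(aln)
  n <- nrow(m)
  S <- 0L
  U <- integer(n)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    obs <- col != "N"
    tab <- table(col[obs])
    if (length(tab) >= 2) {
      S <- S + 1L
      singles <- names(tab)[tab == 1 & tab < max(tab)]
      for (s in singles) {
        U[which(obs & col == s)] <- U[which(obs & col == s)] + 1L
      }
    }
  }
  d <- hamming_matrix(m)
  K <- sum(d[upper.tri(d)]) / choose(n, 2)
  list(n = n, S = S, K = K, U = U, k_obs = length(unique(aln$seq)))
}

#' Ramos-Onsins and Rozas' R2
#'
#' R2 compares the number of singleton mutations carried by each sequence
#' (U_i) with the mean pairwise difference: R2 =
#' sqrt(mean((U_i - K/2)^2)) / S. Low values are expected after recent
#' population growth.
#'
#' @param aln Per-individual `codon_alignment` (duplicated haplotypes
#'   allowed; at least 4 sequences).
#' @return R2, or `NA` when there are no segregating sites.
#' @export
r2_statistic <- function(aln) {
  st <- alignment_sfs_stats(aln)
  if (st$n < 4) abort("R2 requires at least 4 sequences.")
  r2_from_components(st$U, st$S, st$K, st$n)
}

r2_from_components <- function(U, S, K, n) {
  if (S == 0) return(NA_real_)
  sqrt(mean((U - K / 2)^2)) / S
}

# Null statistics (D, Fs, R2) under the standard constant-size coalescent
# with exactly S mutations per replicate. Returns a reps x 3 matrix.
sim_null_stats <- function(n, S, reps, seed = NULL) {
  with_seed_if(seed, {
    out <- matrix(NA_real_, reps, 3,
                  dimnames = list(NULL, c("D", "Fs", "R2")))
    for (r in seq_len(reps)) {
      gen <- sim_genealogy(n)
      st <- mutation_stats(place_mutations(gen, S = S), n)
      out[r, 1] <- tajima_d(n, st$S, st$K)
      out[r, 2] <- fu_fs(n, st$K, st$k_obs)
      out[r, 3] <- r2_from_components(st$U, st$S, st$K, n)
    }
    out
  })
}

#' Coalescent null distribution p-value
#'
#' Simulates standard constant-size coalescent genealogies for `n`
#' samples, places exactly `S_obs` mutations on branches with probability
#' proportional to branch length (fixed-S conditioning, the DnaSP
#' convention), computes the chosen statistic per replicate, and returns
#' the left-tail p-value: the fraction of replicates less than or equal
#' to the observed value (small D, Fs and R2 all signal expansion).
#'
#' @param statistic `"D"`, `"Fs"` or `"R2"`.
#' @param observed Observed value of the statistic.
#' @param n Sample size (>= 4).
#' @param S_obs Observed number of segregating sites.
#' @param reps Number of simulated replicates (default 10000).
#' @param seed Optional integer seed.
#' @return A one-row tibble with columns `statistic`, `observed`,
#'   `p_value`, `reps`.
#' @export
coalescent_null <- function(statistic = c("D", "Fs", "R2"), observed, n,
                            S_obs, reps = 10000, seed = NULL) {
  statistic <- match.arg(statistic)
  if (n < 4) abort("Null simulation requires at least 4 samples.")
  null <- sim_null_stats(n, S_obs, reps, seed)[, statistic]
  tibble::tibble(
    statistic = statistic, observed = observed,
    p_value = mean(null <= observed, na.rm = TRUE),
    reps = as.integer(reps)
  )
}

#' Neutrality test summary with simulated p-values
#'
#' Computes Tajima's D, Fu's Fs and R2 for a per-individual alignment and
#' their p-values against a single shared set of fixed-S coalescent null
#' replicates.
#'
#' @inheritParams r2_statistic
#' @param reps Null-simulation replicates (default 10000).
#' @param seed Optional integer seed.
#' @return A one-row tibble with `n`, `S`, `K`, `k_obs`, `tajima_D`,
#'   `fu_Fs`, `R2`, `p_D`, `p_Fs`, `p_R2`, `reps`.
#' @export
neutrality_summary <- function(aln, reps = 10000, seed = NULL) {
  st <- alignment_sfs_stats(aln)
  if (st$n < 4) abort("Neutrality tests require at least 4 sequences.")
  D <- tajima_d(st$n, st$S, st$K)
  Fs <- fu_fs(st$n, st$K, st$k_obs)
  R2 <- r2_from_components(st$U, st$S, st$K, st$n)
  if (st$S == 0) {
    p <- c(D = NA_real_, Fs = NA_real_, R2 = NA_real_)
  } else {
    null <- sim_null_stats(st$n, st$S, reps, seed)
    p <- c(D = mean(null[, "D"] <= D, na.rm = TRUE),
           Fs = mean(null[, "Fs"] <= Fs, na.rm = TRUE),
           R2 = mean(null[, "R2"] <= R2, na.rm = TRUE))
  }
  tibble::tibble(
    n = st$n, S = st$S, K = st$K, k_obs = st$k_obs,
    tajima_D = D, fu_Fs = Fs, R2 = R2,
    p_D = unname(p["D"]), p_Fs = unname(p["Fs"]), p_R2 = unname(p["R2"]),
    reps = as.integer(reps)
  )
}
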