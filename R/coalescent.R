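# Coalescent genealogy engine shared by the null-distribution machinery,
# the mismatch parametric bootstrap, and the sequence simulator.
#
# Time is measured in mutational units (the units of tau): the pairwise
# coalescence rate is 1/theta1 for t < tau and 1/theta0 for t >= tau, and
# each lineage accumulates mutations at rate 1/2 per unit time, so a pair
# coalescing at time t carries Poisson(t) differences. The waiting-time
# draw is restarted at the rate change, which is exact by memorylessness.

# One genealogy: returns per-branch descendant leaf sets and lengths
# (2n - 2 branches; the root lineage is not a branch).
sim_genealogy <- function(n, tau = 0, theta0 = 1, theta1 = theta0) {
  if (n < 2) abort("A genealogy needs at least 2 samples.")
  if (theta0 <= 0 || theta1 <= 0) abort("theta0 and theta1 must be positive.")
  sets <- as.list(seq_len(n))
  lens <- numeric(n)
  out_sets <- vector("list", 2L * n - 2L)
  out_lens <- numeric(2L * n - 2L)
  nb <- 0L
  t <- 0
  k <- n
  while (k >= 2) {
    rate <- k * (k - 1) / 2 / (if (t < tau) theta1 else theta0)
    w <- stats::rexp(1, rate)
    if (t < tau && t + w > tau) {
      lens <- lens + (tau - t)
      t <- tau
      next
    }
    lens <- lens + w
    t <- t + w
    pick <- sort(sample.int(k, 2))
    for (p in pick) {
      nb <- nb + 1L
      out_sets[[nb]] <- sets[[p]]
      out_lens[nb] <- lens[p]
    }
    merged <- c(sets[[pick[1]]], sets[[pick[2]]])
    sets[[pick[1]]] <- merged
    lens[pick[1]] <- 0
    sets <- sets[-pick[2]]
    lens <- lens[-pick[2]]
    k <- k - 1L
  }
  list(sets = out_sets, lengths = out_lens)
}

# Place mutations on a genealogy. With `S` given, exactly S mutations are
# assigned to branches with probability proportional to branch length
# (fixed-S conditioning); otherwise each branch receives
# Poisson(length / 2) mutations. Returns the list of derived leaf sets,
# one per mutation.
place_mutations <- function(gen, S = NULL) {
  L <- gen$lengths
  if (!is.null(S)) {
    if (S == 0) return(list())
    b <- sample.int(length(L), S, replace = TRUE, prob = L)
  } else {
    counts <- stats::rpois(length(L), L / 2)
    b <- rep.int(seq_along(L), counts)
  }
  gen$sets[b]
}

# Summary statistics of a simulated sample, from the derived-state leaf
# sets (infinite-sites): S, mean pairwise differences K, per-leaf
# singleton counts U, number of distinct haplotypes k_obs.
mutation_stats <- function(mut_sets, n) {
  S <- length(mut_sets)
  if (S == 0) {
    return(list(S = 0L, K = 0, U = integer(n), k_obs = 1L))
  }
  c_m <- lengths(mut_sets)
  K <- sum(c_m * (n - c_m)) / choose(n, 2)
  U <- integer(n)
  for (m in seq_len(S)) {
    if (c_m[m] == 1L) {
      U[mut_sets[[m]]] <- U[mut_sets[[m]]] + 1L
    } else if (c_m[m] == n - 1L) {
      out <- setdiff(seq_len(n), mut_sets[[m]])
      U[out] <- U[out] + 1L
    }
  }
  M <- matrix(0L, n, S)
  for (m in seq_len(S)) M[mut_sets[[m]], m] <- 1L
  k_obs <- nrow(unique(M))
  list(S = as.integer(S), K = K, U = U, k_obs = as.integer(k_obs))
}

# Pairwise-difference counts of a simulated sample (for the mismatch
# parametric bootstrap): vector over all C(n,2) pairs.
mutation_pair_diffs <- function(mut_sets, n) {
  S <- length(mut_sets)
  d <- matrix(0L, n, n)
  for (m in seq_len(S)) {
    inset <- mut_sets[[m]]
    outset <- setdiff(seq_len(n), inset)
    d[inset, outset] <- d[inset, outset] + 1L
  }
  d[upper.tri(d)] + t(d)[upper.tri(d)]
}
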