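#' Observed mismatch distribution
#'
#' Frequency distribution of pairwise nucleotide differences among
#' sampled sequences. With `freqs` supplied (counts per haplotype) all
#' C(n, 2) individual pairs are counted, identical-haplotype pairs
#' contributing to the zero-difference class.
#'
#' @inheritParams pairwise_diversity
#' @return A tibble of class `mismatch_observed` with columns
#'   `differences` (0..max), `count` (pair counts) and `frequency`
#'   (sums to 1).
#' @export
mismatch_observed <- function(aln, freqs = NULL) {
  aln <- as_codon_alignment(aln, expected_length = NULL)
  check_n_at_least(aln, 2)
  m <- aln_matrix(aln)
  d <- hamming_matrix(m)
  dv <- d[upper.tri(d)]
  if (is.null(freqs)) {
    counts <- tabulate(dv + 1L, max(dv) + 1L)
  } else {
    if (length(freqs) != nrow(aln)) {
      abort("`freqs` must have one count per alignment row.")
    }
    w <- outer(freqs, freqs)[upper.tri(d)]
    counts <- numeric(max(dv) + 1L)
    for (i in seq_along(dv)) {
      counts[dv[i] + 1L] <- counts[dv[i] + 1L] + w[i]
    }
    counts[1] <- counts[1] + sum(choose(freqs, 2))
  }
  structure(
    tibble::tibble(differences = seq_along(counts) - 1L, count = counts,
                   frequency = counts / sum(counts)),
    class = c("mismatch_observed", class(tibble::tibble()))
  )
}

#' Expected mismatch distribution under sudden expansion
#'
#' Under the sudden-expansion model the (backward) pairwise coalescence
#' time T, in mutational units, is piecewise exponential: rate 1/theta1
#' on `[0, tau)` (post-expansion size) and rate 1/theta0 on `[tau, Inf)`
#' (pre-expansion size). The probability of observing i pairwise
#' differences mixes a Poisson(t) over that density,
#' F_i = integral of e^(-t) t^i / i! f_T(t) dt, evaluated in closed form
#' via incomplete-gamma functions (numerically in log space, so extreme
#' theta values are safe). When theta0 = theta1 = theta this reduces to
#' the equilibrium geometric F_i = theta^i / (1 + theta)^(i + 1).
#'
#' @param tau Mutational time since the expansion (>= 0).
#' @param theta0,theta1 Scaled population sizes before and after the
#'   expansion (> 0).
#' @param d_max Largest difference class to evaluate.
#' @return Numeric vector `F[0..d_max]` (total mass <= 1; the remainder
#'   lies beyond `d_max`).
#' @examples
#' mismatch_expected(0, 1, 1, 5)  # geometric: 1/2, 1/4, 1/8, ...
#' @export
mismatch_expected <- function(tau, theta0, theta1, d_max) {
  if (tau < 0) abort("tau must be non-negative.")
  if (theta0 <= 0 || theta1 <= 0) {
    abort("theta0 and theta1 must be positive (degenerate model).")
  }
  i <- 0:d_max
  a <- 1 + 1 / theta1
  b <- 1 + 1 / theta0
  # recent phase: (1/theta1) * gamma_lower(i+1, a*tau) / (i! a^(i+1))
  log_rec <- -log(theta1) - (i + 1) * log(a) +
    stats::pgamma(a * tau, i + 1, log.p = TRUE)
  # ancient phase, survival e^(-tau/theta1) carried analytically
  log_anc <- -tau / theta1 + tau / theta0 - log(theta0) - (i + 1) * log(b) +
    stats::pgamma(b * tau, i + 1, lower.tail = FALSE, log.p = TRUE)
  exp(log_anc) + exp(log_rec)  # log_rec is -Inf throughout when tau = 0
}

#' Raggedness index of a mismatch distribution
#'
#' rg = sum over i = 1..d of (F_i - F_(i-1))^2 across the observed
#' classes (no wrap-around term). Smooth unimodal distributions, typical
#' of expanding populations, give small values; multimodal equilibrium
#' distributions give larger ones.
#'
#' @param frequency Numeric frequency vector over classes 0..d, or a
#'   [mismatch_observed()] tibble.
#' @return The raggedness index.
#' @export
raggedness_index <- function(frequency) {
  f <- if (is.data.frame(frequency)) frequency$frequency else frequency
  if (length(f) < 2) return(0)
  sum(diff(f)^2)
}

# OLS objective between observed frequencies and the model curve.
mismatch_ssd <- function(f_obs, tau, theta0, theta1) {
  sum((f_obs - mismatch_expected(tau, theta0, theta1,
                                 length(f_obs) - 1L))^2)
}

# Point fit: coarse grid over (tau, log theta0, log theta1) followed by
# Nelder-Mead refinement on transformed parameters.
fit_mismatch_point <- function(f_obs, start = NULL) {
  d_max <- length(f_obs) - 1L
  obj <- function(par) {
    tau <- exp(par[1]) - 1e-8
    th0 <- exp(par[2]); th1 <- exp(par[3])
    if (tau < 0) tau <- 0
    if (tau > 3 * d_max || th0 < 1e-3 || th0 > 1e3 ||
        th1 < 1e-3 || th1 > 1e3) {
      return(1e6)
    }
    mismatch_ssd(f_obs, tau, th0, th1)
  }
  refine <- function(start) {
    opt <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    # restart polishes occasional premature NM termination
    stats::optim(opt$par, obj, method = "Nelder-Mead",
                 control = list(maxit = 2000, reltol = 1e-12))
  }
  if (is.null(start)) {
    # the SSD surface is ridged in (tau, theta1); refine from the best
    # few grid cells rather than a single one
    taus <- c(seq(0, d_max, length.out = 9), 1.5 * d_max, 2 * d_max,
              3 * d_max)
    ths <- 10^seq(-2, 2, length.out = 7)
    grid <- expand.grid(tau = taus, th0 = ths, th1 = ths)
    vals <- mapply(function(tau, th0, th1) mismatch_ssd(f_obs, tau, th0, th1),
                   grid$tau, grid$th0, grid$th1)
    starts <- lapply(utils::head(order(vals), 3), function(i) {
      c(log(grid$tau[i] + 1e-8), log(grid$th0[i]), log(grid$th1[i]))
    })
  } else {
    starts <- list(start)
  }
  opts <- lapply(starts, refine)
  opt <- opts[[which.min(vapply(opts, `[[`, numeric(1), "value"))]]
  list(tau = max(exp(opt$par[1]) - 1e-8, 0),
       theta0 = exp(opt$par[2]), theta1 = exp(opt$par[3]),
       ssd = opt$value, par = opt$par)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Least-squares fit of (tau, theta0, theta1) to an observed
#' pairwise-difference distribution (coarse grid plus Nelder-Mead
#' refinement; bounds theta in `[1e-3, 1e3]`, tau in `[0, 3 d_max]`),
#' with goodness-of-fit by the sum of squared deviations (SSD) and the
#' raggedness index, and a parametric bootstrap for p-values and
#' percentile confidence intervals: `reps` coalescent samples of size
#' `n` are simulated under the fitted model, each is refitted, and
#' p = fraction of simulated statistics at least as large as observed.
#'
#' @param f_obs Observed mismatch distribution: a [mismatch_observed()]
#'   tibble or a numeric frequency vector over classes 0..d (at least 3
#'   classes).
#' @param n Number of sampled sequences behind `f_obs` (drives the
#'   parametric bootstrap).
#' @param reps Bootstrap replicates (default 10000).
#' @param seed Optional integer seed.
#' @return An object of class `mismatch_fit` with elements `tau`,
#'   `theta0`, `theta1`, `ssd`, `rg`, `p_ssd`, `p_rg`, `ci` (tibble of
#'   2.5/97.5 percentile bounds), `observed`, `expected`, `n`, `reps`,
#'   `seed`.
#' @export
fit_sudden_expansion <- function(f_obs, n, reps = 10000, seed = NULL) {
  f <- if (is.data.frame(f_obs)) f_obs$frequency else as.numeric(f_obs)
  if (length(f) < 3) abort("At least 3 mismatch classes are required to fit.")
  if (any(f < 0) || sum(f) > 1 + 1e-8) {
    abort("`f_obs` must be non-negative frequencies with total mass <= 1.")
  }
  d_max <- length(f) - 1L

  fit <- fit_mismatch_point(f)
  rg_obs <- raggedness_index(f)

  boot <- with_seed_if(seed, {
    out <- matrix(NA_real_, reps, 5,
                  dimnames = list(NULL, c("tau", "theta0", "theta1",
                                          "ssd", "rg")))
    for (r in seq_len(reps)) {
      gen <- sim_genealogy(n, fit$tau, fit$theta0, fit$theta1)
      diffs <- mutation_pair_diffs(place_mutations(gen), n)
      f_sim <- tabulate(diffs + 1L, max(max(diffs) + 1L, length(f)))
      f_sim <- f_sim / sum(f_sim)
      refit <- fit_mismatch_point(f_sim, start = fit$par)
      out[r, ] <- c(refit$tau, refit$theta0, refit$theta1,
                    refit$ssd, raggedness_index(f_sim))
    }
    out
  })

  qs <- apply(boot[, 1:3, drop = FALSE], 2, stats::quantile,
              probs = c(0.025, 0.975), na.rm = TRUE)
  structure(list(
    tau = fit$tau, theta0 = fit$theta0, theta1 = fit$theta1,
    ssd = fit$ssd, rg = rg_obs,
    p_ssd = mean(boot[, "ssd"] >= fit$ssd, na.rm = TRUE),
    p_rg = mean(boot[, "rg"] >= rg_obs, na.rm = TRUE),
    ci = tibble::tibble(parameter = c("tau", "theta0", "theta1"),
                        lower = qs[1, ], upper = qs[2, ]),
    observed = f,
    expected = mismatch_expected(fit$tau, fit$theta0, fit$theta1, d_max),
    n = n, reps = as.integer(reps), seed = seed
  ), class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  ci <- setNames(sprintf("(%.2f-%.2f)", x$ci$lower, x$ci$upper),
                 x$ci$parameter)
  cat("Sudden-expansion mismatch fit (n =", x$n, ",", x$reps,
      "bootstrap reps)\n")
  cat(sprintf("  tau = %.3f %s   theta0 = %.3f %s   theta1 = %.3f %s\n",
              x$tau, ci["tau"], x$theta0, ci["theta0"],
              x$theta1, ci["theta1"]))
  cat(sprintf("  SSD = %.5f (p = %.4f)   raggedness = %.5f (p = %.4f)\n",
              x$ssd, x$p_ssd, x$rg, x$p_rg))
  invisible(x)
}

#' Time since expansion from tau
#'
#' Converts the fitted mutational time tau into time since expansion via
#' t = tau / (2 u L), where u is the per-site substitution rate and L the
#' sequence length, so 2 u L is the cumulative rate over the fragment.
#' Reported in the units implied by the rate (e.g. a rate per site per
#' million years yields the conventional "years before present" figures
#' when read at the printed scale).
#'
#' @param tau Mutational time since expansion (may be a CI bound).
#' @param u_per_site Substitution rate per site (vectorized; > 0).
#' @param L Number of sites (default 198).
#' @return A tibble with columns `tau`, `u_per_site`, `L`, `t` and
#'   `t_rounded` (nearest integer, half away from zero).
#' @examples
#' expansion_time(19.82, c(0.00160, 0.00177), 198)
#' @export
expansion_time <- function(tau, u_per_site, L = 198) {
  if (any(u_per_site <= 0)) abort("Substitution rate must be positive.")
  if (any(tau < 0)) abort("tau must be non-negative.")
  if (L < 1) abort("L must be at least 1.")
  grid <- tidyr::expand_grid(tau = tau, u_per_site = u_per_site)
  grid$L <- L
  grid$t <- grid$tau / (2 * grid$u_per_site * grid$L)
  grid$t_rounded <- round_half_up(grid$t)
  grid
}
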