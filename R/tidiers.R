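# broom-style tidiers for the package's fitted objects.

#' @describeIn ng_dn_ds `tidy()`: one row per quantity (dN, dS, dN-dS)
#'   with estimate and bootstrap standard error.
#' @param x An `ng_result`.
#' @param ... Unused.
#' @export
tidy.ng_result <- function(x, ...) {
  tibble::tibble(
    term = c("dN", "dS", "dN-dS"),
    estimate = c(x$dN, x$dS, x$diff),
    std.error = c(x$dN_se, x$dS_se, x$diff_se)
  )
}

#' @describeIn ng_dn_ds `glance()`: one-row summary with rates, omega,
#'   Z statistics and p-values.
#' @export
glance.ng_result <- function(x, ...) {
  tibble::tibble(
    partition_label = x$partition_label, codons_used = x$codons_used,
    n = x$n, dN = x$dN, dN_se = x$dN_se, dS = x$dS, dS_se = x$dS_se,
    diff = x$diff, diff_se = x$diff_se, omega = x$omega,
    Z = x$Z_neq, p_neq = x$p_neq, p_pos = x$p_pos, p_neg = x$p_neg,
    n_pairs = x$n_pairs, n_pairs_excluded = x$n_pairs_excluded
  )
}

#' @describeIn fit_sudden_expansion `tidy()`: observed and fitted
#'   frequency per difference class.
#' @param x A `mismatch_fit`.
#' @param ... Unused.
#' @export
tidy.mismatch_fit <- function(x, ...) {
  tibble::tibble(
    differences = seq_along(x$observed) - 1L,
    observed = x$observed,
    expected = x$expected
  )
}

#' @describeIn fit_sudden_expansion `glance()`: one-row summary of the
#'   fitted parameters, goodness of fit and confidence intervals.
#' @export
glance.mismatch_fit <- function(x, ...) {
  ci <- x$ci
  tibble::tibble(
    tau = x$tau, theta0 = x$theta0, theta1 = x$theta1,
    tau_lower = ci$lower[ci$parameter == "tau"],
    tau_upper = ci$upper[ci$parameter == "tau"],
    theta0_lower = ci$lower[ci$parameter == "theta0"],
    theta0_upper = ci$upper[ci$parameter == "theta0"],
    theta1_lower = ci$lower[ci$parameter == "theta1"],
    theta1_upper = ci$upper[ci$parameter == "theta1"],
    ssd = x$ssd, p_ssd = x$p_ssd, rg = x$rg, p_rg = x$p_rg,
    n = x$n, reps = x$reps
  )
}

#' @describeIn wu_kabat_profile `tidy()`: the per-codon profile.
#' @param x A `wu_kabat` object.
#' @param ... Unused.
#' @export
tidy.wu_kabat <- function(x, ...) x$profile

#' @describeIn wu_kabat_profile `glance()`: one-row summary.
#' @export
glance.wu_kabat <- function(x, ...) {
  tibble::tibble(
    n = x$n, codons = nrow(x$profile), mean_W = x$mean_W,
    n_polymorphic = length(x$polymorphic_sites),
    n_conserved_runs = nrow(x$conserved_runs)
  )
}

#' @describeIn locus_clusters `tidy()`: the per-haplotype assignments.
#' @param x A `locus_clusters` object.
#' @param ... Unused.
#' @export
tidy.locus_clusters <- function(x, ...) x$assignments

#' @describeIn locus_clusters `glance()`: per-cluster size and support.
#' @export
glance.locus_clusters <- function(x, ...) x$support
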