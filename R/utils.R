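#' Round half away from zero
#'
#' Rounding convention used for report tables: ties are rounded away from
#' zero (so 0.0265 at 2 decimals gives 0.03), unlike base [round()], which
#' rounds half to even. Display tables in the field's software (DnaSP,
#' MEGA, Arlequin) use this convention.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector rounded to `digits` decimals.
#' @examples
#' round_half_up(10.422 / 198, 3)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Deterministic child-seed derivation so stage re-runs match full pipeline
# runs. Kept strictly below 2^31 - 1.
derive_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) + 1009 * k) %% 2147483646L + 1)
}

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream; pass-through when seed is NULL.
with_seed_if <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# log(sum(exp(x))) without overflow
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
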