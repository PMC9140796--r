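# Nei-Gojobori codon machinery.
#
# Potential synonymous sites per codon count, for each of the nine
# possible single-base changes, the fraction that preserve the amino
# acid; changes that create a stop codon count as nonsynonymous, so
# s + n = 3 for every sense codon. Observed synonymous/nonsynonymous
# differences per codon pair are averaged with equal weight over all
# orderings of the substitutions; orderings that pass through a stop
# codon are excluded and the remaining ones reweighted (all orderings
# are used if every one is blocked).

.ng <- new.env(parent = emptyenv())

ng_tables <- function() {
  if (!is.null(.ng$Sd)) return(invisible(.ng))
  bases <- c("T", "C", "A", "G")
  g <- expand.grid(p3 = bases, p2 = bases, p1 = bases,
                   stringsAsFactors = FALSE)
  codons <- paste0(g$p1, g$p2, g$p3)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  syn <- rep(NA_real_, 64)
  for (i in seq_len(64)) {
    if (aa[i] == "*") next
    ch <- strsplit(codons[i], "")[[1]]
    nsyn <- 0L
    for (p in 1:3) {
      for (b in setdiff(bases, ch[p])) {
        mut <- ch; mut[p] <- b
        if (identical(unname(Biostrings::GENETIC_CODE[paste(mut, collapse = "")]),
                      aa[i])) {
          nsyn <- nsyn + 1L
        }
      }
    }
    syn[i] <- nsyn / 3
  }
  Sd <- Nd <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  sense <- which(aa != "*")
  for (i in sense) {
    for (j in sense) {
      if (j < i) {
        Sd[i, j] <- Sd[j, i]; Nd[i, j] <- Nd[j, i]
      } else {
        cnt <- ng_pair_counts_chr(codons[i], codons[j])
        Sd[i, j] <- cnt[1]; Nd[i, j] <- cnt[2]
      }
    }
  }
  .ng$codons <- codons; .ng$aa <- aa; .ng$syn <- syn
  .ng$Sd <- Sd; .ng$Nd <- Nd
  invisible(.ng)
}

perm_orders <- list(
  matrix(1L, 1, 1),
  rbind(c(1L, 2L), c(2L, 1L)),
  rbind(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
        c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
)

ng_pair_counts_chr <- function(codon1, codon2) {
  code <- Biostrings::GENETIC_CODE
  c1 <- strsplit(codon1, "")[[1]]
  c2 <- strsplit(codon2, "")[[1]]
  pos <- which(c1 != c2)
  d <- length(pos)
  if (d == 0) return(c(Sd = 0, Nd = 0))
  orders <- perm_orders[[d]]
  sd_p <- nd_p <- numeric(nrow(orders))
  blocked <- logical(nrow(orders))
  for (r in seq_len(nrow(orders))) {
    cur <- c1
    for (k in seq_len(d)) {
      nxt <- cur
      p <- pos[orders[r, k]]
      nxt[p] <- c2[p]
      aa_cur <- unname(code[paste(cur, collapse = "")])
      aa_nxt <- unname(code[paste(nxt, collapse = "")])
      if (aa_nxt == "*" && k < d) blocked[r] <- TRUE
      if (aa_cur == aa_nxt && aa_cur != "*") {
        sd_p[r] <- sd_p[r] + 1
      } else {
        nd_p[r] <- nd_p[r] + 1
      }
      cur <- nxt
    }
  }
  keep <- if (any(!blocked)) !blocked else rep(TRUE, nrow(orders))
  c(Sd = mean(sd_p[keep]), Nd = mean(nd_p[keep]))
}

#' Synonymous/nonsynonymous counts for one codon pair
#'
#' Pathway-averaged observed synonymous (`Sd`) and nonsynonymous (`Nd`)
#' differences between two sense codons, and the potential synonymous
#' site counts of each codon, under the Nei-Gojobori counting scheme
#' described in [ng_dn_ds()]. Exposed mainly so the counting core can be
#' checked against exhaustive enumeration.
#'
#' @param codon1,codon2 Three-letter sense codons (e.g. `"TTT"`).
#' @return A one-row tibble with columns `Sd`, `Nd`, `s1`, `s2`
#'   (potential synonymous sites of each codon; potential nonsynonymous
#'   sites are `3 - s`).
#' @examples
#' ng_codon_pair_counts("TTT", "TTC")
#' @export
ng_codon_pair_counts <- function(codon1, codon2) {
  t <- ng_tables()
  i <- match(toupper(codon1), t$codons)
  j <- match(toupper(codon2), t$codons)
  if (is.na(i) || is.na(j)) abort("Codons must be unambiguous DNA triplets.")
  if (t$aa[i] == "*" || t$aa[j] == "*") abort("Stop codons are not allowed.")
  tibble::tibble(Sd = t$Sd[i, j], Nd = t$Nd[i, j],
                 s1 = t$syn[i], s2 = t$syn[j])
}

#' Nei-Gojobori dN/dS with Jukes-Cantor correction
#'
#' Estimates average synonymous (dS) and nonsynonymous (dN) substitution
#' rates over all sequence pairs within a codon partition. For each codon
#' the potential synonymous sites are the fraction of the nine possible
#' single-base changes that preserve the amino acid (changes to stop
#' codons count as nonsynonymous, so potential sites sum to 3 per codon).
#' Observed differences in multi-hit codons are averaged with equal
#' weight over all substitution orderings, excluding orderings that pass
#' through a stop codon. Per pair, proportions pS = Sd / S-sites and
#' pN = Nd / N-sites use pair-averaged potential sites, optionally
#' corrected for multiple hits with the Jukes-Cantor transform
#' d = -(3/4) log(1 - (4/3) p); saturated pairs (p >= 3/4) are excluded
#' and counted in `n_pairs_excluded`. Standard errors and the variances
#' behind the Z-tests come from a codon-resampling bootstrap.
#'
#' The Z statistic is (dN - dS) / sqrt(Var(dN) + Var(dS)), tested
#' two-tailed against neutrality (`p_neq`) and one-tailed for positive
#' (`p_pos`: dN > dS) and purifying (`p_neg`: dN < dS) selection.
#'
#' @inheritParams segregating_sites
#' @param correction `"jukes_cantor"` (default) or `"none"` (raw
#'   proportions).
#' @param bootstrap_reps Codon-resampling bootstrap replicates (default
#'   1000).
#' @param seed Optional integer seed.
#' @return An object of class `ng_result` (see [tidy()] / [glance()]
#'   methods) with elements `dN`, `dS`, `diff`, their standard errors,
#'   `omega` (`NA` when dS = 0), `Z_neq`/`Z_pos`/`Z_neg`,
#'   `p_neq`/`p_pos`/`p_neg`, `partition_label`, `codons_used`,
#'   `n_pairs`, `n_pairs_excluded`.
#' @examples
#' aln <- as_codon_alignment(c(a = "TTTGGGAAA", b = "TTCGGGAAA"),
#'                           expected_length = 9)
#' ng_dn_ds(aln, bootstrap_reps = 100, seed = 1)
#' @export
ng_dn_ds <- function(aln, partition = NULL,
                     correction = c("jukes_cantor", "none"),
                     bootstrap_reps = 1000, seed = NULL) {
  correction <- match.arg(correction)
  aln <- as_codon_alignment(aln, expected_length = NULL)
  check_n_at_least(aln, 2)
  codons <- resolve_codons(partition, n_codons(aln))
  label <- if (inherits(partition, "site_partition")) partition$label
           else if (is.null(partition) || identical(partition, "all")) "all"
           else "custom"

  pep <- translate_codons(aln)
  if (any(pep$has_internal_stop)) {
    abort(paste0("Stop codon in `", pep$id[pep$has_internal_stop][1],
                 "`: remove pseudogenes before dN/dS estimation."))
  }
  t <- ng_tables()
  n <- nrow(aln)
  C <- length(codons)
  # n x C matrix of codon indices into the 64-codon table
  ci <- t(matrix(vapply(aln$seq, function(s) {
    cods <- substring(s, 3L * (codons - 1L) + 1L, 3L * codons)
    match(cods, t$codons)
  }, integer(C)), nrow = C))
  if (anyNA(ci)) {
    abort("Ambiguous (N-containing) codons are not supported in dN/dS.")
  }
  smat <- matrix(t$syn[ci], n, C)

  pairs <- utils::combn(n, 2)
  P <- ncol(pairs)
  SdM <- NdM <- sbarM <- matrix(0, P, C)
  for (p in seq_len(P)) {
    i <- pairs[1, p]; j <- pairs[2, p]
    idx <- cbind(ci[i, ], ci[j, ])
    SdM[p, ] <- t$Sd[idx]
    NdM[p, ] <- t$Nd[idx]
    sbarM[p, ] <- (smat[i, ] + smat[j, ]) / 2
  }

  # dN/dS means over pairs for a vector (or matrix) of codon weights
  estimate <- function(W) {
    W <- as.matrix(W)
    Sd <- SdM %*% W; Nd <- NdM %*% W
    Ss <- sbarM %*% W
    Ns <- matrix(3 * colSums(W), P, ncol(W), byrow = TRUE) - Ss
    pS <- ifelse(Ss > 0, Sd / Ss, ifelse(Sd == 0, 0, NA_real_))
    pN <- ifelse(Ns > 0, Nd / Ns, ifelse(Nd == 0, 0, NA_real_))
    if (correction == "jukes_cantor") {
      jc <- function(p) {
        out <- -0.75 * log(pmax(1 - 4 * p / 3, 1e-300))
        out[is.na(p) | p >= 0.75] <- NA_real_
        out
      }
      dS <- jc(pS); dN <- jc(pN)
    } else {
      dS <- pS; dN <- pN
    }
    keep <- !(is.na(dS) | is.na(dN))
    dN[!keep] <- 0; dS[!keep] <- 0
    list(dN = colSums(dN) / colSums(keep),
         dS = colSums(dS) / colSums(keep),
         excluded = P - colSums(keep))
  }

  point <- estimate(rep(1, C))
  boot <- with_seed_if(seed, {
    W <- matrix(vapply(seq_len(bootstrap_reps), function(r) {
      tabulate(sample.int(C, C, replace = TRUE), C)
    }, numeric(C)), nrow = C)
    estimate(W)
  })
  dN_b <- boot$dN[is.finite(boot$dN) & is.finite(boot$dS)]
  dS_b <- boot$dS[is.finite(boot$dN) & is.finite(boot$dS)]
  dN_se <- stats::sd(dN_b); dS_se <- stats::sd(dS_b)
  diff_se <- stats::sd(dN_b - dS_b)
  tot_var <- stats::var(dN_b) + stats::var(dS_b)
  Z <- if (is.finite(tot_var) && tot_var > 0) {
    (point$dN - point$dS) / sqrt(tot_var)
  } else {
    tot_var <- 0
    0
  }

  structure(list(
    dN = point$dN, dN_se = dN_se, dS = point$dS, dS_se = dS_se,
    diff = point$dN - point$dS, diff_se = diff_se,
    omega = if (point$dS > 0) point$dN / point$dS else NA_real_,
    Z_neq = Z, Z_pos = Z, Z_neg = -Z,
    p_neq = if (tot_var > 0) 2 * stats::pnorm(-abs(Z)) else 1,
    p_pos = if (tot_var > 0) stats::pnorm(-Z) else 0.5,
    p_neg = if (tot_var > 0) stats::pnorm(Z) else 0.5,
    partition_label = label, codons_used = C, n = n,
    n_pairs = P, n_pairs_excluded = unname(point$excluded),
    correction = correction, bootstrap_reps = bootstrap_reps, seed = seed
  ), class = "ng_result")
}

#' @export
print.ng_result <- function(x, ...) {
  cat("Nei-Gojobori dN/dS (", x$correction, " correction), partition `",
      x$partition_label, "` (", x$codons_used, " codons, n = ", x$n, ")\n",
      sep = "")
  cat(sprintf("  dN = %.4f +/- %.4f   dS = %.4f +/- %.4f   dN-dS = %.4f +/- %.4f\n",
              x$dN, x$dN_se, x$dS, x$dS_se, x$diff, x$diff_se))
  cat(sprintf("  omega = %s   Z = %.3f   p(dN!=dS) = %.4g   p(dN>dS) = %.4g   p(dN<dS) = %.4g\n",
              ifelse(is.na(x$omega), "-", sprintf("%.3f", x$omega)),
              x$Z_neq, x$p_neq, x$p_pos, x$p_neg))
  invisible(x)
}

#' Z-test of selection from dN/dS estimates
#'
#' Standard-normal test of dN against dS given their variances (e.g.
#' bootstrap variances): Z = (dN - dS) / sqrt(Var(dN) + Var(dS)).
#'
#' @param dN,dS Rate estimates.
#' @param var_dN,var_dS Their variances (both non-negative, not both
#'   zero).
#' @param alternative `"neq"` (two-tailed), `"pos"` (dN > dS) or
#'   `"neg"` (dN < dS).
#' @return A one-row tibble with columns `alternative`, `Z`, `p`.
#' @examples
#' z_test_selection(0.19, 0.04, 0.05^2, 0.03^2, "pos")
#' @export
z_test_selection <- function(dN, dS, var_dN, var_dS,
                             alternative = c("neq", "pos", "neg")) {
  alternative <- match.arg(alternative)
  if (var_dN < 0 || var_dS < 0) abort("Variances must be non-negative.")
  tot <- var_dN + var_dS
  if (tot == 0) abort("Total variance is zero; the Z-test is undefined.")
  Z <- (dN - dS) / sqrt(tot)
  p <- switch(alternative,
    neq = 2 * stats::pnorm(-abs(Z)),
    pos = stats::pnorm(-Z),
    neg = stats::pnorm(Z)
  )
  if (alternative == "neg") Z <- -Z
  tibble::tibble(alternative = alternative, Z = Z, p = p)
}

#' Wu-Kabat variability profile
#'
#' Per-codon amino-acid variability W = N * k / n, where N is the number
#' of sequences, k the number of distinct residues at the site and n the
#' count of the most frequent residue (`X`, i.e. untranslatable codons,
#' excluded from k and n). Invariant sites score 1. Sites scoring more
#' than twice the profile mean are flagged as highly polymorphic, and
#' maximal runs of at least `min_run` consecutive invariant residues are
#' reported as conserved fragments.
#'
#' @param peptides Output of [translate_codons()] (or a character vector
#'   of equal-length amino-acid sequences). Sequences should be
#'   stop-free; drop pseudogenes first.
#' @param min_run Minimum length of a conserved fragment (default 6
#'   residues).
#' @return An object of class `wu_kabat` with elements `profile`
#'   (tibble: codon, W, n_residues, invariant), `mean_W`,
#'   `polymorphic_sites`, `conserved_runs` (tibble: start, end, length),
#'   `n`, `min_run`.
#' @export
wu_kabat_profile <- function(peptides, min_run = 6) {
  aa <- if (is.data.frame(peptides)) peptides$aa else as.character(peptides)
  if (length(aa) < 2) abort("At least 2 sequences are required.")
  if (length(unique(nchar(aa))) > 1) {
    abort("All peptide sequences must have the same length.")
  }
  m <- do.call(rbind, strsplit(aa, ""))
  N <- nrow(m)
  W <- k <- numeric(ncol(m))
  for (i in seq_len(ncol(m))) {
    res <- m[, i]
    res <- res[res != "X"]
    if (length(res) == 0) {
      W[i] <- NA_real_; k[i] <- 0
      next
    }
    tab <- table(res)
    k[i] <- length(tab)
    W[i] <- N * k[i] / max(tab)
  }
  mean_W <- mean(W, na.rm = TRUE)
  invariant <- !is.na(W) & k == 1
  runs <- rle(invariant)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_run
  structure(list(
    profile = tibble::tibble(codon = seq_along(W), W = W,
                             n_residues = as.integer(k),
                             invariant = invariant),
    mean_W = mean_W,
    polymorphic_sites = which(!is.na(W) & W > 2 * mean_W),
    conserved_runs = tibble::tibble(start = starts[keep], end = ends[keep],
                                    length = runs$lengths[keep]),
    n = N, min_run = min_run
  ), class = "wu_kabat")
}

#' @export
print.wu_kabat <- function(x, ...) {
  cat("Wu-Kabat variability profile over", nrow(x$profile), "codons,",
      x$n, "sequences\n")
  cat(sprintf("  mean W = %.3f; %d highly polymorphic site(s): %s\n",
              x$mean_W, length(x$polymorphic_sites),
              paste(x$polymorphic_sites, collapse = ", ")))
  cat(sprintf("  %d conserved fragment(s) of >= %d residues\n",
              nrow(x$conserved_runs), x$min_run))
  invisible(x)
}
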