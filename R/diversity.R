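#' Codon-site partitions
#'
#' Statistics in this package can be restricted to the codons forming the
#' peptide-binding sites (PBS) of the class II beta-1 domain, or to their
#' complement. A partition holds 1-based codon indices within the 66-codon
#' frame (or any other codon count).
#'
#' `pbs_default()` returns the 20-codon PBS set inferred for gull exon 2
#' from site-specific selection scans (codons 8-10, 12, 16, 17, 19, 20,
#' 26, 39, 42, 43, 48, 49, 52, 53, 56, 60, 63 and 66). Alternative sets
#' (e.g. the human-derived peptide-binding region) can be supplied by the
#' caller.
#'
#' @param pbs_codons Integer vector of 1-based codon indices.
#' @param codon_count Total codons in the frame (default 66).
#' @param label Partition label used in reports.
#' @return A `site_partition` list with elements `pbs_codons`,
#'   `non_pbs_codons`, `codon_count`, `label`.
#' @examples
#' site_partition(pbs_default())
#' @export
site_partition <- function(pbs_codons, codon_count = 66, label = "PBS") {
  pbs_codons <- sort(unique(as.integer(pbs_codons)))
  if (length(pbs_codons) == 0) abort("Empty codon partition.")
  if (any(pbs_codons < 1 | pbs_codons > codon_count)) {
    abort(paste0("Partition codons must lie in 1..", codon_count, "."))
  }
  structure(
    list(pbs_codons = pbs_codons,
         non_pbs_codons = setdiff(seq_len(codon_count), pbs_codons),
         codon_count = as.integer(codon_count), label = label),
    class = "site_partition"
  )
}

#' @rdname site_partition
#' @export
pbs_default <- function() {
  c(8L, 9L, 10L, 12L, 16L, 17L, 19L, 20L, 26L, 39L,
    42L, 43L, 48L, 49L, 52L, 53L, 56L, 60L, 63L, 66L)
}

# Resolve a partition argument to a vector of codon indices.
# `partition` may be NULL/"all" (all codons), a site_partition (its PBS
# side), an integer vector of codons, or "non_pbs" relative to `part`.
resolve_codons <- function(partition, codon_count) {
  if (is.null(partition) || identical(partition, "all")) {
    return(seq_len(codon_count))
  }
  if (inherits(partition, "site_partition")) {
    if (partition$codon_count != codon_count) {
      abort("Partition codon count does not match the alignment.")
    }
    return(partition$pbs_codons)
  }
  codons <- sort(unique(as.integer(partition)))
  if (length(codons) == 0 || any(codons < 1 | codons > codon_count)) {
    abort(paste0("Partition codons must lie in 1..", codon_count, "."))
  }
  codons
}

codon_site_columns <- function(codons) {
  as.vector(vapply(codons, function(k) (3L * (k - 1L) + 1L):(3L * k),
                   integer(3)))
}

# Pairwise nucleotide difference matrix over the given site columns,
# with pairwise deletion of sites containing N.
hamming_matrix <- function(m, cols = seq_len(ncol(m)), proportion = FALSE) {
  n <- nrow(m)
  sub <- m[, cols, drop = FALSE]
  ok <- sub != "N"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      valid <- ok[i, ] & ok[j, ]
      diffs <- sum(sub[i, valid] != sub[j, valid])
      d[i, j] <- d[j, i] <- if (proportion) diffs / sum(valid) else diffs
    }
  }
  d
}

check_n_at_least <- function(aln, k) {
  if (nrow(aln) < k) {
    abort(paste0("At least ", k, " sequences are required (got ",
                 nrow(aln), ")."))
  }
}

#' Number of segregating sites
#'
#' Counts nucleotide columns (optionally restricted to a codon partition)
#' with two or more distinct non-N states.
#'
#' @param aln A `codon_alignment` (or data frame with `id`, `seq`).
#' @param partition `NULL`/"all" for all codons, a [site_partition()]
#'   (its PBS side), or an integer vector of codon indices.
#' @return Integer count of segregating sites.
#' @export
segregating_sites <- function(aln, partition = NULL) {
  aln <- as_codon_alignment(aln, expected_length = NULL)
  check_n_at_least(aln, 2)
  m <- aln_matrix(aln)
  cols <- codon_site_columns(resolve_codons(partition, n_codons(aln)))
  sum(apply(m[, cols, drop = FALSE], 2, function(col) {
    length(unique(col[col != "N"])) >= 2
  }))
}

#' Pairwise nucleotide diversity
#'
#' Computes the average number of pairwise nucleotide differences K and
#' the per-site nucleotide diversity pi = K / sites over a codon
#' partition. With `freqs` supplied (haplotype counts over individuals)
#' the estimate is frequency-weighted over all C(n, 2) individual pairs,
#' identical-haplotype pairs contributing zero; without `freqs` it is the
#' unweighted mean over distinct haplotypes.
#'
#' @inheritParams segregating_sites
#' @param freqs Optional integer vector of per-haplotype counts (one per
#'   alignment row).
#' @return A one-row tibble with columns `n`, `sites`, `K`, `pi`.
#' @examples
#' aln <- as_codon_alignment(c(a = "AAA", b = "AAT", c = "ATT"),
#'                           expected_length = 3)
#' pairwise_diversity(aln)
#' @export
pairwise_diversity <- function(aln, partition = NULL, freqs = NULL) {
  aln <- as_codon_alignment(aln, expected_length = NULL)
  check_n_at_least(aln, 2)
  m <- aln_matrix(aln)
  cols <- codon_site_columns(resolve_codons(partition, n_codons(aln)))
  d <- hamming_matrix(m, cols)
  if (is.null(freqs)) {
    n <- nrow(aln)
    K <- sum(d[upper.tri(d)]) / choose(n, 2)
  } else {
    if (length(freqs) != nrow(aln)) {
      abort("`freqs` must have one count per alignment row.")
    }
    n <- sum(freqs)
    if (n < 2) abort("Total frequency must be at least 2.")
    w <- outer(freqs, freqs)
    K <- sum(w[upper.tri(w)] * d[upper.tri(d)]) / choose(n, 2)
  }
  tibble::tibble(n = as.integer(n), sites = length(cols),
                 K = K, pi = K / length(cols))
}

#' Haplotype diversity
#'
#' Hd = n / (n - 1) * (1 - sum(p_i^2)) over haplotype frequencies p_i:
#' the probability that two individuals drawn without replacement carry
#' different haplotypes, with small-sample correction.
#'
#' @param x Either a character vector of haplotype labels (one element
#'   per sampled sequence) or a numeric vector of haplotype counts.
#' @return Haplotype diversity in `[0, 1]`.
#' @examples
#' haplotype_diversity(c(4, 4, 2))
#' @export
haplotype_diversity <- function(x) {
  counts <- if (is.character(x) || is.factor(x)) {
    as.numeric(table(x))
  } else {
    as.numeric(x)
  }
  if (any(counts < 0)) abort("Haplotype counts must be non-negative.")
  n <- sum(counts)
  if (n < 2) abort("At least 2 sampled sequences are required.")
  p <- counts / n
  n / (n - 1) * (1 - sum(p^2))
}

#' Mean p-distance with bootstrap standard error
#'
#' Mean proportion of differing positions over all sequence pairs, at the
#' nucleotide or amino-acid level, within a codon partition. The standard
#' error is the standard deviation of the mean distance across
#' codon-resampled bootstrap replicates (codon resampling preserves the
#' reading frame at both levels).
#'
#' @inheritParams segregating_sites
#' @param level `"nt"` (nucleotide) or `"aa"` (translated amino acids).
#' @param bootstrap_reps Number of bootstrap replicates (default 1000).
#' @param seed Optional integer seed for reproducible bootstrap.
#' @return A one-row tibble with columns `level`, `d`, `se`.
#' @export
mean_p_distance <- function(aln, level = c("nt", "aa"), partition = NULL,
                            bootstrap_reps = 1000, seed = NULL) {
  level <- match.arg(level)
  aln <- as_codon_alignment(aln, expected_length = NULL)
  check_n_at_least(aln, 2)
  codons <- resolve_codons(partition, n_codons(aln))

  if (level == "nt") {
    m <- aln_matrix(aln)
  } else {
    pep <- translate_codons(aln)
    m <- do.call(rbind, strsplit(pep$aa, ""))
    rownames(m) <- pep$id
  }
  # column indices per codon (3 nt columns or 1 aa column)
  codon_cols <- if (level == "nt") {
    lapply(codons, function(k) (3L * (k - 1L) + 1L):(3L * k))
  } else {
    lapply(codons, identity)
  }
  miss <- if (level == "nt") "N" else "X"

  mean_d <- function(codon_idx) {
    cols <- unlist(codon_cols[codon_idx])
    sub <- m[, cols, drop = FALSE]
    ok <- sub != miss
    n <- nrow(sub)
    tot <- 0
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        valid <- ok[i, ] & ok[j, ]
        tot <- tot + sum(sub[i, valid] != sub[j, valid]) / sum(valid)
      }
    }
    tot / choose(n, 2)
  }

  d <- mean_d(seq_along(codons))
  se <- with_seed_if(seed, {
    reps <- vapply(seq_len(bootstrap_reps), function(r) {
      mean_d(sample.int(length(codons), replace = TRUE))
    }, numeric(1))
    stats::sd(reps)
  })
  tibble::tibble(level = level, d = d, se = se)
}

#' Diversity summary for a haplotype set
#'
#' One-stop summary mirroring the diversity tables of clone-based MHC
#' studies: sample size, analyzed sites, segregating sites S, mean
#' pairwise differences K, nucleotide diversity pi, haplotype diversity
#' Hd (when frequencies are supplied or labels repeat), and mean
#' nucleotide / amino-acid p-distances with bootstrap standard errors.
#'
#' @inheritParams pairwise_diversity
#' @inheritParams mean_p_distance
#' @param label Partition label for the output row.
#' @return A one-row tibble.
#' @export
diversity_summary <- function(aln, partition = NULL, freqs = NULL,
                              bootstrap_reps = 1000, seed = NULL,
                              label = "all") {
  aln <- as_codon_alignment(aln, expected_length = NULL)
  pd <- pairwise_diversity(aln, partition, freqs)
  hd <- if (is.null(freqs)) NA_real_ else haplotype_diversity(freqs)
  dnt <- mean_p_distance(aln, "nt", partition, bootstrap_reps,
                         derive_seed(seed, 1))
  daa <- mean_p_distance(aln, "aa", partition, bootstrap_reps,
                         derive_seed(seed, 2))
  tibble::tibble(
    label = label, n = pd$n, sites = pd$sites,
    S = segregating_sites(aln, partition),
    K = pd$K, pi = pd$pi, Hd = hd,
    d_nt = dnt$d, d_nt_se = dnt$se, d_aa = daa$d, d_aa_se = daa$se
  )
}
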