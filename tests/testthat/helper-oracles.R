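# Independent oracle implementations used to cross-check the package.
# These deliberately share no code with the implementations in R/.

make_aln <- function(seqs) {
  as_codon_alignment(setNames(unname(seqs),
                              names(seqs) %||% paste0("s", seq_along(seqs))))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

random_codon_seq <- function(n_codons) {
  code <- Biostrings::GENETIC_CODE
  sense <- names(code)[code != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# Brute-force mean pairwise differences by direct double loop.
oracle_mean_pairwise <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(m)
  tot <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) tot <- tot + sum(m[i, ] != m[j, ])
  }
  tot / (n * (n - 1) / 2)
}

# Tajima's D by direct evaluation of the published constants.
oracle_tajima_d <- function(n, S, K) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (K - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# R2 from scratch: segregating sites, singletons per sequence, mean
# pairwise differences, all recomputed directly from the matrix.
oracle_r2 <- function(seqs) {
  m <- do.call(rbind, strsplit(seqs, ""))
  n <- nrow(m)
  S <- 0L
  U <- integer(n)
  for (j in seq_len(ncol(m))) {
    tab <- table(m[, j])
    if (length(tab) < 2) next
    S <- S + 1L
    mx <- max(tab)
    for (st in names(tab)[tab == 1]) {
      if (1 < mx) U[m[, j] == st] <- U[m[, j] == st] + 1L
    }
  }
  if (S == 0) return(NA_real_)
  K <- oracle_mean_pairwise(seqs)
  sqrt(sum((U - K / 2)^2) / n) / S
}

# Ewens allele-count probabilities by expanding the rising factorial
# theta^(n) = sum_k |s(n,k)| theta^k (coefficient convolution).
oracle_ewens <- function(n, theta) {
  coef <- 1  # polynomial "1", constant term for k = 0 shifts below
  for (m in 0:(n - 1)) {
    # multiply by (theta + m): coef for theta^k gets m*coef[k] + coef[k-1]
    coef <- c(coef * m, 0) + c(0, coef)
  }
  # coef[k + 1] is the coefficient of theta^k, k = 0..n; |s(n,k)| for k>=1
  probs <- coef[2:(n + 1)] * theta^(1:n) / prod(theta + 0:(n - 1))
  probs
}

# Exhaustive Nei-Gojobori pathway enumeration by depth-first recursion
# over which differing position to resolve next (independent of the
# permutation-matrix approach in the package).
oracle_ng_counts <- function(codon1, codon2) {
  code <- Biostrings::GENETIC_CODE
  c1 <- strsplit(codon1, "")[[1]]
  c2 <- strsplit(codon2, "")[[1]]
  paths <- list()
  walk <- function(cur, sd, nd, hit_stop) {
    rest <- which(cur != c2)
    if (length(rest) == 0) {
      paths[[length(paths) + 1]] <<- c(sd, nd, hit_stop)
      return(invisible())
    }
    for (p in rest) {
      nxt <- cur
      nxt[p] <- c2[p]
      aa_a <- unname(code[paste(cur, collapse = "")])
      aa_b <- unname(code[paste(nxt, collapse = "")])
      syn <- aa_a == aa_b && aa_a != "*"
      stop_here <- hit_stop || (aa_b == "*" && !all(nxt == c2))
      walk(nxt, sd + syn, nd + !syn, stop_here)
    }
  }
  walk(c1, 0, 0, FALSE)
  mat <- do.call(rbind, paths)
  keep <- if (any(mat[, 3] == 0)) mat[, 3] == 0 else rep(TRUE, nrow(mat))
  c(Sd = mean(mat[keep, 1]), Nd = mean(mat[keep, 2]))
}

# Potential synonymous sites of a codon by direct enumeration.
oracle_syn_sites <- function(codon) {
  code <- Biostrings::GENETIC_CODE
  ch <- strsplit(codon, "")[[1]]
  nsyn <- 0
  for (p in 1:3) {
    for (b in setdiff(c("A", "C", "G", "T"), ch[p])) {
      mut <- ch
      mut[p] <- b
      if (identical(unname(code[paste(mut, collapse = "")]),
                    unname(code[codon]))) {
        nsyn <- nsyn + 1
      }
    }
  }
  nsyn / 3
}

# Random small alignment with at least one segregating site: a shared
# backbone with a few mutated columns.
random_polymorphic_alignment <- function(n = 6, n_codons = 10) {
  repeat {
    base <- random_codon_seq(n_codons)
    seqs <- vapply(seq_len(n), function(i) {
      ch <- strsplit(base, "")[[1]]
      k <- sample(0:3, 1)
      if (k > 0) {
        at <- sample(seq_along(ch), k)
        ch[at] <- vapply(at, function(p) {
          sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
        }, character(1))
      }
      paste(ch, collapse = "")
    }, character(1))
    if (length(unique(seqs)) > 1) return(make_aln(seqs))
  }
}
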