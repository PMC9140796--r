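# Synthetic-data generators. These emulate the statistical structure of a
# two-locus MHC exon-2 cloning study (divergent locus pools with elevated
# nonsynonymous variation at peptide-binding codons, 1-6 haplotypes per
# individual, 8-24 clones over two PCR replicates with per-base error,
# occasional stop-codon pseudogenes) and of coalescent samples under a
# sudden-expansion demography, so every analysis stage can be tested
# closed-loop against known truth.

sense_codons <- function() {
  t <- ng_tables()
  t$codons[t$aa != "*"]
}

random_coding_seq <- function(n_codons) {
  paste(sample(sense_codons(), n_codons, replace = TRUE), collapse = "")
}

# Apply `n_mut` random substitutions to a coding sequence. Substitutions
# creating stop codons are rejected. At PBS codons, synonymous proposals
# are accepted with probability 1/multiplier (acceptance-rejection), so
# nonsynonymous change concentrates there by the given factor.
mutate_coding_seq <- function(seq, n_mut, pbs_codons = integer(),
                              pbs_nonsyn_multiplier = 1) {
  code <- Biostrings::GENETIC_CODE
  ch <- strsplit(seq, "")[[1]]
  done <- 0L
  guard <- 0L
  while (done < n_mut && guard < 1000L * max(n_mut, 1L)) {
    guard <- guard + 1L
    pos <- sample.int(length(ch), 1)
    cod_idx <- (pos - 1L) %/% 3L + 1L
    base <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1)
    new <- ch
    new[pos] <- base
    cod_range <- (3L * (cod_idx - 1L) + 1L):(3L * cod_idx)
    aa_old <- unname(code[paste(ch[cod_range], collapse = "")])
    aa_new <- unname(code[paste(new[cod_range], collapse = "")])
    if (aa_new == "*") next
    if (cod_idx %in% pbs_codons && aa_new == aa_old &&
        stats::runif(1) > 1 / pbs_nonsyn_multiplier) {
      next
    }
    ch <- new
    done <- done + 1L
  }
  paste(ch, collapse = "")
}

#' Simulate a clone library with known truth
#'
#' Generates a two-locus allele pool (two divergent ancestral sequences,
#' each mutated into a set of distinct alleles with nonsynonymous change
#' concentrated at the PBS codons), injects stop codons into a fraction
#' of pool alleles (pseudogenes), assigns 1-6 haplotypes per individual
#' with locus-skewed frequencies, and emits clone records: each assigned
#' haplotype receives at least three clones spread over the PCR
#' replicates, the remaining clones (up to the per-individual total) are
#' allocated at random, and every clone base is miscopied independently
#' with probability `pcr_error_rate`. Fully seeded and reproducible.
#'
#' @param n_individuals Number of individuals (default 68).
#' @param alleles_per_locus Alleles in each locus pool (length-2 vector
#'   or scalar; default c(12, 17)).
#' @param n_codons Codons per sequence (default 66, i.e. 198 bp).
#' @param pbs_codons PBS codon indices (default [pbs_default()]).
#' @param pbs_nonsyn_multiplier Acceptance-ratio factor concentrating
#'   nonsynonymous change at PBS codons (default 5).
#' @param inter_locus_diffs Fixed substitutions between the two locus
#'   ancestors (default 15).
#' @param haplotypes_per_individual Range of haplotypes per individual
#'   (default 1:6).
#' @param clones_per_individual Range of clones per individual (default
#'   8:24; raised when needed so each haplotype can get 3 clones).
#' @param pcr_replicates Independent PCR replicates (default 2).
#' @param pcr_error_rate Per-base miscopy probability (default 0).
#' @param pseudogene_fraction Fraction of pool alleles given an internal
#'   stop codon (default 0.03).
#' @param seed Optional integer seed.
#' @return A list with `clones` (clone table as in [read_clone_table()])
#'   and `truth`, itself a list with `allele_pool` (tibble:
#'   haplotype_id, seq, locus, class - the class [classify_haplotypes()]
#'   should recover under error-free cloning), `assignments` (tibble:
#'   individual_id, haplotype_id) and `params`.
#' @export
simulate_clone_library <- function(n_individuals = 68,
                                   alleles_per_locus = c(12, 17),
                                   n_codons = 66,
                                   pbs_codons = pbs_default(),
                                   pbs_nonsyn_multiplier = 5,
                                   inter_locus_diffs = 15,
                                   haplotypes_per_individual = 1:6,
                                   clones_per_individual = 8:24,
                                   pcr_replicates = 2,
                                   pcr_error_rate = 0,
                                   pseudogene_fraction = 0.03,
                                   seed = NULL) {
  if (pcr_error_rate < 0 || pcr_error_rate > 1 ||
      pseudogene_fraction < 0 || pseudogene_fraction > 1) {
    abort("Rates must lie in [0, 1].")
  }
  if (length(alleles_per_locus) == 1) {
    alleles_per_locus <- rep(alleles_per_locus, 2)
  }
  if (min(haplotypes_per_individual) < 1 ||
      max(haplotypes_per_individual) > sum(alleles_per_locus)) {
    abort("Impossible haplotypes-per-individual range for this pool size.")
  }
  if (pcr_replicates < 1 || min(clones_per_individual) < 1) {
    abort("Impossible clone/PCR ranges.")
  }
  with_seed_if(seed, {
    L <- 3L * n_codons
    anc1 <- random_coding_seq(n_codons)
    anc2 <- mutate_coding_seq(anc1, inter_locus_diffs, pbs_codons,
                              pbs_nonsyn_multiplier)
    pool <- character(0)
    locus <- character(0)
    for (loc in 1:2) {
      anc <- c(anc1, anc2)[loc]
      made <- character(0)
      while (length(made) < alleles_per_locus[loc]) {
        cand <- mutate_coding_seq(anc, sample(1:6, 1), pbs_codons,
                                  pbs_nonsyn_multiplier)
        if (!cand %in% c(made, pool)) made <- c(made, cand)
      }
      pool <- c(pool, made)
      locus <- c(locus, rep(paste0("L", loc), alleles_per_locus[loc]))
    }
    n_pool <- length(pool)
    # stop-codon pseudogenes
    n_pseudo <- round(pseudogene_fraction * n_pool)
    is_pseudo <- rep(FALSE, n_pool)
    if (n_pseudo > 0) {
      idx <- sample.int(n_pool, n_pseudo)
      for (i in idx) {
        cod <- sample(2:(n_codons - 1), 1)
        s <- pool[i]
        substr(s, 3 * (cod - 1) + 1, 3 * cod) <- "TAA"
        pool[i] <- s
      }
      is_pseudo[idx] <- TRUE
      if (anyDuplicated(pool)) {
        abort("Pseudogene injection produced duplicate sequences; reseed.")
      }
    }
    hap_ids <- sprintf("Sim%02d", seq_len(n_pool))

    # skewed allele frequencies within each locus (one dominant allele)
    weights <- numeric(n_pool)
    for (loc in unique(locus)) {
      ix <- which(locus == loc)
      weights[ix] <- 0.5^(seq_along(ix) - 1)
    }

    ind_ids <- sprintf("Ind%03d", seq_len(n_individuals))
    assignments <- purrr::map(ind_ids, function(ind) {
      nh <- sample(haplotypes_per_individual, 1)
      sample.int(n_pool, nh, prob = weights)
    })

    clone_rows <- purrr::imap(assignments, function(haps, i) {
      nh <- length(haps)
      n_clones <- max(sample(clones_per_individual, 1), 3L * nh)
      # base allocation: 3 clones per haplotype, alternating PCRs
      alloc_h <- rep(haps, each = 3)
      alloc_p <- rep_len(seq_len(pcr_replicates), length(alloc_h))
      extra <- n_clones - length(alloc_h)
      if (extra > 0) {
        alloc_h <- c(alloc_h, haps[sample.int(nh, extra, replace = TRUE)])
        alloc_p <- c(alloc_p, sample.int(pcr_replicates, extra,
                                         replace = TRUE))
      }
      seqs <- pool[alloc_h]
      if (pcr_error_rate > 0) {
        seqs <- vapply(seqs, function(s) {
          k <- stats::rbinom(1, L, pcr_error_rate)
          if (k == 0) return(s)
          ch <- strsplit(s, "")[[1]]
          at <- sample.int(L, k)
          ch[at] <- vapply(at, function(p) {
            sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
          }, character(1))
          paste(ch, collapse = "")
        }, character(1), USE.NAMES = FALSE)
      }
      tibble::tibble(
        individual_id = ind_ids[i],
        pcr_id = paste0("pcr", alloc_p),
        clone_id = sprintf("c%02d", seq_along(alloc_h)),
        sequence = seqs
      )
    })
    clones <- dplyr::bind_rows(clone_rows)

    carriers <- tabulate(unlist(assignments), n_pool)
    class <- ifelse(is_pseudo, "pseudogene",
                    ifelse(carriers >= 2, "putative_true", "unique"))
    class[carriers == 0] <- NA  # unsampled pool alleles
    truth <- list(
      allele_pool = tibble::tibble(haplotype_id = hap_ids, seq = pool,
                                   locus = locus, class = class),
      assignments = tibble::tibble(
        individual_id = rep(ind_ids, lengths(assignments)),
        haplotype_id = hap_ids[unlist(assignments)]
      ),
      params = list(n_individuals = n_individuals,
                    alleles_per_locus = alleles_per_locus,
                    pbs_nonsyn_multiplier = pbs_nonsyn_multiplier,
                    pcr_error_rate = pcr_error_rate,
                    pseudogene_fraction = pseudogene_fraction,
                    pcr_replicates = pcr_replicates, seed = seed)
    )
    list(clones = clones, truth = truth)
  })
}

#' Simulate a coalescent sample under sudden expansion
#'
#' Draws an n-coalescent genealogy with piecewise-constant pairwise
#' coalescence rate (1/theta1 more recently than tau, 1/theta0 beyond),
#' places Poisson mutations on branches at the rate matching the
#' tau-unit time scale, maps them to distinct positions among `L` sites
#' (infinite-sites), and returns nucleotide sequences.
#'
#' @param n Number of sampled sequences.
#' @param L Sequence length in bases (divisible by 3; default 198).
#' @param theta0,theta1 Scaled population sizes before/after expansion.
#' @param tau Mutational time since expansion (0 = constant size
#'   `theta0`).
#' @param seed Optional integer seed.
#' @return A `codon_alignment` with `n` rows.
#' @export
simulate_coalescent_sample <- function(n, L = 198, theta0 = 1,
                                       theta1 = theta0, tau = 0,
                                       seed = NULL) {
  if (n < 2) abort("At least 2 samples are required.")
  if (L < 3 || L %% 3 != 0) abort("L must be a positive multiple of 3.")
  if (tau < 0) abort("tau must be non-negative.")
  with_seed_if(seed, {
    gen <- sim_genealogy(n, tau, theta0, theta1)
    muts <- place_mutations(gen)
    S <- length(muts)
    if (S > L) {
      abort(paste0("Infinite-sites overflow: ", S, " mutations for L = ",
                   L, " sites. Increase L."))
    }
    bases <- c("A", "C", "G", "T")
    anc <- sample(bases, L, replace = TRUE)
    m <- matrix(rep(anc, each = n), n, L)
    if (S > 0) {
      pos <- sample.int(L, S)
      for (s in seq_len(S)) {
        derived <- sample(setdiff(bases, anc[pos[s]]), 1)
        m[muts[[s]], pos[s]] <- derived
      }
    }
    as_codon_alignment(tibble::tibble(
      id = sprintf("ind%03d", seq_len(n)),
      seq = apply(m, 1, paste, collapse = "")
    ), expected_length = L)
  })
}
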