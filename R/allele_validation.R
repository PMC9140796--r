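#' Classify clone-derived haplotypes
#'
#' Collapses a clone library to distinct haplotypes and classifies each one
#' with the validation rules used for clone-based MHC genotyping:
#'
#' * `pseudogene` - the translation carries an internal stop codon and the
#'   haplotype satisfies at least one of the count rules below (pseudogene
#'   status takes precedence over the count-based classes);
#' * `putative_true` - recovered from at least `min_individuals` different
#'   individuals and at least `min_pcr` independent PCR replicates;
#' * `unique` - recovered from a single individual but in at least
#'   `min_clones_unique` identical clones over at least `min_pcr` PCR
#'   replicates;
#' * `artifact` - everything else (presumed PCR/cloning error).
#'
#' Identity is exact nucleotide identity; no mismatch radius is applied.
#' Haplotype IDs are assigned deterministically: `prefix` plus a
#' zero-padded rank by descending clone count, ties broken by sequence
#' lexicographic order, so the catalog is invariant under clone row order.
#'
#' @param clones A clone table: data frame with columns `individual_id`,
#'   `pcr_id`, `clone_id`, `sequence` (see [read_clone_table()]).
#' @param min_individuals Minimum number of carrier individuals for a
#'   putative true allele (default 2).
#' @param min_clones_unique Minimum identical clones for a single-carrier
#'   unique allele (default 3).
#' @param min_pcr Minimum independent PCR replicates required for any
#'   non-artifact class (default 2).
#' @param prefix Prefix for generated haplotype IDs.
#' @return An allele catalog: tibble with columns `haplotype_id`, `seq`,
#'   `class` (factor: putative_true, unique, pseudogene, artifact),
#'   `carriers` (list column of individual IDs), `n_carriers`,
#'   `clone_count` and `pcr_replicates`.
#' @examples
#' clones <- tibble::tibble(
#'   individual_id = c("A", "A", "B"),
#'   pcr_id        = c("p1", "p2", "p1"),
#'   clone_id      = c("c1", "c2", "c1"),
#'   sequence      = rep("ATGAAATTT", 3)
#' )
#' classify_haplotypes(clones)
#' @export
classify_haplotypes <- function(clones, min_individuals = 2,
                                min_clones_unique = 3, min_pcr = 2,
                                prefix = "Hap") {
  cols <- c("individual_id", "pcr_id", "clone_id", "sequence")
  if (!all(cols %in% names(clones))) {
    abort(paste0("Clone table must have columns ",
                 paste(cols, collapse = ", ")))
  }
  if (nrow(clones) == 0) {
    return(tibble::tibble(
      haplotype_id = character(), seq = character(),
      class = factor(character(), levels = allele_classes()),
      carriers = list(), n_carriers = integer(),
      clone_count = integer(), pcr_replicates = integer()
    ))
  }
  if (length(unique(nchar(clones$sequence))) > 1) {
    abort("All clone sequences must have the same length.")
  }

  by_seq <- clones |>
    dplyr::mutate(sequence = toupper(.data$sequence)) |>
    dplyr::group_by(seq = .data$sequence) |>
    dplyr::summarise(
      carriers = list(sort(unique(.data$individual_id))),
      clone_count = dplyr::n(),
      pcr_replicates = length(unique(paste(.data$individual_id,
                                           .data$pcr_id, sep = "\r"))),
      .groups = "drop"
    ) |>
    dplyr::mutate(n_carriers = lengths(.data$carriers))

  stops <- translate_codons(
    tibble::tibble(id = as.character(seq_len(nrow(by_seq))), seq = by_seq$seq)
  )$has_internal_stop

  meets_true <- by_seq$n_carriers >= min_individuals &
    by_seq$pcr_replicates >= min_pcr
  meets_unique <- by_seq$n_carriers == 1 &
    by_seq$clone_count >= min_clones_unique &
    by_seq$pcr_replicates >= min_pcr
  klass <- dplyr::case_when(
    stops & (meets_true | meets_unique) ~ "pseudogene",
    meets_true                          ~ "putative_true",
    meets_unique                        ~ "unique",
    .default = "artifact"
  )

  ord <- order(-by_seq$clone_count, by_seq$seq)
  by_seq <- by_seq[ord, ]
  klass <- klass[ord]
  width <- max(2L, nchar(nrow(by_seq)))
  by_seq$haplotype_id <- sprintf(paste0("%s%0", width, "d"),
                                 prefix, seq_len(nrow(by_seq)))
  tibble::tibble(
    haplotype_id = by_seq$haplotype_id,
    seq = by_seq$seq,
    class = factor(klass, levels = allele_classes()),
    carriers = by_seq$carriers,
    n_carriers = by_seq$n_carriers,
    clone_count = as.integer(by_seq$clone_count),
    pcr_replicates = as.integer(by_seq$pcr_replicates)
  )
}

allele_classes <- function() c("putative_true", "unique", "pseudogene", "artifact")

#' Summarize an allele catalog
#'
#' Counts haplotypes per validation class and tabulates how many
#' non-artifact haplotypes each individual carries (the familiar
#' "haplotypes per individual" distribution, an indirect read-out of
#' locus copy number).
#'
#' @param catalog An allele catalog from [classify_haplotypes()].
#' @return A list with `class_counts` (tibble: class, n) and
#'   `per_individual` (tibble: individual_id, n_haplotypes), the latter
#'   restricted to non-artifact entries.
#' @export
summarize_catalog <- function(catalog) {
  class_counts <- tibble::tibble(class = allele_classes()) |>
    dplyr::left_join(
      dplyr::count(catalog, class = as.character(.data$class)),
      by = "class"
    ) |>
    dplyr::mutate(n = as.integer(tidyr::replace_na(.data$n, 0L)))

  kept <- catalog[catalog$class != "artifact", ]
  per_individual <- if (nrow(kept) == 0) {
    tibble::tibble(individual_id = character(), n_haplotypes = integer())
  } else {
    tibble::tibble(individual_id = unlist(kept$carriers)) |>
      dplyr::count(.data$individual_id, name = "n_haplotypes") |>
      dplyr::mutate(n_haplotypes = as.integer(.data$n_haplotypes))
  }
  list(class_counts = class_counts, per_individual = per_individual)
}

#' Expand an allele catalog to per-individual haplotype records
#'
#' One row per (individual, haplotype) pair over non-artifact entries;
#' useful for frequency-weighted diversity and mismatch analyses where
#' each individual contributes each haplotype it carries once.
#'
#' @inheritParams summarize_catalog
#' @param drop_pseudogenes Drop stop-codon haplotypes (default `TRUE`, as
#'   pseudogenes are excluded from diversity and selection statistics).
#' @return Tibble with columns `individual_id`, `haplotype_id`, `seq`.
#' @export
catalog_individual_records <- function(catalog, drop_pseudogenes = TRUE) {
  kept <- catalog[catalog$class %in%
                    c("putative_true", "unique",
                      if (!drop_pseudogenes) "pseudogene"), ]
  tidyr::unnest(
    tibble::tibble(
      haplotype_id = kept$haplotype_id, seq = kept$seq,
      individual_id = kept$carriers
    ),
    "individual_id"
  )[, c("individual_id", "haplotype_id", "seq")]
}
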