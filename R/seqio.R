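#' Codon alignments
#'
#' A codon alignment is a tibble with columns `id` and `seq` holding
#' equal-length, in-frame, gap-free nucleotide haplotypes (the unit on
#' which every statistic in this package operates). The default frame is
#' the 198-bp / 66-codon exon-2 fragment of the MHC class II beta-1
#' domain, but any length divisible by three is accepted. Sequences are
#' uppercased; the alphabet is restricted to A, C, G, T and (optionally)
#' N. Gap characters are rejected: the amplicon is length-invariant, so a
#' gapped input indicates an upstream alignment problem rather than data
#' this package should repair.
#'
#' @param x A data frame with columns `id` and `seq` (additional columns
#'   are preserved), or a named character vector of sequences.
#' @param expected_length Required sequence length in bases, or `NULL` to
#'   accept any common length divisible by 3.
#' @param allow_n Should `N` bases be accepted (translated as `X` and
#'   excluded from per-site statistics downstream)?
#' @return A tibble of class `codon_alignment` with columns `id`, `seq`
#'   and attribute `sites` (alignment length).
#' @examples
#' as_codon_alignment(c(h1 = "ATGAAATGA", h2 = "ATGAAGTGA"),
#'                    expected_length = 9)
#' @export
as_codon_alignment <- function(x, expected_length = NULL, allow_n = TRUE) {
  if (is.character(x)) {
    ids <- names(x) %||% paste0("seq", seq_along(x))
    x <- tibble::tibble(id = ids, seq = unname(x))
  }
  if (!is.data.frame(x) || !all(c("id", "seq") %in% names(x))) {
    abort("A codon alignment needs a data frame with columns `id` and `seq`.")
  }
  x <- tibble::as_tibble(x)
  x$id <- as.character(x$id)
  x$seq <- toupper(as.character(x$seq))
  if (anyDuplicated(x$id)) {
    dup <- unique(x$id[duplicated(x$id)])
    abort(paste0("Duplicate sequence IDs: ", paste(dup, collapse = ", ")))
  }
  lens <- nchar(x$seq)
  if (!is.null(expected_length)) {
    bad <- which(lens != expected_length)
    if (length(bad) > 0) {
      abort(paste0(
        "Alignment length error: expected ", expected_length, " bases but `",
        x$id[bad[1]], "` has ", lens[bad[1]], "."
      ))
    }
  } else if (length(unique(lens)) > 1) {
    abort("All sequences must have the same length.")
  }
  L <- if (nrow(x) > 0) lens[1] else (expected_length %||% 0L)
  if (nrow(x) > 0 && L %% 3 != 0) {
    abort(paste0("Alignment length ", L, " is not divisible by 3 (not in frame)."))
  }
  if (any(grepl("-", x$seq, fixed = TRUE))) {
    bad <- x$id[grepl("-", x$seq, fixed = TRUE)][1]
    abort(paste0("Gap character in `", bad,
                 "`: codon alignments must be gap-free."))
  }
  alpha <- if (allow_n) "ACGTN" else "ACGT"
  ok <- grepl(paste0("^[", alpha, "]*$"), x$seq)
  if (!all(ok)) {
    abort(paste0("Invalid characters in `", x$id[!ok][1],
                 "`: only ", paste(strsplit(alpha, "")[[1]], collapse = ", "),
                 " are allowed."))
  }
  structure(x, sites = as.integer(L),
            class = c("codon_alignment", class(x)))
}

#' @rdname as_codon_alignment
#' @param aln A `codon_alignment`.
#' @export
n_sites <- function(aln) {
  attr(aln, "sites") %||% (if (nrow(aln) > 0) nchar(aln$seq[1]) else 0L)
}

#' @rdname as_codon_alignment
#' @export
n_codons <- function(aln) as.integer(n_sites(aln) / 3)

# Character matrix of bases, rows = sequences (named by id), cols = sites.
aln_matrix <- function(aln) {
  if (nrow(aln) == 0) return(matrix(character(), 0, 0))
  m <- do.call(rbind, strsplit(aln$seq, ""))
  rownames(m) <- aln$id
  m
}

#' Read a codon alignment from FASTA
#'
#' Reads aligned nucleotide haplotypes with [Biostrings::readDNAStringSet()],
#' preserving record order and IDs verbatim and uppercasing the sequences,
#' then enforces the codon-alignment contract (equal length, in frame,
#' gap-free, restricted alphabet, unique IDs).
#'
#' @param path Path to a FASTA file.
#' @param expected_length Required sequence length (default 198 bases, the
#'   exon-2 amplicon); `NULL` to accept any in-frame length.
#' @inheritParams as_codon_alignment
#' @return A `codon_alignment` tibble.
#' @seealso [write_codon_alignment()]
#' @export
read_codon_alignment <- function(path, expected_length = 198, allow_n = TRUE) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  as_codon_alignment(
    tibble::tibble(id = ids, seq = as.character(ss)),
    expected_length = expected_length, allow_n = allow_n
  )
}

#' Write a codon alignment to FASTA
#'
#' @param aln A `codon_alignment` (or data frame with `id`, `seq`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_codon_alignment <- function(aln, path) {
  ss <- Biostrings::DNAStringSet(setNames(aln$seq, aln$id))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}

#' Read a clone table
#'
#' Reads the tab-delimited clone table that maps each Sanger-sequenced
#' clone to its individual and PCR replicate. Required columns are
#' `individual_id`, `pcr_id`, `clone_id` and `sequence`; rows are kept in
#' file order and lines starting with `#` are ignored.
#'
#' @param path Path to a TSV file.
#' @return A tibble with one row per clone.
#' @export
read_clone_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  tbl <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  needed <- c("individual_id", "pcr_id", "clone_id", "sequence")
  missing <- setdiff(needed, names(tbl))
  if (length(missing) > 0) {
    abort(paste0("Clone table schema error: missing column(s) ",
                 paste(missing, collapse = ", ")))
  }
  key <- paste(tbl$individual_id, tbl$pcr_id, tbl$clone_id, sep = "\r")
  if (anyDuplicated(key)) {
    d <- tbl[duplicated(key), ][1, ]
    abort(paste0("Duplicate clone key: (", d$individual_id, ", ", d$pcr_id,
                 ", ", d$clone_id, ")"))
  }
  tbl$sequence <- toupper(tbl$sequence)
  lens <- unique(nchar(tbl$sequence))
  if (length(lens) > 1) {
    abort("All clone sequences must have the same length.")
  }
  tbl[needed]
}

#' Translate a codon alignment
#'
#' Translates every haplotype in frame (codon 1 = bases 1-3) under the
#' standard genetic code and records internal stop codons, which mark
#' putative pseudogenes. Codons containing `N` translate to `X`.
#'
#' @param aln A `codon_alignment` (or data frame with `id`, `seq`).
#' @return A tibble with columns `id`, `aa` (peptide string, length =
#'   codon count, stops as `*`), `has_internal_stop` and `stop_positions`
#'   (list column of 1-based codon indices of stop codons).
#' @examples
#' translate_codons(as_codon_alignment(c(a = "ATGAAATAA"), expected_length = 9))
#' @export
translate_codons <- function(aln) {
  aln <- as_codon_alignment(aln, expected_length = NULL)
  code <- Biostrings::GENETIC_CODE
  out <- purrr::map(aln$seq, function(s) {
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aa <- unname(code[cods])
    aa[is.na(aa)] <- "X"  # codons containing N (or other ambiguity)
    stops <- which(aa == "*")
    list(aa = paste(aa, collapse = ""), stops = as.integer(stops))
  })
  tibble::tibble(
    id = aln$id,
    aa = purrr::map_chr(out, "aa"),
    has_internal_stop = purrr::map_int(out, ~ length(.x$stops)) > 0L,
    stop_positions = purrr::map(out, "stops")
  )
}
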