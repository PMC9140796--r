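#' Read a pipeline configuration file
#'
#' Flat key-value YAML with the fields understood by [run_pipeline()]:
#' `clones` (clone-table TSV) or `fasta` (validated haplotype FASTA, one
#' of the two required), `pbs` (PBS codon indices), `expected_length`
#' (default 198), `bootstrap_reps`, `sim_reps`, `seed`, `rates`
#' (substitution rates per site for the time conversion), `out_dir`.
#'
#' @param path Path to a YAML file.
#' @return A named list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) abort(paste0("Config file not found: ", path))
  yaml::read_yaml(path)
}

#' Run the full characterization pipeline
#'
#' Orchestrates validation, diversity, selection, Wu-Kabat, network,
#' locus partition, neutrality, mismatch and expansion-time stages over
#' a clone table or a pre-validated haplotype FASTA, writing one
#' TSV/JSON per stage plus a run log. Statistics are computed over
#' putative-true and unique alleles (pseudogenes are cataloged but
#' excluded, artifacts discarded). The global seed fans out to fixed
#' per-stage child seeds, so identical config + seed gives identical
#' outputs. Numbers are stored at full precision in JSON; display TSVs
#' are rounded half away from zero to 3 decimals.
#'
#' @param config A named list (see [read_pipeline_config()]) or a path
#'   to a YAML config.
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @return Invisibly, a list of stage results.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) config <- read_pipeline_config(config)
  out_dir <- out_dir %||% config$out_dir %||%
    abort("Config must name an `out_dir`.")
  expected_length <- config$expected_length %||% 198L
  pbs <- as.integer(config$pbs %||% pbs_default())
  if (any(pbs < 1 | pbs > expected_length / 3)) {
    abort(paste0("Config error: PBS codon indices must lie in 1..",
                 expected_length / 3, "."))
  }
  if (is.null(config$clones) && is.null(config$fasta)) {
    abort("Config must name either `clones` or `fasta`.")
  }
  for (f in c(config$clones, config$fasta)) {
    if (!file.exists(f)) abort(paste0("Config error: file not found: ", f))
  }
  reps <- as.integer(config$bootstrap_reps %||% 1000L)
  sim_reps <- as.integer(config$sim_reps %||% 10000L)
  if (reps < 1 || sim_reps < 1) abort("Config error: reps must be >= 1.")
  seed <- config$seed %||% 1L
  rates <- as.numeric(config$rates %||% c(0.00160, 0.00177))

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- character(0)
  results <- list()
  t0 <- Sys.time()

  emit <- function(name, obj) {
    path <- file.path(out_dir, name)
    if (grepl("\\.json$", name)) {
      jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, force = TRUE)
    } else {
      readr::write_tsv(obj, path)
    }
    manifest <<- c(manifest, name)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(manifest, paste0("INCOMPLETE after stage: ", name)),
                 file.path(out_dir, "MANIFEST"))
      abort(paste0("Pipeline stage `", name, "` failed: ",
                   conditionMessage(e)))
    })
  }

  # --- validate ---------------------------------------------------------
  stage("validate", {
    if (!is.null(config$clones)) {
      clones <- read_clone_table(config$clones)
      catalog <- classify_haplotypes(clones)
      emit("catalog.tsv", dplyr::mutate(
        catalog, carriers = purrr::map_chr(.data$carriers, paste,
                                           collapse = ",")
      ))
      kept <- catalog[catalog$class %in% c("putative_true", "unique"), ]
      aln <- as_codon_alignment(kept[, c("haplotype_id", "seq")] |>
                                  dplyr::rename(id = "haplotype_id"),
                                expected_length = expected_length)
      write_codon_alignment(aln, file.path(out_dir, "alleles.fasta"))
      manifest <- c(manifest, "alleles.fasta")
      records <- catalog_individual_records(catalog)
      results$catalog <- catalog
    } else {
      aln <- read_codon_alignment(config$fasta,
                                  expected_length = expected_length)
      records <- NULL
    }
    results$alignment <- aln
    results$records <- records
  })
  aln <- results$alignment
  part <- site_partition(pbs, codon_count = n_codons(aln))

  # --- diversity --------------------------------------------------------
  stage("diversity", {
    div <- dplyr::bind_rows(
      diversity_summary(aln, NULL, bootstrap_reps = reps,
                        seed = derive_seed(seed, 10), label = "all"),
      diversity_summary(aln, part, bootstrap_reps = reps,
                        seed = derive_seed(seed, 11), label = "PBS"),
      diversity_summary(aln, part$non_pbs_codons, bootstrap_reps = reps,
                        seed = derive_seed(seed, 12), label = "non-PBS")
    )
    emit("diversity.json", div)
    emit("diversity.tsv", dplyr::mutate(div, dplyr::across(
      dplyr::where(is.numeric), ~ round_half_up(.x, 3))))
    results$diversity <- div
  })

  # --- selection --------------------------------------------------------
  stage("selection", {
    sel <- dplyr::bind_rows(
      glance(ng_dn_ds(aln, NULL, bootstrap_reps = reps,
                      seed = derive_seed(seed, 20))),
      glance(ng_dn_ds(aln, part, bootstrap_reps = reps,
                      seed = derive_seed(seed, 21))),
      glance(ng_dn_ds(aln, part$non_pbs_codons, bootstrap_reps = reps,
                      seed = derive_seed(seed, 22)))
    )
    sel$partition <- c("all", "PBS", "non-PBS")
    emit("selection.json", sel)
    emit("selection.tsv", dplyr::mutate(sel, dplyr::across(
      dplyr::where(is.numeric), ~ round_half_up(.x, 3))))
    results$selection <- sel
  })

  # --- wu-kabat ---------------------------------------------------------
  stage("wu_kabat", {
    wk <- wu_kabat_profile(translate_codons(aln))
    emit("wu_kabat.tsv", wk$profile)
    emit("wu_kabat.json", list(mean_W = wk$mean_W,
                               polymorphic_sites = wk$polymorphic_sites,
                               conserved_runs = wk$conserved_runs))
    results$wu_kabat <- wk
  })

  # --- network / clusters ----------------------------------------------
  stage("network", {
    net <- minimum_spanning_network(aln)
    cl <- locus_clusters(aln, k = config$k_loci %||% 2,
                         seed = derive_seed(seed, 30))
    emit("network_edges.tsv", net$edges)
    emit("network_nodes.tsv",
         dplyr::left_join(net$nodes, cl$assignments, by = "id"))
    emit("clusters.json", list(assignments = cl$assignments,
                               support = cl$support))
    results$network <- net
    results$clusters <- cl
  })

  # --- neutrality / mismatch / expansion time --------------------------
  ind_aln <- if (!is.null(results$records)) {
    as_codon_alignment(tibble::tibble(
      id = paste(results$records$individual_id,
                 results$records$haplotype_id, sep = "."),
      seq = results$records$seq
    ))
  } else {
    aln
  }
  stage("neutrality", {
    neu <- neutrality_summary(ind_aln, reps = sim_reps,
                              seed = derive_seed(seed, 40))
    emit("neutrality.json", neu)
    results$neutrality <- neu
  })
  stage("mismatch", {
    fit <- fit_sudden_expansion(mismatch_observed(ind_aln),
                                n = nrow(ind_aln), reps = sim_reps,
                                seed = derive_seed(seed, 50))
    emit("mismatch.json", glance(fit))
    emit("mismatch_distribution.tsv", tidy(fit))
    et <- expansion_time(c(fit$tau, fit$ci$lower[1], fit$ci$upper[1]),
                         rates, L = n_sites(aln))
    emit("expansion_time.json", et)
    results$mismatch <- fit
    results$expansion_time <- et
  })

  # --- run log ----------------------------------------------------------
  emit("run_log.json", list(
    package = as.character(utils::packageVersion("mhc2popkit")),
    r_version = R.version.string,
    seed = seed, bootstrap_reps = reps, sim_reps = sim_reps,
    pbs = pbs, rates = rates,
    started = format(t0), finished = format(Sys.time())
  ))
  writeLines(c(manifest, "COMPLETE"), file.path(out_dir, "MANIFEST"))
  invisible(results)
}
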