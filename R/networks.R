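#' Minimum spanning haplotype network
#'
#' Builds an epsilon = 0 minimum spanning network over distinct
#' haplotypes: pairwise Hamming distances are processed in increasing
#' order, and at each distance level every edge joining components that
#' were distinct at the start of the level enters the network (so all
#' co-minimal alternative connections are retained). Within a level a
#' spanning subset of the admitted edges is flagged `in_mst = TRUE`
#' (n - 1 edges overall); the remaining admitted edges are equally short
#' alternatives with `in_mst = FALSE`. Node sizes carry haplotype
#' frequencies for plotting.
#'
#' @inheritParams pairwise_diversity
#' @param freqs Optional per-haplotype frequencies (defaults to 1 each).
#'   Identical sequences are collapsed, summing their frequencies.
#' @return An object of class `haplotype_network` with `nodes` (tibble:
#'   id, frequency) and `edges` (tibble: from, to, distance, in_mst).
#' @export
minimum_spanning_network <- function(aln, freqs = NULL) {
  aln <- as_codon_alignment(aln, expected_length = NULL)
  if (nrow(aln) == 0) abort("At least one haplotype is required.")
  freqs <- freqs %||% rep(1L, nrow(aln))
  if (length(freqs) != nrow(aln)) {
    abort("`freqs` must have one entry per alignment row.")
  }
  # collapse identical sequences
  grp <- match(aln$seq, unique(aln$seq))
  ids <- aln$id[!duplicated(grp)]
  fr <- as.vector(tapply(freqs, grp, sum))
  aln <- as_codon_alignment(tibble::tibble(id = ids,
                                           seq = unique(aln$seq)))
  n <- nrow(aln)
  nodes <- tibble::tibble(id = aln$id, frequency = fr)
  if (n == 1) {
    return(structure(list(
      nodes = nodes,
      edges = tibble::tibble(from = character(), to = character(),
                             distance = integer(), in_mst = logical())
    ), class = "haplotype_network"))
  }
  d <- hamming_matrix(aln_matrix(aln))
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  ed <- tibble::tibble(i = pairs[, 1], j = pairs[, 2],
                       distance = d[pairs])
  ed <- ed[order(ed$distance, ed$i, ed$j), ]

  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  keep <- logical(nrow(ed))
  in_mst <- logical(nrow(ed))
  for (lev in unique(ed$distance)) {
    at <- which(ed$distance == lev)
    # admission judged against components as of the level start
    comp0 <- vapply(seq_len(n), find, integer(1))
    admit <- at[comp0[ed$i[at]] != comp0[ed$j[at]]]
    keep[admit] <- TRUE
    for (e in admit) {
      ri <- find(ed$i[e]); rj <- find(ed$j[e])
      if (ri != rj) {
        parent[ri] <- rj
        in_mst[e] <- TRUE
      }
    }
  }
  edges <- tibble::tibble(
    from = aln$id[ed$i[keep]], to = aln$id[ed$j[keep]],
    distance = as.integer(ed$distance[keep]), in_mst = in_mst[keep]
  )
  structure(list(nodes = nodes, edges = edges),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat("Minimum spanning haplotype network:", nrow(x$nodes), "haplotypes,",
      sum(x$edges$in_mst), "spanning edges,",
      sum(!x$edges$in_mst), "co-minimal alternatives\n")
  invisible(x)
}

#' Partition haplotypes into putative loci
#'
#' Cuts an average-linkage hierarchical clustering of nucleotide
#' p-distances into `k` clusters (the cross-amplifying loci of a
#' duplicated MHC family typically surface as well-separated sequence
#' clusters). Cluster support is the fraction of site-bootstrap
#' replicates in which the cluster's exact membership reappears as a
#' cluster of the replicate partition.
#'
#' @inheritParams pairwise_diversity
#' @param k Number of clusters/loci (default 2).
#' @param bootstrap_reps Site-bootstrap replicates for support values
#'   (default 100).
#' @param seed Optional integer seed.
#' @return An object of class `locus_clusters` with `assignments`
#'   (tibble: id, cluster, labelled C1, C2, ... by decreasing size) and
#'   `support` (tibble: cluster, size, support).
#' @export
locus_clusters <- function(aln, k = 2, bootstrap_reps = 100, seed = NULL) {
  aln <- as_codon_alignment(aln, expected_length = NULL)
  check_n_at_least(aln, k)
  m <- aln_matrix(aln)
  cluster_once <- function(cols) {
    d <- stats::as.dist(hamming_matrix(m, cols, proportion = TRUE))
    stats::cutree(stats::hclust(d, method = "average"), k = k)
  }
  d_full <- hamming_matrix(m)
  if (all(d_full == 0) && k > 1) {
    abort("All sequences are identical: the partition is degenerate.")
  }
  cl <- cluster_once(seq_len(ncol(m)))
  sizes <- sort(table(cl), decreasing = TRUE)
  relabel <- setNames(paste0("C", seq_len(k)), names(sizes))
  assignments <- tibble::tibble(id = aln$id,
                                cluster = unname(relabel[as.character(cl)]))
  members <- split(aln$id, assignments$cluster)

  hits <- setNames(numeric(k), names(members))
  with_seed_if(seed, {
    for (r in seq_len(bootstrap_reps)) {
      cols <- sample.int(ncol(m), replace = TRUE)
      cl_b <- tryCatch(cluster_once(cols), error = function(e) NULL)
      if (is.null(cl_b)) next
      sets_b <- split(aln$id, cl_b)
      for (nm in names(members)) {
        if (any(vapply(sets_b, setequal, logical(1), y = members[[nm]]))) {
          hits[nm] <- hits[nm] + 1
        }
      }
    }
  })
  structure(list(
    assignments = assignments,
    support = tibble::tibble(cluster = names(members),
                             size = lengths(members),
                             support = unname(hits[names(members)]) /
                               bootstrap_reps),
    k = k, bootstrap_reps = bootstrap_reps
  ), class = "locus_clusters")
}

#' @export
print.locus_clusters <- function(x, ...) {
  cat("Locus partition into", x$k, "clusters (average linkage,",
      x$bootstrap_reps, "site bootstraps)\n")
  print(x$support)
  invisible(x)
}
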