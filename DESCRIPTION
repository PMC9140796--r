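Package: mhc2popkit
Title: MHC Class II Exon 2 Allele Validation, Selection and Demographic Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for characterizing MHC class II exon 2 (beta-1 domain)
    variation from clone-based amplicon libraries in non-model birds and
    other vertebrates. Validates putative alleles from clone tables
    (shared-carrier and replicate-clone rules, stop-codon pseudogene
    calls), partitions codons into peptide-binding and non-binding sites,
    and computes diversity (segregating sites, pairwise differences,
    nucleotide and haplotype diversity, bootstrap p-distances), selection
    statistics (Nei-Gojobori dN/dS with Jukes-Cantor correction and
    Z-tests, Wu-Kabat variability profiles), neutrality tests (Tajima's D,
    Fu's Fs via the Ewens sampling formula, Ramos-Onsins and Rozas' R2)
    with coalescent null distributions, sudden-expansion mismatch
    distribution fitting (tau, theta0, theta1, SSD, raggedness) with
    expansion-time conversion, and minimum spanning haplotype networks
    with locus partitioning. Includes a fully seeded synthetic-data module
    emulating two-locus clone libraries and coalescent samples so that
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    ape,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
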