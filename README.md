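# mhc2popkit

Population-genetic characterization of MHC class II exon 2 (the
beta-1 antigen-binding domain) from clone-based amplicon libraries, for
researchers genotyping duplicated MHC loci in non-model vertebrates —
seabirds and other wild populations in particular — by PCR, cloning and
Sanger sequencing.

The package covers the full chain from raw clone tables to demographic
inference:

* **Allele validation** — collapse clones to haplotypes and classify
  them: *putative true* (≥ 2 individuals, ≥ 2 PCR replicates), *unique*
  (1 individual, ≥ 3 identical clones, ≥ 2 PCRs), *pseudogene*
  (internal stop codon) or *artifact*.
* **Diversity** — segregating sites *S*, mean pairwise differences *K*,
  nucleotide diversity π = *K*/sites, haplotype diversity
  *Hd* = n/(n−1)(1 − Σpᵢ²), and bootstrap p-distances, over all codons
  or a peptide-binding-site (PBS) partition.
* **Selection** — Nei–Gojobori counting with equal-weight pathway
  averaging and Jukes–Cantor correction,
  d = −(3/4)·ln(1 − (4/3)p), with codon-bootstrap variances and
  Z-tests of dN vs dS (ω = dN/dS); Wu–Kabat variability
  W = N·k/n with polymorphic-site and conserved-fragment calls.
* **Neutrality** — Tajima's D, Fu's Fs via the Ewens sampling formula
  (log-space Stirling numbers), Ramos-Onsins & Rozas' R2, with
  p-values from fixed-S coalescent simulation.
* **Demography** — mismatch distributions, closed-form
  sudden-expansion expectation
  F_i = ∫ e^(−t) tⁱ/i! f_T(t) dt for a piecewise-exponential
  coalescence time (rate 1/θ₁ before τ, 1/θ₀ after), least-squares
  fitting of (τ, θ₀, θ₁) with SSD and raggedness goodness-of-fit and a
  parametric bootstrap, and time-since-expansion t = τ/(2uL).
* **Networks** — ε = 0 minimum spanning haplotype networks with
  co-minimal alternative edges, and average-linkage locus partitioning
  with site-bootstrap support.
* **Synthetic data** — seeded generators for two-locus clone libraries
  (with PCR error, pseudogenes and known truth) and coalescent samples
  under sudden expansion, so the whole pipeline is testable offline.

Functions take data frames first and return tibbles; fitted objects
have broom-style `tidy()`/`glance()` methods and ggplot2 `autoplot()`
displays.

## Worked example

```r
library(mhc2popkit)

# a synthetic clone library with known truth: 24 individuals,
# two loci, per-base PCR error 5e-4
sim     <- simulate_clone_library(n_individuals = 24,
                                  pcr_error_rate = 5e-4, seed = 7)
catalog <- classify_haplotypes(sim$clones)
summarize_catalog(catalog)$class_counts
#>   class             n
#> 1 putative_true     9
#> 2 unique            1
#> 3 pseudogene        1
#> 4 artifact         34
```

Thirty-four artifacts from a 0.05% per-base error rate is the expected
picture: most erroneous clones are one-off copies that fail both count
rules. Diversity and selection run on the validated alleles:

```r
alleles <- catalog[catalog$class %in% c("putative_true", "unique"), ]
aln <- as_codon_alignment(data.frame(id = alleles$haplotype_id,
                                     seq = alleles$seq))
diversity_summary(aln, seed = 1)[, c("n", "sites", "S", "K", "pi")]
#>       n sites     S     K     pi
#> 1    10   198    35  12.5 0.0630

ng_dn_ds(aln, site_partition(pbs_default()), seed = 1)
#> Nei-Gojobori dN/dS (jukes_cantor correction), partition `PBS` (20 codons, n = 10)
#>   dN = 0.0775 +/- 0.0340   dS = 0.0000 +/- 0.0000   dN-dS = 0.0775 +/- 0.0340
#>   omega = -   Z = 2.283   p(dN!=dS) = 0.02245   p(dN>dS) = 0.01122   p(dN<dS) = 0.9888
```

The excess of nonsynonymous change at the peptide-binding codons
(dN > dS, one-tailed p ≈ 0.011; ω undefined because dS = 0 here) is the
built-in diversifying-selection signal of the generator. Demographic
statistics use the per-individual records:

```r
recs <- catalog_individual_records(catalog)
ind  <- as_codon_alignment(data.frame(
  id  = paste(recs$individual_id, recs$haplotype_id, sep = "."),
  seq = recs$seq))

neutrality_summary(ind, reps = 2000, seed = 2)
#>      n     S     K k_obs tajima_D fu_Fs    R2   p_D  p_Fs  p_R2
#> 1   71    35  11.4    10     1.86  10.9 0.163 0.974 0.995 0.976

fit <- fit_sudden_expansion(mismatch_observed(ind), n = nrow(ind),
                            reps = 500, seed = 3)
fit
#> Sudden-expansion mismatch fit (n = 71 , 500 bootstrap reps)
#>   tau = 20.639 (14.00-76.98)   theta0 = 0.001 (0.00-4.39)   theta1 = 23.579 (12.46-88.81)
#>   SSD = 0.06371 (p = 0.0000)   raggedness = 0.10551 (p = 0.0000)

expansion_time(fit$tau, c(0.00160, 0.00177))
#>     tau u_per_site     L     t t_rounded
#> 1  20.6    0.0016    198  32.6        33
#> 2  20.6    0.00177   198  29.4        29
```

Here the positive Tajima's D and Fs (p close to 1, i.e. no
low-frequency excess) and the firmly rejected sudden-expansion fit
(SSD p = 0) are exactly right for this input: distinct alleles of two
divergent loci mimic long-term balancing selection, not a population
expansion. On real data the same calls produce the familiar
diversity/selection/neutrality/mismatch tables, and `run_pipeline()`
chains all stages from a YAML config into per-stage TSV/JSON reports
with full seed fan-out.

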