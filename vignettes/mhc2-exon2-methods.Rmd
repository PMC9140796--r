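---
title: "Characterizing MHC class II exon 2 variation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing MHC class II exon 2 variation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhc2popkit)
```

## The analysis problem

Clone-based genotyping of the MHC class II beta-1 domain (exon 2; here a
198-bp, 66-codon amplicon) produces, for each individual, a handful of
Sanger-sequenced clones drawn from several PCR replicates. Because the
primers cross-amplify duplicated loci and PCR introduces errors, the raw
clone library mixes genuine alleles of two or more loci, stop-codon
pseudogenes, and single-clone artifacts. `mhc2popkit` implements the
full downstream chain: validating alleles from the clone table,
partitioning codons into peptide-binding sites (PBS) and the remainder,
quantifying diversity and selection, testing for departures from
neutrality with simulated nulls, and fitting a sudden-expansion model to
the mismatch distribution. A synthetic-data module generates clone
libraries and coalescent samples with known truth, so every stage is
testable end to end without any external data.

## Allele validation

Distinct clone sequences are collapsed by exact nucleotide identity (no
mismatch radius: the amplicon is short, and a clustering radius would
need a calibration the clone counts cannot supply). A haplotype is

* a **putative true allele** when recovered from at least two
  individuals and two independent PCR replicates,
* a **unique allele** when recovered from a single individual but in at
  least three identical clones over at least two PCR replicates,
* a **pseudogene** when its translation contains an internal stop codon
  and it meets either of the count rules above (pseudogene status takes
  precedence: a stop-bearing sequence supported by the count rules is a
  real non-classical locus product, not an artifact),
* an **artifact** otherwise.

The two-PCR requirement is applied to all three non-artifact classes;
it is configurable because reasonable protocols differ on whether
pseudogene calls also need replicate confirmation. Haplotype IDs are
assigned by descending clone count with lexicographic tie-break, which
makes the catalog invariant under clone-table row order.

## Diversity statistics

Over any codon partition the package reports segregating sites $S$
(columns with two or more distinct non-N states), mean pairwise
differences $K$, per-site nucleotide diversity $\pi = K/\text{sites}$,
and haplotype diversity $H_d = \frac{n}{n-1}(1 - \sum_i p_i^2)$.
$K$ and $\pi$ come in two flavours, matching the two ways such tables
are usually built: unweighted over distinct haplotypes (an allele-level
description) and frequency-weighted over individuals (a
population-level one, also used by the neutrality and mismatch stages).
Mean $p$-distances at the nucleotide and amino-acid level carry
standard errors from a codon-resampling bootstrap (default 1000
replicates); codons rather than single sites are resampled so the
reading frame survives in both cases. Sites containing `N` are dropped
pairwise. Display tables round half away from zero to three decimals,
the convention of the field's reporting software.

## Selection statistics

### Nei--Gojobori dN/dS

Potential synonymous sites per codon are counted as the fraction of the
nine possible single-base changes that preserve the amino acid. Changes
that create a stop codon count as nonsynonymous, so each sense codon
contributes exactly three potential sites; this keeps the synonymous
and nonsynonymous site totals complementary and matches the
hand-checkable identity $s + n = 3$. For a codon pair differing at $d$
positions, the $d!$ substitution orderings are averaged with equal
weight; orderings passing through a stop codon are excluded and the
remainder reweighted (if every ordering is blocked, all are used).
Pairwise proportions $p_S = S_d/\bar S$ and $p_N = N_d/\bar N$ use
pair-averaged potential sites and are corrected for multiple hits with
the Jukes--Cantor transform $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$;
saturated pairs ($p \ge 3/4$) are excluded and counted. The package
implements the classic equal-weight (unweighted) counting; a
transition/transversion-weighted variant would require a weight the
downstream comparisons cannot estimate reliably from a 198-bp fragment,
so published values computed with weighted variants should be compared
with a small tolerance.

Standard errors and the variances in the $Z$-tests come from a
codon-resampling bootstrap (default 1000 replicates), matching the
common practice for this statistic; the analytic variance of the
original formulation is not used. The test statistic is
$Z = (d_N - d_S)/\sqrt{\mathrm{Var}(d_N) + \mathrm{Var}(d_S)}$, read
two-tailed against neutrality and one-tailed for diversifying
($d_N > d_S$) or purifying ($d_N < d_S$) selection.

### Wu--Kabat variability

Per codon, $W = N k / n$ with $N$ sequences, $k$ distinct residues and
$n$ copies of the modal residue (`X` from untranslatable codons is
excluded from $k$ and $n$). Sites above twice the profile mean are
flagged as highly polymorphic; maximal runs of at least six invariant
residues are reported as conserved fragments (the run length is
configurable).

### Default PBS set

`pbs_default()` returns the 20 codons (8--10, 12, 16, 17, 19, 20, 26,
39, 42, 43, 48, 49, 52, 53, 56, 60, 63, 66) identified as diversifying
in site-specific scans of gull exon 2; it is a configuration value, not
a recomputed quantity, and any alternative set (e.g. the human-derived
peptide-binding region) can be passed wherever a partition is accepted.
The human PBR positions are deliberately not hard-coded: the
literature's 17-codon set is defined on a different alignment frame and
must be supplied by the caller who knows the mapping.

## Neutrality tests and their nulls

Tajima's $D$ uses the standard constants. Fu's $F_s$ evaluates
$S' = P(K_{\text{alleles}} \ge k_{obs} \mid \hat\theta, n)$ under the
Ewens sampling formula with $\hat\theta$ equal to the mean pairwise
difference (the original estimator choice for this test), computing
unsigned Stirling numbers of the first kind with a log-space recurrence
that is stable far beyond $n = 100$. $R_2$ compares per-sequence
singleton counts with $K/2$. All three are undefined at $S = 0$ and are
reported as missing there.

P-values come from coalescent simulation with **fixed-S conditioning**:
standard constant-size genealogies receive exactly the observed number
of mutations, placed on branches proportionally to branch length. This
is the convention of the simulation engine most users of these tests
know, and it makes the null independent of any $\theta$ estimate. One
consequence worth knowing: under fixed-S the null mean of $F_s$ at
moderate sample sizes is visibly negative (about $-0.25$ at $n = 30$,
$S = 20$), more so than under fixed-$\theta$ simulation (about
$-0.14$); this is a property of the statistic, not a bias in the
simulator, which we verified against an independent
Chinese-restaurant-process simulation of the Ewens distribution.
P-values are left-tailed for all three statistics, since small values
signal expansion.

## Mismatch distribution and expansion time

Under the sudden-expansion model the pairwise coalescence time $T$ (in
mutational units) is piecewise exponential: rate $1/\theta_1$ more
recently than $\tau$, rate $1/\theta_0$ beyond. The expected share of
pairs with $i$ differences mixes a Poisson over that density,

$$F_i = \int_0^\infty e^{-t} \frac{t^i}{i!} f_T(t)\,dt,$$

evaluated in closed form through regularized incomplete-gamma
functions, with the ancient-phase term computed in log space so extreme
$\theta$ values cannot overflow. At $\theta_0 = \theta_1 = \theta$ this
collapses to the equilibrium geometric
$F_i = \theta^i/(1+\theta)^{i+1}$, which the tests check to machine
precision; off equilibrium it is checked against numerical integration
and a million-pair Monte-Carlo simulation.

The point fit minimizes the ordinary sum of squared deviations between
observed and expected frequencies. The weighting matrix of a
generalized least-squares fit is not identifiable from a single
observed distribution without further modelling assumptions, so OLS is
used for the point estimate and all uncertainty comes from the
parametric bootstrap instead. The SSD surface is ridged in
$(\tau, \theta_1)$ — an equilibrium fit with inflated $\theta$ can
shadow the true expansion basin — so the optimizer evaluates a coarse
grid ($\tau$ dense on $[0, d_{max}]$ plus sparse points to
$3 d_{max}$; $\theta$ log-spaced on $[10^{-2}, 10^{2}]$), then runs
Nelder--Mead refinements from the three best cells on
$(\log\theta_0, \log\theta_1, \log\tau)$ with box penalties at
$\theta \in [10^{-3}, 10^{3}]$, keeping the best. A self-fit of an
exact model curve recovers $\tau$ to well below 0.1.

Goodness of fit uses the SSD and the raggedness index
$rg = \sum_{i\ge 1} (F_i - F_{i-1})^2$ over observed classes (no
wrap-around term; validated behaviourally — smooth unimodal
distributions score below multimodal ones — rather than bit-for-bit
against any particular legacy implementation). P-values and percentile
confidence intervals come from a parametric bootstrap: coalescent
samples of the original size are simulated under the fitted model and
refitted, and $p$ is the fraction of simulated statistics at least as
large as observed.

`expansion_time()` converts $\tau$ to time since expansion as
$t = \tau/(2 u L)$, where $u$ is a per-site substitution rate and $L$
the fragment length, so $2uL$ is the cumulative rate over the fragment.
The function reports $t$ on the scale implied by the rate as given;
with avian calibrations quoted per site per million years the
convention in the seabird literature is to read the resulting figure
directly in years before present, and the package reproduces that
convention as printed rather than rescaling units.

## Haplotype networks and locus partitioning

The minimum spanning network uses $\varepsilon = 0$: Hamming distances
are processed level by level, every edge joining components that were
distinct at the start of its level enters the network, and a spanning
subset is flagged (`in_mst`), leaving co-minimal alternatives visible
as the parallel-edge connections familiar from haplotype-network
figures. Larger $\varepsilon$ relaxations are out of scope.

Locus partitioning cuts an average-linkage clustering of nucleotide
p-distances at $k$ clusters (default 2). Tree-based locus assignment
would need a phylogenetic reconstruction this package deliberately does
not perform; for the well-separated clusters that duplicated MHC loci
produce, average linkage recovers the same bipartition, and its
stability is quantified as the fraction of site-bootstrap replicates in
which each cluster's exact membership reappears. On simulated two-locus
pools with inter-locus divergence well above intra-locus variation,
recovery is exact with support above 0.95.

## The synthetic-data module

`simulate_clone_library()` emulates the statistical structure of a
two-locus exon-2 cloning study: two ancestral sequences separated by a
fixed number of substitutions (default 15, comfortably above the
within-locus range) are each mutated into a pool of distinct alleles
(defaults 12 and 17 per locus, echoing a two-locus catalog of a few
dozen alleles); nonsynonymous change concentrates at the PBS codons by
acceptance-rejection (synonymous proposals at PBS codons are accepted
with probability $1/\text{multiplier}$, default multiplier 5); a small
fraction of pool alleles (default 3%) receives an internal stop codon;
each of the default 68 individuals draws 1--6 haplotypes with
locus-skewed frequencies (geometric weights, one dominant allele per
locus); and 8--24 clones per individual are emitted across two PCR
replicates, every assigned haplotype receiving at least three clones
spread over both replicates, with independent per-base miscopies at the
configured error rate. The emitted truth table records each pool
allele's sequence, locus and the class an error-free classification
should assign, which is what the closed-loop tests check exactly.

`simulate_coalescent_sample()` draws an $n$-coalescent with the same
piecewise-constant rate function as the mismatch model and places
Poisson mutations on branches at the matching rate, mapping them to
distinct positions (infinite sites, positions sampled without
replacement; the generator refuses to overflow $L$ and advises a longer
sequence instead). A finite-sites mutation scheme is intentionally not
emulated: the analysis statistics assume low per-site recurrence on
this short fragment, and infinite sites keeps $S$ exactly countable,
matching the fixed-S null logic.

What the generator does **not** emulate — chimeric PCR products,
alignment errors, base-calling quality gradients, recombination and
gene conversion, selection acting within the sampled generation — marks
the boundary of what a green test suite shows: the statistics are
computed correctly on data satisfying the model assumptions, not that
real clone libraries satisfy them.

## Numerical choices and degenerate inputs

* Saturated pairs ($p \ge 3/4$) are excluded from dN/dS means and
  counted in `n_pairs_excluded`; $\omega$ is reported missing when
  $d_S = 0$.
* Zero-variance Z-tests inside `ng_dn_ds()` (identical sequences)
  report $Z = 0$, $p_{neq} = 1$; the standalone `z_test_selection()`
  treats zero total variance as an error.
* $F_s$ is reported missing when $S' \ge 1 - 10^{-15}$.
* Alignment columns containing `N` are excluded pairwise everywhere;
  N-containing codons are not accepted in dN/dS.
* Ties in haplotype-ID assignment and cluster labelling break by
  sequence lexicographic order and cluster size respectively, making
  all outputs order-invariant.
* Every stochastic routine accepts a `seed` and restores the caller's
  RNG state; the pipeline fans one global seed out to fixed per-stage
  child seeds so stage re-runs reproduce full runs.

## Problem sizes used by the test suite

The shipped tests run the null-distribution check at $n = 30$, $S =
20$ with 10,000 replicates; parameter-recovery at $n = 60$ over 50
seeded simulations with 100-replicate bootstrap intervals; the
Monte-Carlo mismatch oracle at $10^6$ pairs; convergence of simulated
mismatch distributions averaged over 40 samples of $n = 200$; and
closed-loop clone-library recovery over 20 seeds at the default 68
individuals. These sizes were chosen to keep Monte-Carlo error well
below each assertion's tolerance while remaining comfortable to run
routinely.

## Known limitations

* Exact-identity collapsing cannot rescue alleles whose every clone
  carries at least one PCR error; at realistic error rates this biases
  the unique-allele count downward and the artifact count upward.
* The two-locus partition assumes the loci are the dominant axis of
  sequence structure; recent duplicates with little divergence will not
  separate.
* The sudden-expansion model is single-pulse; multimodal mismatch
  distributions from multiple demographic events will fit poorly (by
  design, the SSD p-value should flag this).
* Cross-species alignment curation (trimming external sequences into
  this 66-codon frame) is the caller's responsibility.
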