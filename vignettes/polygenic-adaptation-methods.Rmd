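---
title: "Models and methods behind erpoly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind erpoly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpoly)
```

`erpoly` couples a forward simulator of polygenic adaptation after a shift
in trait optimum with the inference chain used to analyse
Evolve-and-Resequence (E&R) Pool-seq time series. This vignette documents
the model, the tunable parameters, the statistical machinery, and the
design choices made where the methods literature leaves the details open.

## The simulated trait and its fitness function

A quantitative trait is controlled by `n_loci` diallelic loci (default 10)
in a region of 1 Mb. Allele 1 is the allele contributing toward the new
optimum. The trait is strictly additive with a homozygous-effect
parameterization: a locus contributes `+a`, `0`, or `-a` (default
`a = 0.05` trait units) for genotypes 11, 01, 00. With all ten loci at
contributing-allele frequency 0.05 in homozygous founders, the ancestral
population mean is `10 * (0.05 a - 0.95 a) = -0.45`.

Phenotypes add Gaussian environmental noise. Heritability (default
`h² = 0.5`) is defined relative to the ancestral population: the
environmental standard deviation is computed once from the founder
genotypic variance as `sqrt(V_G (1 - h²) / h²)` and held fixed. The
alternative — recomputing `V_E` each generation — would make the effective
noise level track the sweep dynamics; a single experiment has a single
heritability, so the founder-anchored definition is used (configurable by
constructing the architecture with `heritability = 1` and adding noise
manually).

Fitness is a scaled Gaussian of the phenotype `z`,

$$ w(z) = w_{\min} + (w_{\max} - w_{\min})
          \exp\!\left(-\frac{(z - z_{opt})^2}{2\sigma_w^2}\right), $$

with defaults `z_opt = 0.5`, `σ_w = 1.2`, `w_max = 4.5`, `w_min = 0.5`.
The floor keeps every individual viable. At the ancestral mean
(−0.45, distance 0.95 from the optimum) this evaluates to ≈ 3.42, and the
population average over noisy phenotypes is ≈ 3.41 — the quantities the
acceptance script recomputes.

## Founder pools and linkage disequilibrium

Both founder constructions place 200 carrier chromosomes among 1000
haplotypes and give every locus a contributing-allele frequency of exactly
0.05 (hypergeometric, not binomial, assignment — the frequencies are exact
for every seed).

* **Strong LD** (`build_high_ld_founders()`): the loci are distributed at
  random among four sets of 50 identical haplotypes. Each locus is
  assigned to one set by an unconditioned multinomial draw, so the number
  of loci per set varies stochastically and a set can be empty. This
  stochastic packaging is the point of the design: a rare, highly skewed
  assignment (for example seven loci on one haplotype set) creates a
  haplotype with a large aggregate effect whose sweep produces a mean
  frequency change above 0.6 — the occasional near-sweep windows that
  distinguish the strong-LD scenario. `require_nonempty = TRUE` restricts
  the assignment to surjections for users who want exactly four distinct
  selected patterns.
* **Linkage equilibrium** (`build_le_founders()`): each locus's 50 copies
  are drawn uniformly without replacement from the `n_carriers = 200`
  carrier haplotypes, independently per locus. Confining the carriers to
  200 chromosomes (rather than all 1000) leaves a small residual
  association between loci — the mean pairwise r² is ≈ 0.047
  analytically — while fully unconstrained placement
  (`n_carriers = 1000`) gives r² ≈ 1/n_hap ≈ 0.001. The confined variant
  is the default because the scenario is defined by the same 200 carrier
  chromosomes as the strong-LD pool.

r² is computed from haplotype co-occurrence as `D²/(p_A q_A p_B q_B)` and
averaged over polymorphic locus pairs; a minor-allele-count filter is
available for haplotype panels.

## The Wright–Fisher simulator

Populations are diploid with constant census size (default 1000) and
non-overlapping generations; founder individual *i* carries two copies of
haplotype *i*. Each offspring draws two distinct parents with probability
proportional to fitness (fitness-proportional multinomial via inverse-CDF
sampling; no selfing, no sexes). Each parent transmits a gamete with a
Poisson number of crossovers, mean `recomb_rate × region_Mb / 100`
(0.0172 at the defaults), breakpoints uniform, no interference. Replicates
share the founders but use independent RNG streams derived from the root
seed by an integer hash, so any replicate can be reproduced in isolation.

Forcing the two parents of an offspring to be distinct removes selfing and
lowers the drift variance by roughly 2% relative to the idealized
Wright–Fisher model — visible in the neutral-drift calibration test, and
irrelevant at the scales analysed here.

## Pool-seq emulation

True allele frequencies become read counts by a single binomial draw per
site and sample at fixed depth (default 50×); an optional Poisson depth is
available. The empirical two-stage sampling of real Pool-seq (pool
construction, then sequencing) is collapsed into this one stage for
simulated data; the test-variance model retains an optional pool-size term
(`pool_size`) so that the same inference code applies to the empirical
setting. Counts are written in the popoolation2 sync dialect (A slot =
allele 0, T slot = allele 1), and `write_sync()`/`read_sync()` round-trip
byte-stably. The coverage filter removes sites at or above the
`1 - top_fraction` coverage quantile — with ties, all tied sites, so a
table with all-equal coverages and a non-zero fraction loses every site
(deterministic rule, documented in the function help).

## Drift-aware candidate tests

The per-SNP, per-replicate statistic is

$$ T = \frac{(\hat p_t - \hat p_0)^2}{ \bar p(1-\bar p)\,
       [1 - (1 - \tfrac{1}{2N_e})^t] + \tfrac{\hat p_0(1-\hat p_0)}{C_0}
       + \tfrac{\hat p_t(1-\hat p_t)}{C_t} } $$

referred to χ² with 1 df, where `p̄` is the two-time-point mean (used in
the drift term; calibration under the two-point mean was verified by
simulation) and `C` the coverages; when `pool_size` is supplied a
`2 p̄(1-p̄)/(2S)` pool-construction term is added. The CMH-type
combination sums the frequency changes and the variances over replicates
before squaring, so consistent changes accumulate and opposing changes
cancel. Monomorphic-in-both SNPs return p = 1. The exact variance
decomposition of the published drift-aware tests lives in their own
references; here the composition above is validated by its type-I error:
on neutral Wright–Fisher simulations at the true `Ne`, both tests hold
0.05 nominal within [0.03, 0.07] (the acceptance suite recomputes this on
10⁴ SNPs).

`Ne` is estimated by the plan-I temporal method in windows (default
10 kb): a ratio-of-sums `F_c = Σ(p_0-p_t)² / Σ p̄(1-p̄)`, corrected by
subtracting the read/pool sampling terms at both time points and adding
the `1/N` census covariance term, then
`Ne = -t / (2 ln(1 - F'))`, median over windows, clipped to
`[10, 10 × census]` with a warning. Intermediate generations enter by
estimating `Ne` for every adjacent pair of time points and taking the
median (`estimate_ne_series()`); the combination rule is not specified in
the methods literature, and the median is robust to a single odd interval.
Within the simulation pipeline the trait loci themselves are under
selection, so their temporal variance overstates drift and the resulting
`Ne` is conservative (smaller), which inflates the drift variance and
makes the candidate calls stricter — acceptable for a pipeline whose SNP
universe is ten selected loci, and irrelevant for genome-scale data where
neutral SNPs dominate every window.

Candidates combine the BH-adjusted CMH test (consistent response) with the
per-replicate BH-adjusted χ² tests (replicate-specific response) at
`alpha = 0.05`, recording which test fired.

## Haplotype-block reconstruction

Co-selected SNPs ride the same haplotype, so their frequency trajectories
share not only the deterministic selection response but the replicate-
specific drift of that haplotype. The deterministic response is common to
*all* selected SNPs in the genome and carries no linkage information;
`erpoly` therefore correlates **replicate-centered trajectories**: each
SNP's per-replicate frequencies minus its own cross-replicate mean at each
time point. Read noise is independent between SNPs and attenuates these
correlations, so they are **disattenuated** — the expected binomial noise
variance is subtracted from each SNP's feature variance before
standardizing (the signal variance is floored at 5% of the observed
variance to cap the correction).

Clustering proceeds in two scales:

1. a strict average-linkage cut (at correlation 0.8 or the user threshold,
   whichever is higher) yields high-purity initial clusters — premature
   merges cannot be undone later, whereas fragments can be re-joined;
2. clusters of at least five SNPs (or the largest cluster, if smaller)
   become *anchors*, claiming members greedily from the largest cluster
   down via the correlation with their member-averaged (hence
   noise-reduced) consensus trajectory;
3. anchors are merged when their consensus trajectories correlate in
   *increment* space — adjacent-time-point changes, which are independent
   across intervals and give several-fold more effective degrees of
   freedom than the cumulative deviations — above a bar halfway between
   the user threshold and 1. Fragments of one block reach ≈ 1 there while
   chance alignment of distinct blocks rarely does;
4. assignment is polished by up to three expectation-style passes
   (reassign by best consensus correlation at the user threshold,
   recompute consensus), which purifies anchors that picked up foreign
   markers.

Clusters below the minimum number of correlated SNPs
(`ceiling(mncs × n_candidates)`, floor 2; the fraction default 0.01
mirrors the usual genome-scale setting, where it corresponds to dozens of
SNPs) are discarded; no passing cluster at all returns an empty list, the
situation of a chromosome with too few outliers for reconstruction. The
default correlation threshold is 0.6. Blocks are not forced to be
contiguous; their interval is the span of member positions. The clustering
is deterministic and invariant under SNP reordering up to boundary-tie
assignments of single markers.

On planted simulations (blocks of 50 perfectly linked markers at the
experiment's own design: 5 replicates, 6 time points, coverage 100,
starting frequencies 0.06–0.40 inversely paired with s 0.11–0.04), the
count of recovered blocks equals the planted count in roughly 90–100% of
seeds for up to three blocks and ≈ 75–85% for four or five — the residual
failures are chance alignments of independent drift trajectories, which
the 30-dimensional feature space cannot always distinguish.

**Early-time-point refinement** re-runs the clustering on a strict prefix
of the generations (default up to 31): a block whose members split into
two or more early-data clusters that each pass the size rule is replaced
by those sub-blocks (labelled a, b, c), the signature of multiple targets
that recombined onto one winning haplotype. Splits are conservative:
sub-clusters below the size rule leave the parent intact.

**Selection targets** are the `ceiling(0.10 × members)` most significant
member SNPs (ties broken by position, left to right); the target's
trajectory is the per-time-point, per-replicate median over those markers,
and its starting frequency the first-generation median. The median over
marker SNPs is taken on raw observed frequencies; boundary clamping (below)
happens afterwards, inside the selection-coefficient fit.

## Selection coefficients

`s` is the OLS slope of `logit p` on generation — exact for a logistic
trajectory. Frequencies at 0 or 1 are first clamped to
`[1/(2C), 1 − 1/(2C)]`, the resolution limit of a depth-`C` read sample,
and a run of records stuck at the same boundary is reduced to its first
record (the plateau carries no slope information). Because drift makes the
regression errors non-iid, the p-value against neutrality is empirical:
`n_null` (default 1000) neutral Wright–Fisher trajectories are simulated
from the same starting frequency, `Ne`, coverage and time grid, fitted
identically, and the two-sided tail probability of `|s|` is reported with
the add-one correction. Calibration (fraction of p < 0.05 on neutral
trajectories within 0.05 ± 0.02) is enforced by test.

Per-target summaries use only replicates with `p < 0.05` and `s > 0` —
replicates in which the target did not rise significantly are excluded —
and report their median. The frequency–selection regression fits
`log10(s)` on starting frequency (optionally with a quadratic term) and
`log10(block size)`, with Shapiro–Wilk normality and a Spearman
|residual|-vs-fitted homogeneity check as diagnostics.

## Parallelism and diversity summaries

Replicate-by-target presence/absence uses either the significant-`s` rule
or a median frequency change above a cutoff (default 0.1, strict
inequality). Jaccard similarity is intersection over union; a pair with an
empty union is defined as 1 (identical emptiness) and flagged — the paper
leaves this degenerate case, which occurs only in null experiments, open.
The parallelism CV is the coefficient of variation (|sd/mean|) of the
per-replicate mean frequency change, flagged as undefined when the mean
change is below 10⁻⁶. Windowed π sums per-site heterozygosities
`2p(1−p)·C/(C−1)` over non-overlapping windows (default 10 kb) and divides
by the window length — the genome-scan convention — rather than by the
covered-site count.

`run_ld_experiment()` is the paired-scenario driver: `n_sims` independent
simulations per founder scenario with matched seeds, each summarized by
founder r², founder mean genotypic/phenotypic value and fitness, final
mean phenotype, mean frequency change, and the parallelism CV, in a tidy
one-row-per-simulation data frame (plus a long format for violin plots).

## Numerical choices and degenerate inputs

* Exact-count (hypergeometric) founder assignment; frequencies are exactly
  `p0` for every seed.
* All RNG flows through one integer-hash seed derivation
  (`derive_seed()`), keeping every derived seed below 2³¹; rerunning any
  stage with the same configuration is byte-identical.
* Monomorphic sites: p = 1 in the tests, zero contribution to π, excluded
  from r².
* `F' ≤ 0` in the temporal method (no drift signal): the window reports the
  upper clip with a warning rather than a negative `Ne`.
* The pipeline estimates `Ne` in a single window spanning the simulated
  region, because ten loci never fill genome-scan-sized windows.

## Problem sizes in the test suite

The packaged tests run the study at its native scale where that is cheap
(100 paired simulations of 5 replicates × 50 generations for the
linkage-disequilibrium experiment; 10⁴ neutral SNPs for test calibration;
100 planted targets for recovery) and at reduced scale where only the
mechanism is under test (e.g., 300-individual populations in the pipeline
round-trip test). The vignette states these as the package's own choices
of simulation size.

## Known limitations

* One chromosome, no neutral background variation inside the region, no
  mutation, no dominance or epistasis, constant optimum — by design, the
  scope of the simulation study.
* The block-reconstruction engine substitutes a transparent
  correlation-clustering algorithm for the published adaptive-threshold
  tool it emulates; equivalence is enforced at the level of recovery
  properties on planted truth, not formula identity.
* With five replicates and six time points, the feature space for block
  reconstruction has few effective degrees of freedom; chance correlation
  of independent drift trajectories occasionally merges blocks, and
  recovery of four or five simultaneous targets fails in roughly one seed
  in five.
* The residual founder LD of the linkage-equilibrium construction
  (r² ≈ 0.047) follows analytically from confining carriers to 200
  chromosomes; published descriptions of comparable constructions report
  0.03–0.04, suggesting an additional placement detail that is not
  recoverable from the text.
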