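---
title: "Dating a balanced haplotype and scanning its candidate region"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dating a balanced haplotype and scanning its candidate region}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The system and the questions

The black-bellied seedcracker (*Pyrenestes ostrinus*) segregates three
discrete bill-size morphs -- small, large and mega, with mean lower mandible
widths (LMW) around 12.8, 16.4 and 19.6 mm -- inside randomly mating
populations. Crosses behave Mendelian: a single locus with a dominant
large-bill allele separates small from large. At the molecular level the
locus is a ~300 Kb low-recombination interval containing *IGF1*, where two
deeply divergent haplogroups (an ancestral "small" and a derived "large"
haplotype) are held segregating by balancing selection.

`seedcracker` implements the quantitative analyses such a system calls for:

1. **How old is the derived haplotype?** Rejection ABC over forward
   Wright-Fisher trajectories under heterozygote advantage, coupled to a
   structured coalescent conditional on each trajectory.
2. **Where is the locus?** A delta (allele-frequency-difference) scan of
   pooled sequencing data and a gap-clustering rule that bounds the
   candidate region.
3. **Is it an inversion?** A shared-polymorphism density scan whose
   depleted intervals are breakpoint predictions.
4. **Which genes are special to the third morph?** A gene-length-weighted
   bootstrap null for private-allele counts per gene.
5. **Does the haplotype predict the phenotype?** Haplotype-dosage OLS
   association and sliding-window observed heterozygosity.

A synthetic-data generator produces truth-known cohorts, pooled frequency
tables and gene annotations with the statistical structure these analyses
assume, so the whole pipeline is testable without any sequencing archive.

## The trajectory model

A balanced polymorphism under heterozygote advantage is parameterised by
three quantities (`trajectory_params()`):

* `S` -- the *scaled heterozygote selection coefficient*. We define
  `S = 4 * Ne * s2`, where `s2` is the heterozygote's fitness advantage
  over the ancestral homozygote. This matches the 4N-scaled selection
  arguments of msms-style simulators and makes `(S, f_eq)` a complete,
  orthogonal parameterisation; which of the two homozygote contrasts a
  "scaled heterozygous selection coefficient" refers to is a genuine
  convention choice, and this one is fixed throughout the package.
* `f_eq` -- the deterministic equilibrium frequency of the derived allele.
  With fitnesses `w_het = 1`, `w_anc_hom = 1 - s2`, `w_der_hom = 1 - s1`,
  the equilibrium is `s2 / (s1 + s2)`; the generator inverts this, setting
  `s1 = s2 (1 - f_eq) / f_eq` so that any `(S, f_eq)` pair is feasible.
* `T_age` -- the allele age in *coalescent units* of `4 Ne` generations
  (the convention in which a posterior mode of 2.21 reads "2.21 x 4Ne
  generations").

`simulate_trajectory()` runs the model forward from a single copy at the
origin: each generation applies the deterministic selection update and then
binomially resamples `2 * N_sim` copies. Paths that lose or fix the allele
before the present are rejected and resimulated; the rejection count is
reported, and an informative error is raised when a parameter corner (small
`S`, long `T_age`) is loss-dominated. Trajectories are conditioned only on
segregation, not on any particular present-day frequency -- the sample
class counts are conditioned downstream, in the coalescent.

`N_sim` is a *rescaled* population size (default 5,000). Selection
(`s = S / (4 N_sim)`) and mutation (`mu = theta / (4 N_sim)`) are scaled
through it, so summary statistics are invariant to its value up to
Monte-Carlo error; the test suite checks this invariance explicitly
(`N_sim` 2,000 vs 8,000). The only cost of a small `N_sim` is
discreteness, addressed next.

## The structured coalescent

`simulate_genealogy()` walks backward on the trajectory's own generation
grid. With `k_d` derived lineages at derived frequency `x(t)`, every
derived pair coalesces with probability `1 / (2 N_sim x(t))` that
generation, and every ancestral pair with probability
`1 / (2 N_sim (1 - x(t)))`. No lineage changes class while the allele
segregates -- the model assumes no recombination between the haplogroups,
which is what the empirical low recombination rate and the 300 Kb of high
LD justify. At the origin generation every remaining derived lineage is
merged (the allele was then a single copy) and the merged lineage joins
the ancestral class; older than the origin a standard single-class
coalescent runs to the root, with geometric waiting times.

Numerical choices worth knowing:

* Events are sampled by accumulating the per-generation hazard
  `-C(k,2) * log(1 - p)` per class against a unit-exponential threshold;
  at an event one uniformly chosen pair merges. This is equivalent in rate
  to per-pair Bernoulli sampling but costs O(1) per generation instead of
  O(k^2). If the trajectory dips back to a single copy mid-path, all
  derived lineages merge at once -- a documented small-`N_sim` artifact
  (a multifurcation) that vanishes under rescaling.
* With `n_der = 0` the trajectory is ignored entirely and a plain Kingman
  coalescent of size `N_sim` is simulated. Conditioning the ancestral
  class on `1 - x(t)` would make an all-ancestral sample coalesce faster
  than neutral, and the neutral limit is precisely the configuration used
  as an oracle (E[T2] = 2N generations, E[pi] = theta per locus,
  E[S] = a_n * theta); the package therefore treats "no derived lineages
  sampled" as "no conditioning requested".
* Mutations (`drop_mutations()`) are Poisson per branch at
  `theta / (4 N_sim)` per bp per generation under infinite sites; each
  mutation takes a fresh continuous uniform position in `(0, L]`, so
  positions are unique almost surely and every emitted site is
  polymorphic. Branch segments older than the root carry no mutations.

The batch path used by the ABC (`run_reference_table()`) performs the same
simulation in compiled code but reduces each genealogy directly to the
three summary statistics from per-branch leaf counts, without
materialising a haplotype matrix; the test suite verifies the R-level
matrix path and the batch path against the same neutral expectations.

## Summary statistics

The three ABC statistics are per-bp nucleotide diversity within the
ancestral class, within the derived class, and the average between-class
divergence (`nucleotide_diversity()`, `dxy()`, `summary_stats()`). Two
denominator conventions coexist deliberately: per-bp statistics divide by
the locus length `L`, while `mismatch_matrix()` divides by the number of
assayed sites, matching "percent mismatches" usage on SNP panels. Missing
genotypes are handled pairwise-complete, which changes denominators and is
therefore stated here rather than hidden.

`watterson_theta()` supplies the plug-in scaled mutation rate; the
pipeline's default is to estimate it on the observed *ancestral* class
(the larger, older sample) -- how the published 0.001/bp was obtained is
not stated in the source material, so the choice is exposed rather than
buried.

## Rejection ABC

`abc_estimate_age()` draws `(S, f_eq, T_age)` from independent uniform
priors (defaults 50-1000, 0.2-0.8, 0-5 coalescent units), simulates one
coalescent sample per draw, and keeps the `n_accept = 200` draws whose
statistics are closest to the observed triple.

* **Distance.** The default is the raw Euclidean distance on
  `(pi_anc, pi_der, d_xy)`, mirroring the method being reimplemented; the
  three statistics share units and comparable scale here, so the raw
  distance is defensible. Standardising each statistic by its
  reference-table standard deviation is nevertheless standard ABC practice
  and is available via `abc_config(distance = "normalized_euclidean")`.
* **Posterior mode.** Gaussian KDE with Silverman's bandwidth on a
  512-point grid over the prior support, argmax returned. A histogram peak
  depends on binning; the KDE rule is fixed for reproducibility.
* **Failed draws.** Parameter corners whose trajectories exceed the
  rejection limit are excluded (not resampled) with the acceptance count
  unchanged, keeping the reference table i.i.d. from the prior restricted
  to feasible parameters; more than 10% failures aborts loudly.
* **Scaling out.** `theta_hat` is a plug-in, not co-estimated:
  `Ne = theta_hat / (4 mu)` with `mu = 2.2e-9` per bp per generation, ages
  convert as `generations = T_age * 4 * Ne` and `years = generations * g`
  with `g = 5` years. With `theta_hat = 0.001` this yields Ne ~ 114,000
  (nearest thousand) and turns a mode of 2.21 coalescent units into
  roughly a million generations, i.e. five million years.

Desk-scale problem sizes are the package defaults: 20,000 simulations with
200 accepted, a 30 kb locus with `theta` rescaled to preserve the
per-locus mutation supply of the 285,969-bp analysis interval, and
`N_sim = 5000`. The acceptance tests run ten seeded replicates of the full
estimator against pseudo-observed statistics at known parameters and
require the `f_eq` and `T_age` modes to land within +/-0.10 and +/-0.75 in
at least eight, with posterior variance below prior variance in all -- a
direct check that the three statistics are informative about exactly the
two parameters the method claims to recover. The pseudo-observation is the
*expected* statistic vector at truth (the mean of 100 replicate
simulations): a single no-recombination locus is a single genealogy, and
its realised within-class diversities scatter several-fold around their
expectations, an observation noise that no estimator can remove and that
would otherwise dominate the recovery error for `f_eq`. `S` is only weakly
identified, as expected: very different selection strengths produce
near-identical statistics once the allele is near equilibrium.

## The synthetic-data generator

`generate_haplotype_panel()` builds two founder haplotypes differing at
`ceiling(divergence * L)` sites (at `divergence = 1` they are 100%
divergent, the observed configuration for the two focal haplotypes),
copies them with independent per-site mutations at rate `intra_diversity`
(~0.09 reproduces the observed 9% intra-haplogroup mismatches), and adds
single-breakpoint recombinant mosaics with the breakpoints recorded as
truth. Real recombinant haplotypes at the locus are few, so a single
breakpoint per recombinant is the default; multi-breakpoint mosaics are
out of scope.

`generate_cohort()` enforces the dominance rule by construction (small
individuals carry two ancestral haplotypes; any derived haplotype makes a
non-small morph) and draws LMW from equal-variance Gaussians per morph.
The within-morph standard deviation is not stated in the source material
and is exposed as `morph_sd` (default 0.3 mm, a realistic measurement
spread for a ~13-20 mm trait) rather than asserted. Heterozygous large
individuals get a small negative offset (default 0.5 mm), emulating the
observed incomplete dominance where heterozygotes are marginally smaller.

`generate_pool_af()` separates signal from noise explicitly: background
sites get binomial read-sampling noise around a shared frequency, while
the implanted candidate-region sites are emitted with *exact* frequencies
satisfying `|freq_small - freq_large| >= delta_in_region`, with the two
boundary SNPs placed exactly at the interval ends. That exactness is what
lets scan-recovery tests assert *equality* with the implanted truth rather
than a tolerance. What the generator does **not** emulate is equally
important for interpreting green tests: no linkage disequilibrium between
sites, no mapping or reference bias, no depth-dependent allele-frequency
error beyond binomial sampling, and a single panmictic population. Passing
tests demonstrate the algorithms are correct on data with the assumed
structure, not that the assumptions hold for any particular dataset.

## Region scans

* **Span convention.** `region_span()` is `end - start`, not
  `end - start + 1`; the published spans (301,630; 499,630; 319.3 Kb) are
  differences of boundary-SNP coordinates, and the package matches that
  arithmetic exactly.
* **Delta scan.** Delta is the absolute reference-allele frequency
  difference between two pools; sites must pass the Pool-seq depth filters
  first (per-pool depth in [10, 40]; the site's minor allele covered by at
  least 2 reads across the two pools, so fixed differences pass but
  monomorphic noise does not). The retention threshold is 0.9.
* **Region bounding.** No clustering rule was published, only the outcome,
  so the rule here is explicit and configurable: sites split into clusters
  at gaps > 100 kb, the cluster with most sites wins, ties prefer the
  smaller span, and the region runs SNP-to-SNP.
* **Inversion scan.** Shared polymorphisms (sites segregating within both
  haplogroups) are densely present wherever recombination moves variation
  between backgrounds and absent where it cannot; `density_track()` uses a
  rectangular kernel with a 1.5 kb bandwidth interpreted as the
  *half*-width (the full-width convention is available, since kernel
  conventions differ across tools). `predict_breakpoints()` normalises by
  the median density of the outer 15% of grid points at each end (the
  flanks) and reports runs below a fraction of that median -- the run
  edges are the breakpoint estimates, accurate to about the kernel width.

## Enrichment test

The null model redistributes the `M` in-gene private alleles across genes
with probabilities proportional to gene length (a multinomial), so each
gene's null count is marginally `Binomial(M, len_g / sum(len))` -- the
property the tests verify against exact binomial tails. Per gene,
`p = #{null > observed} / B` with *strict* inequality, as the p-value is
defined in the method being reimplemented; a conservative
`(1 + #{null >= observed}) / (1 + B)` variant is available because the
strict version can return exactly zero. Only in-gene alleles are
redistributed: redistributing all private alleles (including intergenic
ones) or resampling genes rather than alleles are alternative readings of
a terse published description, and only the interpretation that actually
yields a per-gene null count distribution is implemented. P-values are
reported raw, without multiple-testing correction, matching the original
usage.

## Known limitations

* The coalescent is discrete-generation; per-generation pair-coalescence
  probabilities must stay below 1, which the fitness feasibility check
  guarantees for sensible `N_sim`. Simultaneous multi-mergers can occur at
  small `N_sim` and vanish under rescaling.
* `S` is reported but weakly identified by these three statistics.
* The delta scan and enrichment test operate on frequencies, not reads:
  depth enters only through the filters and the generator's binomial
  noise.
* Recombination within the locus, gene conversion, population structure
  and time-varying population size are out of scope throughout.
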