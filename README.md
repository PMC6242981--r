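# seedcracker

Population-genetic analyses for a Mendelian bill-size polymorphism
maintained by balancing selection, modelled on the black-bellied
seedcracker (*Pyrenestes ostrinus*). The finch segregates discrete small,
large and mega bill morphs inside randomly mating populations; a single
~300 Kb low-recombination locus containing *IGF1* carries two deeply
divergent haplogroups, with the large-bill haplotype dominant. This
package is for population geneticists who want to (a) date such a
balanced haplotype and (b) run the companion candidate-region analyses on
pooled and phased data — with a synthetic-data generator so every stage is
testable against known truth.

## What it computes

**Haplotype age by rejection ABC.** Forward Wright–Fisher trajectories of
a derived allele under heterozygote advantage start from a single copy and
converge to the equilibrium frequency f_eq = s2/(s1+s2) implied by the
genotype fitnesses (w_het = 1, w_anc_hom = 1 − s2, w_der_hom = 1 − s1,
with S = 4·Ne·s2 the scaled selection coefficient). Conditional on each
trajectory x(t), a structured coalescent simulates a genealogy of n_anc
ancestral and n_der derived haplotypes — derived pairs coalesce at rate
1/(2N·x(t)), ancestral pairs at 1/(2N·(1−x(t))), no movement between
classes while the allele segregates, forced merge of derived lineages at
the allele's origin — and infinite-sites mutations yield three summary
statistics: π within the ancestral class, π within the derived class, and
d_xy between classes (all per bp). Rejection sampling over uniform priors
(S ∈ [50, 1000], f_eq ∈ [0.2, 0.8], T_age ∈ [0, 5] coalescent units of
4·Ne generations) keeps the draws with the smallest Euclidean distance to
the observed statistics; posterior modes come from a Gaussian KDE. Ages
convert via Ne = θ̂/(4μ) with μ = 2.2×10⁻⁹ and a 5-year generation time.

**Candidate-region scans.** Δ = |p_ref(pool A) − p_ref(pool B)| per SNP
from Pool-seq frequency tables (depth-filtered), Δ ≥ 0.9 retention,
gap-clustering to bound the candidate region (span convention
`end − start`), shared-polymorphism density with a 1.5 kb rectangular
kernel to predict inversion breakpoints, gene-length-weighted multinomial
bootstrap for private-allele enrichment (null count per gene is
Binomial(M, len_g/Σlen)), sliding-window observed heterozygosity, and OLS
association of haplotype dosage (0/1/2) with lower mandible width.

## Worked example

```r
library(seedcracker)

# synthetic cohort: two fully divergent haplogroups, dominance enforced
panel  <- generate_haplotype_panel(n_anc = 6, n_der = 6, L = 972,
                                   divergence = 1, intra_diversity = 0.05,
                                   seed = 1)
cohort <- generate_cohort(panel, n_small = 12, n_large = 12, seed = 1)

# pooled frequencies with an implanted high-delta candidate region
pool <- generate_pool_af(cohort, candidate_interval = c(55070008, 55371638),
                         background_sites = 1000, region_sites = 38,
                         delta_in_region = 0.95, chrom_length = 6e7, seed = 1)
hits <- delta_scan(pool, "small", "large", threshold = 0.9)
bound_candidate_region(hits, max_gap = 1e5)
#> TGU1A: 55,070,008-55,371,638 (span 301,630 bp)

# ABC age estimate from pseudo-observed summary statistics
cfg   <- sample_config(n_anc = 20, n_der = 10, L = 30000,
                       theta = 0.001 * 285969 / 30000)
truth <- data.frame(S = 500, f_eq = 0.45, T_age = 2.21)
ref0  <- run_reference_table(truth[rep(1, 100), ], cfg, N_sim = 5000,
                             seed = 2)
obs   <- colMeans(ref0[, c("pi_anc", "pi_der", "dxy")])
fit   <- abc_estimate_age(obs, theta_hat = 0.001,
                          config = abc_config(n_sims = 20000, n_accept = 200),
                          sample_cfg = cfg, N_sim = 5000, seed = 3)
fit
#> Rejection-ABC age estimate
#>   accepted 200 draws (61 simulation failures excluded)
#>   posterior modes: S = 418, f_eq = 0.344, T_age = 2.51 (x 4Ne generations)
#>   theta_hat = 0.001 /bp  =>  Ne = 114,000
#>   age: 2.51 coalescent units = 1,140,000 generations = 5,720,000 years
```

The region scan returns exactly the implanted boundary SNPs, whose span
reproduces the 301,630 bp candidate-region arithmetic. The ABC, given
statistics generated at f_eq = 0.45 and T_age = 2.21, recovers an age
near 2.2–2.5 coalescent units, which the plug-in θ̂ = 0.001/bp converts
to Ne ≈ 114,000 and an age of roughly one million generations (about
five million years). Single-run posterior modes scatter around the truth
(here f_eq = 0.34 for a truth of 0.45); the test suite quantifies the
recovery over ten seeded replicates (f_eq within ±0.10 and T_age within
±0.75 in at least eight). The selection coefficient S is weakly
identified by these statistics, which is expected: once the allele is
near equilibrium, very different selection strengths produce
near-identical diversity patterns.

## Package layout

| Area | Functions |
| --- | --- |
| Synthetic data | `generate_haplotype_panel`, `generate_cohort`, `generate_pool_af`, `generate_gene_annotation` |
| Trajectories | `trajectory_params`, `fitnesses_from_params`, `equilibrium_frequency`, `simulate_trajectory` |
| Coalescent | `sample_config`, `simulate_genealogy`, `drop_mutations`, `simulate_sample`, `genealogy_to_phylo`, `write_ms` |
| Summary statistics | `nucleotide_diversity`, `dxy`, `watterson_theta`, `mismatch_matrix`, `summary_stats`, `observed_heterozygosity_windows`, `haplotype_dosage_association` |
| ABC | `prior_spec`, `abc_config`, `sample_prior`, `run_reference_table`, `rejection_select`, `posterior_mode`, `ne_from_theta`, `age_to_generations_years`, `abc_estimate_age` |
| Region scans | `delta_scan`, `bound_candidate_region`, `region`, `region_span`, `shared_polymorphism_sites`, `density_track`, `predict_breakpoints` |
| Enrichment | `private_fixed_sites`, `assign_to_genes`, `bootstrap_enrichment` |
| I/O | VCF (phased GT), phenotype/pool/reference-table TSV, BED3+1, bedGraph, ms-style text, trajectory TSV |

The methods vignette (`vignettes/haplotype-age-and-region-scans.Rmd`)
documents the model assumptions, parameter conventions, numerical choices
and the limits of what the synthetic-data tests demonstrate.
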