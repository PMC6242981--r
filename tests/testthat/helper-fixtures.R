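# Small builders shared across test files. Everything is generated in code;
# no fixtures are read from disk.

# a minimal cohort object built directly from phased haplotype matrices
make_cohort <- function(hap1, hap2, morph, positions = seq_len(ncol(hap1)),
                        lmw = NULL, chrom = "TGU1A") {
  n <- nrow(hap1)
  ids <- sprintf("I%02d", seq_len(n))
  rownames(hap1) <- rownames(hap2) <- ids
  structure(list(
    pheno = data.frame(individual_id = ids, morph = morph,
                       lmw = lmw %||% rep(15, n),
                       hap1_id = rep("h", n), hap2_id = rep("h", n),
                       derived_dosage = rep(NA_integer_, n)),
    hap1 = hap1, hap2 = hap2, positions = positions, chrom = chrom),
    class = "cohort")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# default small cohort for pool-table generation
tiny_cohort <- function(seed = 1) {
  panel <- generate_haplotype_panel(4, 4, L = 20, divergence = 1, seed = seed)
  generate_cohort(panel, n_small = 3, n_large = 3, n_mega = 3, seed = seed)
}

# brute-force mean pairwise difference between rows of a binary matrix
brute_pi <- function(haps, L) {
  n <- nrow(haps)
  tot <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    tot <- tot + sum(haps[i, ] != haps[j, ])
  tot / choose(n, 2) / L
}

brute_dxy <- function(A, B, L) {
  tot <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(B)))
    tot <- tot + sum(A[i, ] != B[j, ])
  tot / (nrow(A) * nrow(B)) / L
}

# flat trajectory stand-in for Kingman-limit genealogies (n_der = 0)
null_trajectory <- function(N_sim = 5000) {
  structure(list(freqs = 1 / (2 * N_sim), N_sim = N_sim,
                 params = trajectory_params(100, 0.5, 0), rejects = 0L),
            class = "trajectory")
}

a_harmonic <- function(n) sum(1 / seq_len(n - 1))
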