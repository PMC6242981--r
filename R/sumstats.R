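#' Nucleotide diversity (pi) of a haplotype matrix
#'
#' Average number of pairwise differences over all unordered haplotype
#' pairs, divided by the locus length `L`. Missing genotypes (NA) are
#' handled pairwise-complete: a pair contributes only the sites at which
#' both haplotypes are called.
#'
#' @param haps binary matrix, haplotypes in rows, sites in columns.
#' @param L locus length in bp used as the per-bp denominator.
#' @return Per-bp nucleotide diversity (>= 0).
#' @examples
#' h <- rbind(c(0, 0, 0), c(1, 1, 1))
#' nucleotide_diversity(h, L = 100)  # 0.03
#' @export
nucleotide_diversity <- function(haps, L) {
  haps <- as.matrix(haps)
  n <- nrow(haps)
  if (n < 2) stop("need at least 2 haplotypes", call. = FALSE)
  stopifnot(L >= 1)
  if (ncol(haps) == 0L) return(0)
  if (!anyNA(haps)) {
    c1 <- colSums(haps == 1L)
    return(sum(c1 * (n - c1)) / choose(n, 2) / L)
  }
  tot <- 0
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    ok <- !is.na(haps[i, ]) & !is.na(haps[j, ])
    tot <- tot + sum(haps[i, ok] != haps[j, ok])
  }
  tot / choose(n, 2) / L
}

#' Average pairwise divergence between two haplotype groups (d_xy)
#'
#' Mean pairwise difference count over all between-group haplotype pairs,
#' divided by `L`. NA genotypes are pairwise-complete as in
#' [nucleotide_diversity()].
#'
#' @param hapsA,hapsB binary matrices over the same sites (columns).
#' @param L locus length in bp.
#' @return Per-bp divergence (>= 0).
#' @export
dxy <- function(hapsA, hapsB, L) {
  hapsA <- as.matrix(hapsA); hapsB <- as.matrix(hapsB)
  if (nrow(hapsA) < 1 || nrow(hapsB) < 1)
    stop("both groups must be non-empty", call. = FALSE)
  if (ncol(hapsA) != ncol(hapsB))
    stop("groups must be typed at the same sites", call. = FALSE)
  stopifnot(L >= 1)
  if (ncol(hapsA) == 0L) return(0)
  nA <- nrow(hapsA); nB <- nrow(hapsB)
  if (!anyNA(hapsA) && !anyNA(hapsB)) {
    cA <- colSums(hapsA == 1L); cB <- colSums(hapsB == 1L)
    return(sum(cA * (nB - cB) + (nA - cA) * cB) / (nA * nB) / L)
  }
  tot <- 0
  for (i in seq_len(nA)) for (j in seq_len(nB)) {
    ok <- !is.na(hapsA[i, ]) & !is.na(hapsB[j, ])
    tot <- tot + sum(hapsA[i, ok] != hapsB[j, ok])
  }
  tot / (nA * nB) / L
}

#' Watterson's estimator of the scaled mutation rate
#'
#' `theta_W = K / (a_n * L)` with `K` the number of segregating sites and
#' `a_n = sum(1/i, i = 1..n-1)`.
#'
#' @inheritParams nucleotide_diversity
#' @return Per-bp Watterson estimate.
#' @export
watterson_theta <- function(haps, L) {
  haps <- as.matrix(haps)
  n <- nrow(haps)
  if (n < 2) stop("need at least 2 haplotypes", call. = FALSE)
  stopifnot(L >= 1)
  if (ncol(haps) == 0L) return(0)
  seg <- apply(haps, 2L, function(col) {
    u <- unique(col[!is.na(col)])
    length(u) > 1L
  })
  a_n <- sum(1 / seq_len(n - 1L))
  sum(seg) / (a_n * L)
}

#' Pairwise mismatch matrix over assayed SNP sites
#'
#' Per haplotype pair, the fraction of (pairwise-complete) assayed sites at
#' which the two haplotypes differ. The denominator is the number of sites,
#' not the locus length: this matches "percent mismatches" usage on SNP
#' panels.
#'
#' @param haps binary matrix, >= 2 haplotypes, >= 1 site.
#' @return Symmetric matrix with zero diagonal and entries in \[0, 1\].
#' @export
mismatch_matrix <- function(haps) {
  haps <- as.matrix(haps)
  n <- nrow(haps)
  if (n < 2) stop("need at least 2 haplotypes", call. = FALSE)
  if (ncol(haps) < 1) stop("need at least one assayed site", call. = FALSE)
  m <- matrix(0, n, n, dimnames = list(rownames(haps), rownames(haps)))
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    ok <- !is.na(haps[i, ]) & !is.na(haps[j, ])
    m[i, j] <- m[j, i] <-
      if (any(ok)) mean(haps[i, ok] != haps[j, ok]) else NA_real_
  }
  m
}

#' The three ABC summary statistics of a haplotype sample
#'
#' @param sample a `"hap_sample"` from [simulate_sample()] /
#'   [drop_mutations()], or any list with `mat`, `class_labels`, `L`.
#' @return Class `"summary_stats"`: list with per-bp `pi_anc`, `pi_der`,
#'   `dxy`.
#' @export
summary_stats <- function(sample) {
  a <- sample$mat[sample$class_labels == "anc", , drop = FALSE]
  d <- sample$mat[sample$class_labels == "der", , drop = FALSE]
  structure(list(
    pi_anc = if (nrow(a) >= 2) nucleotide_diversity(a, sample$L) else NA_real_,
    pi_der = if (nrow(d) >= 2) nucleotide_diversity(d, sample$L) else NA_real_,
    dxy = if (nrow(a) >= 1 && nrow(d) >= 1) dxy(a, d, sample$L) else NA_real_),
    class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("pi_anc = %.6g, pi_der = %.6g, d_xy = %.6g (per bp)\n",
              x$pi_anc, x$pi_der, x$dxy))
  invisible(x)
}

#' Observed heterozygosity in sliding SNP windows
#'
#' `H_O` is the fraction of heterozygous calls per individual per window;
#' windows advance in SNP index space (default 200 SNPs with a 100-SNP
#' step). The trailing partial window is retained and flagged.
#'
#' @param cohort a `"cohort"` object ([generate_cohort()]), or a logical /
#'   0-1 matrix of per-individual, per-site heterozygosity calls.
#' @param window,step window size and step in SNPs.
#' @param group optional grouping vector for the group means (defaults to
#'   the cohort's morph).
#' @return List with `per_individual` (long data frame: individual, group,
#'   window index, SNP bounds, `h_obs`, `partial`) and `group_means`.
#' @export
observed_heterozygosity_windows <- function(cohort, window = 200, step = 100,
                                            group = NULL) {
  if (window < 1) stop("`window` must be >= 1", call. = FALSE)
  if (step < 1) stop("`step` must be >= 1", call. = FALSE)
  if (inherits(cohort, "cohort")) {
    het <- cohort$hap1 != cohort$hap2
    ids <- cohort$pheno$individual_id
    group <- group %||% cohort$pheno$morph
  } else {
    het <- as.matrix(cohort)
    ids <- rownames(het) %||% paste0("ind", seq_len(nrow(het)))
    group <- group %||% rep("all", nrow(het))
  }
  S <- ncol(het)
  starts <- seq.int(1L, max(S - window + 1L, 1L), by = step)
  # retain a trailing partial window when the last full window stops short
  last_end <- starts[length(starts)] + window - 1L
  if (last_end < S) starts <- c(starts, starts[length(starts)] + step)
  per <- do.call(rbind, lapply(seq_along(starts), function(w) {
    s <- starts[w]; e <- min(s + window - 1L, S)
    data.frame(individual_id = ids, group = group, window = w,
               snp_start = s, snp_end = e,
               h_obs = rowMeans(het[, s:e, drop = FALSE], na.rm = TRUE),
               partial = (e - s + 1L) < window,
               row.names = NULL)
  }))
  gm <- aggregate(h_obs ~ group + window + snp_start + snp_end + partial,
                  data = per, FUN = mean)
  list(per_individual = per, group_means = gm[order(gm$window, gm$group), ])
}

#' Quantitative association between haplotype dosage and a trait
#'
#' Ordinary least-squares regression of the trait (lower mandible width, mm)
#' on the per-individual count of a focal haplotype (0, 1 or 2), with the
#' Wald t-statistic `T = beta / SE` and a two-sided p-value on `n - 2`
#' degrees of freedom.
#'
#' @param dosages per-individual haplotype counts in \{0, 1, 2\}.
#' @param lmw trait values (same length).
#' @return Class `"dosage_assoc"`: list with `beta`, `se`, `t`, `r2`, `p`,
#'   `n`.
#' @export
haplotype_dosage_association <- function(dosages, lmw) {
  if (length(dosages) != length(lmw))
    stop("`dosages` and `lmw` must have equal length", call. = FALSE)
  ok <- !is.na(dosages) & !is.na(lmw)
  dosages <- dosages[ok]; lmw <- lmw[ok]
  n <- length(lmw)
  if (n < 3) stop("need at least 3 individuals", call. = FALSE)
  if (var(dosages) == 0)
    stop("dosage has zero variance; association is undefined", call. = FALSE)
  fit <- lm(lmw ~ dosages)
  sm <- summary(fit)
  beta <- unname(coef(fit)[2])
  se <- sm$coefficients[2, 2]
  tval <- beta / se
  structure(list(beta = beta, se = se, t = tval, r2 = sm$r.squared,
                 p = 2 * pt(abs(tval), df = n - 2, lower.tail = FALSE),
                 n = n),
            class = "dosage_assoc")
}

#' @importFrom stats pt
#' @export
print.dosage_assoc <- function(x, ...) {
  cat(sprintf("beta = %.3f +/- %.3f s.e., T = %.2f, R2 = %.3f, P = %.3g (n = %d)\n",
              x$beta, x$se, x$t, x$r2, x$p, x$n))
  invisible(x)
}
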