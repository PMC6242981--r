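#' Generate a two-haplogroup haplotype panel
#'
#' Emulates the structure observed at the candidate locus: two divergent
#' founder haplotypes (ancestral and derived) that differ at
#' `ceiling(divergence * L)` sites, panel members that are copies of a
#' founder with independent per-site mutations at rate `intra_diversity`,
#' and optional single-breakpoint recombinant mosaics of one ancestral and
#' one derived panel member.
#'
#' @param n_anc,n_der number of ancestral- / derived-class panel haplotypes.
#' @param L number of assayed SNP sites.
#' @param divergence fraction of sites at which the founders differ.
#' @param intra_diversity per-site mutation (flip) probability within a
#'   haplogroup.
#' @param n_recombinants number of single-breakpoint recombinant haplotypes.
#' @param seed optional integer seed.
#' @return Class `"hap_panel"`: binary matrix `haps` (rows = haplotypes),
#'   `class_labels` in \{"anc", "der", "rec"\}, site `positions` (1-based),
#'   founder haplotypes and recorded recombination `breakpoints` as truth.
#' @examples
#' p <- generate_haplotype_panel(4, 4, L = 10, divergence = 1, seed = 1)
#' mean(p$founder_anc != p$founder_der)  # 1: founders 100% divergent
#' @export
generate_haplotype_panel <- function(n_anc, n_der, L, divergence,
                                     intra_diversity = 0,
                                     n_recombinants = 0, seed = NULL) {
  stop_if_not_scalar_prob(divergence, "divergence")
  stop_if_not_scalar_prob(intra_diversity, "intra_diversity")
  stopifnot(L >= 1, n_anc >= 0, n_der >= 0, n_recombinants >= 0)
  if (n_recombinants > 0 && (n_anc < 1 || n_der < 1))
    stop("recombinants need at least one panel member of each class",
         call. = FALSE)
  if (n_recombinants > 0 && L < 2)
    stop("recombinants need at least two sites", call. = FALSE)
  set_op_seed(seed, "generate_haplotype_panel")
  founder_anc <- integer(L)
  founder_der <- integer(L)
  n_div <- ceiling(divergence * L)
  if (n_div > 0) founder_der[sample.int(L, n_div)] <- 1L
  mutate <- function(h) {
    if (intra_diversity > 0) {
      flip <- runif(L) < intra_diversity
      h[flip] <- 1L - h[flip]
    }
    h
  }
  haps <- matrix(0L, n_anc + n_der + n_recombinants, L)
  for (i in seq_len(n_anc)) haps[i, ] <- mutate(founder_anc)
  for (i in seq_len(n_der)) haps[n_anc + i, ] <- mutate(founder_der)
  breakpoints <- NULL
  if (n_recombinants > 0) {
    breakpoints <- data.frame(recombinant = character(0), anc_parent = integer(0),
                              der_parent = integer(0), breakpoint = integer(0),
                              left_class = character(0))
    for (i in seq_len(n_recombinants)) {
      ia <- sample.int(n_anc, 1L)
      id <- n_anc + sample.int(n_der, 1L)
      b <- if (L > 1) sample.int(L - 1L, 1L) else 1L   # last site of left block
      left_anc <- runif(1) < 0.5
      left <- if (left_anc) haps[ia, ] else haps[id, ]
      right <- if (left_anc) haps[id, ] else haps[ia, ]
      haps[n_anc + n_der + i, ] <- c(left[seq_len(b)],
                                     right[seq.int(b + 1L, L)])
      breakpoints <- rbind(breakpoints, data.frame(
        recombinant = paste0("rec_", i), anc_parent = ia, der_parent = id,
        breakpoint = b, left_class = if (left_anc) "anc" else "der"))
    }
  }
  class_labels <- rep(c("anc", "der", "rec"),
                      c(n_anc, n_der, n_recombinants))
  rownames(haps) <- paste0(class_labels, "_",
                           unlist(lapply(c(n_anc, n_der, n_recombinants),
                                         seq_len)))
  structure(list(haps = haps, class_labels = class_labels,
                 positions = seq_len(L), L = L,
                 founder_anc = founder_anc, founder_der = founder_der,
                 breakpoints = breakpoints),
            class = "hap_panel")
}

#' Generate a phenotyped cohort from a haplotype panel
#'
#' Assigns two panel haplotypes to each individual under the dominance rule
#' of the system: small-morph individuals carry two ancestral-class
#' haplotypes; large-morph individuals carry at least one derived-class
#' haplotype, with both heterozygous (anc/der) and homozygous-derived
#' genotypes represented (half each, heterozygotes rounded down); mega
#' individuals are homozygous derived. Lower mandible width is drawn
#' `Normal(mean_morph, morph_sd)`; heterozygous large individuals receive a
#' small negative offset (incomplete dominance).
#'
#' @param panel a `"hap_panel"`.
#' @param n_small,n_large,n_mega individuals per morph.
#' @param morph_means mean LMW (mm) for small, large, mega.
#' @param morph_sd common within-morph LMW standard deviation (mm).
#' @param het_large_offset LMW reduction (mm) for heterozygous large
#'   individuals.
#' @param chrom chromosome name for downstream interval work.
#' @param seed optional integer seed.
#' @return Class `"cohort"`: `pheno` data frame (individual_id, morph, lmw,
#'   hap1_id, hap2_id, derived_dosage), phased haplotype matrices `hap1`,
#'   `hap2` (individuals x sites), site `positions`, `chrom`.
#' @export
generate_cohort <- function(panel, n_small, n_large, n_mega = 0,
                            morph_means = c(12.8, 16.4, 19.6),
                            morph_sd = 0.3, het_large_offset = 0.5,
                            chrom = "TGU1A", seed = NULL) {
  stopifnot(inherits(panel, "hap_panel"), n_small >= 0, n_large >= 0,
            n_mega >= 0, length(morph_means) == 3)
  if (morph_sd < 0) stop("`morph_sd` must be >= 0", call. = FALSE)
  anc_rows <- which(panel$class_labels == "anc")
  der_rows <- which(panel$class_labels == "der")
  if ((n_small > 0 || n_large > 0) && length(anc_rows) == 0)
    stop("panel has no ancestral-class haplotypes; cannot build the ",
         "requested small/heterozygous genotypes", call. = FALSE)
  if ((n_large > 0 || n_mega > 0) && length(der_rows) == 0)
    stop("panel has no derived-class haplotypes; cannot build the ",
         "requested large/mega genotypes", call. = FALSE)
  set_op_seed(seed, "generate_cohort")
  draw <- function(rows, n) rows[sample.int(length(rows), n, replace = TRUE)]
  n_het <- if (n_large >= 2) floor(n_large / 2) else 0L
  n_hom <- n_large - n_het
  morph <- rep(c("small", "large", "mega"), c(n_small, n_large, n_mega))
  n_tot <- length(morph)
  hap1_row <- c(draw(anc_rows, n_small),            # small: anc/anc
                draw(der_rows, n_hom),              # large hom: der/der
                draw(der_rows, n_het),              # large het: der/anc
                draw(der_rows, n_mega))             # mega: der/der
  hap2_row <- c(draw(anc_rows, n_small),
                draw(der_rows, n_hom),
                draw(anc_rows, n_het),
                draw(der_rows, n_mega))
  is_het_large <- rep(c(FALSE, FALSE, TRUE, FALSE),
                      c(n_small, n_hom, n_het, n_mega))
  mu <- morph_means[match(morph, c("small", "large", "mega"))] -
    het_large_offset * is_het_large
  lmw <- rnorm(n_tot, mean = mu, sd = morph_sd)
  ids <- sprintf("%s%02d", c("S", "L", "M")[match(morph, c("small", "large", "mega"))],
                 unlist(lapply(c(n_small, n_large, n_mega), seq_len)))
  pheno <- data.frame(
    individual_id = ids, morph = morph, lmw = lmw,
    hap1_id = rownames(panel$haps)[hap1_row],
    hap2_id = rownames(panel$haps)[hap2_row],
    derived_dosage = (panel$class_labels[hap1_row] == "der") +
      (panel$class_labels[hap2_row] == "der"),
    row.names = NULL)
  hap1 <- panel$haps[hap1_row, , drop = FALSE]
  hap2 <- panel$haps[hap2_row, , drop = FALSE]
  rownames(hap1) <- rownames(hap2) <- ids
  structure(list(pheno = pheno, hap1 = hap1, hap2 = hap2,
                 positions = panel$positions, chrom = chrom),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Cohort of %d individuals (%s) at %d sites on %s\n",
              nrow(x$pheno),
              paste(names(table(x$pheno$morph)), table(x$pheno$morph),
                    sep = " = ", collapse = ", "),
              ncol(x$hap1), x$chrom))
  invisible(x)
}

#' Generate a pooled allele-frequency table with an implanted candidate region
#'
#' Background sites carry per-pool reference-allele frequencies drawn by
#' binomial read sampling around a shared site frequency (low
#' differentiation). Sites inside `candidate_interval` are implanted with
#' `|freq_small - freq_large| >= delta_in_region` and are emitted exactly
#' (no read noise) so the contract holds deterministically; the interval's
#' boundary SNPs sit exactly at its start and end. The mega pool tracks the
#' large pool inside the region. Optional mega-private sites (fixed
#' alternate in mega, pure reference elsewhere) support the enrichment
#' analyses.
#'
#' @param cohort a `"cohort"` (supplies the chromosome name; must be
#'   non-empty).
#' @param candidate_interval numeric `c(start, end)` in bp (1-based SNP
#'   coordinates).
#' @param background_sites number of background SNPs.
#' @param region_sites number of SNPs implanted inside the interval.
#' @param delta_in_region minimum small-large frequency difference inside
#'   the region, in \[0, 1\].
#' @param depth_range integer `c(min, max)` per-pool read depth.
#' @param background_freq_range `c(min, max)` range of the shared
#'   background site frequency.
#' @param chrom_length chromosome length in bp over which background sites
#'   scatter (default: interval end + 100 kb).
#' @param mega_private_sites integer count, or vector of bp positions, of
#'   mega-private fixed sites.
#' @param seed optional integer seed.
#' @return Class `"pool_af"` data frame: chrom, pos, ref, alt,
#'   freq_small/large/mega, depth_small/large/mega; attributes
#'   `region_positions`, `mega_private_positions`, `candidate_interval`
#'   record the truth.
#' @export
generate_pool_af <- function(cohort, candidate_interval,
                             background_sites = 1000, region_sites = 40,
                             delta_in_region = 0.95,
                             depth_range = c(10, 40),
                             background_freq_range = c(0.05, 0.95),
                             chrom_length = NULL,
                             mega_private_sites = 0, seed = NULL) {
  stopifnot(inherits(cohort, "cohort"))
  if (nrow(cohort$pheno) == 0) stop("cohort is empty", call. = FALSE)
  stop_if_not_scalar_prob(delta_in_region, "delta_in_region")
  stopifnot(length(candidate_interval) == 2,
            candidate_interval[2] >= candidate_interval[1],
            region_sites >= 2 || region_sites == 0)
  set_op_seed(seed, "generate_pool_af")
  chrom_length <- chrom_length %||% (candidate_interval[2] + 1e5)
  rdepth <- function(n) sample.int(depth_range[2] - depth_range[1] + 1L, n,
                                   replace = TRUE) + depth_range[1] - 1L

  # background: shared frequency, binomial read noise per pool
  bg_pos <- sort(sample(setdiff(seq_len(chrom_length),
                                seq.int(candidate_interval[1],
                                        candidate_interval[2])),
                        background_sites))
  p_shared <- runif(background_sites, background_freq_range[1],
                    background_freq_range[2])
  bg <- lapply(c("small", "large", "mega"), function(pool) {
    d <- rdepth(background_sites)
    list(freq = rbinom(background_sites, d, p_shared) / d, depth = d)
  })

  # candidate region: exact high-delta frequencies, boundary SNPs at the ends
  if (region_sites > 0) {
    inner <- if (region_sites > 2)
      sort(sample(seq.int(candidate_interval[1] + 1,
                          candidate_interval[2] - 1), region_sites - 2L))
    else integer(0)
    rg_pos <- c(candidate_interval[1], inner, candidate_interval[2])
    dlt <- runif(region_sites, delta_in_region, 1)
    base <- runif(region_sites, 0, 1 - dlt)
    f_small <- base + dlt       # reference allele rides the small haplotype
    f_large <- base
    rg <- list(
      list(freq = f_small, depth = rdepth(region_sites)),
      list(freq = f_large, depth = rdepth(region_sites)),
      list(freq = f_large, depth = rdepth(region_sites)))
  } else {
    rg_pos <- integer(0)
    rg <- list(list(freq = numeric(0), depth = integer(0)),
               list(freq = numeric(0), depth = integer(0)),
               list(freq = numeric(0), depth = integer(0)))
  }

  # mega-private fixed sites: a scalar is a count (positions sampled), a
  # vector is taken as literal bp positions
  if (length(mega_private_sites) == 1L) {
    stopifnot(mega_private_sites >= 0,
              mega_private_sites == round(mega_private_sites))
    mp_pos <- if (mega_private_sites == 0) integer(0)
      else sort(sample(setdiff(seq_len(chrom_length), c(bg_pos, rg_pos)),
                       mega_private_sites))
  } else {
    mp_pos <- sort(as.numeric(mega_private_sites))
  }
  n_mp <- length(mp_pos)
  mp <- list(list(freq = rep(1, n_mp), depth = rdepth(n_mp)),
             list(freq = rep(1, n_mp), depth = rdepth(n_mp)),
             list(freq = rep(0, n_mp), depth = rdepth(n_mp)))

  pos <- c(bg_pos, rg_pos, mp_pos)
  ord <- order(pos)
  nt <- c("A", "C", "G", "T")
  ref <- sample(nt, length(pos), replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(nt, r), 1L), character(1))
  out <- data.frame(
    chrom = cohort$chrom, pos = pos,
    ref = ref, alt = unname(alt),
    freq_small = c(bg[[1]]$freq, rg[[1]]$freq, mp[[1]]$freq),
    freq_large = c(bg[[2]]$freq, rg[[2]]$freq, mp[[2]]$freq),
    freq_mega = c(bg[[3]]$freq, rg[[3]]$freq, mp[[3]]$freq),
    depth_small = c(bg[[1]]$depth, rg[[1]]$depth, mp[[1]]$depth),
    depth_large = c(bg[[2]]$depth, rg[[2]]$depth, mp[[2]]$depth),
    depth_mega = c(bg[[3]]$depth, rg[[3]]$depth, mp[[3]]$depth),
    row.names = NULL)[ord, ]
  rownames(out) <- NULL
  structure(out, class = c("pool_af", "data.frame"),
            region_positions = rg_pos,
            mega_private_positions = mp_pos,
            candidate_interval = candidate_interval)
}

#' Generate a non-overlapping gene annotation
#'
#' Gene intervals are BED-convention half-open with 0-based starts; lengths
#' are uniform in `length_range` and placement is uniform subject to
#' non-overlap.
#'
#' @param chrom_length chromosome length in bp.
#' @param n_genes number of genes.
#' @param length_range `c(min, max)` gene length in bp.
#' @param chrom chromosome name.
#' @param seed optional integer seed.
#' @return Class `"gene_annotation"` data frame: gene_id, chrom, start,
#'   end, length (= end - start).
#' @export
generate_gene_annotation <- function(chrom_length, n_genes,
                                     length_range = c(1000, 20000),
                                     chrom = "TGU1A", seed = NULL) {
  stopifnot(chrom_length >= 1, n_genes >= 0, length(length_range) == 2,
            length_range[1] >= 1, length_range[2] >= length_range[1])
  if (n_genes == 0)
    return(structure(data.frame(gene_id = character(0), chrom = character(0),
                                start = numeric(0), end = numeric(0),
                                length = numeric(0)),
                     class = c("gene_annotation", "data.frame")))
  set_op_seed(seed, "generate_gene_annotation")
  len <- round(runif(n_genes, length_range[1], length_range[2]))
  free <- chrom_length - sum(len)
  if (free < 0)
    stop("cannot pack ", n_genes, " genes of these lengths into ",
         chrom_length, " bp", call. = FALSE)
  gaps <- floor(sort(runif(n_genes, 0, free)))
  start <- gaps + cumsum(c(0, len[-n_genes]))    # 0-based, half-open
  structure(data.frame(gene_id = sprintf("gene%03d", seq_len(n_genes)),
                       chrom = chrom, start = start, end = start + len,
                       length = len, row.names = NULL),
            class = c("gene_annotation", "data.frame"))
}
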