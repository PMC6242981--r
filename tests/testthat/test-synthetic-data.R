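test_that("founder divergence is controlled exactly", {
  # fully divergent founders mismatch everywhere
  p <- generate_haplotype_panel(2, 2, L = 50, divergence = 1, seed = 1)
  expect_equal(mean(p$founder_anc != p$founder_der), 1)
  mm <- mismatch_matrix(p$haps)
  expect_equal(mm[1, 3], 1)       # anc vs der copies, no intra mutation

  # identity case: no divergence, no diversity
  p0 <- generate_haplotype_panel(3, 3, L = 40, divergence = 0, seed = 1)
  expect_true(all(mismatch_matrix(p0$haps) == 0))

  # exact mismatch count, reproducible under the seed
  p5 <- generate_haplotype_panel(1, 1, L = 10, divergence = 0.5, seed = 9)
  expect_equal(sum(p5$founder_anc != p5$founder_der), 5)
  p5b <- generate_haplotype_panel(1, 1, L = 10, divergence = 0.5, seed = 9)
  expect_identical(p5, p5b)

  expect_error(generate_haplotype_panel(2, 2, 10, divergence = 1.2),
               "divergence")
})

test_that("recombinants are single-breakpoint mosaics with recorded truth", {
  p <- generate_haplotype_panel(3, 3, L = 30, divergence = 1,
                                n_recombinants = 4, seed = 2)
  expect_equal(sum(p$class_labels == "rec"), 4)
  for (i in seq_len(4)) {
    bp <- p$breakpoints[i, ]
    rec <- p$haps[6 + i, ]
    left_parent <- if (bp$left_class == "anc") bp$anc_parent else bp$der_parent
    right_parent <- if (bp$left_class == "anc") bp$der_parent else bp$anc_parent
    expect_equal(rec[1:bp$breakpoint], p$haps[left_parent, 1:bp$breakpoint])
    expect_equal(rec[(bp$breakpoint + 1):30],
                 p$haps[right_parent, (bp$breakpoint + 1):30])
  }
})

test_that("cohorts respect the dominance rule and the morph means", {
  p <- generate_haplotype_panel(4, 4, L = 25, divergence = 1, seed = 3)
  co <- generate_cohort(p, n_small = 12, n_large = 12, seed = 3)
  expect_equal(nrow(co$pheno), 24)
  expect_equal(nrow(co$hap1) + nrow(co$hap2), 48)

  # dominance consistency: small <=> zero derived haplotypes
  expect_true(all((co$pheno$morph == "small") ==
                    (co$pheno$derived_dosage == 0)))
  # both het and hom-derived genotypes represented among the large
  large_dose <- co$pheno$derived_dosage[co$pheno$morph == "large"]
  expect_setequal(unique(large_dose), c(1, 2))

  # vanishing within-morph variance pins LMW at the morph means
  co0 <- generate_cohort(p, 5, 5, 5, morph_sd = 1e-12,
                         het_large_offset = 0, seed = 4)
  agg <- aggregate(lmw ~ morph, co0$pheno, mean)
  expect_equal(agg$lmw[agg$morph == "small"], 12.8, tolerance = 1e-9)
  expect_equal(agg$lmw[agg$morph == "large"], 16.4, tolerance = 1e-9)
  expect_equal(agg$lmw[agg$morph == "mega"], 19.6, tolerance = 1e-9)

  # byte-identical regeneration under the seed
  a <- generate_cohort(p, 6, 6, 2, seed = 11)
  b <- generate_cohort(p, 6, 6, 2, seed = 11)
  expect_identical(a, b)

  # impossible mixes are refused
  p_anc_only <- generate_haplotype_panel(3, 0, L = 10, divergence = 0.5,
                                         seed = 5)
  expect_error(generate_cohort(p_anc_only, 2, 2, seed = 1),
               "no derived-class")
  p_der_only <- generate_haplotype_panel(0, 3, L = 10, divergence = 0.5,
                                         seed = 5)
  expect_error(generate_cohort(p_der_only, 2, 0, seed = 1),
               "no ancestral-class")
})

test_that("heterozygous large individuals can carry a small LMW offset", {
  p <- generate_haplotype_panel(4, 4, L = 10, divergence = 1, seed = 6)
  co <- generate_cohort(p, 0, 12, morph_sd = 1e-12, het_large_offset = 0.5,
                        seed = 6)
  het <- co$pheno$derived_dosage == 1
  expect_equal(unique(round(co$pheno$lmw[het], 6)), 15.9)
  expect_equal(unique(round(co$pheno$lmw[!het], 6)), 16.4)
})

test_that("pooled tables implant the candidate region as promised", {
  co <- tiny_cohort()
  pool <- generate_pool_af(co, candidate_interval = c(55070008, 55371638),
                           background_sites = 300, region_sites = 20,
                           delta_in_region = 1.0, seed = 7)
  rg <- attr(pool, "region_positions")
  inr <- pool$pos %in% rg
  expect_equal(sum(inr), 20)
  d <- abs(pool$freq_small - pool$freq_large)
  expect_true(all(d[inr] == 1))
  # boundary SNPs sit exactly on the interval ends
  expect_true(all(c(55070008, 55371638) %in% rg))

  # frequencies and depths respect their bounds
  for (cl in grep("^freq_", names(pool), value = TRUE))
    expect_true(all(pool[[cl]] >= 0 & pool[[cl]] <= 1))
  for (cl in grep("^depth_", names(pool), value = TRUE))
    expect_true(all(pool[[cl]] >= 10 & pool[[cl]] <= 40))
  expect_false(is.unsorted(pool$pos))
  expect_false(anyDuplicated(pool$pos) > 0)

  # delta_in_region is a floor on the implanted contrast
  pool95 <- generate_pool_af(co, c(1000, 9000), background_sites = 100,
                             region_sites = 15, delta_in_region = 0.95,
                             seed = 8)
  inr <- pool95$pos %in% attr(pool95, "region_positions")
  expect_true(all(abs(pool95$freq_small - pool95$freq_large)[inr] >= 0.95))

  expect_error(generate_pool_af(make_cohort(matrix(0, 0, 3), matrix(0, 0, 3),
                                            character(0)),
                                c(10, 20)), "empty")
})

test_that("background differentiation matches the binomial sampling oracle", {
  # fixed shared frequency 0.5 and depth 30: E|p1 - p2| by exact enumeration
  co <- tiny_cohort()
  pool <- generate_pool_af(co, candidate_interval = c(900000, 950000),
                           background_sites = 1000, region_sites = 0,
                           depth_range = c(30, 30),
                           background_freq_range = c(0.5, 0.5),
                           chrom_length = 800000, seed = 9)
  d_obs <- abs(pool$freq_small - pool$freq_large)
  pr <- dbinom(0:30, 30, 0.5)
  grid <- abs(outer(0:30, 0:30, "-")) / 30
  e_delta <- sum(outer(pr, pr) * grid)
  se <- sd(d_obs) / sqrt(length(d_obs))
  expect_lt(abs(mean(d_obs) - e_delta), 3 * se)
})

test_that("mega-private sites are implanted as fixed differences", {
  co <- tiny_cohort()
  pos <- c(1234, 5678, 9999)
  pool <- generate_pool_af(co, c(50000, 60000), background_sites = 50,
                           mega_private_sites = pos, seed = 10)
  mp <- pool[pool$pos %in% pos, ]
  expect_equal(nrow(mp), 3)
  expect_true(all(mp$freq_mega == 0))
  expect_true(all(mp$freq_small == 1 & mp$freq_large == 1))
})

test_that("gene annotations are non-overlapping with controlled lengths", {
  ann <- generate_gene_annotation(1e5, 12, length_range = c(1000, 5000),
                                  seed = 11)
  expect_equal(nrow(ann), 12)
  expect_true(all(ann$end > ann$start))
  expect_equal(ann$length, ann$end - ann$start)
  o <- order(ann$start)
  expect_true(all(ann$start[o][-1] >= ann$end[o][-12]))   # no overlap

  fixed <- generate_gene_annotation(1e5, 2, length_range = c(1000, 1000),
                                    seed = 12)
  expect_equal(fixed$length, c(1000, 1000))
  expect_equal(nrow(generate_gene_annotation(1e5, 0)), 0)
  expect_identical(generate_gene_annotation(1e5, 5, seed = 13),
                   generate_gene_annotation(1e5, 5, seed = 13))
  expect_error(generate_gene_annotation(5000, 10,
                                        length_range = c(1000, 1000)),
               "pack")
})
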