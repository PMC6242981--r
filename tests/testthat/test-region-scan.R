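test_that("region spans reproduce the boundary-SNP arithmetic (end - start)", {
  expect_equal(region_span(region("TGU1A", 55070008, 55371638)), 301630)
  expect_equal(region_span(region("TGU1A", 54971008, 55470638)), 499630)
  expect_equal(region_span(region("TGU1A", 55067422, 55386717)), 319295)
  expect_equal(region_span(region("chr", 7, 7)), 0)
  # translation invariance
  expect_equal(region_span(region("chr", 7 + 1e6, 10 + 1e6)),
               region_span(region("chr", 7, 10)))
  expect_error(region("chr", 10, 5), ">=")
})

test_that("delta values and the retention threshold behave as defined", {
  pool <- structure(data.frame(
    chrom = "TGU1A", pos = c(100, 200, 300),
    ref = "A", alt = "T",
    freq_small = c(0.95, 0.5, 1.0), freq_large = c(0.02, 0.5, 0.0),
    freq_mega = 0.5,
    depth_small = 30L, depth_large = 30L, depth_mega = 30L),
    class = c("pool_af", "data.frame"))
  hits <- delta_scan(pool, "small", "large", threshold = 0.9)
  expect_equal(hits$pos, c(100, 300))
  expect_equal(hits$delta, c(0.93, 1.0))
  # identical frequencies are never retained at a positive threshold
  expect_false(200 %in% hits$pos)
  expect_error(delta_scan(pool, "small", "huge"), "not present")
})

test_that("depth filters exclude under/over-covered and non-SNP sites", {
  pool <- structure(data.frame(
    chrom = "c", pos = c(1, 2, 3, 4),
    ref = "A", alt = "T",
    freq_small = c(1, 1, 1, 1), freq_large = c(0, 0, 0, 1),
    freq_mega = 0,
    depth_small = c(30L, 5L, 45L, 30L), depth_large = rep(30L, 4),
    depth_mega = 30L), class = c("pool_af", "data.frame"))
  hits <- delta_scan(pool, "small", "large", threshold = 0.9)
  # site 2 fails min depth, 3 fails max depth, 4 is monomorphic across pools
  expect_equal(hits$pos, 1)
  expect_equal(attr(hits, "n_filtered"), 3)
})

test_that("candidate-region bounding picks the densest cluster", {
  expect_equal(region_span(bound_candidate_region(c(12345))), 0)

  # ten clustered sites beat three scattered ones
  sites <- data.frame(chrom = "TGU1A",
                      pos = c(seq(55070008, 55371638, length.out = 10),
                              c(1e6, 30e6, 70e6)))
  r <- bound_candidate_region(sites, max_gap = 1e5)
  expect_equal(r$start, 55070008)
  expect_equal(r$end, 55371638)
  expect_equal(region_span(r), 301630)
  expect_equal(attr(r, "n_sites"), 10)

  # size ties break toward the smaller span
  tie <- data.frame(chrom = "c", pos = c(1, 2, 3, 1e6, 1.05e6, 1.1e6))
  r2 <- bound_candidate_region(tie, max_gap = 1e5)
  expect_equal(c(r2$start, r2$end), c(1, 3))

  expect_error(bound_candidate_region(numeric(0)), "no sites")
})

test_that("the delta scan recovers the implanted candidate region exactly", {
  co <- tiny_cohort(seed = 20)
  interval <- c(55070008, 55371638)
  pool <- generate_pool_af(co, interval, background_sites = 800,
                           region_sites = 38, delta_in_region = 0.95,
                           chrom_length = 6e7, seed = 21)
  hits <- delta_scan(pool, "small", "large", threshold = 0.9)
  truth <- attr(pool, "region_positions")
  # background deltas sit far below threshold, so the retained set is exactly
  # the implanted sites, and the bounding recovers the boundary SNPs
  expect_setequal(hits$pos, truth)
  r <- bound_candidate_region(hits, max_gap = 1e5)
  expect_equal(c(r$start, r$end), interval)
  expect_equal(region_span(r), 301630)
})

test_that("shared polymorphisms are sites segregating within both groups", {
  #          site: 1  2  3  4
  hap1 <- rbind(c(0, 0, 1, 0),   # A1
                c(0, 1, 1, 0),   # A2
                c(0, 0, 0, 1),   # B1
                c(0, 1, 0, 0))   # B2
  hap2 <- rbind(c(0, 1, 1, 1),
                c(0, 0, 1, 0),
                c(0, 0, 0, 0),
                c(0, 1, 0, 1))
  co <- make_cohort(hap1, hap2, morph = c("small", "small", "large", "large"),
                    positions = c(10, 20, 30, 40))
  shared <- shared_polymorphism_sites(co, c("I01", "I02"), c("I03", "I04"))
  # site 1 monomorphic everywhere; site 3 fixed-different between groups;
  # sites 2 and 4 segregate in both
  expect_equal(shared, c(20, 40))
  expect_error(shared_polymorphism_sites(co, "I01", c("I03", "I04")),
               "at least 2")
  expect_error(shared_polymorphism_sites(co, c("I01", "nope"), c("I03", "I04")),
               "unknown individual")
})

test_that("brute-force agreement on random genotype matrices", {
  set.seed(22)
  n <- 6; S <- 40
  hap1 <- matrix(rbinom(n * S, 1, 0.4), n)
  hap2 <- matrix(rbinom(n * S, 1, 0.4), n)
  co <- make_cohort(hap1, hap2, morph = rep(c("small", "large"), each = 3))
  ga <- co$pheno$individual_id[1:3]; gb <- co$pheno$individual_id[4:6]
  shared <- shared_polymorphism_sites(co, ga, gb)
  brute <- co$positions[vapply(seq_len(S), function(s) {
    xa <- c(hap1[1:3, s], hap2[1:3, s]); xb <- c(hap1[4:6, s], hap2[4:6, s])
    length(unique(xa)) > 1 && length(unique(xb)) > 1
  }, logical(1))]
  expect_equal(shared, brute)
})

test_that("rectangular-kernel density tracks integrate to the site count", {
  ext <- region("c", 1000, 51000)
  z <- density_track(numeric(0), bandwidth = 1500, step = 100, extent = ext)
  expect_true(all(z$density == 0))

  # single position: 1/(2*1500) inside the window, 0 outside
  tr <- density_track(26000, bandwidth = 1500, step = 100, extent = ext)
  inside <- abs(tr$pos - 26000) <= 1500
  expect_true(all(tr$density[inside] == 1 / 3000))
  expect_true(all(tr$density[!inside] == 0))

  # dense uniform positions: density ~ 1/spacing away from the edges
  pos <- seq(1000, 51000, by = 50)
  tr2 <- density_track(pos, bandwidth = 1500, step = 100, extent = ext)
  mid <- tr2$pos > 4000 & tr2$pos < 48000
  expect_equal(unique(round(tr2$density[mid], 6)), round(1 / 50, 6),
               tolerance = 0.02)

  # integral: sum(density) * step ~ number of positions (edge loss <= 2*bw)
  set.seed(23)
  pos3 <- sort(runif(400, 1000, 51000))
  tr3 <- density_track(pos3, bandwidth = 1500, step = 100, extent = ext)
  integral <- sum(tr3$density) * 100
  expect_lt(abs(integral - 400) / 400, 0.1)

  expect_error(density_track(1, bandwidth = 0, step = 10, extent = ext),
               "bandwidth")
  expect_error(density_track(1, extent = region("c", 5, 5)), "zero length")
})

test_that("breakpoint prediction recovers a constructed depleted interval", {
  set.seed(24)
  ext <- region("c", 0, 6e5)
  bw <- 1500
  # shared polymorphisms every ~150 bp except a 300 kb silent interior
  pos <- seq(0, 6e5, by = 150)
  hole <- c(150000, 450000)
  pos <- pos[pos < hole[1] | pos > hole[2]]
  tr <- density_track(pos, bandwidth = bw, step = 100, extent = ext)

  flat <- density_track(seq(0, 6e5, by = 150), bandwidth = bw, step = 100,
                        extent = ext)
  expect_equal(nrow(predict_breakpoints(flat, min_run = 1e4)), 0)

  dep <- predict_breakpoints(tr, depletion_threshold = 0.25, min_run = 1e4)
  expect_equal(nrow(dep), 1)
  expect_lt(abs(dep$start - hole[1]), 2 * bw)
  expect_lt(abs(dep$end - hole[2]), 2 * bw)

  # two depleted runs are both reported, in positional order
  pos2 <- seq(0, 6e5, by = 150)
  pos2 <- pos2[!(pos2 > 1e5 & pos2 < 1.5e5) & !(pos2 > 4e5 & pos2 < 4.8e5)]
  dep2 <- predict_breakpoints(
    density_track(pos2, bandwidth = bw, step = 100, extent = ext),
    depletion_threshold = 0.25, min_run = 1e4)
  expect_equal(nrow(dep2), 2)
  expect_true(all(diff(dep2$start) > 0))
  expect_lt(abs(dep2$start[1] - 1e5), 2 * bw)
  expect_lt(abs(dep2$end[2] - 4.8e5), 2 * bw)

  zero <- density_track(numeric(0), bandwidth = bw, step = 100, extent = ext)
  expect_error(predict_breakpoints(zero), "flank median")
})
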