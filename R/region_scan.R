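#' A genomic region bounded by SNP positions
#'
#' Boundary coordinates are 1-based bp positions of the boundary SNPs; the
#' span convention is `end - start` (not `end - start + 1`), matching the
#' arithmetic used for the candidate-region coordinates
#' (55,371,638 - 55,070,008 = 301,630).
#'
#' @param chrom chromosome name.
#' @param start,end boundary positions with `start <= end`.
#' @return Class `"region"`.
#' @export
region <- function(chrom, start, end) {
  if (end < start) stop("`end` must be >= `start`", call. = FALSE)
  structure(list(chrom = chrom, start = start, end = end), class = "region")
}

#' @export
print.region <- function(x, ...) {
  cat(sprintf("%s: %s-%s (span %s bp)\n", x$chrom,
              format(x$start, big.mark = ","), format(x$end, big.mark = ","),
              format(region_span(x), big.mark = ",")))
  invisible(x)
}

#' Span of a region in bp
#'
#' @param region a `"region"` object (or any list with start/end).
#' @return `end - start`.
#' @examples
#' region_span(region("TGU1A", 55070008, 55371638))  # 301630
#' @export
region_span <- function(region) {
  region$end - region$start
}

#' Delta scan: high allele-frequency-difference sites between two pools
#'
#' Delta is the absolute difference of the reference-allele frequency
#' between two pools. Sites failing the Pool-seq depth filters are excluded
#' first: each pool's total depth must lie in
#' `[min_total_depth, max_total_depth]`, and the site's minor allele must be
#' covered by at least `min_minor_depth` reads summed over the two pools
#' (so the site is a credible SNP; fixed differences pass because the
#' alternate allele is deeply covered in one pool).
#'
#' @param pool a `"pool_af"` table.
#' @param poolA,poolB pool names (must match `freq_<name>` /
#'   `depth_<name>` columns).
#' @param threshold minimum delta retained (default 0.9).
#' @param min_minor_depth,min_total_depth,max_total_depth depth filters.
#' @return The retained rows with a `delta` column; attribute `n_filtered`
#'   counts sites removed by the depth filters.
#' @export
delta_scan <- function(pool, poolA = "small", poolB = "large",
                       threshold = 0.9, min_minor_depth = 2,
                       min_total_depth = 10, max_total_depth = 40) {
  for (p in c(poolA, poolB)) {
    if (!all(paste0(c("freq_", "depth_"), p) %in% names(pool)))
      stop("pool `", p, "` not present in the table", call. = FALSE)
  }
  fA <- pool[[paste0("freq_", poolA)]]
  fB <- pool[[paste0("freq_", poolB)]]
  dA <- pool[[paste0("depth_", poolA)]]
  dB <- pool[[paste0("depth_", poolB)]]
  depth_ok <- dA >= min_total_depth & dA <= max_total_depth &
    dB >= min_total_depth & dB <= max_total_depth
  ref_reads <- round(fA * dA) + round(fB * dB)
  alt_reads <- (dA + dB) - ref_reads
  minor_ok <- pmin(ref_reads, alt_reads) >= min_minor_depth
  kept <- pool[depth_ok & minor_ok, , drop = FALSE]
  kept$delta <- abs(kept[[paste0("freq_", poolA)]] -
                      kept[[paste0("freq_", poolB)]])
  out <- kept[kept$delta >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_filtered") <- sum(!(depth_ok & minor_ok))
  out
}

#' Bound the candidate region from a set of high-delta sites
#'
#' Sites on the same chromosome are partitioned into clusters wherever the
#' gap between consecutive sites exceeds `max_gap`; the cluster with the
#' most sites wins (ties broken by smaller span, then by order). The region
#' runs from the cluster's first to its last SNP.
#'
#' @param sites data frame with `chrom` and `pos` columns (e.g. the output
#'   of [delta_scan()]), or a numeric position vector (single chromosome).
#' @param max_gap maximum within-cluster gap in bp (default 100 kb).
#' @return A [region()]; attribute `n_sites` is the winning cluster size.
#' @export
bound_candidate_region <- function(sites, max_gap = 1e5) {
  if (is.numeric(sites))
    sites <- data.frame(chrom = rep("chr", length(sites)), pos = sites)
  if (nrow(sites) == 0) stop("no sites to bound", call. = FALSE)
  best <- NULL
  for (ch in unique(sites$chrom)) {
    pos <- sort(sites$pos[sites$chrom == ch])
    cl <- cumsum(c(1L, as.integer(diff(pos) > max_gap)))
    for (k in unique(cl)) {
      p <- pos[cl == k]
      cand <- list(chrom = ch, n = length(p), span = max(p) - min(p),
                   start = min(p), end = max(p))
      if (is.null(best) || cand$n > best$n ||
          (cand$n == best$n && cand$span < best$span))
        best <- cand
    }
  }
  out <- region(best$chrom, best$start, best$end)
  attr(out, "n_sites") <- best$n
  out
}

#' Sites polymorphic within both of two groups (shared polymorphisms)
#'
#' A site is a shared polymorphism when its alternate-allele frequency lies
#' strictly between 0 and 1 within group A and within group B. Because a
#' new arrangement (e.g. an inversion) arises on a single chromosome,
#' depletion of shared polymorphisms inside a region, against free
#' recombination in the flanks, is the variant-level signature used to
#' search for inversion breakpoints.
#'
#' @param cohort a `"cohort"` object.
#' @param groupA,groupB character vectors of `individual_id`s (>= 2 each).
#' @return Vector of bp positions of shared polymorphisms.
#' @export
shared_polymorphism_sites <- function(cohort, groupA, groupB) {
  stopifnot(inherits(cohort, "cohort"))
  if (length(groupA) < 2 || length(groupB) < 2)
    stop("both groups need at least 2 individuals", call. = FALSE)
  idx <- function(ids) {
    i <- match(ids, cohort$pheno$individual_id)
    if (anyNA(i)) stop("unknown individual id(s): ",
                       paste(ids[is.na(i)], collapse = ", "), call. = FALSE)
    i
  }
  segregating <- function(ids) {
    i <- idx(ids)
    f <- colMeans(rbind(cohort$hap1[i, , drop = FALSE],
                        cohort$hap2[i, , drop = FALSE]))
    f > 0 & f < 1
  }
  cohort$positions[segregating(groupA) & segregating(groupB)]
}

#' Rectangular-kernel density track of site positions
#'
#' At each grid point `g` (fixed `step`), density =
#' `#\{positions with |pos - g| <= bandwidth\} / (2 * bandwidth)`, i.e. a
#' rectangular kernel whose `bandwidth` is interpreted as the half-width
#' (set `kernel_width = "full"` for the full-width convention).
#'
#' @param positions bp positions of events (may be empty: all-zero track).
#' @param bandwidth kernel bandwidth in bp (default 1500).
#' @param step grid step in bp (default 100).
#' @param extent a [region()] fixing the grid range.
#' @param kernel_width `"half"` (default) or `"full"`.
#' @return Class `"density_track"` data frame: `pos`, `density` (events per
#'   bp); attributes `bandwidth`, `step`, `chrom`.
#' @export
density_track <- function(positions, bandwidth = 1500, step = 100, extent,
                          kernel_width = c("half", "full")) {
  kernel_width <- match.arg(kernel_width)
  if (bandwidth <= 0) stop("`bandwidth` must be > 0", call. = FALSE)
  if (region_span(extent) == 0)
    stop("`extent` has zero length", call. = FALSE)
  half <- if (kernel_width == "half") bandwidth else bandwidth / 2
  grid <- seq(extent$start, extent$end, by = step)
  pos <- sort(positions)
  eps <- 1e-9 * max(half, 1)
  cnt <- findInterval(grid + half + eps, pos) -
    findInterval(grid - half - eps, pos)
  structure(data.frame(pos = grid, density = cnt / (2 * half)),
            class = c("density_track", "data.frame"),
            bandwidth = half, step = step, chrom = extent$chrom)
}

#' Predict depleted intervals (putative inversion breakpoints)
#'
#' Normalises the track by the median density of its flanks (the outer
#' `flank_frac` of grid points at each end) and reports maximal runs of at
#' least `min_run` bp whose density falls below
#' `depletion_threshold x flank median`. The run edges are the breakpoint
#' estimates.
#'
#' @param track a [density_track()].
#' @param depletion_threshold fraction of the flank median (default 0.25).
#' @param min_run minimum run length in bp (default 10 kb).
#' @param flank_frac fraction of grid points at each end treated as flank.
#' @return Data frame with `start`, `end`, `length` per depleted interval
#'   (possibly zero rows), sorted by position.
#' @export
predict_breakpoints <- function(track, depletion_threshold = 0.25,
                                min_run = 1e4, flank_frac = 0.15) {
  if (nrow(track) == 0) stop("empty density track", call. = FALSE)
  n <- nrow(track)
  k <- max(1L, ceiling(flank_frac * n))
  flank <- c(track$density[seq_len(k)],
             track$density[seq.int(n - k + 1L, n)])
  med <- median(flank)
  if (med == 0)
    stop("flank median density is zero; cannot normalise", call. = FALSE)
  low <- track$density < depletion_threshold * med
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- data.frame(start = numeric(0), end = numeric(0),
                    length = numeric(0))
  for (i in seq_along(r$values)) {
    if (!r$values[i]) next
    s <- track$pos[starts[i]]; e <- track$pos[ends[i]]
    if (e - s >= min_run)
      out <- rbind(out, data.frame(start = s, end = e, length = e - s))
  }
  out[order(out$start), , drop = FALSE]
}
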