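#' Sample configuration for coalescent simulation
#'
#' Defaults mirror the empirical configuration used for the haplotype-age
#' analysis: 10 individuals homozygous for the ancestral (small-bill)
#' haplotype and 5 homozygous for the derived (large-bill) haplotype give 20
#' ancestral and 10 derived haplotypes; the non-recombining analysis
#' interval is 285,969 bp; the scaled mutation rate is 0.001 per bp.
#'
#' @param n_anc number of ancestral-class haplotypes sampled.
#' @param n_der number of derived-class haplotypes sampled.
#' @param L locus length in bp.
#' @param theta scaled mutation rate per bp (`4 Ne mu`).
#' @return An object of class `"sample_config"`.
#' @export
sample_config <- function(n_anc = 20, n_der = 10, L = 285969, theta = 0.001) {
  stopifnot(n_anc >= 0, n_der >= 0, L >= 1, theta > 0)
  if (n_anc + n_der < 2)
    stop("need at least two sampled haplotypes in total", call. = FALSE)
  structure(list(n_anc = as.integer(n_anc), n_der = as.integer(n_der),
                 L = L, theta = theta),
            class = "sample_config")
}

#' Simulate a genealogy under the structured coalescent
#'
#' Runs backward in time on the trajectory's own generation grid. While the
#' derived allele segregates at frequency `x(t)`, each pair of derived
#' lineages coalesces with probability `1 / (2 N_sim x(t))` per generation
#' and each ancestral pair with probability `1 / (2 N_sim (1 - x(t)))`;
#' there is no movement between classes (no recombination across the
#' haplotype boundary). At the allele's origin all remaining derived
#' lineages merge and the resulting lineage joins the ancestral class;
#' older than that, a standard single-class coalescent runs to the root.
#'
#' With `n_der = 0` the trajectory is ignored and a plain Kingman coalescent
#' of diploid size `N_sim` is simulated (the neutral limit used as an
#' oracle in the tests).
#'
#' @param trajectory a `"trajectory"` object ([simulate_trajectory()]).
#' @param config a [sample_config()].
#' @param seed optional integer seed.
#' @return An object of class `"genealogy"`: node times in generations
#'   before present, parent pointers (NA at the root), per-node leaf counts
#'   of each class, leaf class labels, and the simulation scale `N_sim`.
#'   Leaves are nodes `1..n` (ancestral class first); internal nodes follow
#'   in coalescence order. The forced merge at the origin can produce one
#'   multifurcating node.
#' @export
simulate_genealogy <- function(trajectory, config, seed = NULL) {
  stopifnot(inherits(trajectory, "trajectory"), inherits(config, "sample_config"))
  if (config$n_der > 0 && length(trajectory$freqs) < 1)
    stop("derived lineages require a non-empty trajectory", call. = FALSE)
  set_op_seed(seed, "simulate_genealogy")
  res <- .structured_genealogy_cpp(
    if (config$n_der > 0) trajectory$freqs else numeric(0),
    as.integer(trajectory$N_sim), config$n_anc, config$n_der)
  n <- config$n_anc + config$n_der
  parent <- res$parent + 1L
  parent[parent == 0L] <- NA_integer_
  structure(list(
    time = res$time, parent = parent,
    a_below = res$a_below, d_below = res$d_below,
    leaf_class = rep(c("anc", "der"), c(config$n_anc, config$n_der)),
    n_anc = config$n_anc, n_der = config$n_der,
    N_sim = trajectory$N_sim,
    origin_gen = length(trajectory$freqs) - 1L),
    class = "genealogy")
}

#' @export
print.genealogy <- function(x, ...) {
  cat(sprintf(paste0("Structured-coalescent genealogy: %d anc + %d der ",
                     "leaves\n  root at %.0f generations before present ",
                     "(allele origin at %s)\n"),
              x$n_anc, x$n_der, max(x$time),
              if (x$n_der > 0) sprintf("%d", x$origin_gen) else "NA"))
  invisible(x)
}

# leaf index sets below every node; parents always have larger indices than
# their children, so one forward pass suffices
leaves_below <- function(genealogy) {
  n_nodes <- length(genealogy$time)
  n_leaves <- genealogy$n_anc + genealogy$n_der
  sets <- vector("list", n_nodes)
  for (v in seq_len(n_nodes))
    sets[[v]] <- if (v <= n_leaves) v else integer(0)
  for (v in seq_len(n_nodes)) {
    p <- genealogy$parent[v]
    if (!is.na(p)) sets[[p]] <- c(sets[[p]], sets[[v]])
  }
  sets
}

#' Drop infinite-sites mutations onto a genealogy
#'
#' Each branch receives `Poisson(len * mu_sim * L)` mutations with
#' `mu_sim = theta / (4 N_sim)` per bp per generation; each mutation gets a
#' fresh position drawn uniformly on the locus (continuous coordinates, so
#' positions are unique almost surely) and flips the leaves below its branch
#' to the derived state. Every emitted site is polymorphic in the full
#' sample by construction.
#'
#' @param genealogy a `"genealogy"` object.
#' @param config the [sample_config()] supplying `theta` and `L`.
#' @param seed optional integer seed.
#' @return An object of class `"hap_sample"`: binary matrix `mat`
#'   (haplotypes x segregating sites, columns ordered by position),
#'   `positions` in (0, L], `L`, and per-haplotype `class` labels.
#' @export
drop_mutations <- function(genealogy, config, seed = NULL) {
  stopifnot(inherits(genealogy, "genealogy"), inherits(config, "sample_config"))
  set_op_seed(seed, "drop_mutations")
  n_nodes <- length(genealogy$time)
  n_leaves <- genealogy$n_anc + genealogy$n_der
  mu_locus <- config$theta / (4 * genealogy$N_sim) * config$L
  blen <- rep(0, n_nodes)
  has_parent <- !is.na(genealogy$parent)
  blen[has_parent] <- genealogy$time[genealogy$parent[has_parent]] -
    genealogy$time[has_parent]
  n_mut <- rpois(n_nodes, blen * mu_locus)
  total <- sum(n_mut)
  mat <- matrix(0L, nrow = n_leaves, ncol = total)
  if (total > 0) {
    below <- leaves_below(genealogy)
    col <- 0L
    for (v in seq_len(n_nodes)) {
      if (n_mut[v] == 0L) next
      for (k in seq_len(n_mut[v])) {
        col <- col + 1L
        mat[below[[v]], col] <- 1L
      }
    }
    pos <- runif(total, 0, config$L)
    ord <- order(pos)
    mat <- mat[, ord, drop = FALSE]
    pos <- pos[ord]
  } else {
    pos <- numeric(0)
  }
  rownames(mat) <- paste0(genealogy$leaf_class, "_",
                          seq_len(n_leaves))
  structure(list(mat = mat, positions = pos, L = config$L,
                 class_labels = genealogy$leaf_class),
            class = "hap_sample")
}

#' @export
print.hap_sample <- function(x, ...) {
  cat(sprintf("Haplotype sample: %d haplotypes (%d anc, %d der), %d segregating sites on %s bp\n",
              nrow(x$mat), sum(x$class_labels == "anc"),
              sum(x$class_labels == "der"), ncol(x$mat),
              format(x$L, big.mark = ",")))
  invisible(x)
}

#' Simulate a haplotype sample end to end
#'
#' Composition of [simulate_trajectory()], [simulate_genealogy()] and
#' [drop_mutations()] under a single seed. The trajectory used is attached
#' as an attribute.
#'
#' @inheritParams simulate_trajectory
#' @param config a [sample_config()].
#' @return A `"hap_sample"` with attribute `"trajectory"`.
#' @export
simulate_sample <- function(params, config, N_sim = 5000, max_rejects = 1000,
                            seed = NULL) {
  set_op_seed(seed, "simulate_sample")
  tr <- simulate_trajectory(params, N_sim = N_sim, max_rejects = max_rejects)
  g <- simulate_genealogy(tr, config)
  hs <- drop_mutations(g, config)
  attr(hs, "trajectory") <- tr
  hs
}

#' Convert a genealogy to an ape "phylo" tree
#'
#' Branch lengths are in generations. Useful for newick export and plotting;
#' the forced merge at the allele origin may appear as a multifurcation.
#'
#' @param genealogy a `"genealogy"` object.
#' @return An [ape::as.phylo] compatible `"phylo"` object.
#' @export
genealogy_to_phylo <- function(genealogy) {
  n_nodes <- length(genealogy$time)
  n_leaves <- genealogy$n_anc + genealogy$n_der
  has_parent <- which(!is.na(genealogy$parent))
  # ape numbering: tips 1..n, root n+1, internals onward. Our internals are
  # already in increasing-time creation order; the root is the last node.
  internal <- seq.int(n_leaves + 1L, n_nodes)
  ape_id <- integer(n_nodes)
  ape_id[seq_len(n_leaves)] <- seq_len(n_leaves)
  # root gets n_leaves+1, remaining internals keep creation order after it
  root <- n_nodes
  others <- setdiff(internal, root)
  ape_id[root] <- n_leaves + 1L
  ape_id[others] <- n_leaves + 1L + seq_along(others)
  edge <- cbind(ape_id[genealogy$parent[has_parent]], ape_id[has_parent])
  edge_length <- genealogy$time[genealogy$parent[has_parent]] -
    genealogy$time[has_parent]
  phy <- structure(list(
    edge = edge, edge.length = edge_length,
    tip.label = paste0(genealogy$leaf_class, "_", seq_len(n_leaves)),
    Nnode = n_nodes - n_leaves), class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

#' Export a haplotype sample in ms-style text
#'
#' Writes `//`, `segsites:`, `positions:` (normalised to (0, 1)) and one
#' 0/1 row per haplotype, preceded by a comment line with the class labels.
#'
#' @param sample a `"hap_sample"`.
#' @param file output path.
#' @export
write_ms <- function(sample, file) {
  stopifnot(inherits(sample, "hap_sample"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste("# classes:", paste(sample$class_labels, collapse = " ")),
             con)
  writeLines("//", con)
  writeLines(sprintf("segsites: %d", ncol(sample$mat)), con)
  writeLines(paste("positions:",
                   paste(sprintf("%.8f", sample$positions / sample$L),
                         collapse = " ")), con)
  apply(sample$mat, 1L, function(r) writeLines(paste(r, collapse = ""), con))
  invisible(file)
}
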