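#' Sites carrying alleles private to a focal pool
#'
#' A site qualifies when the focal pool is fixed (reference-allele
#' frequency `<= tol` or `>= 1 - tol`) for an allele that is absent
#' (frequency within `tol` of zero) from every other pool, i.e. a fixed
#' difference between the focal morph and the rest.
#'
#' @param pool a `"pool_af"` table.
#' @param focal_pool focal pool name (default `"mega"`).
#' @param other_pools the remaining pool names.
#' @param fixation_tol tolerance around 0/1 (default 0, strict fixation).
#' @return The qualifying rows with a `private_allele` column ("ref" or
#'   "alt").
#' @export
private_fixed_sites <- function(pool, focal_pool = "mega",
                                other_pools = c("small", "large"),
                                fixation_tol = 0) {
  for (p in c(focal_pool, other_pools))
    if (!paste0("freq_", p) %in% names(pool))
      stop("pool `", p, "` not present in the table", call. = FALSE)
  tol <- fixation_tol
  f_foc <- pool[[paste0("freq_", focal_pool)]]
  others <- vapply(other_pools, function(p) pool[[paste0("freq_", p)]],
                   numeric(nrow(pool)))
  others <- matrix(others, nrow = nrow(pool))
  # focal fixed for alt (ref freq ~0), alt absent elsewhere (ref freq ~1)
  alt_private <- f_foc <= tol & apply(others >= 1 - tol, 1L, all)
  # focal fixed for ref, ref absent elsewhere
  ref_private <- f_foc >= 1 - tol & apply(others <= tol, 1L, all)
  out <- pool[alt_private | ref_private, , drop = FALSE]
  out$private_allele <- ifelse(alt_private[alt_private | ref_private],
                               "alt", "ref")
  rownames(out) <- NULL
  out
}

#' Count sites per annotated gene
#'
#' Half-open interval membership (`start <= pos < end`, BED convention):
#' a site at a gene's start coordinate is counted, one at its end
#' coordinate is not. Genes are assumed non-overlapping (the generator
#' guarantees this). Sites outside every gene are tallied as intergenic.
#'
#' @param sites data frame with a `pos` column (e.g.
#'   [private_fixed_sites()] output) or a numeric position vector.
#' @param annotation a `"gene_annotation"` data frame.
#' @return The annotation with an `observed` count column; attribute
#'   `n_intergenic` counts unassigned sites.
#' @export
assign_to_genes <- function(sites, annotation) {
  pos <- if (is.numeric(sites)) sites else sites$pos
  stopifnot(is.data.frame(annotation),
            all(c("gene_id", "start", "end") %in% names(annotation)))
  ord <- order(annotation$start)
  ann <- annotation[ord, ]
  counts <- integer(nrow(ann))
  gene_of <- rep(NA_integer_, length(pos))
  if (length(pos) > 0 && nrow(ann) > 0) {
    idx <- findInterval(pos, ann$start)          # pos >= start[idx]
    inside <- idx > 0 & pos < ann$end[pmax(idx, 1L)]
    gene_of[inside] <- idx[inside]
    tab <- table(gene_of[inside])
    counts[as.integer(names(tab))] <- as.integer(tab)
  }
  out <- annotation
  out$observed <- counts[order(ord)]
  attr(out, "n_intergenic") <- sum(is.na(gene_of))
  out
}

#' Gene-length-weighted bootstrap test for private-allele enrichment
#'
#' Null model: each of the `M` in-gene private alleles is independently
#' reassigned to a gene with probability proportional to the gene's total
#' length, for `B` replicates (a multinomial redistribution). Per gene, the
#' p-value is the proportion of replicates whose null count strictly
#' exceeds the observed count; `tail = "greater_equal"` gives the
#' conservative `(1 + #\{null >= obs\}) / (1 + B)` variant. Marginally each
#' gene's null count is `Binomial(M, length_g / sum(lengths))`.
#'
#' @param per_gene_counts observed in-gene counts, or the data frame from
#'   [assign_to_genes()] (uses its `observed` and `length` columns).
#' @param gene_lengths gene lengths (ignored when a data frame is given).
#' @param B bootstrap replicates (default 10,000).
#' @param tail `"greater_strict"` (default, as the p-value is defined) or
#'   `"greater_equal"`.
#' @param seed optional integer seed.
#' @return Class `"enrichment_result"` data frame: gene_id, length,
#'   observed, null_mean, p; attribute `B`.
#' @export
bootstrap_enrichment <- function(per_gene_counts, gene_lengths = NULL,
                                 B = 10000,
                                 tail = c("greater_strict", "greater_equal"),
                                 seed = NULL) {
  tail <- match.arg(tail)
  if (is.data.frame(per_gene_counts)) {
    gene_id <- per_gene_counts$gene_id %||%
      paste0("gene", seq_len(nrow(per_gene_counts)))
    gene_lengths <- gene_lengths %||% per_gene_counts$length
    obs <- per_gene_counts$observed
  } else {
    obs <- per_gene_counts
    gene_id <- names(obs) %||% paste0("gene", seq_along(obs))
  }
  stopifnot(length(obs) == length(gene_lengths), B >= 1)
  if (all(gene_lengths == 0))
    stop("all gene lengths are zero; cannot weight the null", call. = FALSE)
  M <- sum(obs)
  if (M < 1) stop("no in-gene alleles to redistribute", call. = FALSE)
  set_op_seed(seed, "bootstrap_enrichment")
  null <- rmultinom(B, M, prob = gene_lengths / sum(gene_lengths))
  p <- if (tail == "greater_strict") rowMeans(null > obs)
    else (1 + rowSums(null >= obs)) / (1 + B)
  structure(data.frame(gene_id = gene_id, length = gene_lengths,
                       observed = obs, null_mean = rowMeans(null), p = p,
                       row.names = NULL),
            class = c("enrichment_result", "data.frame"), B = B)
}
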