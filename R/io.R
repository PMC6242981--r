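# Plain-text interchange: VCF v4.2 for phased cohort genotypes (read back
# through vcfR), TSV for phenotypes / pooled frequencies / trajectories,
# BED3+1 for gene annotations. Frequencies are printed with 17 significant
# digits so write -> read round-trips are exact.

fmt_num <- function(x) {
  out <- sprintf("%.17g", x)
  out[x == round(x)] <- sprintf("%d", as.integer(x[x == round(x)]))
  out
}

#' Write phased cohort genotypes as VCF v4.2
#'
#' One column per individual with phased `GT` (`h1|h2`). REF/ALT are
#' placeholder alleles (A/T): the binary matrix, not the nucleotide, is the
#' object of interest.
#'
#' @param cohort a `"cohort"` object.
#' @param file output path.
#' @rdname cohort_io
#' @export
write_cohort_vcf <- function(cohort, file) {
  stopifnot(inherits(cohort, "cohort"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               sprintf("##contig=<ID=%s>", cohort$chrom),
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"),
             con)
  ids <- cohort$pheno$individual_id
  writeLines(paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", ids), collapse = "\t"), con)
  gt <- matrix(paste0(t(cohort$hap1), "|", t(cohort$hap2)),
               nrow = length(cohort$positions))   # sites x individuals
  body <- cbind(cohort$chrom, cohort$positions,
                paste0("snp", seq_along(cohort$positions)),
                "A", "T", ".", "PASS", ".", "GT", gt)
  writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  invisible(file)
}

#' @param pheno_file optional phenotype TSV written by
#'   [write_phenotype_tsv()]; when given, the full `"cohort"` object is
#'   reassembled, otherwise only the genotype part is returned.
#' @rdname cohort_io
#' @export
read_cohort_vcf <- function(file, pheno_file = NULL) {
  v <- vcfR::read.vcfR(file, verbose = FALSE)
  gt <- vcfR::extract.gt(v)                       # sites x individuals
  hap1 <- t(matrix(as.integer(substr(gt, 1L, 1L)), nrow = nrow(gt)))
  hap2 <- t(matrix(as.integer(substr(gt, 3L, 3L)), nrow = nrow(gt)))
  ids <- colnames(gt)
  rownames(hap1) <- rownames(hap2) <- ids
  out <- list(hap1 = hap1, hap2 = hap2,
              positions = as.integer(vcfR::getPOS(v)),
              chrom = vcfR::getCHROM(v)[1])
  if (!is.null(pheno_file)) {
    pheno <- read_phenotype_tsv(pheno_file)
    stopifnot(identical(pheno$individual_id, ids))
    out <- structure(c(list(pheno = pheno), out), class = "cohort")
  }
  out
}

#' Write / read the per-individual phenotype table
#'
#' Tab-separated with columns individual_id, morph, lmw (mm), hap1_id,
#' hap2_id, derived_dosage.
#'
#' @param cohort a `"cohort"` object (or its `pheno` data frame).
#' @param file path.
#' @rdname pheno_io
#' @export
write_phenotype_tsv <- function(cohort, file) {
  pheno <- if (inherits(cohort, "cohort")) cohort$pheno else cohort
  pheno$lmw <- sprintf("%.17g", pheno$lmw)
  write.table(pheno, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname pheno_io
#' @export
read_phenotype_tsv <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t",
                   colClasses = c(individual_id = "character",
                                  morph = "character", lmw = "numeric",
                                  hap1_id = "character",
                                  hap2_id = "character",
                                  derived_dosage = "integer"))
  df
}

#' Write / read a pooled allele-frequency table as TSV
#'
#' @param pool a `"pool_af"` data frame.
#' @param file path.
#' @rdname pool_io
#' @export
write_pool_af <- function(pool, file) {
  out <- as.data.frame(pool)
  for (cl in grep("^freq_", names(out), value = TRUE))
    out[[cl]] <- sprintf("%.17g", out[[cl]])
  write.table(out, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname pool_io
#' @export
read_pool_af <- function(file) {
  df <- read.table(file, header = TRUE, sep = "\t",
                   colClasses = c(chrom = "character", ref = "character",
                                  alt = "character"))
  structure(df, class = c("pool_af", "data.frame"))
}

#' Write / read gene annotations as BED3+1
#'
#' BED convention: 0-based half-open intervals; the fourth column is the
#' gene id. Length is recomputed as `end - start` on read.
#'
#' @param annotation a `"gene_annotation"` data frame.
#' @param file path.
#' @rdname bed_io
#' @export
write_gene_bed <- function(annotation, file) {
  write.table(annotation[, c("chrom", "start", "end", "gene_id")], file,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(file)
}

#' @rdname bed_io
#' @export
read_gene_bed <- function(file) {
  df <- read.table(file, header = FALSE, sep = "\t",
                   col.names = c("chrom", "start", "end", "gene_id"),
                   colClasses = c("character", "numeric", "numeric",
                                  "character"))
  structure(data.frame(gene_id = df$gene_id, chrom = df$chrom,
                       start = df$start, end = df$end,
                       length = df$end - df$start),
            class = c("gene_annotation", "data.frame"))
}

#' Write regions / density tracks for genome browsers
#'
#' Regions go to BED (0-based half-open, so `start - 1`); density tracks to
#' bedGraph with one fixed-step interval per grid point.
#'
#' @param regions data frame with chrom, start, end (1-based bp).
#' @param file path.
#' @rdname track_io
#' @export
write_region_bed <- function(regions, file) {
  write.table(data.frame(regions$chrom, regions$start - 1, regions$end),
              file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}

#' @param track a `"density_track"` from [density_track()].
#' @rdname track_io
#' @export
write_density_bedgraph <- function(track, file) {
  step <- attr(track, "step")
  chrom <- attr(track, "chrom") %||% "chr"
  write.table(data.frame(chrom, track$pos - 1, track$pos - 1 + step,
                         track$density),
              file, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(file)
}
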