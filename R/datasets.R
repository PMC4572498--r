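#' Construct a methylation dataset
#'
#' Bundles a sample-by-probe matrix of methylation beta values (fractions
#' of methylated signal, in \[0, 1\]) with per-probe genomic annotation.
#' All pipeline readers and the simulator return this container.
#'
#' @param beta numeric matrix, samples in rows, probes in columns, values
#'   in \[0, 1\]. Row names are sample ids, column names probe ids.
#' @param probes data.frame with one row per probe: `probe_id`, `chrom`,
#'   `pos` (1-based bp), and optionally logical `snp_at_target` (a known
#'   SNP at the target CpG) and `autosomal`. Missing flags default to
#'   `FALSE` / `TRUE` respectively.
#' @return an object of class `methylation_dataset`: a list with elements
#'   `beta`, `probes`, `sample_ids`.
#' @export
methylation_dataset <- function(beta, probes) {
  stopifnot(is.matrix(beta), is.data.frame(probes))
  if (is.null(colnames(beta)) || is.null(rownames(beta)))
    stop("beta matrix must carry sample row names and probe column names")
  if (!all(c("probe_id", "chrom", "pos") %in% names(probes)))
    stop("probe annotation needs columns probe_id, chrom, pos")
  probes$probe_id <- as.character(probes$probe_id)
  probes$chrom <- as.character(probes$chrom)
  if (anyDuplicated(probes$probe_id))
    stop("duplicate probe ids in annotation: ",
         paste(head(probes$probe_id[duplicated(probes$probe_id)], 3), collapse = ", "))
  if (is.null(probes$snp_at_target)) probes$snp_at_target <- FALSE
  if (is.null(probes$autosomal)) probes$autosomal <- TRUE
  missing_ann <- setdiff(colnames(beta), probes$probe_id)
  if (length(missing_ann))
    stop("annotation missing for probe(s): ",
         paste(head(missing_ann, 5), collapse = ", "))
  probes <- probes[match(colnames(beta), probes$probe_id), , drop = FALSE]
  rownames(probes) <- NULL
  bad <- which(beta < 0 | beta > 1 | !is.finite(beta), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("beta value outside [0,1] at probe %s, sample %s (value %g)",
                 colnames(beta)[bad[1, 2]], rownames(beta)[bad[1, 1]],
                 beta[bad[1, 1], bad[1, 2]]))
  structure(list(beta = beta, probes = probes, sample_ids = rownames(beta)),
            class = "methylation_dataset")
}

#' @export
print.methylation_dataset <- function(x, ...) {
  cat(sprintf("methylation_dataset: %d samples x %d probes\n",
              nrow(x$beta), ncol(x$beta)))
  cat(sprintf("  chromosomes: %s\n",
              paste(unique(x$probes$chrom), collapse = ", ")))
  invisible(x)
}

#' Construct a genotype dataset
#'
#' @param dosage numeric matrix of effect-allele counts, samples in rows,
#'   SNPs in columns; values in \[0, 2\] (0/1/2 for hard calls, fractional
#'   allowed for imputed dosages). `NA` marks missing calls.
#' @param snps data.frame with one row per SNP: `snp_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`. The dosage counts the effect allele.
#' @return an object of class `genotype_dataset` with elements `dosage`,
#'   `snps`, `sample_ids`.
#' @export
genotype_dataset <- function(dosage, snps) {
  stopifnot(is.matrix(dosage), is.data.frame(snps))
  if (is.null(colnames(dosage)) || is.null(rownames(dosage)))
    stop("dosage matrix must carry sample row names and SNP column names")
  need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele")
  if (!all(need %in% names(snps)))
    stop("SNP annotation needs columns: ", paste(need, collapse = ", "))
  snps$snp_id <- as.character(snps$snp_id)
  if (anyDuplicated(snps$snp_id)) stop("duplicate SNP ids in annotation")
  if (any(snps$effect_allele == snps$other_allele))
    stop("effect allele equals other allele for SNP(s): ",
         paste(head(snps$snp_id[snps$effect_allele == snps$other_allele], 3),
               collapse = ", "))
  missing_ann <- setdiff(colnames(dosage), snps$snp_id)
  if (length(missing_ann))
    stop("annotation missing for SNP(s): ",
         paste(head(missing_ann, 5), collapse = ", "))
  snps <- snps[match(colnames(dosage), snps$snp_id), , drop = FALSE]
  rownames(snps) <- NULL
  rng <- range(dosage, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2)
    stop("dosages must lie in [0, 2]; observed range ",
         paste(signif(rng, 4), collapse = " .. "))
  structure(list(dosage = dosage, snps = snps, sample_ids = rownames(dosage)),
            class = "genotype_dataset")
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat(sprintf("genotype_dataset: %d samples x %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}
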