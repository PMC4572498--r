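# Readers and writers for every file the pipeline touches. All tabular
# formats are plain TSV written with full numeric precision so every
# write/read pair round-trips; genotypes can additionally travel as a
# minimal VCF (GT genotypes). Genomic coordinates are 1-based and fully
# closed throughout (Illumina/VCF convention) -- including the BED-like
# probe annotation file, which stores a single 1-based `pos` column.

.fread_df <- function(path, ...) {
  if (!file.exists(path)) stop("file not found: ", path)
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE, ...))
}

.fwrite_df <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
}

#' Read a methylation beta matrix with probe annotation
#'
#' The matrix file is TSV with probes in rows: first column `probe_id`,
#' remaining columns one per sample (header = sample ids). The companion
#' annotation file is TSV with columns `probe_id`, `chrom`, `pos`
#' (1-based bp) and optional logical `snp_at_target`, `autosomal`.
#'
#' @param path path to the beta-matrix TSV.
#' @param annotation_path path to the probe annotation TSV.
#' @return a [methylation_dataset()].
#' @export
read_methylation <- function(path, annotation_path) {
  d <- .fread_df(path)
  if (names(d)[1] != "probe_id")
    stop("first column of the methylation matrix must be 'probe_id'")
  ann <- .fread_df(annotation_path)
  beta <- t(as.matrix(d[, -1, drop = FALSE]))
  colnames(beta) <- d$probe_id
  if (!is.numeric(beta)) stop("non-numeric beta values in ", path)
  methylation_dataset(beta, ann)
}

#' Write a methylation dataset (matrix + annotation TSV)
#'
#' @param meth a [methylation_dataset()].
#' @param path output path for the probe-by-sample beta matrix TSV.
#' @param annotation_path output path for the probe annotation TSV.
#' @return invisibly, `meth`.
#' @export
write_methylation <- function(meth, path, annotation_path) {
  stopifnot(inherits(meth, "methylation_dataset"))
  d <- data.frame(probe_id = colnames(meth$beta), t(meth$beta),
                  check.names = FALSE, stringsAsFactors = FALSE)
  .fwrite_df(d, path)
  .fwrite_df(meth$probes, annotation_path)
  invisible(meth)
}

#' Read genotypes from a minimal VCF or a dosage TSV
#'
#' For `format = "vcf"` the GT field is parsed; the ALT allele is taken
#' as the effect allele and the dosage counts ALT copies (0/1/2, `NA`
#' for missing calls). Multi-allelic records are skipped with a warning.
#' For `format = "dosage"` the file is a TSV with columns `snp_id`,
#' `chrom`, `pos`, `effect_allele`, `other_allele` followed by one
#' column per sample.
#'
#' @param path input file.
#' @param format `"auto"` (by extension), `"vcf"` or `"dosage"`.
#' @return a [genotype_dataset()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "dosage"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
    multi <- grepl(",", fx$ALT)
    if (any(multi))
      warning(sprintf("skipping %d multi-allelic record(s)", sum(multi)))
    gt <- vcfR::extract.gt(v, element = "GT")
    gt <- gt[!multi, , drop = FALSE]
    fx <- fx[!multi, , drop = FALSE]
    if (nrow(fx) == 0) stop("no biallelic records in ", path)
    alt_count <- nchar(gt) - nchar(gsub("1", "", gt))
    alt_count[gt %in% c(".", "./.", ".|.") | is.na(gt)] <- NA
    dosage <- t(matrix(as.numeric(alt_count), nrow = nrow(gt),
                       dimnames = dimnames(gt)))
    ids <- ifelse(is.na(fx$ID) | fx$ID == ".",
                  paste0(fx$CHROM, ":", fx$POS), fx$ID)
    colnames(dosage) <- ids
    snps <- data.frame(snp_id = ids, chrom = fx$CHROM,
                       pos = as.integer(fx$POS),
                       effect_allele = fx$ALT, other_allele = fx$REF,
                       stringsAsFactors = FALSE)
    genotype_dataset(dosage, snps)
  } else {
    d <- .fread_df(path)
    need <- c("snp_id", "chrom", "pos", "effect_allele", "other_allele")
    if (!all(need %in% names(d)))
      stop("dosage TSV needs leading columns: ", paste(need, collapse = ", "))
    sample_cols <- setdiff(names(d), need)
    dosage <- t(as.matrix(d[, sample_cols, drop = FALSE]))
    colnames(dosage) <- d$snp_id
    genotype_dataset(dosage, d[, need])
  }
}

#' Write genotypes as a dosage TSV
#'
#' @param geno a [genotype_dataset()].
#' @param path output path.
#' @return invisibly, `geno`.
#' @export
write_dosage <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_dataset"))
  d <- cbind(geno$snps, as.data.frame(t(geno$dosage), check.names = FALSE))
  .fwrite_df(d, path)
  invisible(geno)
}

#' Write genotypes as a minimal VCF (GT field)
#'
#' Dosages must be hard calls (0/1/2 or `NA`); the effect allele is
#' written as ALT. For fractional imputed dosages use [write_dosage()].
#'
#' @param geno a [genotype_dataset()].
#' @param path output path (`.vcf`).
#' @return invisibly, `geno`.
#' @export
write_vcf <- function(geno, path) {
  stopifnot(inherits(geno, "genotype_dataset"))
  d <- geno$dosage
  if (any(d[!is.na(d)] != round(d[!is.na(d)])))
    stop("VCF output requires integer dosages (0/1/2); use write_dosage() for fractional dosages")
  gt_code <- c("0/0", "0/1", "1/1")
  lines <- c("##fileformat=VCFv4.2",
             "##source=methscore",
             '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", geno$sample_ids), collapse = "\t"))
  body <- vapply(seq_len(ncol(d)), function(j) {
    g <- d[, j]
    gt <- ifelse(is.na(g), "./.", gt_code[g + 1L])
    paste(c(geno$snps$chrom[j], geno$snps$pos[j], geno$snps$snp_id[j],
            geno$snps$other_allele[j], geno$snps$effect_allele[j],
            ".", "PASS", ".", "GT", gt), collapse = "\t")
  }, "")
  writeLines(c(lines, body), path)
  invisible(geno)
}

#' Read a feature weights file
#'
#' TSV with columns `feature_id`, `feature_kind` (`"cpg"` or `"snp"`),
#' `weight`, optional `effect_allele` (required and non-missing for every
#' `snp` row) and optional `source`.
#'
#' @param path input TSV.
#' @return data.frame of class `weights_file`.
#' @export
read_weights <- function(path) {
  d <- .fread_df(path)
  if (!all(c("feature_id", "feature_kind", "weight") %in% names(d)))
    stop("weights file needs columns feature_id, feature_kind, weight")
  if (anyDuplicated(d$feature_id))
    stop("duplicate feature ids in weights file: ",
         paste(head(d$feature_id[duplicated(d$feature_id)], 3), collapse = ", "))
  if (!all(d$feature_kind %in% c("cpg", "snp")))
    stop("feature_kind must be 'cpg' or 'snp'")
  if (any(!is.finite(d$weight))) stop("weights must be finite")
  snp_rows <- d$feature_kind == "snp"
  if (any(snp_rows) &&
      (is.null(d$effect_allele) || anyNA(d$effect_allele[snp_rows]) ||
       any(d$effect_allele[snp_rows] == "")))
    stop("snp rows in a weights file require an effect_allele")
  class(d) <- c("weights_file", "data.frame")
  d
}

#' Write a feature weights file
#'
#' @param weights data.frame with at least `feature_id`, `feature_kind`,
#'   `weight` (a `score_weights` from [prune_probes()] works directly).
#' @param path output TSV.
#' @return invisibly, `weights`.
#' @export
write_weights <- function(weights, path) {
  stopifnot(is.data.frame(weights),
            all(c("feature_id", "feature_kind", "weight") %in% names(weights)))
  .fwrite_df(as.data.frame(weights), path)
  invisible(weights)
}

#' Split a mixed weights file by feature kind
#'
#' @param weights a [read_weights()] result.
#' @return list with elements `cpg` and `snp` (either may have 0 rows).
#' @export
split_weights <- function(weights) {
  stopifnot(is.data.frame(weights), !is.null(weights$feature_kind))
  list(cpg = weights[weights$feature_kind == "cpg", , drop = FALSE],
       snp = weights[weights$feature_kind == "snp", , drop = FALSE])
}

#' Read / write MWAS summary statistics
#'
#' TSV with fixed columns `probe_id`, `beta`, `se`, `t`, `p`, `n`.
#' Write/read round-trips are stable to better than 12 significant
#' digits.
#'
#' @param path input/output TSV.
#' @return `read_mwas()`: an `mwas_result` data.frame.
#' @export
read_mwas <- function(path) {
  d <- .fread_df(path)
  need <- c("probe_id", "beta", "se", "p", "n")
  if (!all(need %in% names(d)))
    stop("MWAS file needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(d$probe_id)) stop("duplicate probe ids in MWAS file")
  class(d) <- c("mwas_result", "data.frame")
  d
}

#' @param results an `mwas_result` (or compatible data.frame).
#' @rdname read_mwas
#' @return `write_mwas()`: invisibly, `results`.
#' @export
write_mwas <- function(results, path) {
  stopifnot(is.data.frame(results),
            all(c("probe_id", "beta", "se", "p", "n") %in% names(results)))
  .fwrite_df(as.data.frame(results), path)
  invisible(results)
}

#' Read / write a phenotype + covariate table
#'
#' TSV with one row per sample; must contain a `sample_id` column.
#'
#' @param path input/output TSV.
#' @return `read_phenotypes()`: data.frame.
#' @export
read_phenotypes <- function(path) {
  d <- .fread_df(path)
  if (!"sample_id" %in% names(d)) stop("phenotype table needs a sample_id column")
  if (anyDuplicated(d$sample_id)) stop("duplicate sample ids in phenotype table")
  d$sample_id <- as.character(d$sample_id)
  d
}

#' @param phenotypes data.frame with a `sample_id` column.
#' @rdname read_phenotypes
#' @return `write_phenotypes()`: invisibly, `phenotypes`.
#' @export
write_phenotypes <- function(phenotypes, path) {
  stopifnot(is.data.frame(phenotypes), "sample_id" %in% names(phenotypes))
  .fwrite_df(phenotypes, path)
  invisible(phenotypes)
}

#' Read / write simulation ground truth as JSON
#'
#' @param truth a `sim_truth` object from [simulate_cohort()].
#' @param path input/output JSON path.
#' @return `read_truth()`: a `sim_truth` list; `write_truth()`:
#'   invisibly, `truth`.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(truth)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "sim_truth")
}

#' Write a variance-partition report as JSON
#'
#' @param partition a [fit_partition()] result.
#' @param path output JSON path.
#' @return invisibly, `partition`.
#' @export
write_partition <- function(partition, path) {
  stopifnot(inherits(partition, "variance_partition"))
  jsonlite::write_json(unclass(partition), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(partition)
}
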