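# Profile scores: per-individual weighted sums over selected features.
# Methylation scores sum residualized/inverse-normal probe values with
# MWAS effect sizes as weights (the scale on which the weights were
# estimated); genetic scores sum effect-allele dosages with external GWAS
# effect sizes, after allele harmonization.

.new_profile_score <- function(sample_ids, score, kind, n_used, n_dropped,
                               source) {
  out <- data.frame(sample_id = sample_ids, score = as.numeric(score),
                    stringsAsFactors = FALSE)
  attr(out, "feature_kind") <- kind
  attr(out, "n_features_used") <- as.integer(n_used)
  attr(out, "n_features_dropped") <- as.integer(n_dropped)
  attr(out, "source") <- source
  class(out) <- c("profile_score", "data.frame")
  out
}

#' @export
print.profile_score <- function(x, ...) {
  cat(sprintf("profile_score (%s): n = %d, %d feature(s) used, %d dropped\n",
              attr(x, "feature_kind"), nrow(x),
              attr(x, "n_features_used"), attr(x, "n_features_dropped")))
  print(unclass(summary(x$score)))
  invisible(x)
}

#' Methylation-profile score
#'
#' Computes, per sample, the weighted sum of residualized/inverse-normal
#' methylation values over the probes in `weights`. Weighted probes
#' absent from the methylation matrix are dropped and counted.
#'
#' @param methylation `resid_methylation` (or a sample-by-probe matrix
#'   with probe column names). By design the score is computed on the
#'   analysis scale on which the weights were estimated; to score on raw
#'   beta values instead, pass that matrix explicitly.
#' @param weights a `score_weights` (from [prune_probes()]) or any
#'   data.frame with `feature_id` and `weight` columns.
#' @return a `profile_score` data.frame (`sample_id`, `score`) with
#'   attributes `n_features_used`, `n_features_dropped`.
#' @export
methylation_score <- function(methylation, weights) {
  values <- if (inherits(methylation, "resid_methylation")) methylation$values
            else as.matrix(methylation)
  stopifnot(is.data.frame(weights),
            all(c("feature_id", "weight") %in% names(weights)))
  if (anyDuplicated(weights$feature_id)) stop("duplicate feature ids in weights")
  present <- weights$feature_id %in% colnames(values)
  n_dropped <- sum(!present)
  if (n_dropped > 0)
    message(sprintf("%d weighted probe(s) absent from methylation data; dropped",
                    n_dropped))
  w <- weights[present, , drop = FALSE]
  if (nrow(w) == 0) stop("no usable probes: all weighted probes are missing")
  if (any(!is.finite(w$weight))) stop("weights must be finite")
  s <- as.vector(values[, w$feature_id, drop = FALSE] %*% w$weight)
  .new_profile_score(rownames(values) %||% seq_len(nrow(values)), s, "cpg",
                     nrow(w), n_dropped,
                     unique(as.character(w$source %||% "weights")))
}

#' Genetic-profile (polygenic) score
#'
#' Computes, per sample, the weighted sum of effect-allele counts over
#' the SNPs in `weights`. Allele harmonization: if a weight's effect
#' allele matches the dataset's effect allele the dosage is used as-is;
#' if it matches the dataset's *other* allele the dosage is flipped to
#' `2 - d`; otherwise the SNP is dropped and counted. Missing dosages are
#' mean-imputed per SNP before scoring.
#'
#' @param genotypes a [genotype_dataset()].
#' @param weights data.frame with `feature_id`, `weight`, `effect_allele`
#'   (e.g. from [read_weights()]).
#' @return a `profile_score` data.frame (`sample_id`, `score`).
#' @export
genetic_score <- function(genotypes, weights) {
  stopifnot(inherits(genotypes, "genotype_dataset"), is.data.frame(weights),
            all(c("feature_id", "weight") %in% names(weights)))
  if (is.null(weights$effect_allele) || anyNA(weights$effect_allele))
    stop("SNP weights require an effect_allele for every row")
  if (anyDuplicated(weights$feature_id)) stop("duplicate feature ids in weights")
  if (any(!is.finite(weights$weight))) stop("weights must be finite")

  ix <- match(weights$feature_id, genotypes$snps$snp_id)
  status <- ifelse(is.na(ix), "missing",
            ifelse(weights$effect_allele ==
                     genotypes$snps$effect_allele[ix], "match",
            ifelse(weights$effect_allele ==
                     genotypes$snps$other_allele[ix], "flip", "mismatch")))
  n_dropped <- sum(status %in% c("missing", "mismatch"))
  if (n_dropped > 0)
    message(sprintf("%d SNP(s) dropped (%d absent, %d allele-mismatched)",
                    n_dropped, sum(status == "missing"),
                    sum(status == "mismatch")))
  keep <- status %in% c("match", "flip")
  if (!any(keep)) stop("no matchable SNPs between weights and genotypes")

  d <- genotypes$dosage[, ix[keep], drop = FALSE]
  if (anyNA(d)) {
    mu <- colMeans(d, na.rm = TRUE)
    for (j in which(colSums(is.na(d)) > 0)) d[is.na(d[, j]), j] <- mu[j]
  }
  flip <- status[keep] == "flip"
  if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  s <- as.vector(d %*% weights$weight[keep])
  .new_profile_score(genotypes$sample_ids, s, "snp", sum(keep), n_dropped,
                     unique(as.character(weights$source %||% "weights")))
}
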