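# Beta values -> analysis-ready probes: logit (M-value) transform,
# residualization on technical + biological covariates, rank-based
# inverse-normal transform. Phenotypes -> sex/age-adjusted Z scores.
# The pipeline order is fixed: logit -> residualize -> inverse-normal.

#' Logit (M-value) transform of methylation beta values
#'
#' Computes `log(beta / (1 - beta))` elementwise. Values at exactly 0 or 1
#' are clamped to `eps` / `1 - eps` first (they would otherwise map to
#' +/-Inf); the number of clamped cells is reported as a warning.
#'
#' @param beta numeric matrix or vector of beta values in \[0, 1\].
#' @param eps boundary clamp, default `1e-6`.
#' @return matrix/vector of M-values, same shape as input.
#' @export
logit_beta <- function(beta, eps = 1e-6) {
  if (any(!is.finite(beta)) || any(beta < 0) || any(beta > 1))
    stop("beta values must be finite and in [0, 1]")
  n_clamp <- sum(beta <= 0 | beta >= 1)
  if (n_clamp > 0) {
    warning(sprintf("%d beta value(s) at 0 or 1 clamped to [%g, %g]",
                    n_clamp, eps, 1 - eps))
    beta <- pmin(pmax(beta, eps), 1 - eps)
  }
  log(beta / (1 - beta))
}

#' Residualize a matrix on a covariate set
#'
#' Regresses every column of `mat` on the covariates by one shared OLS
#' design and returns the residuals. Character/factor covariates are
#' one-hot encoded with the first level dropped. With an empty covariate
#' set the result is the column-centered input (intercept only).
#'
#' @param mat numeric matrix, samples in rows.
#' @param covariates data.frame of covariates (one row per sample), or
#'   `NULL` for centering only.
#' @param drop_aliased if `TRUE`, columns of the expanded design that are
#'   linearly dependent on earlier ones are dropped with a message (as
#'   `lm()` would drop aliased terms); if `FALSE` (default) a
#'   rank-deficient design is an error naming the collinear columns.
#' @return matrix of residuals with the input's dimnames.
#' @export
residualize <- function(mat, covariates = NULL, drop_aliased = FALSE) {
  mat <- as.matrix(mat)
  if (is.null(covariates) || ncol(as.data.frame(covariates)) == 0)
    return(scale(mat, center = TRUE, scale = FALSE)[, , drop = FALSE])
  covariates <- as.data.frame(covariates)
  if (nrow(covariates) != nrow(mat))
    stop("covariates must have one row per sample")
  for (j in names(covariates))
    if (is.character(covariates[[j]]) || is.logical(covariates[[j]]))
      covariates[[j]] <- factor(covariates[[j]])
  constant <- vapply(covariates, function(x)
    if (is.factor(x)) nlevels(droplevels(x)) < 2 else var(x) == 0, TRUE)
  if (any(constant)) {
    message("dropping constant covariate(s): ",
            paste(names(covariates)[constant], collapse = ", "))
    covariates <- covariates[, !constant, drop = FALSE]
    if (ncol(covariates) == 0)
      return(scale(mat, center = TRUE, scale = FALSE)[, , drop = FALSE])
  }
  X <- model.matrix(~ ., data = covariates)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    aliased <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    if (!drop_aliased)
      stop("rank-deficient design; collinear column(s): ",
           paste(aliased, collapse = ", "))
    message(sprintf("dropping %d aliased design column(s): %s",
                    length(aliased), paste(head(aliased, 5), collapse = ", ")))
    X <- X[, setdiff(colnames(X), aliased), drop = FALSE]
    qx <- qr(X)
  }
  res <- qr.resid(qx, mat)
  dimnames(res) <- dimnames(mat)
  res
}

#' Rank-based inverse-normal transform (Blom offset)
#'
#' Per column, maps values to standard-normal quantiles of
#' `(rank - 3/8) / (n + 1/4)`, with ties assigned their average rank. The
#' output is invariant to any strictly monotone transform of a column.
#'
#' @param mat numeric matrix, samples in rows.
#' @return matrix of transformed values, same dimnames.
#' @export
inverse_normal <- function(mat) {
  mat <- as.matrix(mat)
  if (any(!is.finite(mat))) stop("inverse_normal requires finite values")
  n <- nrow(mat)
  out <- mat
  for (j in seq_len(ncol(mat))) {
    x <- mat[, j]
    if (max(x) - min(x) == 0)
      stop("constant column (undefined ranks): ",
           colnames(mat)[j] %||% as.character(j))
    out[, j] <- qnorm((rank(x, ties.method = "average") - 3 / 8) / (n + 1 / 4))
  }
  out
}

#' Full methylation preprocessing pipeline
#'
#' Drops non-autosomal probes and probes with a known SNP at the target
#' CpG, logit-transforms the beta values, residualizes each probe on
#' technical variables (plate, array, array position) plus sex and age
#' (and optionally five blood cell counts for a sensitivity analysis),
#' and inverse-normal transforms the residuals.
#'
#' @param meth a [methylation_dataset()].
#' @param phenotypes data.frame with `sample_id` plus the covariate
#'   columns named in `covariates` (and the cell-count columns when
#'   `cell_counts = TRUE`).
#' @param covariates character vector of covariate column names; plate,
#'   array and array position are treated as unordered factors. Arrays
#'   nested within plates make the joint design aliased; aliased columns
#'   are dropped automatically here (see [residualize()]).
#' @param cell_counts include lymphocytes, monocytes, neutrophils,
#'   eosinophils, basophils in the adjustment set (sensitivity path).
#' @return object of class `resid_methylation`: list with `values`
#'   (sample x probe matrix of inverse-normal residuals), `probes`
#'   (annotation of the retained probes), `adjustment_set`, `sample_ids`.
#' @export
preprocess_methylation <- function(meth, phenotypes,
                                   covariates = c("plate", "array",
                                                  "array_position",
                                                  "sex", "age"),
                                   cell_counts = FALSE) {
  stopifnot(inherits(meth, "methylation_dataset"))
  idx <- match(meth$sample_ids, phenotypes$sample_id)
  if (anyNA(idx))
    stop("phenotype table is missing sample(s): ",
         paste(head(meth$sample_ids[is.na(idx)], 5), collapse = ", "))
  phenotypes <- phenotypes[idx, , drop = FALSE]

  keep <- meth$probes$autosomal & !meth$probes$snp_at_target
  n_drop <- sum(!keep)
  if (n_drop > 0)
    message(sprintf("excluding %d non-autosomal or SNP-at-target probe(s)",
                    n_drop))
  beta <- meth$beta[, keep, drop = FALSE]
  probes <- meth$probes[keep, , drop = FALSE]
  if (ncol(beta) == 0) stop("no probes left after annotation filtering")

  if (cell_counts)
    covariates <- union(covariates, c("lymphocytes", "monocytes",
                                      "neutrophils", "eosinophils",
                                      "basophils"))
  missing_cov <- setdiff(covariates, names(phenotypes))
  if (length(missing_cov))
    stop("phenotype table lacks covariate column(s): ",
         paste(missing_cov, collapse = ", "))
  covdf <- phenotypes[, covariates, drop = FALSE]

  mvals <- logit_beta(beta)
  res <- residualize(mvals, covdf, drop_aliased = TRUE)
  values <- inverse_normal(res)
  structure(list(values = values, probes = probes,
                 adjustment_set = covariates,
                 sample_ids = meth$sample_ids),
            class = "resid_methylation")
}

#' @export
print.resid_methylation <- function(x, ...) {
  cat(sprintf("resid_methylation: %d samples x %d probes (adjusted for %s)\n",
              nrow(x$values), ncol(x$values),
              paste(x$adjustment_set, collapse = ", ")))
  invisible(x)
}

#' Sex/age-adjusted, standardized phenotype (Z score)
#'
#' Residualizes the trait on sex and age by OLS and divides the residuals
#' by their sample standard deviation, giving the Z-score phenotype used
#' as the MWAS outcome.
#'
#' @param trait numeric trait values (e.g. BMI in kg/m^2 or height in cm).
#' @param sex,age covariates, same length as `trait`.
#' @param sample_ids optional ids attached as names.
#' @return class `adjusted_phenotype`: a named numeric vector with
#'   attributes `adjustment_set` and `family_corrected`.
#' @export
adjust_phenotype <- function(trait, sex, age, sample_ids = NULL) {
  if (anyNA(trait) || anyNA(sex) || anyNA(age))
    stop("trait, sex and age must be complete")
  r <- stats::resid(lm(trait ~ factor(sex) + age))
  s <- sd(r)
  if (!is.finite(s) || s < 1e-12)
    stop("trait has zero residual variance after sex/age adjustment")
  z <- as.numeric(r / s)
  names(z) <- sample_ids
  structure(z, adjustment_set = c("sex", "age"), family_corrected = FALSE,
            class = "adjusted_phenotype")
}

#' @export
print.adjusted_phenotype <- function(x, ...) {
  cat(sprintf("adjusted_phenotype: n = %d, adjusted for %s%s\n",
              length(x), paste(attr(x, "adjustment_set"), collapse = ", "),
              if (isTRUE(attr(x, "family_corrected")))
                " (family-structure corrected)" else ""))
  print(unclass(summary(as.numeric(x))))
  invisible(x)
}
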