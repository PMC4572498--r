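# Variance partitioning across four nested regression models
#   model 1: trait ~ methylation score
#   model 2: trait ~ genetic score
#   model 3: trait ~ methylation score + genetic score
#   model 4: trait ~ methylation score + genetic score + interaction
# with the interaction tested by ANOVA of model 4 against model 3, plus
# the machinery for related samples: a GCTA-style genetic relationship
# matrix, sparsification of negligible relatedness, MZ-duplicate removal,
# and a single-component REML mixed model whose residuals serve as the
# family-structure-corrected phenotype.

.score_vector <- function(x, label) {
  if (inherits(x, "profile_score")) setNames(x$score, x$sample_id)
  else if (is.numeric(x)) x
  else stop(label, " must be a profile_score or numeric vector")
}

#' Partition phenotypic variance over methylation and genetic scores
#'
#' Fits the four models above by OLS and reports each model's adjusted
#' R^2 (reported as-is, so small negative values are possible), the
#' significance of each score alone and within the additive model
#' (coefficient t-tests), and the ANOVA p-value of the interaction model
#' against the additive model. Adjusted R^2 and all p-values are
#' invariant to affine rescaling of either score.
#'
#' @param trait [adjust_phenotype()] result or numeric vector.
#' @param mwas_score,gwas_score `profile_score` objects or numeric
#'   vectors; aligned to `trait` by sample id when ids are available.
#' @return class `variance_partition`: list with `adj_r2_mwas`,
#'   `adj_r2_gwas`, `adj_r2_additive`, `adj_r2_interaction`, raw `r2`
#'   vector, `p_mwas_only`, `p_gwas_only`, `p_mwas_in_additive`,
#'   `p_gwas_in_additive`, `anova_p_interaction`, `n`.
#' @export
fit_partition <- function(trait, mwas_score, gwas_score) {
  y <- as.numeric(trait)
  ids <- names(trait)
  s1 <- .score_vector(mwas_score, "mwas_score")
  s2 <- .score_vector(gwas_score, "gwas_score")
  if (!is.null(ids) && !is.null(names(s1))) {
    if (!all(ids %in% names(s1))) stop("mwas_score is missing trait samples")
    s1 <- s1[ids]
  }
  if (!is.null(ids) && !is.null(names(s2))) {
    if (!all(ids %in% names(s2))) stop("gwas_score is missing trait samples")
    s2 <- s2[ids]
  }
  n <- length(y)
  if (length(s1) != n || length(s2) != n)
    stop("trait and scores must cover the same samples")
  if (n <= 5) stop("at least 6 samples are required")
  if (sd(s1) > 0 && sd(s2) > 0 && abs(cor(s1, s2)) > 0.9999)
    stop("scores are collinear (|r| > 0.9999); partition is not identifiable")

  d <- data.frame(y = y, s1 = as.numeric(s1), s2 = as.numeric(s2))
  m1 <- lm(y ~ s1, data = d)
  m2 <- lm(y ~ s2, data = d)
  m3 <- lm(y ~ s1 + s2, data = d)
  m4 <- lm(y ~ s1 * s2, data = d)
  sm <- lapply(list(m1, m2, m3, m4), summary)
  r2 <- vapply(sm, function(s) s$r.squared, 0)
  # nesting sanity: models 1 and 2 are submodels of 3, and 3 of 4
  stopifnot(r2[3] >= max(r2[1], r2[2]) - 1e-10, r2[4] >= r2[3] - 1e-10)
  structure(list(
    adj_r2_mwas = sm[[1]]$adj.r.squared,
    adj_r2_gwas = sm[[2]]$adj.r.squared,
    adj_r2_additive = sm[[3]]$adj.r.squared,
    adj_r2_interaction = sm[[4]]$adj.r.squared,
    r2 = setNames(r2, c("mwas", "gwas", "additive", "interaction")),
    p_mwas_only = sm[[1]]$coefficients["s1", "Pr(>|t|)"],
    p_gwas_only = sm[[2]]$coefficients["s2", "Pr(>|t|)"],
    p_mwas_in_additive = sm[[3]]$coefficients["s1", "Pr(>|t|)"],
    p_gwas_in_additive = sm[[3]]$coefficients["s2", "Pr(>|t|)"],
    anova_p_interaction = anova(m3, m4)[2, "Pr(>F)"],
    n = n), class = "variance_partition")
}

#' @export
print.variance_partition <- function(x, ...) {
  cat("variance_partition (n =", x$n, ")\n")
  cat(sprintf("  model 1 (methylation score):        adj R^2 = %7.4f  p = %.3g\n",
              x$adj_r2_mwas, x$p_mwas_only))
  cat(sprintf("  model 2 (genetic score):            adj R^2 = %7.4f  p = %.3g\n",
              x$adj_r2_gwas, x$p_gwas_only))
  cat(sprintf("  model 3 (additive):                 adj R^2 = %7.4f\n",
              x$adj_r2_additive))
  cat(sprintf("     marginal p (methylation, genetic) = %.3g, %.3g\n",
              x$p_mwas_in_additive, x$p_gwas_in_additive))
  cat(sprintf("  model 4 (+ interaction):            adj R^2 = %7.4f  ANOVA p (4 vs 3) = %.3g\n",
              x$adj_r2_interaction, x$anova_p_interaction))
  invisible(x)
}

#' Genetic relationship matrix (GRM) from SNP dosages
#'
#' GCTA-style estimator: with standardized dosages
#' `w_ij = (x_ij - 2 p_j) / sqrt(2 p_j (1 - p_j))`, the relatedness of
#' individuals i and k is the average of `w_ij * w_kj` over SNPs.
#' Monomorphic SNPs are skipped; missing dosages are mean-imputed.
#'
#' @param genotypes [genotype_dataset()] or a sample-by-SNP dosage matrix.
#' @return symmetric n x n matrix with sample ids as dimnames; diagonal
#'   close to 1 (plus inbreeding).
#' @export
compute_grm <- function(genotypes) {
  X <- if (inherits(genotypes, "genotype_dataset")) genotypes$dosage
       else as.matrix(genotypes)
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    for (j in which(colSums(is.na(X)) > 0)) X[is.na(X[, j]), j] <- mu[j]
  }
  p <- colMeans(X) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all SNPs are monomorphic; GRM is undefined")
  if (sum(poly) < 100)
    warning(sprintf("only %d polymorphic SNP(s); GRM estimates will be noisy",
                    sum(poly)))
  Xp <- X[, poly, drop = FALSE]
  pp <- p[poly]
  W <- sweep(Xp, 2, 2 * pp, "-")
  W <- sweep(W, 2, sqrt(2 * pp * (1 - pp)), "/")
  A <- tcrossprod(W) / ncol(W)
  dimnames(A) <- list(rownames(X), rownames(X))
  A
}

#' Sparsify a GRM by zeroing negligible relatedness
#'
#' Off-diagonal entries strictly below `cutoff` are set to exactly 0
#' (entries equal to the cutoff are retained); the diagonal is untouched.
#' This removes spurious distant-relatedness noise so the mixed model
#' captures close family structure only.
#'
#' @param grm symmetric relatedness matrix.
#' @param cutoff relatedness cutoff, default 0.05.
#' @return thresholded matrix.
#' @export
threshold_grm <- function(grm, cutoff = 0.05) {
  stopifnot(is.matrix(grm), nrow(grm) == ncol(grm))
  off <- row(grm) != col(grm)
  grm[off & grm < cutoff] <- 0
  grm
}

#' Identify and drop duplicate genomes (MZ twins)
#'
#' Finds sample pairs whose GRM relatedness exceeds `threshold`
#' (genetically identical individuals, e.g. monozygotic twins) and
#' returns the sample set with one member of each such pair removed.
#'
#' @param grm relatedness matrix with sample-id dimnames.
#' @param threshold relatedness above which a pair is treated as
#'   duplicate genomes, default 0.95.
#' @return list with `keep` (sample ids retained), `dropped` (ids
#'   removed), `pairs` (data.frame of detected pairs).
#' @export
drop_mz_duplicates <- function(grm, threshold = 0.95) {
  stopifnot(is.matrix(grm), !is.null(rownames(grm)))
  ut <- which(upper.tri(grm) & grm > threshold, arr.ind = TRUE)
  pairs <- data.frame(a = rownames(grm)[ut[, 1]], b = rownames(grm)[ut[, 2]],
                      relatedness = grm[ut], stringsAsFactors = FALSE)
  dropped <- character(0)
  for (i in seq_len(nrow(pairs)))  # keep the first member of each pair
    if (!(pairs$a[i] %in% dropped)) dropped <- union(dropped, pairs$b[i])
  list(keep = setdiff(rownames(grm), dropped), dropped = dropped,
       pairs = pairs)
}

#' Single-GRM REML variance components
#'
#' Fits `y = mu + g + e` with `g ~ N(0, sigma2_g * GRM)` and
#' `e ~ N(0, sigma2_e * I)` by restricted maximum likelihood, using one
#' eigendecomposition of the GRM and a 1-D search over the heritability
#' ratio `h2 = sigma2_g / (sigma2_g + sigma2_e)`. Exact for a single
#' relatedness component. Negative GRM eigenvalues (possible after
#' thresholding) are clipped at zero with a warning.
#'
#' @param y numeric phenotype vector.
#' @param grm relatedness matrix, same order as `y`.
#' @return list with `h2`, `se_h2` (from the observed information of the
#'   profiled restricted likelihood; `NA` at the boundary), `sigma2_g`,
#'   `sigma2_e`, `mu`, `blup` (predicted genetic values), `residuals`
#'   (`y - mu - blup`), `loglik`.
#' @export
grm_reml <- function(y, grm) {
  n <- length(y)
  stopifnot(is.matrix(grm), nrow(grm) == n, ncol(grm) == n)
  eg <- eigen((grm + t(grm)) / 2, symmetric = TRUE)
  d <- eg$values
  if (any(d < -1e-8)) {
    warning("GRM is not positive semi-definite; clipping negative eigenvalues at 0")
  }
  d <- pmax(d, 0)
  U <- eg$vectors
  yt <- as.vector(crossprod(U, y))
  xt <- as.vector(crossprod(U, rep(1, n)))

  neg_restricted_ll <- function(h2) {
    w <- h2 * d + (1 - h2)
    xwx <- sum(xt^2 / w)
    bhat <- sum(xt * yt / w) / xwx
    rss <- sum((yt - bhat * xt)^2 / w)
    s2 <- rss / (n - 1)
    0.5 * ((n - 1) * log(s2) + sum(log(w)) + log(xwx) + (n - 1))
  }
  lo <- 1e-6; hi <- 1 - 1e-6
  opt <- optimize(neg_restricted_ll, c(lo, hi), tol = 1e-9)
  h2 <- opt$minimum

  eps <- 1e-4
  se <- NA_real_
  if (h2 > lo + eps && h2 < hi - eps) {
    info <- (neg_restricted_ll(h2 + eps) - 2 * opt$objective +
               neg_restricted_ll(h2 - eps)) / eps^2
    if (is.finite(info) && info > 0) se <- 1 / sqrt(info)
  }
  w <- h2 * d + (1 - h2)
  xwx <- sum(xt^2 / w)
  mu <- sum(xt * yt / w) / xwx
  s2 <- sum((yt - mu * xt)^2 / w) / (n - 1)
  blup <- as.vector(U %*% ((h2 * d / w) * (yt - mu * xt)))
  list(h2 = h2, se_h2 = se,
       sigma2_g = h2 * s2, sigma2_e = (1 - h2) * s2, mu = mu,
       blup = blup, residuals = y - mu - blup, loglik = -opt$objective)
}

#' Correct a phenotype for family structure via a mixed model
#'
#' Fits the single-GRM REML model of [grm_reml()] on the adjusted
#' phenotype and returns the restandardized residuals
#' `y - mu - BLUP(g)`: the family-structure-corrected phenotype used in
#' downstream variance-partition regressions. With an identity-like GRM
#' the genetic component is unidentifiable and the output equals the
#' standardized input.
#'
#' @param trait [adjust_phenotype()] result or named numeric vector.
#' @param grm (thresholded) relatedness matrix; reordered to the trait's
#'   samples by dimnames when available.
#' @return an `adjusted_phenotype` with `family_corrected = TRUE` and
#'   attributes `h2`, `se_h2` from the REML fit.
#' @export
family_correct <- function(trait, grm) {
  y <- as.numeric(trait)
  ids <- names(trait)
  if (!is.null(ids) && !is.null(rownames(grm))) {
    if (!all(ids %in% rownames(grm)))
      stop("GRM is missing sample(s) present in the trait")
    grm <- grm[ids, ids]
  } else if (nrow(grm) != length(y))
    stop("GRM dimension does not match the trait")
  fit <- grm_reml(y, grm)
  r <- fit$residuals
  s <- sd(r)
  if (!is.finite(s) || s < 1e-12)
    stop("degenerate residuals from the family-structure model")
  z <- (r - mean(r)) / s
  names(z) <- ids
  structure(z,
            adjustment_set = union(attr(trait, "adjustment_set") %||%
                                     character(0), "family"),
            family_corrected = TRUE, h2 = fit$h2, se_h2 = fit$se_h2,
            class = "adjusted_phenotype")
}
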