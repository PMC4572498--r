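# Fixed-effect inverse-variance meta-analysis of two MWAS result sets
# over their common probes, and Bonferroni selection on the pooled
# p-values. Probes are harmonized by id only (methylation array ids are
# canonical; there is no strand/allele flipping concept).

#' Fixed-effect meta-analysis of two MWAS scans
#'
#' For each probe present in both studies, pools the effect estimates
#' with inverse-variance weights `w = 1/se^2`:
#' `beta_meta = sum(w * beta) / sum(w)`, `se_meta = 1 / sqrt(sum(w))`,
#' with a two-sided normal p-value on `z = beta_meta / se_meta`. Probes
#' present in only one study are excluded.
#'
#' @param a,b `mwas_result` objects (or data.frames with `probe_id`,
#'   `beta`, `se`, `n`).
#' @return class `meta_result`: data.frame with `probe_id`, `beta_meta`,
#'   `se_meta`, `z`, `p_meta`, `n_total`, `n_studies`; attribute
#'   `n_common`.
#' @export
fixed_effect_meta <- function(a, b) {
  for (x in list(a, b))
    stopifnot(is.data.frame(x), all(c("probe_id", "beta", "se") %in% names(x)))
  common <- intersect(a$probe_id, b$probe_id)
  if (length(common) == 0)
    stop(sprintf("no common probes (study A: %d probes, study B: %d probes)",
                 nrow(a), nrow(b)))
  ia <- match(common, a$probe_id)
  ib <- match(common, b$probe_id)
  if (any(a$se[ia] <= 0) || any(b$se[ib] <= 0))
    stop("standard errors must be positive")
  wa <- 1 / a$se[ia]^2
  wb <- 1 / b$se[ib]^2
  beta <- (wa * a$beta[ia] + wb * b$beta[ib]) / (wa + wb)
  se <- 1 / sqrt(wa + wb)
  z <- beta / se
  p <- pmax(2 * pnorm(-abs(z)), .P_FLOOR)
  na <- if (!is.null(a$n)) a$n[ia] else NA_integer_
  nb <- if (!is.null(b$n)) b$n[ib] else NA_integer_
  out <- data.frame(probe_id = common, beta_meta = beta, se_meta = se,
                    z = z, p_meta = p, n_total = na + nb, n_studies = 2L,
                    stringsAsFactors = FALSE)
  attr(out, "n_common") <- length(common)
  class(out) <- c("meta_result", "data.frame")
  out
}

#' Bonferroni probe selection on meta-analysis results
#'
#' Returns the probes whose pooled p-value falls below
#' `alpha / n_common`, the Bonferroni threshold for the number of probes
#' shared by the meta-analyzed studies. The result feeds
#' [prune_probes()] as an external candidate list.
#'
#' @param meta a [fixed_effect_meta()] result.
#' @param alpha family-wise error rate, default 0.05.
#' @return character vector of probe ids (possibly empty, with a
#'   warning); attribute `threshold` carries the p cutoff used.
#' @export
meta_select <- function(meta, alpha = 0.05) {
  stopifnot(inherits(meta, "meta_result"))
  thr <- bonferroni_threshold(attr(meta, "n_common"), alpha)
  ids <- meta$probe_id[meta$p_meta < thr]
  if (length(ids) == 0)
    warning("no probes pass the meta-analysis Bonferroni threshold")
  attr(ids, "threshold") <- thr
  ids
}
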