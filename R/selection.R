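# Bonferroni probe selection and windowed correlation pruning. If several
# probes pass the significance threshold and are mutually correlated
# (|Pearson r| above a threshold on the residualized values) within a
# short genomic window, only the most significant of them is kept for the
# profile score. Realized as a greedy most-significant-first sweep, which
# is deterministic and keeps exactly one representative per conflicting
# group.

#' Bonferroni significance threshold
#'
#' @param n_probes number of probes tested (>= 1).
#' @param alpha family-wise error rate, default 0.05.
#' @return `alpha / n_probes`.
#' @export
bonferroni_threshold <- function(n_probes, alpha = 0.05) {
  if (length(n_probes) != 1 || !is.finite(n_probes) || n_probes < 1)
    stop("n_probes must be a single count >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  alpha / n_probes
}

#' Prune correlated probes to a non-redundant score set
#'
#' Selects candidate probes below a significance threshold (Bonferroni by
#' default, or an explicit override such as p < 0.001 for weakly
#' associated traits) and greedily sweeps them in ascending-p order: a
#' candidate is retained iff no already-retained probe lies within
#' `prune_window_bp` on the same chromosome with absolute Pearson
#' correlation above `prune_r` (computed on the residualized /
#' inverse-normal values). Ties in p are broken by chromosome, position,
#' then probe id. Retained probes carry their MWAS effect size as score
#' weight.
#'
#' For cross-cohort scoring, pass `candidates` (probe ids selected in a
#' discovery cohort); weights are then pulled from `results` (the weight
#' cohort's scan) for exactly those probes, with no further thresholding.
#'
#' @param results an `mwas_result` supplying p-values and weights.
#' @param methylation `resid_methylation` (or matrix) used for pairwise
#'   correlations; must contain every candidate probe.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param p_override explicit p threshold replacing Bonferroni (e.g.
#'   `0.001`), or `NULL`.
#' @param prune_window_bp genomic window in bp (pairwise distance, same
#'   chromosome); `0` disables genomic pruning entirely.
#' @param prune_r absolute-correlation threshold; conflicts require
#'   |r| strictly greater than this, so `prune_r >= 1` retains all
#'   candidates.
#' @param candidates optional character vector of externally selected
#'   probe ids (cross-cohort mode).
#' @return class `score_weights`: data.frame with `feature_id`,
#'   `feature_kind = "cpg"`, `weight`, `chrom`, `pos`, `p`, `source`.
#'   Empty (with a warning) when no probe passes.
#' @export
prune_probes <- function(results, methylation, alpha = 0.05,
                         p_override = NULL, prune_window_bp = 500,
                         prune_r = 0.1, candidates = NULL) {
  stopifnot(inherits(results, "mwas_result") || is.data.frame(results))
  values <- if (inherits(methylation, "resid_methylation")) methylation$values
            else as.matrix(methylation)
  ann <- if (inherits(methylation, "resid_methylation")) methylation$probes
         else stop("probe annotation required: pass a resid_methylation object")
  if (prune_window_bp < 0) stop("prune_window_bp must be nonnegative")

  if (is.null(candidates)) {
    thr <- if (!is.null(p_override)) {
      if (p_override <= 0 || p_override >= 1)
        stop("p_override must lie in (0, 1)")
      p_override
    } else bonferroni_threshold(nrow(results), alpha)
    cand <- results[results$p < thr, , drop = FALSE]
  } else {
    missing_ids <- setdiff(candidates, results$probe_id)
    if (length(missing_ids))
      warning(sprintf("%d candidate probe(s) absent from the weight scan",
                      length(missing_ids)))
    cand <- results[results$probe_id %in% candidates, , drop = FALSE]
  }
  empty <- data.frame(feature_id = character(0), feature_kind = character(0),
                      weight = numeric(0), chrom = character(0),
                      pos = integer(0), p = numeric(0), source = character(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("score_weights", "data.frame")
  if (nrow(cand) == 0) {
    warning("no probes pass the selection threshold; returning empty weights")
    return(empty)
  }
  ai <- match(cand$probe_id, ann$probe_id)
  if (anyNA(ai))
    stop("candidate probe(s) missing from methylation annotation: ",
         paste(head(cand$probe_id[is.na(ai)], 5), collapse = ", "))
  cand$chrom <- ann$chrom[ai]
  cand$pos <- ann$pos[ai]
  ord <- order(cand$p, cand$chrom, cand$pos, cand$probe_id)
  cand <- cand[ord, , drop = FALSE]

  if (is.null(candidates)) {
    vals <- values[, cand$probe_id, drop = FALSE]
    retained <- integer(0)
    for (i in seq_len(nrow(cand))) {
      conflict <- FALSE
      if (prune_window_bp > 0 && prune_r < 1 && length(retained)) {
        near <- retained[cand$chrom[retained] == cand$chrom[i] &
                           abs(cand$pos[retained] - cand$pos[i]) <= prune_window_bp]
        if (length(near)) {
          rr <- abs(suppressWarnings(cor(vals[, i], vals[, near, drop = FALSE])))
          conflict <- any(rr > prune_r, na.rm = TRUE)
        }
      }
      if (!conflict) retained <- c(retained, i)
    }
  } else {
    # externally selected candidate list: take it as-is, weights only
    retained <- seq_len(nrow(cand))
  }
  out <- data.frame(feature_id = cand$probe_id[retained],
                    feature_kind = "cpg",
                    weight = cand$beta[retained],
                    chrom = cand$chrom[retained],
                    pos = cand$pos[retained],
                    p = cand$p[retained],
                    source = attr(results, "trait") %||% "mwas",
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("score_weights", "data.frame")
  out
}
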