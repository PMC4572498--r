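# Independent oracles used across test files. These deliberately avoid
# the package's own code paths: plain-formula OLS, a literal
# inverse-variance pooling, an all-pairs check of the pruning rule, and a
# paired-sibling intraclass correlation.

# textbook simple-regression summaries from explicit sums
ols_oracle <- function(x, y) {
  n <- length(x)
  xb <- mean(x); yb <- mean(y)
  sxx <- sum((x - xb)^2)
  b <- sum((x - xb) * (y - yb)) / sxx
  a <- yb - b * xb
  sse <- sum((y - a - b * x)^2)
  se <- sqrt(sse / (n - 2) / sxx)
  t <- b / se
  list(beta = b, se = se, t = t, p = 2 * pt(-abs(t), n - 2))
}

# literal inverse-variance fixed-effect pooling, probe by probe
meta_oracle <- function(beta_a, se_a, beta_b, se_b) {
  out <- data.frame(beta = numeric(length(beta_a)), se = NA_real_, p = NA_real_)
  for (i in seq_along(beta_a)) {
    w <- c(1 / se_a[i]^2, 1 / se_b[i]^2)
    out$beta[i] <- sum(w * c(beta_a[i], beta_b[i])) / sum(w)
    out$se[i] <- sqrt(1 / sum(w))
    out$p[i] <- 2 * pnorm(-abs(out$beta[i] / out$se[i]))
  }
  out
}

# all-pairs verification of a pruned candidate set:
#  (1) no two retained probes conflict (distance <= window on the same
#      chromosome AND |r| > r_thresh), and
#  (2) every dropped candidate conflicts with at least one retained
#      candidate of smaller p (ties broken by chrom, pos, id).
check_pruning <- function(cand, values, retained_ids, window, r_thresh) {
  conflicts <- function(i, j) {
    if (window <= 0) return(FALSE)
    if (cand$chrom[i] != cand$chrom[j]) return(FALSE)
    if (abs(cand$pos[i] - cand$pos[j]) > window) return(FALSE)
    abs(cor(values[, cand$probe_id[i]], values[, cand$probe_id[j]])) > r_thresh
  }
  before <- function(i, j) {  # candidate i strictly precedes j in the sweep
    ki <- cand[i, c("p", "chrom", "pos", "probe_id")]
    kj <- cand[j, c("p", "chrom", "pos", "probe_id")]
    for (f in names(ki)) {
      if (ki[[f]] < kj[[f]]) return(TRUE)
      if (ki[[f]] > kj[[f]]) return(FALSE)
    }
    FALSE
  }
  ret <- which(cand$probe_id %in% retained_ids)
  drop <- setdiff(seq_len(nrow(cand)), ret)
  for (a in ret) for (b in ret) if (a < b && conflicts(a, b)) return(FALSE)
  for (d in drop) {
    ok <- any(vapply(ret, function(r) before(r, d) && conflicts(r, d), TRUE))
    if (!ok) return(FALSE)
  }
  TRUE
}

# intraclass correlation as a variance-components ratio,
# sigma2_family / (sigma2_family + sigma2_residual), from a random-
# intercept model; the family variance component is bounded below at 0
pair_icc <- function(x, fam) {
  fit <- lme4::lmer(x ~ 1 + (1 | fam),
                    data = data.frame(x = x, fam = fam))
  vc <- as.data.frame(lme4::VarCorr(fit))
  v_fam <- vc$vcov[vc$grp == "fam"]
  v_res <- vc$vcov[vc$grp == "Residual"]
  v_fam / (v_fam + v_res)
}

# raw pairwise within-family correlation (can be negative)
pair_cor <- function(x, fam) {
  byfam <- split(x, fam)
  byfam <- byfam[lengths(byfam) == 2]
  m <- do.call(rbind, byfam)
  cor(c(m[, 1], m[, 2]), c(m[, 2], m[, 1]))
}
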