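test_that("per-probe OLS matches the closed-form oracle on a small fixture", {
  x1 <- c(1.2, -0.4, 0.3, 2.1, -1.5, 0.8, -0.9, 1.1, 0.2, -0.6)
  x2 <- c(0.5, 0.1, -1.2, 0.7, 1.9, -0.3, 0.4, -1.1, 0.9, 0.0)
  y <- c(0.9, -0.2, 0.5, 1.8, -1.1, 0.2, -0.7, 0.6, 0.1, -0.4)
  X <- cbind(cgA = x1, cgB = x2)
  rownames(X) <- sprintf("s%02d", 1:10)
  res <- run_mwas(X, y)
  for (j in 1:2) {
    o <- ols_oracle(X[, j], y)
    expect_equal(res$beta[j], o$beta, tolerance = 1e-12)
    expect_equal(res$se[j], o$se, tolerance = 1e-12)
    expect_equal(res$t[j], o$t, tolerance = 1e-12)
    expect_equal(res$p[j], o$p, tolerance = 1e-12)
  }
  expect_identical(res$n, rep(10L, 2))
})

test_that("p-values stay consistent with t on n-2 df, and underflow is guarded", {
  set.seed(6)
  X <- matrix(rnorm(50 * 20), 50, 20,
              dimnames = list(NULL, sprintf("cg%02d", 1:20)))
  y <- rnorm(50)
  res <- run_mwas(X, y)
  expect_equal(res$p, 2 * pt(-abs(res$t), 48), tolerance = 1e-10)
  # phenotype identical to a probe: slope one, p at the floor
  y2 <- X[, 1]
  res2 <- run_mwas(X, y2)
  expect_equal(res2$beta[1], 1, tolerance = 1e-12)
  expect_gt(res2$p[1], 0)
  expect_lte(res2$p[1], 1e-250)
})

test_that("null simulation yields uniform p-values (KS bound)", {
  sim <- simulate_cohort(sim_config(n_samples = 300, n_probes = 2000,
                                    probes_per_block = 1, n_snps = 10,
                                    var_genetic = 0, var_methylation = 0,
                                    n_causal_probes = 1, n_causal_snps = 1,
                                    cellcount_confounding = 0, seed = 8))
  res <- preprocess_methylation(sim$methylation, sim$phenotypes,
                                covariates = c("sex", "age"))
  z <- adjust_phenotype(sim$phenotypes$trait, sim$phenotypes$sex,
                        sim$phenotypes$age, sim$phenotypes$sample_id)
  scan <- run_mwas(res, z)
  P <- nrow(scan)
  ks <- max(abs(sort(scan$p) - (seq_len(P) - 0.5) / P))
  expect_lt(ks, 1.63 / sqrt(P))  # alpha = 0.01 critical value
})

test_that("lambda equals 1 at the chi-square unit points and ignores probe order", {
  p_unit <- pchisq(1, 1, lower.tail = FALSE)  # 0.3173...
  expect_equal(genomic_lambda(rep(p_unit, 10)), 1, tolerance = 1e-10)
  p_pair <- pchisq(c(0, 2), 1, lower.tail = FALSE)
  expect_equal(genomic_lambda(p_pair), 1, tolerance = 1e-10)
  set.seed(9)
  p <- runif(200)
  expect_equal(genomic_lambda(p), genomic_lambda(sample(p)))
})

test_that("effective probe count is 2 over the squared permutation SD", {
  expect_equal(effective_probes(0.1), 200, tolerance = 1e-12)
  expect_equal(effective_probes(sqrt(2)), 1, tolerance = 1e-12)
  expect_equal(effective_probes(0.05), 800, tolerance = 1e-12)
  expect_error(effective_probes(0), "positive")
  expect_error(effective_probes(-1), "positive")
})

test_that("chunked scans agree bit-for-bit with the full scan", {
  set.seed(10)
  X <- matrix(rnorm(80 * 40), 80, 40,
              dimnames = list(NULL, sprintf("cg%02d", 1:40)))
  y <- rnorm(80)
  full <- run_mwas(X, y)
  left <- run_mwas(X[, 1:17], y)
  right <- run_mwas(X[, 18:40], y)
  expect_identical(full$beta, c(left$beta, right$beta))
  expect_identical(full$p, c(left$p, right$p))
})

test_that("permutation lambdas center on 1 and need at least 2 permutations", {
  sim <- simulate_cohort(sim_config(n_samples = 300, n_probes = 1000,
                                    n_snps = 10, var_genetic = 0,
                                    var_methylation = 0, n_causal_probes = 1,
                                    n_causal_snps = 1,
                                    cellcount_confounding = 0, seed = 12))
  res <- preprocess_methylation(sim$methylation, sim$phenotypes,
                                covariates = c("sex", "age"))
  z <- adjust_phenotype(sim$phenotypes$trait, sim$phenotypes$sex,
                        sim$phenotypes$age, sim$phenotypes$sample_id)
  expect_error(permutation_lambda(res, z, n_perm = 1, seed = 1), "n_perm")
  inf <- permutation_lambda(res, z, n_perm = 50, seed = 3)
  expect_length(inf$perm_lambdas, 50)
  expect_lt(abs(inf$perm_mean - 1), 3 * inf$perm_sd / sqrt(50))
  expect_equal(inf$m_effective, 2 / inf$perm_sd^2)
  # same seed, same permutation stream
  inf2 <- permutation_lambda(res, z, n_perm = 50, seed = 3)
  expect_identical(inf$perm_lambdas, inf2$perm_lambdas)
})

test_that("independent probes recover their own count as M_effective", {
  sim <- simulate_cohort(sim_config(n_samples = 4000, n_probes = 1000,
                                    probes_per_block = 1, n_snps = 10,
                                    var_genetic = 0, var_methylation = 0,
                                    n_causal_probes = 1, n_causal_snps = 1,
                                    cellcount_confounding = 0, seed = 14))
  res <- preprocess_methylation(sim$methylation, sim$phenotypes,
                                covariates = c("sex", "age"))
  z <- adjust_phenotype(sim$phenotypes$trait, sim$phenotypes$sex,
                        sim$phenotypes$age, sim$phenotypes$sample_id)
  inf <- permutation_lambda(res, z, n_perm = 200, seed = 15)
  expect_gt(inf$m_effective, 1000 / 1.5)
  expect_lt(inf$m_effective, 1000 * 1.5)
})

test_that("M_effective decreases as within-block correlation grows", {
  m_eff <- vapply(c(0, 0.5, 0.9), function(r) {
    sim <- simulate_cohort(sim_config(n_samples = 1000, n_probes = 500,
                                      probes_per_block = 5, within_block_r = r,
                                      n_snps = 10, var_genetic = 0,
                                      var_methylation = 0, n_causal_probes = 1,
                                      n_causal_snps = 1,
                                      cellcount_confounding = 0, seed = 16))
    res <- preprocess_methylation(sim$methylation, sim$phenotypes,
                                  covariates = c("sex", "age"))
    z <- adjust_phenotype(sim$phenotypes$trait, sim$phenotypes$sex,
                          sim$phenotypes$age, sim$phenotypes$sample_id)
    permutation_lambda(res, z, n_perm = 100, seed = 18)$m_effective
  }, 0)
  expect_true(all(diff(m_eff) < 0))
})
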