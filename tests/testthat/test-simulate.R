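test_that("infeasible configurations are rejected", {
  expect_error(sim_config(var_genetic = 0.6, var_methylation = 0.6),
               "exceeds 1")
  expect_error(sim_config(n_probes = 10, n_causal_probes = 20),
               "n_causal_probes")
  expect_error(sim_config(n_snps = 10, n_causal_snps = 20), "n_causal_snps")
  expect_error(sim_config(within_block_r = 1), "within_block_r")
  expect_error(sim_config(n_probes = 100, probes_per_block = 50,
                          n_causal_probes = 5),
               "distinct blocks")
})

test_that("the same seed reproduces the cohort bit-identically", {
  cfg <- sim_config(n_samples = 60, n_probes = 100, n_snps = 50,
                    n_causal_probes = 3, n_causal_snps = 10, seed = 11,
                    batch_effect_sd = 0.2)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$methylation$beta, b$methylation$beta)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth$true_snp_effects, b$truth$true_snp_effects)
})

test_that("beta values are strictly inside (0, 1)", {
  sim <- simulate_cohort(sim_config(n_samples = 80, n_probes = 300,
                                    n_snps = 20, n_causal_probes = 2,
                                    n_causal_snps = 5, seed = 2,
                                    batch_effect_sd = 1))
  expect_true(all(sim$methylation$beta > 0 & sim$methylation$beta < 1))
})

test_that("allele frequencies track the drawn MAFs within binomial error", {
  sim <- simulate_cohort(sim_config(n_samples = 1000, n_probes = 10,
                                    n_snps = 400, n_causal_probes = 1,
                                    n_causal_snps = 5, seed = 7))
  maf <- sim$truth$maf
  obs <- colMeans(sim$genotypes$dosage) / 2
  se <- sqrt(maf * (1 - maf) / (2 * 1000))
  # ~99.99% of SNPs expected within 4 SE; allow a couple of excursions
  expect_lt(sum(abs(obs - maf) > 4 * se), 4)
})

test_that("MZ pairs share identical genotype rows; sibs obey Mendel", {
  mz <- simulate_cohort(sim_config(n_samples = 40, n_probes = 10, n_snps = 60,
                                   n_causal_probes = 1, n_causal_snps = 5,
                                   family_structure = "mz_pairs", seed = 4))
  fam <- mz$truth$family_assignments
  for (f in unique(fam)) {
    ix <- which(fam == f)
    if (length(ix) == 2)
      expect_identical(mz$genotypes$dosage[ix[1], ], mz$genotypes$dosage[ix[2], ])
  }
  tr <- simulate_cohort(sim_config(n_samples = 60, n_probes = 10, n_snps = 80,
                                   n_causal_probes = 1, n_causal_snps = 5,
                                   family_structure = "trios", seed = 5))
  d <- tr$genotypes$dosage
  fam <- tr$truth$family_assignments
  for (f in unique(fam)) {
    ix <- which(fam == f)
    if (length(ix) == 3) {  # father, mother, child
      child <- d[ix[3], ]; psum <- d[ix[1], ] + d[ix[2], ]
      expect_true(all(child[psum == 0] == 0))
      expect_true(all(child[psum == 4] == 2))
      # a child allele needs a carrier parent
      expect_true(all(child <= pmin(d[ix[1], ], 1) + pmin(d[ix[2], ], 1) + 0))
    }
  }
})

test_that("within-block probe correlation reaches the configured level", {
  sim <- simulate_cohort(sim_config(n_samples = 1000, n_probes = 50,
                                    probes_per_block = 5,
                                    within_block_r = 0.9, n_snps = 10,
                                    n_causal_probes = 1, n_causal_snps = 2,
                                    seed = 9))
  lg <- logit_beta(sim$methylation$beta)
  rs <- c()
  for (b in seq_len(10)) {
    cols <- ((b - 1) * 5 + 1):(b * 5)
    cm <- abs(cor(lg[, cols]))
    rs <- c(rs, cm[upper.tri(cm)])
  }
  expect_gte(mean(rs), 0.7)
})

test_that("block positions stay within the configured genomic span", {
  sim <- simulate_cohort(sim_config(n_samples = 20, n_probes = 40,
                                    probes_per_block = 4, block_size_bp = 500,
                                    n_snps = 10, n_causal_probes = 1,
                                    n_causal_snps = 2, seed = 1))
  ann <- sim$methylation$probes
  blocks <- rep(seq_len(10), each = 4)
  span <- tapply(ann$pos, blocks, function(p) max(p) - min(p))
  expect_true(all(span <= 500))
})

test_that("a single causal probe recovers its configured variance share", {
  sim <- simulate_cohort(sim_config(n_samples = 2000, n_probes = 50,
                                    n_snps = 10, n_causal_probes = 1,
                                    n_causal_snps = 2, var_genetic = 0,
                                    var_methylation = 0.5,
                                    cellcount_confounding = 0, seed = 21))
  expect_equal(sim$truth$realized_var_methylation, 0.5, tolerance = 0.05)
  z <- adjust_phenotype(sim$phenotypes$trait, sim$phenotypes$sex,
                        sim$phenotypes$age)
  x <- logit_beta(sim$methylation$beta[, sim$truth$causal_probe_ids[1]])
  r2 <- summary(lm(z ~ x))$r.squared
  expect_equal(r2, sim$truth$realized_var_methylation, tolerance = 0.06)
})

test_that("a null cohort carries no phenotype signal", {
  sim <- simulate_cohort(sim_config(n_samples = 400, n_probes = 100,
                                    n_snps = 50, var_genetic = 0,
                                    var_methylation = 0, n_causal_probes = 1,
                                    n_causal_snps = 1, seed = 30))
  expect_equal(sim$truth$realized_var_genetic, 0)
  expect_equal(sim$truth$realized_var_methylation, 0)
  expect_identical(unname(sim$truth$true_snp_effects), 0)
})

test_that("realized variance fractions match the configuration at n >= 1000", {
  sim <- simulate_cohort(sim_config(n_samples = 1200, n_probes = 100,
                                    n_snps = 200, n_causal_probes = 5,
                                    n_causal_snps = 40, var_genetic = 0.2,
                                    var_methylation = 0.1, seed = 13))
  # components are rescaled in-sample; only cross-component covariance
  # perturbs the realized fractions (O(1/sqrt(n)))
  mc_se <- 3 / sqrt(1200)
  expect_lt(abs(sim$truth$realized_var_genetic - 0.2), 3 * mc_se)
  expect_lt(abs(sim$truth$realized_var_methylation - 0.1), 3 * mc_se)
})
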