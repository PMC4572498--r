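# methscore

Combining epigenetic and genetic association information to predict
complex traits.

Blood DNA methylation at individual CpG sites associates with traits
such as body mass index strongly enough that a handful of probes,
identified in one cohort, carry predictive information in another. This
package implements the analysis chain that quantifies that information
and asks whether it adds to — or interacts with — what common genetic
variants already explain:

* **MWAS** — per-probe linear regression of a sex/age-adjusted Z-score
  phenotype on residualized, inverse-normal transformed methylation
  M-values;
* **inflation diagnostics** — the mean-χ² genomic inflation factor λ and
  its permutation distribution, whose SD yields the effective number of
  independent probes, M = 2/SD²;
* **probe selection** — Bonferroni thresholding (α/P) plus greedy pruning
  of correlated probes (|r| > 0.1 within 500 bp keeps only the most
  significant);
* **profile scores** — methylation scores Σⱼ wⱼ mᵢⱼ with MWAS effect sizes
  as weights, and polygenic scores Σⱼ wⱼ dᵢⱼ over effect-allele dosages
  with allele harmonization;
* **variance partitioning** — adjusted R² of four nested models
  (methylation score | genetic score | both | both + interaction) with
  marginal t-tests and the interaction ANOVA;
* **family correction** — a GCTA-style GRM, sparsified below relatedness
  0.05, one-component REML, and BLUP residuals as the
  family-structure-corrected phenotype;
* **meta-analysis** — fixed-effect inverse-variance pooling of two MWAS
  result sets over their common probes.

A synthetic-cohort generator (`simulate_cohort()`) with recorded ground
truth emulates the relevant data structure — correlated probe blocks,
Hardy–Weinberg genotypes with optional family structure, controlled
variance fractions, cell-count confounding, plate batch effects — and
drives the package's calibration and recovery tests.

## Worked example

```r
library(methscore)

cfg <- sim_config(n_samples = 750, n_probes = 5000, n_snps = 2000,
                  n_causal_probes = 10, n_causal_snps = 100, seed = 42)
sim <- simulate_cohort(cfg)

res  <- preprocess_methylation(sim$methylation, sim$phenotypes)
z    <- adjust_phenotype(sim$phenotypes$trait, sim$phenotypes$sex,
                         sim$phenotypes$age, sim$phenotypes$sample_id)
scan <- run_mwas(res, z, trait = "bmi")

permutation_lambda(res, z, n_perm = 100, seed = 43)
#> inflation_report: observed lambda = 1.013
#>   100 permutations: mean lambda = 0.998, SD = 0.0308
#>   effective independent probes M = 2/SD^2 = 2114.8

w  <- prune_probes(scan, res, alpha = 0.05)   # Bonferroni: p < 0.05/5000
ms <- methylation_score(res, w)
wg <- data.frame(feature_id = sim$truth$causal_snp_ids,
                 weight = unname(sim$truth$true_snp_effects),
                 effect_allele = sim$genotypes$snps$effect_allele[
                   match(sim$truth$causal_snp_ids, sim$genotypes$snps$snp_id)])
gs <- genetic_score(sim$genotypes, wg)

fit_partition(z, ms, gs)
#> variance_partition (n = 750 )
#>   model 1 (methylation score):        adj R^2 =  0.0245  p = 9.82e-06
#>   model 2 (genetic score):            adj R^2 =  0.1290  p = 1.82e-24
#>   model 3 (additive):                 adj R^2 =  0.1536
#>      marginal p (methylation, genetic) = 2.18e-06, 4.51e-25
#>   model 4 (+ interaction):            adj R^2 =  0.1536  ANOVA p (4 vs 3) = 0.327
```

Reading the output: the permutation lambdas sit at 1 (the scan is
calibrated; the observed λ of 1.013 reflects real signal, not test
miscalibration), and their SD implies ~2,100 effectively independent
probes among the 5,000 — probes in a block are largely redundant. One
probe survives Bonferroni selection at this sample size; its score
explains 2.5% of phenotypic variance, the genetic score 12.9%, the
additive model 15.4% with both scores independently significant, and the
interaction adds nothing (ANOVA p = 0.33) — the two information sources
combine additively.

The methods vignette
(`vignettes/methylation-profile-scores.Rmd`) documents the models,
parameter choices and limitations.

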