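---
title: "Methylation and genetic profile scores: models and methods"
author: "methscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methylation and genetic profile scores: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question the package answers

For a complex trait such as body mass index, how much inter-individual
variance is captured by blood DNA-methylation differences, how much by
common genetic variants, and do the two sources of information add up or
interact? `methscore` implements the full analysis chain needed to answer
this on array-style methylation data (beta values at CpG probes) and SNP
dosages: a methylome-wide association scan (MWAS), construction of
per-individual profile scores, and nested-model variance partitioning,
together with the diagnostics (permutation-based inflation analysis) and
corrections (cell counts, family structure) that make the estimates
interpretable.

## Preprocessing model

Methylation beta values $\beta_{ij} \in [0,1]$ (sample $i$, probe $j$) are
analysed after three fixed steps, in this order:

1. **Logit (M-value) transform**: $m_{ij} = \log(\beta_{ij}/(1-\beta_{ij}))$.
   Exact 0/1 values are clamped to $[\varepsilon, 1-\varepsilon]$ with
   $\varepsilon = 10^{-6}$ (reported as a warning count); without the clamp
   they map to $\pm\infty$.
2. **Residualization**: each probe is regressed on technical variables
   (plate, array, array position; unordered factors) and biological
   covariates (sex, age), with the five blood cell counts (lymphocytes,
   monocytes, neutrophils, eosinophils, basophils) added in a sensitivity
   path. Non-autosomal probes and probes with a known SNP at the target
   CpG are dropped beforehand.
3. **Rank-based inverse-normal transform** with the Blom offset:
   $\Phi^{-1}\!\big((r_{ij} - 3/8)/(n + 1/4)\big)$, ties receiving average
   ranks. The output is invariant to any strictly monotone (hence any
   affine) transform of its input, which makes downstream effect sizes
   comparable across probes.

The trait is adjusted for sex and age by OLS and standardized to a
Z score (`adjust_phenotype()`); all variance fractions quoted below are
fractions of this adjusted phenotype's variance.

Two deliberate numerical choices here: the Blom offset is the common
default for EWAS-style rank transforms (the plain `(r)/(n+1)` variant
differs negligibly at these sample sizes), and arrays are nested within
plates, so a design containing both is rank-deficient by construction.
The low-level `residualize()` treats rank deficiency as an error naming
the collinear columns — silent dropping is dangerous on user-supplied
covariates — while the pipeline wrapper `preprocess_methylation()`
passes `drop_aliased = TRUE`, reproducing `lm()`'s aliased-term
behaviour for the standard technical design. Covariates that are
constant in the analysis sample (for example a single plate in a small
cohort) are dropped with a message before the design is built. Residuals are orthogonal to
the retained columns, hence also to every aliased combination of them.

## The association scan and its diagnostics

`run_mwas()` fits, per probe, the simple regression of the Z-score
phenotype on the residualized/transformed probe value, with two-sided
p-values on $n-2$ df. Because covariates were removed upstream, the
per-probe model needs no further adjustment; the scan is therefore a
one-pass vectorized OLS, and results are bit-identical however the probe
set is chunked.

The inflation factor $\lambda$ is defined as the **mean** 1-df
$\chi^2$ statistic across probes (obtained from each p-value by the
quantile transform, so its null expectation is exactly 1 regardless of
small-sample t-vs-normal discrepancies). This is deliberately not the
conventional median-based $\lambda$; the median variant is available via
`genomic_lambda(x, method = "median")` for comparison. Under probe
independence $\operatorname{Var}(\lambda) = 2/M$ for $M$ probes, so the
SD of $\lambda$ across phenotype permutations estimates the *effective
number of independent probes* $M_\mathrm{eff} = 2/\mathrm{SD}^2$
(`permutation_lambda()`, `effective_probes()`). A permutation SD of 0.1
implies $M_\mathrm{eff} = 200$: methylation probes are strongly
correlated along the genome, and real scans have far fewer independent
tests than probes. The default of 100 permutations estimates the SD to
about ±7% ($\mathrm{SD}/\sqrt{2(n_\mathrm{perm}-1)}$), adequate for an
order-of-magnitude statement; permutations shuffle the phenotype vector
freely because covariate structure is already residualized out.

## Probe selection and pruning

Candidate probes pass a Bonferroni threshold $\alpha/P$ (default
$\alpha = 0.05$); for weakly associated traits an explicit override
(e.g. $p < 10^{-3}$) can replace it. Redundant candidates are removed by
a greedy most-significant-first sweep: a candidate is retained unless an
already-retained probe lies within 500 bp on the same chromosome *and*
has absolute Pearson correlation above 0.1 on the analysis-scale values.
Choices worth stating:

* *absolute* correlation on the residualized/inverse-normal scale — the
  scale on which the weights are estimated;
* "within a window" means pairwise distance $\le$ 500 bp, not fixed
  genomic tiles;
* ties in p are broken by (chromosome, position, probe id), making the
  output independent of input row order;
* a window of 0 or a correlation threshold $\ge 1$ disables pruning.

Every retained probe carries its MWAS effect size as score weight. For
cross-cohort designs (probes selected in one study, weights estimated in
another) `prune_probes(candidates = ...)` takes an external probe list
as-is and only pulls weights.

## Profile scores

Both scores are plain weighted sums. The methylation score is
$\sum_j w_j m_{ij}$ over selected probes on the residualized/transformed
scale — using the scale the weights were estimated on is what makes the
weights meaningful; pass a raw beta matrix explicitly for a
sensitivity check. The genetic score is $\sum_j w_j d_{ij}$ over
effect-allele dosages, with standard polygenic-score conventions: if an
external weight's effect allele matches the dataset's other allele the
dosage is flipped to $2-d$; unmatchable SNPs are dropped and counted;
missing dosages are mean-imputed per SNP. Scores are not internally
standardized (adjusted $R^2$ and the model p-values are invariant to
affine rescaling, so standardization is cosmetic).

## Variance partitioning

`fit_partition()` fits four OLS models — trait on the methylation score,
on the genetic score, on both, and on both plus their product — and
reports each adjusted $R^2$
($1 - (1-R^2)(n-1)/(n-k-1)$, reported as-is: small negative values are
legitimate for uninformative predictors), the marginal coefficient
t-tests of each score inside the additive model (this is the evidence
that each source of information contributes independently), and the
ANOVA F-test of the interaction model against the additive model. Raw
$R^2$ monotonicity across the nested models is asserted on every fit.

## Related samples

For family cohorts three steps precede the partition:

1. `compute_grm()` builds the GCTA-style genetic relationship matrix
   $A_{ik} = m^{-1}\sum_j (x_{ij}-2p_j)(x_{ik}-2p_j)/(2p_j(1-p_j))$
   (monomorphic SNPs skipped, missing dosages mean-imputed). With few
   SNPs or few samples the entries carry the usual small-sample biases
   (off-diagonals centred near $-1/(n-1)$), which is why at least a few
   thousand SNPs are recommended.
2. `threshold_grm()` zeroes off-diagonal relatedness below 0.05
   (entries at exactly 0.05 are kept — the cutoff is strict), so the
   mixed model sees close family structure only;
   `drop_mz_duplicates()` removes one member of any pair with
   relatedness above 0.95 (genetically identical individuals). MZ
   removal is done first and the GRM recomputed on the reduced sample.
3. `family_correct()` fits $y = \mu + g + e$,
   $g \sim N(0, \sigma^2_g A)$, by REML — one eigendecomposition of the
   GRM plus a 1-D search over $h^2 = \sigma^2_g/(\sigma^2_g+\sigma^2_e)$,
   exact for a single relatedness component — and returns the
   restandardized residuals $y - \mu - \mathrm{BLUP}(g)$ as the
   family-structure-corrected phenotype. The SE of $\hat h^2$ comes from
   the observed information of the profiled restricted likelihood
   (finite differences); at a boundary it is reported as `NA`. A
   non-PSD thresholded GRM is repaired by clipping negative eigenvalues
   at zero (with a warning); for an identity-like GRM $h^2$ is
   unidentifiable and the output equals the standardized input.

One property of this correction deserves emphasis: BLUP residuals do not
merely remove family resemblance, they slightly *anti*-correlate within
families (for a family block with phenotypic correlation $r$, the
residual pairwise correlation is $\approx -r$, since
$\operatorname{Cov}(V^{-1}y) = V^{-1}$ has negative off-diagonals). The
family *variance component* of the corrected phenotype — the
intraclass correlation in Fisher's variance-ratio sense — is zero, and
that is what the package's tests verify (via an independent `lme4`
random-intercept fit); the raw pairwise sibling correlation flips from
$+0.5\,h^2$ to a comparable negative value. Downstream regressions are
unaffected: the corrected phenotype carries no shared family signal
that could masquerade as score performance.

## Meta-analysis

`fixed_effect_meta()` pools two scans over their common probe ids with
inverse-variance weights ($\beta = \sum w\beta/\sum w$,
$\mathrm{se} = (\sum w)^{-1/2}$, $w = 1/\mathrm{se}^2$; normal
p-values). Inverse-variance weighting is the standard fixed-effect
estimator; heterogeneity statistics are out of scope. `meta_select()`
applies a Bonferroni cutoff over the *common* probe count, feeding
`prune_probes()` as an external candidate list. Probes are harmonized by
id only — array probe ids are canonical and have no allele-flip concept.

## What the synthetic cohorts emulate — and what they do not

`simulate_cohort()` generates the data structure the analysis assumes,
with recorded ground truth (`sim_truth`) for recovery tests:

* **Probes**: blocks of `probes_per_block` probes (default 5) spanning at
  most `block_size_bp` (default 500 bp) on one synthetic chromosome;
  within-block latent values share a single Gaussian factor giving
  equicorrelation `within_block_r` (default 0.5). Beta values are the
  inverse logit of probe-mean offsets (SD 1.5, covering the (0,1) range)
  plus 0.5 × the latent value, so all lie strictly in (0,1).
* **Genotypes**: Hardy–Weinberg draws at MAF ~ U(0.05, 0.5); family
  structures (`trios`, `sib_pairs`, `mz_pairs`) share genotypes by
  per-SNP Mendelian transmission, MZ pairs by row duplication.
* **Phenotype**: causal-SNP, causal-probe and residual components, each
  rescaled in-sample so the realized variance fractions equal the
  configuration (defaults 0.08 genetic / 0.07 methylation — the
  magnitudes reported for BMI in mid-sized cohorts); causal probes sit
  in distinct blocks so pruning keeps one representative per signal.
  Sex and age effects (age 45.5 ± 13.3 y) are layered on top and removed
  again by `adjust_phenotype()`; the trait is reported on a BMI-like
  scale (25.4 ± 4.2 kg/m²).
* **Nuisance structure**: five cell counts with a configurable loading on
  the phenotype (default 0.3) and typical blood-count magnitudes;
  per-plate, per-probe logit-scale shifts of SD `batch_effect_sd`;
  plate/array/position follow a 96-well, 12-sample-per-array layout.
* **meQTL switch**: methylation and genotype are independent by default
  (the joint distribution is not identified by the study design);
  `snp_probe_effect` adds SNP→probe loadings for interaction
  experiments.

Not emulated: probe-type chemistry differences, age-related methylation
drift, genome-wide LD decay (equicorrelated blocks only), population
stratification, longitudinal sampling. Passing recovery tests on these
cohorts therefore demonstrates correctness of the estimators under the
assumed structure, not robustness to everything real data can do.

## Problem sizes used by the test suite

The suite exercises the calibration claims at deliberately chosen sizes:
null-lambda calibration on a 500-sample × 20,000-probe cohort with 100
permutations; effective-probe recovery on independent probes at
n = 4,000 × 1,000 probes × 200 permutations; additive-recovery on 100
replicates of n = 1,500 cohorts (8% genetic + 7% methylation → 15%
additive, each mean within 3 Monte-Carlo SE); interaction-test
calibration on 500 null replicates (KS uniformity at α = 0.01); REML
recovery on 300 sib pairs at $h^2 = 0.5$. The whole suite runs in about
a minute on one core.

## Known limitations

* The MWAS is plain OLS; robust-SE or mixed-model per-probe scans and
  bacon-style inflation correction are out of scope (inflation is
  *diagnosed*, not corrected).
* `fixed_effect_meta()` pools exactly two studies.
* The REML machinery handles one relatedness component; multi-component
  variance decomposition is a non-goal.
* Raw array processing (IDAT import, normalization, detection-p QC) is
  assumed done upstream; the package starts from a beta matrix.
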