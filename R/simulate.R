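# Synthetic cohort generator. Emulates the data structure the pipeline
# assumes -- correlated CpG probe blocks on a genome, Hardy-Weinberg
# genotypes with optional family structure, a phenotype composed of
# genetic, methylation-linked and residual variance components at
# controlled fractions, cell-count confounding and plate batch effects --
# and records the generating truth for recovery tests.

#' Simulation configuration
#'
#' Collects and validates all knobs of the synthetic-cohort generator.
#' Defaults describe a single mid-sized population cohort: 750 unrelated
#' adults (mean age 45.5, SD 13.3 years), a BMI-like trait with a genetic
#' component of 8% and a methylation-linked component of 7% of phenotypic
#' variance, and CpG probes arranged in equicorrelated blocks of 5 probes
#' spanning at most 500 bp.
#'
#' @param n_samples number of individuals.
#' @param n_probes number of CpG probes.
#' @param n_snps number of SNPs.
#' @param block_size_bp maximum genomic span (bp) of one probe block.
#' @param probes_per_block probes per correlated block (1 = independent
#'   probes).
#' @param within_block_r target pairwise correlation of latent methylation
#'   within a block, in \[0, 1); induced by a single shared Gaussian
#'   factor (equicorrelation).
#' @param var_genetic fraction of phenotypic variance from causal SNPs.
#' @param var_methylation fraction of phenotypic variance from causal
#'   probes. `var_genetic + var_methylation` must not exceed 1.
#' @param n_causal_probes number of causal probes; placed in distinct
#'   blocks so correlation pruning can retain one representative per
#'   signal.
#' @param n_causal_snps number of causal SNPs.
#' @param family_structure one of `"unrelated"`, `"trios"`,
#'   `"sib_pairs"`, `"mz_pairs"`. Families share genotypes by Mendelian
#'   transmission; MZ pairs duplicate genotype rows.
#' @param cellcount_confounding loading of the phenotype on the five
#'   simulated blood cell counts (0 = independent counts).
#' @param batch_effect_sd SD of per-plate, per-probe shifts added to
#'   methylation on the logit scale (0 = no batch effects).
#' @param snp_probe_effect if nonzero, each probe additionally loads on a
#'   randomly assigned driver SNP with this coefficient (a crude meQTL
#'   switch; default keeps methylation and genotype independent).
#' @param seed integer seed; the same configuration yields bit-identical
#'   cohorts.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 750,
                       n_probes = 5000,
                       n_snps = 2000,
                       block_size_bp = 500,
                       probes_per_block = 5,
                       within_block_r = 0.5,
                       var_genetic = 0.08,
                       var_methylation = 0.07,
                       n_causal_probes = 10,
                       n_causal_snps = 100,
                       family_structure = c("unrelated", "trios",
                                            "sib_pairs", "mz_pairs"),
                       cellcount_confounding = 0.3,
                       batch_effect_sd = 0,
                       snp_probe_effect = 0,
                       seed = 1L) {
  family_structure <- match.arg(family_structure)
  cfg <- list(n_samples = as.integer(n_samples),
              n_probes = as.integer(n_probes),
              n_snps = as.integer(n_snps),
              block_size_bp = as.integer(block_size_bp),
              probes_per_block = as.integer(probes_per_block),
              within_block_r = within_block_r,
              var_genetic = var_genetic,
              var_methylation = var_methylation,
              n_causal_probes = as.integer(n_causal_probes),
              n_causal_snps = as.integer(n_causal_snps),
              family_structure = family_structure,
              cellcount_confounding = cellcount_confounding,
              batch_effect_sd = batch_effect_sd,
              snp_probe_effect = snp_probe_effect,
              seed = as.integer(seed))
  err <- function(...) stop("configuration error: ", sprintf(...), call. = FALSE)
  with(cfg, {
    if (n_samples < 2 || n_probes < 1 || n_snps < 1)
      err("counts must be positive (n_samples >= 2)")
    if (probes_per_block < 1) err("probes_per_block must be >= 1")
    if (within_block_r < 0 || within_block_r >= 1)
      err("within_block_r must lie in [0, 1)")
    if (var_genetic < 0 || var_methylation < 0)
      err("variance fractions must be nonnegative")
    if (var_genetic + var_methylation > 1)
      err("var_genetic + var_methylation = %.3f exceeds 1",
          var_genetic + var_methylation)
    if (n_causal_probes > n_probes)
      err("n_causal_probes (%d) exceeds n_probes (%d)", n_causal_probes, n_probes)
    if (n_causal_snps > n_snps)
      err("n_causal_snps (%d) exceeds n_snps (%d)", n_causal_snps, n_snps)
    n_blocks <- ceiling(n_probes / probes_per_block)
    if (n_causal_probes > n_blocks)
      err("n_causal_probes (%d) exceeds the number of probe blocks (%d); causal probes are placed in distinct blocks",
          n_causal_probes, n_blocks)
    if (var_methylation > 0 && n_causal_probes < 1)
      err("var_methylation > 0 requires at least one causal probe")
    if (var_genetic > 0 && n_causal_snps < 1)
      err("var_genetic > 0 requires at least one causal SNP")
    if (batch_effect_sd < 0) err("batch_effect_sd must be nonnegative")
  })
  structure(cfg, class = "sim_config")
}

# Hardy-Weinberg genotype matrix: rows individuals, one column per SNP
.hwe_genotypes <- function(n, maf) {
  m <- length(maf)
  matrix(rbinom(n * m, 2L, rep(maf, each = n)), nrow = n, ncol = m)
}

# one transmitted allele per SNP from each parent (Mendelian)
.transmit <- function(parents) {
  matrix(rbinom(length(parents), 1L, as.vector(parents) / 2),
         nrow = nrow(parents))
}

# genotypes + family assignment under the requested structure
.sim_genotypes <- function(n, maf, structure) {
  m <- length(maf)
  dosage <- matrix(0L, n, m)
  fam <- integer(n)
  fill_singletons <- function(idx, next_fam) {
    if (length(idx)) {
      dosage[idx, ] <<- .hwe_genotypes(length(idx), maf)
      fam[idx] <<- next_fam + seq_along(idx) - 1L
    }
  }
  if (structure == "unrelated") {
    dosage <- .hwe_genotypes(n, maf)
    fam <- seq_len(n)
  } else if (structure == "mz_pairs") {
    k <- n %/% 2L
    base <- .hwe_genotypes(k, maf)
    i1 <- seq(1L, by = 2L, length.out = k)
    dosage[i1, ] <- base
    dosage[i1 + 1L, ] <- base
    fam[i1] <- fam[i1 + 1L] <- seq_len(k)
    fill_singletons(if (n %% 2L) n else integer(0), k + 1L)
  } else if (structure == "sib_pairs") {
    k <- n %/% 2L
    fa <- .hwe_genotypes(k, maf)
    mo <- .hwe_genotypes(k, maf)
    i1 <- seq(1L, by = 2L, length.out = k)
    dosage[i1, ] <- .transmit(fa) + .transmit(mo)
    dosage[i1 + 1L, ] <- .transmit(fa) + .transmit(mo)
    fam[i1] <- fam[i1 + 1L] <- seq_len(k)
    fill_singletons(if (n %% 2L) n else integer(0), k + 1L)
  } else { # trios: father, mother, offspring
    k <- n %/% 3L
    fa <- .hwe_genotypes(k, maf)
    mo <- .hwe_genotypes(k, maf)
    i1 <- seq(1L, by = 3L, length.out = k)
    dosage[i1, ] <- fa
    dosage[i1 + 1L, ] <- mo
    dosage[i1 + 2L, ] <- .transmit(fa) + .transmit(mo)
    fam[i1] <- fam[i1 + 1L] <- fam[i1 + 2L] <- seq_len(k)
    fill_singletons(setdiff(seq_len(n), c(i1, i1 + 1L, i1 + 2L)), k + 1L)
  }
  list(dosage = dosage, family = sprintf("F%04d", fam))
}

#' Simulate a cohort with methylation, genotypes, phenotype and truth
#'
#' Generates one synthetic cohort under a [sim_config()]. Genotypes are
#' drawn per SNP under Hardy-Weinberg equilibrium with minor allele
#' frequencies uniform on (0.05, 0.5); probes are placed in blocks on a
#' single synthetic chromosome, with a shared Gaussian factor per block
#' giving the configured within-block correlation; beta values are the
#' inverse logit of the latent methylation, so all lie strictly in (0, 1).
#' The phenotype is the sum of a causal-SNP component, a causal-probe
#' component and Gaussian noise, each rescaled so the realized in-sample
#' variance fractions match the configuration; sex and age effects are
#' then layered on top (and are removed again by [adjust_phenotype()]).
#'
#' @param config a [sim_config()] object.
#' @return list with elements
#'   \describe{
#'     \item{methylation}{[methylation_dataset()]}
#'     \item{genotypes}{[genotype_dataset()]}
#'     \item{phenotypes}{data.frame with `sample_id`, `trait` (BMI-like,
#'       kg/m^2), `sex`, `age`, five cell counts, `plate`, `array`,
#'       `array_position`, `family_id`}
#'     \item{truth}{class `sim_truth`: causal ids, true effects (per
#'       dosage unit for SNPs, per latent-SD unit for probes), realized
#'       variance fractions, family assignments, the seed}
#'   }
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config"))
    stop("config must be built with sim_config()")
  set.seed(config$seed)
  n <- config$n_samples
  P <- config$n_probes
  m <- config$n_snps
  sample_ids <- sprintf("S%04d", seq_len(n))

  ## --- genotypes -----------------------------------------------------
  maf <- runif(m, 0.05, 0.5)
  bases <- c("A", "C", "G", "T")
  other <- sample(bases, m, replace = TRUE)
  effect <- vapply(other, function(b) resample(setdiff(bases, b), 1L), "")
  g <- .sim_genotypes(n, maf, config$family_structure)
  snp_ids <- sprintf("snp_%05d", seq_len(m))
  dosage <- g$dosage
  dimnames(dosage) <- list(sample_ids, snp_ids)
  snps <- data.frame(snp_id = snp_ids, chrom = "2",
                     pos = seq(10000L, by = 5000L, length.out = m),
                     effect_allele = unname(effect), other_allele = other,
                     stringsAsFactors = FALSE)

  ## --- probe placement and latent methylation ------------------------
  k <- config$probes_per_block
  n_blocks <- ceiling(P / k)
  block_id <- rep(seq_len(n_blocks), each = k)[seq_len(P)]
  block_start <- (block_id - 1L) * (10L * config$block_size_bp) + 1L
  offsets <- unlist(lapply(split(seq_len(P), block_id), function(ix) {
    kb <- length(ix)
    if (kb == 1L) 0L else as.integer(round(seq(0, config$block_size_bp,
                                               length.out = kb)))
  }), use.names = FALSE)
  pos <- block_start + offsets
  probe_ids <- sprintf("cg%08d", seq_len(P))
  probes <- data.frame(probe_id = probe_ids, chrom = "1", pos = pos,
                       snp_at_target = FALSE, autosomal = TRUE,
                       stringsAsFactors = FALSE)

  r <- config$within_block_r
  fac <- matrix(rnorm(n * n_blocks), n, n_blocks)
  latent <- sqrt(r) * fac[, block_id, drop = FALSE] +
    sqrt(1 - r) * matrix(rnorm(n * P), n, P)
  if (config$snp_probe_effect != 0) {
    driver <- sample.int(m, P, replace = TRUE)
    zd <- scale(dosage)
    zd[, apply(dosage, 2, var) == 0] <- 0
    latent <- latent + config$snp_probe_effect * zd[, driver, drop = FALSE]
  }

  ## --- phenotype components ------------------------------------------
  causal_snps <- sort(resample(seq_len(m), config$n_causal_snps))
  causal_blocks <- resample(seq_len(n_blocks), config$n_causal_probes)
  causal_probes <- sort(vapply(causal_blocks,
                               function(b) resample(which(block_id == b), 1L),
                               integer(1)))
  scale_to <- function(x, v) {
    if (v == 0) return(list(x = numeric(n), k = 0))
    s <- sd(x)
    if (s < 1e-12) stop("degenerate component in simulation (zero variance)")
    list(x = x * sqrt(v) / s, k = sqrt(v) / s)
  }
  b_snp_raw <- rnorm(config$n_causal_snps)
  b_probe_raw <- rnorm(config$n_causal_probes)
  g_comp <- if (config$var_genetic > 0) {
    xc <- scale(dosage[, causal_snps, drop = FALSE], scale = FALSE)
    scale_to(as.vector(xc %*% b_snp_raw), config$var_genetic)
  } else list(x = numeric(n), k = 0)
  m_comp <- if (config$var_methylation > 0) {
    lc <- scale(latent[, causal_probes, drop = FALSE], scale = FALSE)
    scale_to(as.vector(lc %*% b_probe_raw), config$var_methylation)
  } else list(x = numeric(n), k = 0)
  e_comp <- scale_to(rnorm(n), 1 - config$var_genetic - config$var_methylation)
  y_core <- g_comp$x + m_comp$x + e_comp$x
  vy <- var(y_core)

  ## --- covariates, batch, observable trait ---------------------------
  sex <- sample(c("F", "M"), n, replace = TRUE)
  age <- rnorm(n, 45.5, 13.3)
  well <- sample.int(n)                       # randomized plate layout
  plate <- sprintf("P%02d", (well - 1L) %/% 96L + 1L)
  array <- sprintf("A%03d", (well - 1L) %/% 12L + 1L)
  array_position <- sprintf("R%02d", (well - 1L) %% 12L + 1L)
  if (config$batch_effect_sd > 0) {
    plates <- sort(unique(plate))
    shift <- matrix(rnorm(length(plates) * P, sd = config$batch_effect_sd),
                    length(plates), P, dimnames = list(plates, NULL))
    latent_obs <- 0.5 * latent + shift[plate, , drop = FALSE]
  } else latent_obs <- 0.5 * latent
  mu_probe <- rnorm(P, 0, 1.5)
  beta <- stats::plogis(sweep(latent_obs, 2, mu_probe, "+"))
  dimnames(beta) <- list(sample_ids, probe_ids)

  y_std <- if (vy > 0) (y_core - mean(y_core)) / sqrt(vy) else y_core
  cc_mu <- c(lymphocytes = 2.0, monocytes = 0.5, neutrophils = 4.0,
             eosinophils = 0.2, basophils = 0.05)
  cc_sd <- c(0.6, 0.15, 1.2, 0.12, 0.03)
  cells <- sapply(seq_along(cc_mu), function(j) {
    pmax(0, cc_mu[j] + cc_sd[j] *
           (config$cellcount_confounding * y_std + rnorm(n)))
  })
  colnames(cells) <- names(cc_mu)

  y_obs <- y_core + 0.2 * (age - 45.5) / 13.3 + 0.1 * (sex == "M")
  trait <- 25.4 + 4.2 * y_obs

  phenotypes <- data.frame(sample_id = sample_ids, trait = trait,
                           sex = sex, age = age, cells,
                           plate = plate, array = array,
                           array_position = array_position,
                           family_id = g$family,
                           stringsAsFactors = FALSE)

  truth <- structure(list(
    causal_probe_ids = probe_ids[causal_probes],
    causal_snp_ids = snp_ids[causal_snps],
    true_probe_effects = setNames(b_probe_raw * m_comp$k,
                                  probe_ids[causal_probes]),
    true_snp_effects = setNames(b_snp_raw * g_comp$k, snp_ids[causal_snps]),
    realized_var_genetic = var(g_comp$x) / vy,
    realized_var_methylation = var(m_comp$x) / vy,
    family_assignments = setNames(g$family, sample_ids),
    maf = maf,
    seed = config$seed,
    config = unclass(config)), class = "sim_truth")

  list(methylation = methylation_dataset(beta, probes),
       genotypes = genotype_dataset(dosage, snps),
       phenotypes = phenotypes,
       truth = truth)
}
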