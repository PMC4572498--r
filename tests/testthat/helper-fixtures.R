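# Small programmatic fixtures shared across test files.

# a tiny methylation dataset with explicit values and annotation
tiny_meth <- function() {
  beta <- matrix(c(0.10, 0.20,
                   0.50, 0.60,
                   0.90, 0.30),
                 nrow = 2, ncol = 3,
                 dimnames = list(c("s1", "s2"), c("cgA", "cgB", "cgC")))
  ann <- data.frame(probe_id = c("cgA", "cgB", "cgC"), chrom = "1",
                    pos = c(100L, 350L, 5000L))
  methylation_dataset(beta, ann)
}

tiny_geno <- function() {
  dosage <- matrix(c(0, 1, 2,
                     2, 1, 0),
                   nrow = 3, ncol = 2,
                   dimnames = list(c("s1", "s2", "s3"), c("rsA", "rsB")))
  snps <- data.frame(snp_id = c("rsA", "rsB"), chrom = "2",
                     pos = c(1000L, 2000L),
                     effect_allele = c("A", "C"), other_allele = c("G", "T"))
  genotype_dataset(dosage, snps)
}

# wrap a matrix of residualized values as a resid_methylation object
as_resid <- function(values, chrom = "1", pos = NULL) {
  structure(list(values = values,
                 probes = data.frame(probe_id = colnames(values),
                                     chrom = chrom,
                                     pos = pos %||% seq(100L, by = 1000L,
                                                        length.out = ncol(values)),
                                     snp_at_target = FALSE, autosomal = TRUE),
                 adjustment_set = character(0),
                 sample_ids = rownames(values)),
            class = "resid_methylation")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# a random pruning instance: n_cand candidate probes in clumps with
# correlated values, plus an mwas_result carrying their p-values
random_prune_instance <- function(n_cand = 20, n = 120) {
  n_groups <- max(2L, rpois(1, 5) + 1L)
  grp <- sample.int(n_groups, n_cand, replace = TRUE)
  chrom <- as.character(sample(1:2, n_groups, replace = TRUE))[grp]
  pos <- sample(0:800, n_cand, replace = TRUE) + grp * 10000L
  fac <- matrix(rnorm(n * n_groups), n)
  lam <- runif(n_cand)  # per-probe loading on its group factor
  values <- sapply(seq_len(n_cand), function(j)
    sqrt(lam[j]) * fac[, grp[j]] + sqrt(1 - lam[j]) * rnorm(n))
  colnames(values) <- sprintf("cg%03d", seq_len(n_cand))
  rownames(values) <- sprintf("s%03d", seq_len(n))
  res <- data.frame(probe_id = colnames(values),
                    beta = rnorm(n_cand), se = runif(n_cand, 0.05, 0.2),
                    t = 0, p = runif(n_cand, 1e-12, 1e-4), n = n)
  class(res) <- c("mwas_result", "data.frame")
  meth <- as_resid(values, chrom = chrom, pos = pos)
  list(results = res, methylation = meth)
}
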