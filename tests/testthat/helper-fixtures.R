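# Small fixture builders used across the suite. All randomness is locally
# seeded so tests are order-independent.

# Random aligned effect pairs with heterogeneous precision.
rand_dataset <- function(k, seed, theta = 0.3, noise = 0) {
  set.seed(seed)
  bx <- runif(k, 0.02, 0.2) * sample(c(-1, 1), k, replace = TRUE)
  sy <- runif(k, 0.005, 0.05)
  by <- theta * bx + rnorm(k, 0, noise) + rnorm(k, 0, sy)
  mr_dataset(sprintf("v%03d", seq_len(k)), bx, runif(k, 0.001, 0.01),
             by, sy)
}

# Minimal well-formed summary-statistic data frame.
toy_stats <- function(variant_id = c("rs1", "rs2", "rs3"),
                      chrom = "1",
                      pos = c(1e5, 2e6, 4e6),
                      effect_allele = c("A", "C", "G"),
                      other_allele = c("G", "T", "C"),
                      eaf = c(0.2, 0.3, 0.4),
                      beta = c(0.1, -0.05, 0.08),
                      se = c(0.01, 0.012, 0.02),
                      pvalue = c(1e-20, 1e-9, 1e-8),
                      n = 10000) {
  data.frame(variant_id = variant_id, chrom = chrom, pos = pos,
             effect_allele = effect_allele, other_allele = other_allele,
             eaf = eaf, beta = beta, se = se, pvalue = pvalue, n = n,
             stringsAsFactors = FALSE)
}

toy_sumstats <- function(..., trait_id = "trait",
                         trait_type = "continuous") {
  as_gwas_sumstats(toy_stats(...), trait_id = trait_id,
                   trait_type = trait_type)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}
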