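test_that("significance filtering keeps exactly the sub-threshold rows in order", {
  stats <- toy_sumstats(pvalue = c(1e-9, 4e-8, 6e-8))
  kept <- select_candidates(stats, 5e-8)
  expect_equal(kept$variant_id, c("rs1", "rs2"))
  expect_equal(nrow(select_candidates(stats, 1e-10)), 0L)
  expect_equal(nrow(select_candidates(stats, 1)), 3L)
})

test_that("the distance rule alone collapses a 1-Mb cluster to its best variant", {
  stats <- toy_sumstats(pos = c(1, 5e5, 9e5), pvalue = c(1e-10, 1e-9, 1e-8))
  iset <- ld_clump(stats, window_bp = 1e6)
  expect_equal(iset$variants$variant_id, "rs1")
  two_chrom <- toy_sumstats(variant_id = c("rs1", "rs2", "rs3"),
                            chrom = c("1", "2", "2"),
                            pos = c(1e5, 1e5, 5e7))
  expect_equal(nrow(ld_clump(two_chrom)$variants), 3L)
})

test_that("LD pruning discards variants linked to an accepted variant", {
  stats <- toy_sumstats(chrom = c("1", "2", "3"),
                        pvalue = c(1e-12, 1e-10, 1e-9))
  ld <- ld_source_table(data.frame(id_a = c("rs1", "rs1"),
                                   id_b = c("rs2", "rs3"),
                                   r2 = c(0.5, 0.005)))
  iset <- ld_clump(stats, ld = ld, r2_threshold = 0.01)
  expect_setequal(iset$variants$variant_id, c("rs1", "rs3"))
  strict <- ld_clump(stats, ld = ld, r2_threshold = 0.001)
  expect_equal(strict$variants$variant_id, "rs1")
})

test_that("greedy clumping matches an independent rule-replay oracle", {
  set.seed(101)
  for (rep in 1:5) {
    k <- 20
    df <- toy_stats(variant_id = sprintf("s%02d", 1:k),
                    chrom = as.character(sample(1:3, k, replace = TRUE)),
                    pos = sample(1:5e6, k),
                    effect_allele = "A", other_allele = "G",
                    eaf = runif(k, 0.1, 0.9),
                    beta = rnorm(k, 0, 0.1), se = runif(k, 0.005, 0.02),
                    pvalue = runif(k, 1e-12, 1e-4), n = 1e5)
    stats <- as_gwas_sumstats(df, "t")
    pairs <- t(combn(df$variant_id, 2))
    ld_tab <- data.frame(id_a = pairs[, 1], id_b = pairs[, 2],
                         r2 = sample(c(0, 0, 0.3), nrow(pairs),
                                     replace = TRUE))
    ld <- ld_source_table(ld_tab)
    iset <- ld_clump(stats, ld = ld, r2_threshold = 0.01, window_bp = 1e6)
    # independent oracle: walk variants in p order, keep those compatible
    # with every previously kept variant under both rules
    ord <- df[order(df$pvalue, df$chrom, df$pos, df$variant_id), ]
    kept <- character()
    for (i in seq_len(nrow(ord))) {
      v <- ord[i, ]
      ok <- TRUE
      for (u in kept) {
        urow <- ord[ord$variant_id == u, ]
        if (ld_r2(ld, v$variant_id, u) > 0.01 ||
            (urow$chrom == v$chrom && abs(urow$pos - v$pos) < 1e6)) {
          ok <- FALSE
          break
        }
      }
      if (ok) kept <- c(kept, v$variant_id)
    }
    expect_setequal(iset$variants$variant_id, kept)
  }
})

test_that("clumping is invariant to input row order and idempotent", {
  set.seed(77)
  df <- toy_stats(variant_id = sprintf("s%02d", 1:12),
                  chrom = as.character(sample(1:4, 12, replace = TRUE)),
                  pos = sample(1:1e7, 12),
                  effect_allele = "A", other_allele = "G",
                  eaf = 0.3, beta = 0.05, se = 0.01,
                  pvalue = rep(1e-9, 12), n = 1e5)  # all ties
  stats <- as_gwas_sumstats(df, "t")
  shuffled <- as_gwas_sumstats(df[sample(12), ], "t")
  a <- ld_clump(stats)$variants$variant_id
  b <- ld_clump(shuffled)$variants$variant_id
  expect_identical(a, b)
  again <- ld_clump(ld_clump(stats)$variants)
  expect_identical(again$variants$variant_id, a)
})

test_that("candidates without positions are rejected by name", {
  df <- toy_stats()
  df$pos[2] <- NA
  expect_error(ld_clump(as_gwas_sumstats(df, "t")), "rs2",
               class = "mrkit_validation_error")
})

test_that("F-statistics are (beta/se)^2 and flag weak instruments under F < 10", {
  d <- data.frame(beta = c(0.1, 0, 0.03), se = c(0.01, 0.01, 0.01))
  f <- f_statistic(d)
  expect_equal(f, c(100, 0, 9))
  expect_equal(which(f < 10), c(2L, 3L))
  expect_error(f_statistic(data.frame(beta = 1, se = 0)),
               class = "mrkit_validation_error")
})

test_that("continuous variance explained inverts the F quantile", {
  # independent oracle: solve pf(F, 1, n - 2, lower = FALSE) = p by root search
  oracle <- function(p, n) {
    f <- uniroot(function(f) pf(f, 1, n - 2, lower.tail = FALSE) - p,
                 c(0, 1e4), tol = 1e-12)$root
    f / (f + n - 2)
  }
  expect_equal(variance_explained_continuous(0.05, 102), oracle(0.05, 102),
               tolerance = 1e-8)
  expect_equal(variance_explained_continuous(0.05, 102), 0.0379,
               tolerance = 1e-3)
  expect_equal(variance_explained_continuous(1, 100), 0)
  expect_gt(variance_explained_continuous(1e-300, 100), 0.9)
  grid <- 10^seq(-10, -0.1, length.out = 100)
  r2 <- variance_explained_continuous(grid, 5000)
  expect_true(all(diff(r2) < 0))  # smaller p (earlier) -> larger r2
  expect_error(variance_explained_continuous(0.05, 2),
               class = "mrkit_validation_error")
})

test_that("binary variance explained is liability-scale and symmetric", {
  expect_equal(variance_explained_binary(0, 0.3, 100, 900), 0)
  expect_equal(variance_explained_binary(0.4, 0.3, 100, 900),
               variance_explained_binary(-0.4, 0.7, 100, 900))
  expect_error(variance_explained_binary(0.4, 0, 100, 900),
               class = "mrkit_validation_error")
  expect_error(variance_explained_binary(0.4, 0.3, 100, 900, prevalence = 1),
               class = "mrkit_validation_error")
})

test_that("summed binary variance explained recovers a known liability heritability", {
  # forward-construct log ORs from liability effects via the same threshold
  # model written independently here, add sampling noise, and recover the sum
  set.seed(2024)
  k <- 40
  prev <- 0.05
  z <- dnorm(qnorm(1 - prev))
  eaf <- runif(k, 0.1, 0.9)
  h2 <- 0.03
  shares <- rexp(k); shares <- shares / sum(shares)
  b_liab <- sqrt(h2 * shares / (2 * eaf * (1 - eaf)))
  log_or <- b_liab * z / (prev * (1 - prev))
  n_case <- 2e4; n_control <- 3.8e5
  se <- 1 / sqrt(2 * eaf * (1 - eaf) * effective_n(n_case, n_control))
  reps <- 200
  sums <- replicate(reps, {
    obs <- rnorm(k, log_or, se)
    sum(variance_explained_binary(obs, eaf, n_case, n_control,
                                  prevalence = prev))
  })
  mc_se <- sd(sums) / sqrt(reps)
  # sampling noise inflates E[beta^2] by sum(se^2)-worth of liability r2
  noise_bias <- sum(2 * eaf * (1 - eaf) * (se * prev * (1 - prev) / z)^2)
  expect_lt(abs(mean(sums) - noise_bias - h2), 3 * mc_se)
})

test_that("instrument sets carry per-variant diagnostics and config", {
  stats <- toy_sumstats(n = 50000)
  iset <- ld_clump(stats, r2_threshold = 0.01, window_bp = 1e6)
  expect_s3_class(iset, "instrument_set")
  expect_equal(iset$selection_config$r2_threshold, 0.01)
  expect_equal(length(iset$f_statistic), nrow(iset$variants))
  expect_true(all(iset$f_statistic >= 0))
  expect_true(sum(iset$r2_explained, na.rm = TRUE) >= 0)
  expect_true(sum(iset$r2_explained, na.rm = TRUE) <= 1)
})

test_that("LD sources obey the lookup contract", {
  tab <- data.frame(id_a = "a", id_b = "b", r2 = 0.7)
  ld <- ld_source_table(tab)
  expect_equal(ld_r2(ld, "a", "b"), 0.7)
  expect_equal(ld_r2(ld, "b", "a"), 0.7)   # symmetry
  expect_equal(ld_r2(ld, "a", "a"), 1)     # identity
  expect_equal(ld_r2(ld, "a", "zzz"), 0)   # absent pair
  mat <- matrix(c(1, 0.2, 0.2, 1), 2, 2,
                dimnames = list(NULL, c("x", "y")))
  expect_equal(ld_r2(ld_source_matrix(mat), "x", "y"), 0.2)
  expect_error(ld_source_table(data.frame(id_a = "a", id_b = "b", r2 = 2)),
               class = "mrkit_config_error")
})

test_that("LD files in both dialects read back the same lookups", {
  tab <- data.frame(id_a = c("a", "a"), id_b = c("b", "c"),
                    r2 = c(0.5, 0.02))
  p1 <- write_tsv(tab, withr::local_tempfile(fileext = ".tsv"))
  mat <- matrix(c(1, 0.5, 0.02, 0.5, 1, 0, 0.02, 0, 1), 3, 3,
                dimnames = list(NULL, c("a", "b", "c")))
  p2 <- write_tsv(as.data.frame(mat), withr::local_tempfile(fileext = ".tsv"))
  ld1 <- read_ld_source(p1)
  ld2 <- read_ld_source(p2)
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    expect_equal(ld_r2(ld1, pair[1], pair[2]), ld_r2(ld2, pair[1], pair[2]))
  }
})

test_that("candidates absent from a real LD source trigger a warning", {
  stats <- toy_sumstats(chrom = c("1", "2", "3"))
  ld <- ld_source_table(data.frame(id_a = "rs1", id_b = "rs2", r2 = 0))
  expect_warning(ld_clump(stats, ld = ld), "absent from the LD source")
  expect_silent(ld_clump(stats))  # the explicit empty source is quiet
})
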