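# Summary-statistic simulator: paired exposure/outcome GWAS tables with
# known causal truth, emulating the regime of large published GWASs feeding
# a two-sample MR of a rare binary outcome.
#
# Effects are generated directly on the summary scale: a continuous exposure
# with per-variant effects gamma_j sized to hit a target variance explained,
# and a binary outcome on the log-odds scale whose sampling error uses the
# effective sample size 4/(1/n_case + 1/n_control), so extreme case/control
# imbalance propagates into the outcome standard errors. Instruments are
# oriented to the exposure-increasing allele (gamma_j > 0), the convention of
# published MR instrument tables; directional pleiotropy is defined relative
# to that orientation.

#' Pleiotropy regimes for the simulator
#'
#' `pleiotropy_none()` satisfies the exclusion-restriction assumption;
#' `pleiotropy_balanced(sd)` draws direct variant-outcome effects with mean
#' zero (InSIDE holds, no directional bias); `pleiotropy_directional(mean,
#' sd)` shifts them, biasing IVW and moving the Egger intercept off zero.
#'
#' @param sd Standard deviation of the per-variant direct effects
#'   (log-odds).
#' @param mean Mean direct effect (log-odds).
#' @return A `pleiotropy_spec`.
#' @export
pleiotropy_none <- function() {
  structure(list(type = "none", mean = 0, sd = 0), class = "pleiotropy_spec")
}

#' @rdname pleiotropy_none
#' @export
pleiotropy_balanced <- function(sd) {
  stopifnot(is_scalar_number(sd), sd >= 0)
  structure(list(type = "balanced", mean = 0, sd = sd),
            class = "pleiotropy_spec")
}

#' @rdname pleiotropy_none
#' @export
pleiotropy_directional <- function(mean, sd = abs(mean) / 2) {
  stopifnot(is_scalar_number(mean), is_scalar_number(sd), sd >= 0)
  structure(list(type = "directional", mean = mean, sd = sd),
            class = "pleiotropy_spec")
}

#' Simulation configuration
#'
#' Defaults emulate the study regime this simulator is built around: ~50
#' approximately independent instruments jointly explaining ~2% of a
#' continuous exposure measured in a GWAS of ~339,000 people, against a
#' binary outcome with extreme case/control imbalance (6,406 cases /
#' 902,088 controls). Per-variant variance-explained shares are exponential
#' by default, matching the strongly skewed per-locus contributions of real
#' complex-trait GWASs.
#'
#' @param n_variants Number of instruments.
#' @param n_exposure Exposure GWAS sample size.
#' @param n_case,n_control Outcome case and control counts.
#' @param theta True causal effect (outcome log-odds per exposure SD).
#' @param pleiotropy A `pleiotropy_spec` (see [pleiotropy_none()]).
#' @param total_r2 Total exposure variance explained by the instruments.
#' @param r2_distribution `"exponential"` (skewed shares) or `"equal"`.
#' @param eaf_range Range of the uniform effect-allele-frequency draw.
#' @param palindrome_fraction Fraction of variants assigned palindromic
#'   (A/T or C/G) allele pairs.
#' @param exposure_id,outcome_id Trait identifiers.
#' @param seed Integer seed; all draws derive from it.
#' @return A `sim_config`.
#' @export
sim_config <- function(n_variants = 50, n_exposure = 339224,
                       n_case = 6406, n_control = 902088,
                       theta = 0, pleiotropy = pleiotropy_none(),
                       total_r2 = 0.02,
                       r2_distribution = c("exponential", "equal"),
                       eaf_range = c(0.05, 0.95),
                       palindrome_fraction = 0.1,
                       exposure_id = "exposure", outcome_id = "outcome",
                       seed = 1) {
  r2_distribution <- match.arg(r2_distribution)
  stopifnot(is_scalar_number(n_variants), n_variants >= 1,
            is_scalar_number(n_exposure), n_exposure > 2,
            is_scalar_number(n_case), n_case > 0,
            is_scalar_number(n_control), n_control > 0,
            is_scalar_number(theta),
            inherits(pleiotropy, "pleiotropy_spec"),
            is_scalar_number(total_r2), total_r2 > 0, total_r2 < 1,
            length(eaf_range) == 2L, eaf_range[1] > 0, eaf_range[2] < 1,
            eaf_range[1] < eaf_range[2],
            is_scalar_number(palindrome_fraction),
            palindrome_fraction >= 0, palindrome_fraction <= 1,
            is_scalar_number(seed))
  structure(list(n_variants = as.integer(n_variants),
                 n_exposure = n_exposure, n_case = n_case,
                 n_control = n_control, theta = theta,
                 pleiotropy = pleiotropy, total_r2 = total_r2,
                 r2_distribution = r2_distribution, eaf_range = eaf_range,
                 palindrome_fraction = palindrome_fraction,
                 exposure_id = exposure_id, outcome_id = outcome_id,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Effective sample size of an unbalanced case/control GWAS
#' @param n_case,n_control Case and control counts.
#' @return `4 / (1/n_case + 1/n_control)`.
#' @export
effective_n <- function(n_case, n_control) {
  4 / (1 / n_case + 1 / n_control)
}

draw_r2_shares <- function(k, total_r2, distribution) {
  shares <- switch(distribution,
                   equal = rep(1 / k, k),
                   exponential = { e <- rexp(k); e / sum(e) })
  r2 <- total_r2 * shares
  if (any(r2 >= 1)) {
    stop_mr("per-variant variance explained reaches 1; lower total_r2",
            class = "mrkit_config_error")
  }
  r2
}

draw_alleles <- function(k, palindrome_fraction) {
  n_pal <- round(palindrome_fraction * k)
  pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
  bases <- c("A", "C", "G", "T")
  nonpal <- list()
  for (a in bases) for (b in bases) {
    if (a != b && ALLELE_COMPLEMENT[[a]] != b) {
      nonpal[[length(nonpal) + 1L]] <- c(a, b)
    }
  }
  idx_pal <- sample(seq_len(k), n_pal)
  ea <- oa <- character(k)
  pick <- function(pool, n) pool[sample.int(length(pool), n, replace = TRUE)]
  if (n_pal) {
    pp <- pick(pal_pairs, n_pal)
    ea[idx_pal] <- vapply(pp, `[[`, character(1), 1L)
    oa[idx_pal] <- vapply(pp, `[[`, character(1), 2L)
  }
  rest <- setdiff(seq_len(k), idx_pal)
  np <- pick(nonpal, length(rest))
  ea[rest] <- vapply(np, `[[`, character(1), 1L)
  oa[rest] <- vapply(np, `[[`, character(1), 2L)
  list(effect = ea, other = oa)
}

# Deterministic genome placement: consecutive variants cycle through 22
# chromosomes with >= 2 Mb spacing within a chromosome, so simulated
# instruments are independent by distance as well as by construction.
place_variants <- function(k) {
  chrom <- as.character(((seq_len(k) - 1L) %% 22L) + 1L)
  pos <- 1e6 + 2.5e6 * ((seq_len(k) - 1L) %/% 22L)
  list(chrom = chrom, pos = pos)
}

assemble_sumstats <- function(vid, chrom, pos, alleles, eaf, beta, se,
                              trait_id, trait_type, n = NA, n_case = NA,
                              n_control = NA, unit_label) {
  df <- data.frame(
    variant_id = vid, chrom = chrom, pos = pos,
    effect_allele = alleles$effect, other_allele = alleles$other,
    eaf = eaf, beta = beta, se = se,
    pvalue = pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
    n = n, n_case = n_case, n_control = n_control,
    stringsAsFactors = FALSE
  )
  as_gwas_sumstats(df, trait_id = trait_id, trait_type = trait_type,
                   unit_label = unit_label,
                   n_case = if (is.na(n_case)) NULL else n_case,
                   n_control = if (is.na(n_control)) NULL else n_control)
}

#' Simulate a paired exposure/outcome GWAS
#'
#' Draws effect-allele frequencies, sizes per-variant exposure effects
#' `gamma_j = sqrt(r2_j / (2 f_j (1 - f_j)))` to hit the configured variance
#' explained (exposure standardized to unit variance), adds pleiotropic
#' direct effects `alpha_j` per the configured regime, and observes both
#' sides with GWAS sampling noise: `se_x = 1/sqrt(2 n_exposure f (1-f))` and
#' `se_y = 1/sqrt(2 n_eff f (1-f))` with `n_eff = 4/(1/n_case +
#' 1/n_control)`. The true variant-outcome effect is `theta gamma_j +
#' alpha_j` on the log-odds scale. Exposure and outcome noise are drawn from
#' separate RNG streams (two-sample independence); everything derives from
#' the single configured seed.
#'
#' @param config A [sim_config()].
#' @return List with `exposure` and `outcome` (`gwas_sumstats` tables) and
#'   `truth` (a `simulation_truth`: theta, gamma, alpha, eaf, per-variant
#'   r2, seed).
#' @export
simulate_gwas_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$n_variants
  structure_draw <- with_seed(config$seed, {
    list(eaf = runif(k, config$eaf_range[1], config$eaf_range[2]),
         r2 = draw_r2_shares(k, config$total_r2, config$r2_distribution),
         alleles = draw_alleles(k, config$palindrome_fraction),
         alpha = switch(config$pleiotropy$type,
                        none = rep(0, k),
                        rnorm(k, config$pleiotropy$mean,
                              config$pleiotropy$sd)),
         streams = sample.int(.Machine$integer.max - 1L, 2L))
  })
  eaf <- structure_draw$eaf
  het <- 2 * eaf * (1 - eaf)
  gamma <- sqrt(structure_draw$r2 / het)
  se_x <- 1 / sqrt(het * config$n_exposure)
  n_eff <- effective_n(config$n_case, config$n_control)
  se_y <- 1 / sqrt(het * n_eff)
  b_y <- config$theta * gamma + structure_draw$alpha

  beta_x <- with_seed(structure_draw$streams[1L], rnorm(k, gamma, se_x))
  beta_y <- with_seed(structure_draw$streams[2L], rnorm(k, b_y, se_y))

  vid <- sprintf("sim%04d", seq_len(k))
  loc <- place_variants(k)
  exposure <- assemble_sumstats(vid, loc$chrom, loc$pos,
                                structure_draw$alleles, eaf, beta_x, se_x,
                                config$exposure_id, "continuous",
                                n = config$n_exposure, unit_label = "SD")
  outcome <- assemble_sumstats(vid, loc$chrom, loc$pos,
                               structure_draw$alleles, eaf, beta_y, se_y,
                               config$outcome_id, "binary",
                               n = config$n_case + config$n_control,
                               n_case = config$n_case,
                               n_control = config$n_control,
                               unit_label = "log-odds")
  truth <- structure(list(theta = config$theta, gamma = gamma,
                          alpha = structure_draw$alpha, eaf = eaf,
                          r2 = structure_draw$r2, n_eff = n_eff,
                          seed = config$seed),
                     class = "simulation_truth")
  list(exposure = exposure, outcome = outcome, truth = truth)
}

#' Harmonized dataset straight from a simulated pair
#'
#' Convenience wrapper used heavily in calibration loops: simulated variants
#' are already aligned, so this skips table I/O and builds the `mr_dataset`
#' directly (identical to harmonizing with the palindrome filter off).
#'
#' @param sim Output of [simulate_gwas_pair()].
#' @return An `mr_dataset`.
#' @export
sim_mr_dataset <- function(sim) {
  mr_dataset(sim$exposure$variant_id,
             sim$exposure$beta, sim$exposure$se,
             sim$outcome$beta, sim$outcome$se,
             eaf = sim$exposure$eaf,
             exposure_id = attr(sim$exposure, "trait_meta")$trait_id,
             outcome_id = attr(sim$outcome, "trait_meta")$trait_id)
}

#' Simulate a multi-exposure GWAS system with optional mediation
#'
#' Generates `m` exposures, each with its own block of variants carrying
#' direct effects sized to hit per-exposure variance-explained targets, and
#' a matrix of exposure-on-exposure path coefficients: `cross_effects[l, q]`
#' is the causal effect of exposure q on exposure l, so exposure q's variants
#' acquire downstream effects on exposure l (mediation). Total genetic
#' effects solve `Gamma_l = G_l + sum_q cross[l, q] Gamma_q`. The outcome is
#' generated from the total effects via `theta` (one entry per exposure),
#' allowing designs whose effect flows entirely through a mediator. Every
#' exposure table reports all variants, as multivariable MR requires.
#'
#' @param n_variants Integer vector: direct-instrument count per exposure.
#' @param n_exposure Sample size per exposure GWAS.
#' @param n_case,n_control Outcome counts.
#' @param theta Per-exposure direct causal effects on the outcome.
#' @param cross_effects m x m matrix of exposure-on-exposure effects (zero
#'   diagonal, acyclic); default none.
#' @param total_r2 Per-exposure variance explained by its direct variants.
#' @param pleiotropy A `pleiotropy_spec` applied to the outcome.
#' @param r2_distribution,eaf_range,palindrome_fraction,seed As
#'   [sim_config()].
#' @param exposure_ids,outcome_id Trait identifiers.
#' @return List with `exposures` (list of `gwas_sumstats`), `outcome`, and
#'   `truth` (direct effects `gamma_direct`, total effects `gamma_total`,
#'   `cross_effects`, `theta`, `alpha`, `seed`).
#' @export
simulate_multi_exposure <- function(n_variants = c(25, 25),
                                    n_exposure = c(339224, 898130),
                                    n_case = 6406, n_control = 902088,
                                    theta = c(0, 0.3),
                                    cross_effects = NULL,
                                    total_r2 = c(0.02, 0.02),
                                    pleiotropy = pleiotropy_none(),
                                    r2_distribution = c("exponential",
                                                        "equal"),
                                    eaf_range = c(0.05, 0.95),
                                    palindrome_fraction = 0.1,
                                    exposure_ids = NULL,
                                    outcome_id = "outcome",
                                    seed = 1) {
  r2_distribution <- match.arg(r2_distribution)
  m <- length(n_variants)
  stopifnot(m >= 1, length(n_exposure) == m, length(theta) == m,
            length(total_r2) == m)
  if (is.null(cross_effects)) cross_effects <- matrix(0, m, m)
  cross_effects <- as.matrix(cross_effects)
  stopifnot(nrow(cross_effects) == m, ncol(cross_effects) == m,
            all(diag(cross_effects) == 0))
  exposure_ids <- exposure_ids %||% paste0("exposure", seq_len(m))
  k <- sum(n_variants)
  block <- rep(seq_len(m), n_variants)

  sd_ <- with_seed(seed, {
    list(eaf = runif(k, eaf_range[1], eaf_range[2]),
         shares = lapply(seq_len(m), function(l) {
           draw_r2_shares(n_variants[l], total_r2[l], r2_distribution)
         }),
         alleles = draw_alleles(k, palindrome_fraction),
         alpha = switch(pleiotropy$type,
                        none = rep(0, k),
                        rnorm(k, pleiotropy$mean, pleiotropy$sd)),
         streams = sample.int(.Machine$integer.max - 1L, m + 1L))
  })
  het <- 2 * sd_$eaf * (1 - sd_$eaf)
  G <- matrix(0, k, m)
  for (l in seq_len(m)) {
    rows <- which(block == l)
    G[rows, l] <- sqrt(sd_$shares[[l]] / het[rows])
  }
  # Gamma^T = (I - B)^{-1} G^T with B the exposure-on-exposure matrix.
  Gamma <- t(solve(diag(m) - cross_effects, t(G)))
  colnames(Gamma) <- exposure_ids
  n_eff <- effective_n(n_case, n_control)
  b_y <- drop(Gamma %*% theta) + sd_$alpha
  se_y <- 1 / sqrt(het * n_eff)
  beta_y <- with_seed(sd_$streams[m + 1L], rnorm(k, b_y, se_y))

  vid <- sprintf("sim%04d", seq_len(k))
  loc <- place_variants(k)
  exposures <- lapply(seq_len(m), function(l) {
    se_x <- 1 / sqrt(het * n_exposure[l])
    beta_x <- with_seed(sd_$streams[l], rnorm(k, Gamma[, l], se_x))
    assemble_sumstats(vid, loc$chrom, loc$pos, sd_$alleles, sd_$eaf,
                      beta_x, se_x, exposure_ids[l], "continuous",
                      n = n_exposure[l], unit_label = "SD")
  })
  names(exposures) <- exposure_ids
  outcome <- assemble_sumstats(vid, loc$chrom, loc$pos, sd_$alleles, sd_$eaf,
                               beta_y, se_y, outcome_id, "binary",
                               n = n_case + n_control, n_case = n_case,
                               n_control = n_control, unit_label = "log-odds")
  truth <- structure(list(theta = theta, gamma_direct = G,
                          gamma_total = Gamma, cross_effects = cross_effects,
                          alpha = sd_$alpha, eaf = sd_$eaf, block = block,
                          n_eff = n_eff, seed = seed),
                     class = "simulation_truth")
  list(exposures = exposures, outcome = outcome, truth = truth)
}

#' Multi-exposure `mr_dataset` straight from a simulated system
#' @param sim Output of [simulate_multi_exposure()].
#' @return A multi-exposure `mr_dataset` over all simulated variants.
#' @export
sim_mvmr_dataset <- function(sim) {
  m <- length(sim$exposures)
  beta_x <- do.call(cbind, lapply(sim$exposures, `[[`, "beta"))
  se_x <- do.call(cbind, lapply(sim$exposures, `[[`, "se"))
  colnames(beta_x) <- colnames(se_x) <- names(sim$exposures)
  mr_dataset_multi(sim$outcome$variant_id, beta_x, se_x,
                   sim$outcome$beta, sim$outcome$se,
                   outcome_id = attr(sim$outcome, "trait_meta")$trait_id)
}
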