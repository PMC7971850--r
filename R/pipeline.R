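# Screening pipeline: many exposures x several outcomes with Bonferroni
# control, sensitivity batteries and power diagnostics.

#' Bonferroni significance threshold for an exposure-by-outcome screen
#'
#' `alpha / (n_exposures * n_outcomes)`, returned exactly along with the
#' display rounding used in study reports: the shortest decimal value within
#' 5% relative error of the exact threshold (so 0.05/17/2 displays as 0.0015
#' and 0.05/4/2 as 0.006).
#'
#' @param n_exposures,n_outcomes Positive test-grid dimensions.
#' @param alpha Family-wise error rate (default 0.05).
#' @return List with `exact` (numeric) and `display` (character).
#' @export
bonferroni_threshold <- function(n_exposures, n_outcomes, alpha = 0.05) {
  stopifnot(is_scalar_number(n_exposures), n_exposures >= 1,
            is_scalar_number(n_outcomes), n_outcomes >= 1,
            is_scalar_number(alpha), alpha > 0, alpha < 1)
  exact <- alpha / (n_exposures * n_outcomes)
  display <- exact
  for (digits in 1:15) {
    cand <- round(exact, digits)
    if (cand > 0 && abs(cand - exact) / exact <= 0.05) {
      display <- cand
      break
    }
  }
  list(exact = exact, display = format(display, scientific = FALSE))
}

#' Run a multi-exposure, multi-outcome MR screen
#'
#' For each exposure/outcome pair: select genome-wide-significant candidates,
#' clump them, harmonize to the outcome, and fit the primary random-effects
#' IVW estimate plus the requested sensitivity estimators, heterogeneity Q
#' and a leave-one-out scan (optionally MR-PRESSO). Significance flags are
#' set only on the primary IVW row against the Bonferroni threshold for the
#' full grid; sensitivity methods never set flags but feed the per-pair
#' direction-concordance indicator (true when all methods' estimates share a
#' sign). Pairs that fail (e.g. no shared variants) are recorded as failed
#' rows and the screen continues.
#'
#' @param exposures Named list of exposure summary-statistic tables.
#' @param outcomes Named list of outcome summary-statistic tables.
#' @param methods Sensitivity estimators to add to the primary IVW:
#'   any of `"egger"`, `"weighted_median"`, `"mode"`.
#' @param alpha Family-wise error rate for the Bonferroni threshold.
#' @param p_threshold,ld,r2_threshold,window_bp Instrument-selection
#'   parameters (see [ld_clump()]).
#' @param af_window Palindrome ambiguity window for harmonization.
#' @param presso Set `TRUE` to add MR-PRESSO per pair.
#' @param n_boot Bootstrap replicates for median/mode standard errors.
#' @param n_sim MR-PRESSO null replicates.
#' @param seed Master seed; per-pair seeds are derived from it, making the
#'   screen bit-reproducible.
#' @return A `screen_result`: long-format `results` data frame (one row per
#'   pair and method), the Bonferroni threshold, and run metadata.
#' @export
run_screen <- function(exposures, outcomes,
                       methods = c("egger", "weighted_median", "mode"),
                       alpha = 0.05, p_threshold = 5e-8,
                       ld = ld_source_empty(), r2_threshold = 0.01,
                       window_bp = 1e6, af_window = c(0.4, 0.6),
                       presso = FALSE, n_boot = 1000, n_sim = 1000,
                       seed = 1) {
  stopifnot(is.list(exposures), is.list(outcomes),
            length(exposures) >= 1, length(outcomes) >= 1)
  methods <- match.arg(methods, several.ok = TRUE)
  ex_names <- names(exposures) %||% paste0("exposure", seq_along(exposures))
  out_names <- names(outcomes) %||% paste0("outcome", seq_along(outcomes))
  thr <- bonferroni_threshold(length(exposures), length(outcomes), alpha)
  grid <- expand.grid(exposure = ex_names, outcome = out_names,
                      stringsAsFactors = FALSE)
  pair_seeds <- derive_seeds(seed, nrow(grid))

  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    ex <- exposures[[grid$exposure[i]]]
    out <- outcomes[[grid$outcome[i]]]
    rows[[i]] <- tryCatch(
      screen_pair(ex, out, grid$exposure[i], grid$outcome[i], methods,
                  thr$exact, p_threshold, ld, r2_threshold, window_bp,
                  af_window, presso, n_boot, n_sim, pair_seeds[i]),
      error = function(e) {
        data.frame(exposure = grid$exposure[i], outcome = grid$outcome[i],
                   method = "ivw_re", beta = NA_real_, se = NA_real_,
                   ci_low = NA_real_, ci_high = NA_real_, pvalue = NA_real_,
                   n_variants = 0L, q = NA_real_, q_pvalue = NA_real_,
                   intercept_pvalue = NA_real_, loo_flagged = NA_integer_,
                   significant = NA, direction_concordant = NA,
                   status = paste0("failed: ", conditionMessage(e)),
                   stringsAsFactors = FALSE)
      })
  }
  structure(list(results = do.call(rbind, rows),
                 bonferroni_alpha = thr$exact,
                 bonferroni_display = thr$display,
                 alpha = alpha, methods = methods, seed = seed),
            class = "screen_result")
}

screen_pair <- function(ex, out, ex_name, out_name, methods, bonferroni,
                        p_threshold, ld, r2_threshold, window_bp, af_window,
                        presso, n_boot, n_sim, pair_seed) {
  cands <- select_candidates(ex, p_threshold)
  iset <- ld_clump(cands, ld = ld, r2_threshold = r2_threshold,
                   window_bp = window_bp, p_threshold = p_threshold)
  data <- harmonize_dataset(iset, out, af_window = af_window)
  check_mr_dataset(data, 1L, "screen")
  seeds <- derive_seeds(pair_seed, 3L)

  ests <- list(mr_ivw(data, "random"))
  if (nrow(data) >= 3L) {
    if ("egger" %in% methods) ests <- c(ests, list(mr_egger(data)))
    if ("weighted_median" %in% methods) {
      ests <- c(ests, list(mr_weighted_median(data, n_boot, seeds[1L])))
    }
    if ("mode" %in% methods) {
      ests <- c(ests, list(mr_mode(data, 1, n_boot, seeds[2L])))
    }
  }
  loo_flagged <- if (nrow(data) >= 3L) sum(leave_one_out(data)$flagged)
                 else NA_integer_
  betas <- vapply(ests, `[[`, numeric(1), "beta")
  concordant <- length(unique(sign(betas[betas != 0]))) <= 1L
  df <- do.call(rbind, lapply(ests, as.data.frame))
  df <- df[, c("method", "beta", "se", "ci_low", "ci_high", "pvalue",
               "n_variants", "q", "q_pvalue", "intercept_pvalue")]
  df$loo_flagged <- c(loo_flagged, rep(NA_integer_, nrow(df) - 1L))
  df$significant <- c(df$pvalue[1L] < bonferroni,
                      rep(NA, nrow(df) - 1L))
  df$direction_concordant <- concordant
  df$status <- "ok"
  if (presso && nrow(data) >= 4L) {
    pr <- run_presso(data, n_sim = n_sim, significance = 0.05,
                     seed = seeds[3L])
    df$status <- paste0("ok; presso_global_p=", signif(pr$global_pvalue, 3),
                        "; presso_outliers=", length(pr$outlier_ids))
  }
  cbind(data.frame(exposure = ex_name, outcome = out_name,
                   stringsAsFactors = FALSE), df)
}

#' @export
print.screen_result <- function(x, digits = 3, ...) {
  cat("<screen_result>", nrow(x$results), "rows; Bonferroni alpha =",
      x$bonferroni_display, sprintf("(exact %.6g)\n", x$bonferroni_alpha))
  primary <- x$results[x$results$method == "ivw_re", , drop = FALSE]
  print(format(primary[, c("exposure", "outcome", "beta", "pvalue",
                           "n_variants", "significant")], digits = digits),
        row.names = FALSE)
  invisible(x)
}

#' Smallest detectable odds ratio of a two-sample MR study
#'
#' Normal-approximation power calculation for a binary outcome: the IVW
#' estimate of the log odds ratio per exposure SD has standard error
#' approximately `1/sqrt(n_eff * r2)` with `n_eff = 4/(1/n_case +
#' 1/n_control)` (the same effective-sample-size convention as the
#' simulator) and `r2` the exposure variance explained by the instruments.
#' The smallest detectable effect at two-sided level `alpha` and the given
#' power is `(z_{1-alpha/2} + z_{power}) * se`, returned as an odds ratio.
#' Monotone decreasing in `r2` and in both sample sizes.
#'
#' @param r2_explained Exposure variance explained by the instruments,
#'   in (0, 1).
#' @param n_case,n_control Outcome case and control counts.
#' @param alpha Two-sided type-I error rate.
#' @param power Target power, in (alpha, 1).
#' @return Smallest detectable odds ratio per exposure SD (> 1).
#' @export
detectable_or <- function(r2_explained, n_case, n_control,
                          alpha = 0.05, power = 0.8) {
  stopifnot(all(r2_explained > 0), all(r2_explained < 1),
            all(n_case > 0), all(n_control > 0),
            is_scalar_number(alpha), alpha > 0, alpha < 1)
  if (any(power >= 1 | power <= alpha)) {
    stop_mr("power must lie in (alpha, 1)", class = "mrkit_config_error")
  }
  se <- 1 / sqrt(effective_n(n_case, n_control) * r2_explained)
  exp((qnorm(1 - alpha / 2) + qnorm(power)) * se)
}
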