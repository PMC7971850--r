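# Univariable two-sample MR estimators and sensitivity diagnostics.
#
# All estimators consume an mr_dataset of aligned per-variant effect pairs
# (beta_x, se_x, beta_y, se_y). Point estimates are invariant under a joint
# sign flip of (beta_x, beta_y); outcome-side weights are 1/se_y^2 throughout
# (the convention of summary-data MR), with the first-order delta-method
# variance se_y^2/beta_x^2 for per-variant Wald ratios.

new_mr_estimate <- function(method, beta, se, pvalue, n_variants,
                            ci_mult = qnorm(0.975),
                            q = NULL, q_pvalue = NULL,
                            intercept = NULL, intercept_se = NULL,
                            intercept_pvalue = NULL, note = NULL,
                            seed = NULL, n_boot = NULL) {
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - ci_mult * se, ci_high = beta + ci_mult * se,
                 pvalue = pvalue, n_variants = n_variants,
                 q = q, q_pvalue = q_pvalue,
                 intercept = intercept, intercept_se = intercept_se,
                 intercept_pvalue = intercept_pvalue,
                 note = note, seed = seed, n_boot = n_boot),
            class = "mr_estimate")
}

#' @export
print.mr_estimate <- function(x, digits = 4, ...) {
  cat(sprintf("<mr_estimate> %s: beta = %.*g (se %.*g), 95%% CI [%.*g, %.*g], p = %.*g, k = %d\n",
              x$method, digits, x$beta, digits, x$se, digits, x$ci_low,
              digits, x$ci_high, digits, x$pvalue, x$n_variants))
  if (!is.null(x$q)) {
    cat(sprintf("  Cochran Q = %.*g (p = %.*g)\n", digits, x$q, digits,
                x$q_pvalue))
  }
  if (!is.null(x$intercept)) {
    cat(sprintf("  Egger intercept = %.*g (se %.*g, p = %.*g)\n", digits,
                x$intercept, digits, x$intercept_se, digits,
                x$intercept_pvalue))
  }
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

# Wald ratios and their first-order delta-method variances.
wald_components <- function(data) {
  if (any(data$beta_x == 0)) {
    stop_mr("beta_x = 0 gives an undefined Wald ratio",
            class = "mrkit_degenerate_instruments")
  }
  list(ratio = data$beta_y / data$beta_x,
       se = data$se_y / abs(data$beta_x))
}

#' Single-variant Wald ratio estimate
#'
#' `beta_y / beta_x` with the first-order delta-method standard error
#' `se_y / |beta_x|` (exposure-side uncertainty enters at second order and is
#' ignored, the summary-data MR convention).
#'
#' @param v One-row `mr_dataset` (or list with `beta_x`, `se_x`, `beta_y`,
#'   `se_y`).
#' @return An `mr_estimate` with `method = "wald"`.
#' @export
wald_ratio <- function(v) {
  v <- as.data.frame(as.list(v)[c("beta_x", "se_x", "beta_y", "se_y")])
  check_mr_dataset(v, 1L, "wald_ratio")
  w <- wald_components(v)
  beta <- w$ratio; se <- w$se
  new_mr_estimate("wald", beta, se,
                  pvalue = 2 * pnorm(-abs(beta / se)), n_variants = 1L)
}

#' Inverse-variance-weighted MR estimate
#'
#' Weighted regression of variant-outcome on variant-exposure coefficients
#' through the origin with weights 1/se_y^2:
#' `beta = sum(w beta_x beta_y) / sum(w beta_x^2)`. The fixed-effect standard
#' error is `1/sqrt(sum(w beta_x^2))`; the random-effects model inflates it
#' multiplicatively by `max(1, sqrt(Q/(k-1)))` (overdispersion floored at 1,
#' never shrunk for underdispersion).
#'
#' @param data An `mr_dataset` with >= 2 variants (a single variant degrades
#'   to the Wald ratio with a note).
#' @param effects_model `"random"` (default) or `"fixed"`.
#' @return An `mr_estimate` carrying Cochran's Q and its p-value.
#' @export
mr_ivw <- function(data, effects_model = c("random", "fixed")) {
  effects_model <- match.arg(effects_model)
  check_mr_dataset(data, 1L, "mr_ivw")
  k <- nrow(data)
  tag <- if (effects_model == "random") "ivw_re" else "ivw_fe"
  if (k == 1L) {
    est <- wald_ratio(data)
    est$method <- tag
    est$note <- "single variant: estimate equals the Wald ratio"
    est$n_variants <- 1L
    return(est)
  }
  if (all(data$beta_x == 0)) {
    stop_mr("all beta_x are zero: degenerate instruments",
            class = "mrkit_degenerate_instruments")
  }
  w <- 1 / data$se_y^2
  sxx <- sum(w * data$beta_x^2)
  beta <- sum(w * data$beta_x * data$beta_y) / sxx
  se_fixed <- 1 / sqrt(sxx)
  q <- sum(w * (data$beta_y - beta * data$beta_x)^2)
  q_pvalue <- pchisq(q, df = k - 1, lower.tail = FALSE)
  scale <- if (effects_model == "random") max(1, sqrt(q / (k - 1))) else 1
  se <- se_fixed * scale
  new_mr_estimate(tag, beta, se, pvalue = 2 * pnorm(-abs(beta / se)),
                  n_variants = k, q = q, q_pvalue = q_pvalue)
}

#' Cochran's Q heterogeneity statistic
#'
#' `Q = sum(w_j (theta_j - beta_hat)^2)` over per-variant Wald ratios
#' `theta_j`, with `w_j` their inverse first-order variances
#' (`beta_x^2/se_y^2`); referred to chi-square with k - 1 df. Algebraically
#' identical to the weighted residual sum of the IVW regression.
#'
#' @param data An `mr_dataset` with >= 2 variants and nonzero `beta_x`.
#' @param beta_hat Pooled estimate to test against (default: the IVW slope).
#' @return List with elements `q` and `q_pvalue`.
#' @export
cochran_q <- function(data, beta_hat = NULL) {
  check_mr_dataset(data, 2L, "cochran_q")
  wc <- wald_components(data)
  w <- 1 / wc$se^2
  if (is.null(beta_hat)) beta_hat <- sum(w * wc$ratio) / sum(w)
  q <- sum(w * (wc$ratio - beta_hat)^2)
  list(q = q, q_pvalue = pchisq(q, df = nrow(data) - 1, lower.tail = FALSE))
}

#' MR-Egger regression
#'
#' Weighted regression of variant-outcome on variant-exposure coefficients
#' with a free intercept (weights 1/se_y^2), after orienting every variant to
#' a nonnegative exposure effect. The slope is the pleiotropy-corrected
#' causal estimate; the intercept with its standard error and p-value is the
#' test for directional pleiotropy (valid under the InSIDE assumption). Both
#' standard errors carry the multiplicative overdispersion factor
#' `max(1, sqrt(Q_egger/(k-2)))`; inference uses the t distribution with
#' k - 2 df (small-sample convention).
#'
#' @param data An `mr_dataset` with >= 3 variants.
#' @return An `mr_estimate` with intercept fields and the Egger residual Q.
#' @export
mr_egger <- function(data) {
  check_mr_dataset(data, 3L, "mr_egger")
  k <- nrow(data)
  flip <- sign(data$beta_x)
  flip[flip == 0] <- 1
  bx <- data$beta_x * flip
  by <- data$beta_y * flip
  w <- 1 / data$se_y^2
  X <- cbind(intercept = 1, slope = bx)
  xtw <- t(X * w)
  A <- xtw %*% X
  if (kappa(A) > 1e12) {
    stop_mr("exposure effects nearly constant: Egger intercept not identified",
            class = "mrkit_degenerate_instruments")
  }
  coefs <- drop(solve(A, xtw %*% by))
  resid <- by - drop(X %*% coefs)
  q <- sum(w * resid^2)
  scale <- max(1, sqrt(q / (k - 2)))
  ses <- sqrt(diag(solve(A))) * scale
  tcrit <- qt(0.975, df = k - 2)
  pvals <- 2 * pt(-abs(coefs / ses), df = k - 2)
  new_mr_estimate("egger", coefs[["slope"]], ses[["slope"]],
                  pvalue = pvals[["slope"]], n_variants = k,
                  ci_mult = tcrit,
                  q = q, q_pvalue = pchisq(q, df = k - 2, lower.tail = FALSE),
                  intercept = coefs[["intercept"]],
                  intercept_se = ses[["intercept"]],
                  intercept_pvalue = pvals[["intercept"]])
}

weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]
  w <- weight[ord]
  p <- (cumsum(w) - w / 2) / sum(w)
  approx(p, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

bootstrap_se <- function(data, point_fun, n_boot, seed) {
  with_seed(seed, {
    ests <- vapply(seq_len(n_boot), function(b) {
      bx <- rnorm(nrow(data), data$beta_x, data$se_x)
      by <- rnorm(nrow(data), data$beta_y, data$se_y)
      point_fun(bx, by)
    }, numeric(1))
    sd(ests)
  })
}

#' Weighted median MR estimate
#'
#' The weighted median of per-variant Wald ratios (weights: inverse
#' first-order ratio variances), consistent when valid instruments carry at
#' least half of the total weight. The point estimate interpolates the
#' weighted quantile function at 0.5; the standard error comes from a seeded
#' parametric bootstrap resampling `beta_x` and `beta_y` from their sampling
#' distributions.
#'
#' @param data An `mr_dataset` with >= 3 variants.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap (required; recorded in the
#'   result).
#' @return An `mr_estimate` with `method = "weighted_median"`.
#' @export
mr_weighted_median <- function(data, n_boot = 1000, seed) {
  check_mr_dataset(data, 3L, "mr_weighted_median")
  wc <- wald_components(data)
  weight <- 1 / wc$se^2
  beta <- weighted_median_point(wc$ratio, weight)
  point_fun <- function(bx, by) {
    ok <- bx != 0
    weighted_median_point(by[ok] / bx[ok], bx[ok]^2 / data$se_y[ok]^2)
  }
  se <- bootstrap_se(data, point_fun, n_boot, seed)
  new_mr_estimate("weighted_median", beta, se,
                  pvalue = 2 * pnorm(-abs(beta / se)),
                  n_variants = nrow(data), seed = seed, n_boot = n_boot)
}

mode_point <- function(ratio, weight, bandwidth_factor) {
  scale <- mad(ratio)
  if (scale == 0) scale <- sd(ratio)
  if (!is.finite(scale) || scale == 0) {
    return(list(beta = ratio[1L], bandwidth = 0))
  }
  h <- bandwidth_factor * scale
  grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 2001L)
  dens <- colSums(weight * dnorm(outer(ratio, grid, "-") / h))
  list(beta = grid[which.max(dens)], bandwidth = h)
}

#' Mode-based MR estimate
#'
#' The mode of the smoothed distribution of per-variant Wald ratios
#' (weighted kernel density, weights proportional to inverse ratio
#' variances), consistent when the largest cluster of similar ratios comes
#' from valid instruments even if they are a minority. The bandwidth is
#' `bandwidth_factor` times the median absolute deviation (scaled) of the
#' ratios; the argmax is located on a 2001-point grid spanning the ratios
#' plus/minus 3 bandwidths. Standard error by seeded parametric bootstrap.
#'
#' @param data An `mr_dataset` with >= 3 variants.
#' @param bandwidth_factor Multiplier on the robust scale (default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return An `mr_estimate` with `method = "mode_based"`.
#' @export
mr_mode <- function(data, bandwidth_factor = 1, n_boot = 1000, seed) {
  check_mr_dataset(data, 3L, "mr_mode")
  wc <- wald_components(data)
  weight <- 1 / wc$se^2
  weight <- weight / sum(weight)
  pt_ <- mode_point(wc$ratio, weight, bandwidth_factor)
  point_fun <- function(bx, by) {
    ok <- bx != 0
    wgt <- bx[ok]^2 / data$se_y[ok]^2
    mode_point(by[ok] / bx[ok], wgt / sum(wgt), bandwidth_factor)$beta
  }
  se <- bootstrap_se(data, point_fun, n_boot, seed)
  new_mr_estimate("mode_based", pt_$beta, se,
                  pvalue = 2 * pnorm(-abs(pt_$beta / se)),
                  n_variants = nrow(data), seed = seed, n_boot = n_boot)
}

#' Leave-one-out sensitivity analysis
#'
#' Refits the random-effects IVW estimate k times, omitting one variant each
#' time, and flags variants whose omission moves the estimate by more than
#' `se_multiple` full-data standard errors (a variant driving the pooled
#' estimate suggests an outlying pleiotropic effect).
#'
#' @param data An `mr_dataset` with >= 3 variants.
#' @param se_multiple Flagging threshold in units of the full-data standard
#'   error (default 1).
#' @return Data frame with one row per omitted variant (`variant_id`, the
#'   re-estimate, the shift `delta`, and `flagged`); the full-data estimate
#'   is attached as the `"full_estimate"` attribute.
#' @export
leave_one_out <- function(data, se_multiple = 1) {
  check_mr_dataset(data, 3L, "leave_one_out")
  full <- mr_ivw(data, "random")
  rows <- lapply(seq_len(nrow(data)), function(j) {
    est <- mr_ivw(data[-j, , drop = FALSE], "random")
    data.frame(variant_id = data$variant_id[j], beta = est$beta, se = est$se,
               ci_low = est$ci_low, ci_high = est$ci_high,
               pvalue = est$pvalue, delta = full$beta - est$beta,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- abs(out$delta) > se_multiple * full$se
  structure(out, full_estimate = full, se_multiple = se_multiple)
}
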