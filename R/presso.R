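# MR-PRESSO: residual-sum global heterogeneity test, per-variant outlier
# test, and distortion test, all by parametric resampling of the summary
# statistics under the no-pleiotropy null.

ivw_slope <- function(bx, by, w) sum(w * bx * by) / sum(w * bx^2)

# Leave-one-out IVW slopes, vectorized over columns when bx/by are matrices.
loo_slopes <- function(bx, by, w) {
  txy <- colSums(w * bx * by)
  txx <- colSums(w * bx^2)
  sweep2 <- function(tot, part) rep(tot, each = nrow(part)) - part
  (sweep2(txy, w * bx * by)) / (sweep2(txx, w * bx^2))
}

#' MR-PRESSO outlier detection
#'
#' (1) The observed residual sum of squares is
#' `RSS = sum_j w_j (beta_yj - theta_(-j) beta_xj)^2` with `w = 1/se_y^2` and
#' `theta_(-j)` the leave-one-out IVW slope. (2) A null distribution is built
#' by drawing `beta_x* ~ N(beta_x, se_x)` and
#' `beta_y* ~ N(theta_(-j) beta_x, se_y)` for `n_sim` replicates and
#' recomputing RSS the same way; the global p-value is the empirical
#' exceedance with the (r+1)/(n_sim+1) correction (never exactly zero).
#' (3) Each variant's observed residual contribution against its simulated
#' distribution gives a per-variant outlier p-value, Bonferroni-adjusted
#' across variants; adjusted p below `significance` flags an outlier.
#' (4) When outliers are flagged, the distortion test compares the observed
#' displacement between the raw and outlier-removed IVW slopes with the
#' displacement obtained by removing the same variants in each null
#' replicate.
#'
#' @param data An `mr_dataset` with >= 4 variants.
#' @param n_sim Number of null replicates (>= 1000 recommended; < 100 warns).
#' @param significance Family-wise threshold for outlier flagging
#'   (default 0.05).
#' @param seed Integer seed; results are bit-reproducible given
#'   (data, n_sim, seed).
#' @return An `mr_presso_result`: global RSS and p-value, per-variant
#'   Bonferroni-adjusted outlier p-values, flagged outlier ids, distortion
#'   p-value (when outliers exist), the raw random-effects IVW estimate, and
#'   the outlier-corrected estimate (plain IVW on the remaining variants).
#' @export
run_presso <- function(data, n_sim = 1000, significance = 0.05, seed) {
  check_mr_dataset(data, 4L, "run_presso")
  stopifnot(is_scalar_number(n_sim), n_sim >= 1)
  if (n_sim < 100) {
    warning("n_sim < 100 gives a very coarse empirical null", call. = FALSE)
  }
  n_sim <- as.integer(n_sim)
  k <- nrow(data)
  bx <- data$beta_x; by <- data$beta_y
  sx <- data$se_x; sy <- data$se_y
  w <- 1 / sy^2

  theta_loo <- drop(loo_slopes(cbind(bx), cbind(by), w))
  d_obs <- w * (by - theta_loo * bx)^2
  rss_obs <- sum(d_obs)

  sim <- with_seed(seed, {
    bx_sim <- matrix(rnorm(k * n_sim, mean = bx, sd = sx), nrow = k)
    by_sim <- matrix(rnorm(k * n_sim, mean = theta_loo * bx, sd = sy),
                     nrow = k)
    list(bx = bx_sim, by = by_sim)
  })
  theta_loo_sim <- loo_slopes(sim$bx, sim$by, w)
  d_sim <- w * (sim$by - theta_loo_sim * sim$bx)^2
  rss_sim <- colSums(d_sim)

  global_pvalue <- (sum(rss_sim >= rss_obs) + 1) / (n_sim + 1)
  p_raw <- (rowSums(d_sim >= d_obs) + 1) / (n_sim + 1)
  p_adj <- pmin(1, k * p_raw)
  names(p_adj) <- data$variant_id
  outlier_ids <- data$variant_id[p_adj < significance]

  raw_estimate <- mr_ivw(data, "random")
  corrected <- NULL
  distortion_pvalue <- NULL
  if (length(outlier_ids)) {
    keep <- !(data$variant_id %in% outlier_ids)
    if (sum(keep) >= 2L) {
      corrected <- mr_ivw(data[keep, , drop = FALSE], "random")
      theta_raw <- ivw_slope(bx, by, w)
      theta_corr <- ivw_slope(bx[keep], by[keep], w[keep])
      disp_obs <- theta_raw - theta_corr
      disp_sim <- apply_displacement(sim$bx, sim$by, w, keep)
      distortion_pvalue <- (sum(abs(disp_sim) >= abs(disp_obs)) + 1) /
        (n_sim + 1)
    }
  }
  structure(list(global_rss = rss_obs, global_pvalue = global_pvalue,
                 outlier_pvalues = p_adj, outlier_ids = outlier_ids,
                 distortion_pvalue = distortion_pvalue,
                 raw_estimate = raw_estimate, corrected_estimate = corrected,
                 n_sim = n_sim, significance = significance, seed = seed),
            class = "mr_presso_result")
}

apply_displacement <- function(bx_sim, by_sim, w, keep) {
  all_xy <- colSums(w * bx_sim * by_sim)
  all_xx <- colSums(w * bx_sim^2)
  sub_xy <- colSums(w[keep] * bx_sim[keep, , drop = FALSE] *
                      by_sim[keep, , drop = FALSE])
  sub_xx <- colSums(w[keep] * bx_sim[keep, , drop = FALSE]^2)
  all_xy / all_xx - sub_xy / sub_xx
}

#' @export
print.mr_presso_result <- function(x, digits = 4, ...) {
  cat(sprintf("<mr_presso_result> global RSS = %.*g, p = %.*g (%d simulations)\n",
              digits, x$global_rss, digits, x$global_pvalue, x$n_sim))
  if (length(x$outlier_ids)) {
    cat("  outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
    if (!is.null(x$distortion_pvalue)) {
      cat(sprintf("  distortion test p = %.*g\n", digits, x$distortion_pvalue))
    }
    if (!is.null(x$corrected_estimate)) {
      cat(sprintf("  corrected IVW beta = %.*g (raw %.*g)\n", digits,
                  x$corrected_estimate$beta, digits, x$raw_estimate$beta))
    }
  } else {
    cat("  no outlying variants at adjusted p <", x$significance, "\n")
  }
  invisible(x)
}
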