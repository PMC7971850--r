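# Multivariable MR: joint conditioning of the outcome on several exposures'
# genetic effects, with conditional instrument-strength diagnostics.

#' Extract the exposure effect matrices of a multi-exposure dataset
#' @param data Multi-exposure `mr_dataset` from [build_mvmr_dataset()] or
#'   [mr_dataset_multi()].
#' @return List with `beta` and `se` matrices (variants x exposures).
#' @keywords internal
exposure_matrices <- function(data) {
  ids <- attr(data, "exposure_ids")
  if (is.null(ids)) {
    stop_mr("not a multi-exposure dataset (missing exposure_ids attribute)",
            class = "mrkit_usage_error")
  }
  beta <- as.matrix(data[, paste0("beta_x_", ids), drop = FALSE])
  se <- as.matrix(data[, paste0("se_x_", ids), drop = FALSE])
  colnames(beta) <- colnames(se) <- ids
  list(beta = beta, se = se, ids = ids)
}

#' Construct a multi-exposure `mr_dataset` from aligned effects
#'
#' @param variant_id Variant identifiers.
#' @param beta_x,se_x Matrices (variants x exposures) of exposure effects and
#'   standard errors, columns named by exposure.
#' @param beta_y,se_y Outcome effects and standard errors.
#' @param outcome_id Outcome trait identifier.
#' @return A multi-exposure `mr_dataset`.
#' @export
mr_dataset_multi <- function(variant_id, beta_x, se_x, beta_y, se_y,
                             outcome_id = "outcome") {
  beta_x <- as.matrix(beta_x); se_x <- as.matrix(se_x)
  ids <- colnames(beta_x) %||% paste0("exposure", seq_len(ncol(beta_x)))
  colnames(beta_x) <- colnames(se_x) <- ids
  stopifnot(all(se_x > 0), all(se_y > 0),
            nrow(beta_x) == length(beta_y))
  out <- data.frame(variant_id = as.character(variant_id),
                    stringsAsFactors = FALSE)
  for (id in ids) {
    out[[paste0("beta_x_", id)]] <- beta_x[, id]
    out[[paste0("se_x_", id)]] <- se_x[, id]
  }
  out$beta_y <- beta_y
  out$se_y <- se_y
  structure(out, exposure_ids = ids, outcome_id = outcome_id,
            class = c("mr_dataset", "data.frame"))
}

#' Assemble a harmonized multi-exposure MR dataset
#'
#' Takes the union of variants reaching `p_threshold` in at least one
#' exposure, clumps the union jointly (each variant ranked by its best
#' p-value across exposures), requires every retained variant to be present
#' in all exposure tables and the outcome table, and harmonizes everything to
#' the first exposure's effect alleles with palindromic exclusion.
#'
#' @param exposures Named list of two or more summary-statistic tables.
#' @param outcome Outcome summary-statistic table.
#' @param ld An `ld_source` for the joint clumping.
#' @param p_threshold Per-exposure significance threshold (default 5e-8).
#' @param r2_threshold,window_bp Clumping parameters (defaults 0.01, 1 Mb).
#' @param af_window Palindrome ambiguity window (default `c(0.4, 0.6)`).
#' @return A multi-exposure `mr_dataset`; the `"exclusion_log"` attribute
#'   counts variants dropped at each step.
#' @export
build_mvmr_dataset <- function(exposures, outcome, ld = ld_source_empty(),
                               p_threshold = 5e-8, r2_threshold = 0.01,
                               window_bp = 1e6, af_window = c(0.4, 0.6)) {
  if (!is.list(exposures) || length(exposures) < 2L) {
    stop_mr("need at least 2 exposure tables", class = "mrkit_usage_error")
  }
  ids <- names(exposures) %||% paste0("exposure", seq_along(exposures))
  ids[!nzchar(ids)] <- paste0("exposure", which(!nzchar(ids)))
  exposures <- lapply(exposures, as.data.frame)

  sig_ids <- unique(unlist(lapply(exposures, function(e) {
    select_candidates(e, p_threshold)$variant_id
  })))
  log <- list()
  present_all <- Reduce(intersect, lapply(exposures, `[[`, "variant_id"))
  missing_exposure <- setdiff(sig_ids, present_all)
  log$missing_from_exposure <- length(missing_exposure)
  union_ids <- setdiff(sig_ids, missing_exposure)

  # Rank each variant by its best association across exposures, then clump.
  ref <- exposures[[1L]]
  anchor <- ref[match(union_ids, ref$variant_id), , drop = FALSE]
  anchor$pvalue <- vapply(union_ids, function(v) {
    min(vapply(exposures, function(e) {
      p <- e$pvalue[match(v, e$variant_id)]
      if (is.na(p)) 1 else p
    }, numeric(1)))
  }, numeric(1))
  clumped <- ld_clump(anchor, ld = ld, r2_threshold = r2_threshold,
                      window_bp = window_bp, p_threshold = p_threshold)
  kept_ids <- clumped$variants$variant_id
  log$removed_by_clumping <- length(union_ids) - length(kept_ids)

  # Harmonize every non-reference exposure and the outcome to exposure 1.
  ref_rows <- ref[match(kept_ids, ref$variant_id), , drop = FALSE]
  harmon_to_ref <- function(tab) {
    rows <- lapply(seq_along(kept_ids), function(i) {
      harmonize_pair(ref_rows[i, , drop = FALSE],
                     tab[match(kept_ids[i], tab$variant_id), , drop = FALSE],
                     af_window = af_window)
    })
    list(status = vapply(rows, `[[`, character(1), "status"),
         beta = vapply(rows, `[[`, numeric(1), "beta_y"),
         se = vapply(rows, `[[`, numeric(1), "se_y"))
  }
  aligned <- lapply(exposures[-1L], harmon_to_ref)
  outcome_df <- as.data.frame(outcome)
  in_outcome <- kept_ids %in% outcome_df$variant_id
  log$missing_from_outcome <- sum(!in_outcome)
  y_aligned <- harmon_to_ref(outcome_df[outcome_df$variant_id %in% kept_ids,
                                        , drop = FALSE])
  ok <- in_outcome &
    Reduce(`&`, lapply(aligned, function(a) {
      a$status %in% c("aligned", "flipped")
    }), y_aligned$status %in% c("aligned", "flipped"))
  log$excluded_harmonization <- sum(in_outcome) - sum(ok)
  if (!any(ok)) {
    stop_mr("no shared variants after harmonization",
            class = "mrkit_usage_error")
  }

  beta_x <- cbind(ref_rows$beta[ok],
                  do.call(cbind, lapply(aligned, function(a) a$beta[ok])))
  se_x <- cbind(ref_rows$se[ok],
                do.call(cbind, lapply(aligned, function(a) a$se[ok])))
  colnames(beta_x) <- colnames(se_x) <- ids
  out <- mr_dataset_multi(kept_ids[ok], beta_x, se_x,
                          y_aligned$beta[ok], y_aligned$se[ok],
                          outcome_id = attr(outcome, "trait_meta")$trait_id %||%
                            unique(outcome_df$trait_id)[1L])
  attr(out, "exclusion_log") <- data.frame(
    reason = names(log), count = unlist(log, use.names = FALSE),
    stringsAsFactors = FALSE)
  out
}

# Exposures whose effect column is identically zero carry no information and
# would make the normal equations singular; they are dropped from the solve
# (their conditional effect is unidentified and reported as NA), so a
# two-exposure fit with one null column reduces exactly to univariable IVW.
mvmr_design <- function(data) {
  em <- exposure_matrices(data)
  active <- colSums(em$beta != 0) > 0L
  X <- em$beta[, active, drop = FALSE]
  w <- 1 / data$se_y^2
  A <- t(X * w) %*% X
  if (kappa(A) > 1e10) {
    stop_mr("exposure effect columns are nearly collinear (condition number ",
            format(kappa(A), digits = 3), ")",
            class = "mrkit_collinear_exposures")
  }
  list(X = X, w = w, A = A, em = em, active = active)
}

#' Multivariable MR fit
#'
#' Weighted multiple regression of variant-outcome effects on all exposures'
#' variant effects jointly, with no intercept and weights 1/se_y^2. Each
#' exposure's coefficient is its direct (conditional) effect on the outcome.
#' Standard errors carry the multiplicative random-effects factor
#' `max(1, sqrt(Q/(k-m)))` as in univariable IVW; with a single exposure the
#' fit reduces exactly to univariable random-effects IVW. Per-exposure
#' conditional instrument strength is reported via
#' [instrument_strength_q()].
#'
#' @param data Multi-exposure `mr_dataset` with more variants than exposures.
#' @return An `mvmr_result` with per-exposure estimates and strength
#'   diagnostics.
#' @export
mvmr_fit <- function(data) {
  if (!all(c("beta_y", "se_y") %in% names(data))) {
    stop_mr("mvmr_fit needs outcome columns beta_y and se_y",
            class = "mrkit_usage_error")
  }
  des <- mvmr_design(data)
  k <- nrow(data); m <- ncol(des$X)
  if (k <= m) {
    stop_mr("need more variants (", k, ") than exposures (", m, ")",
            class = "mrkit_insufficient_instruments")
  }
  m_active <- ncol(des$X)
  Ainv <- solve(des$A)
  fit <- drop(Ainv %*% t(des$X * des$w) %*% data$beta_y)
  resid <- data$beta_y - drop(des$X %*% fit)
  q <- sum(des$w * resid^2)
  scale <- max(1, sqrt(q / (k - m_active)))
  fit_se <- sqrt(diag(Ainv)) * scale
  coefs <- ses <- rep(NA_real_, m)
  coefs[des$active] <- fit
  ses[des$active] <- fit_se
  z <- coefs / ses
  strength <- lapply(des$em$ids, function(id) {
    tryCatch(instrument_strength_q(data, id),
             error = function(e) list(q = NA_real_, pvalue = NA_real_))
  })
  est <- data.frame(
    exposure = des$em$ids, beta = unname(coefs), se = unname(ses),
    ci_low = unname(coefs - qnorm(0.975) * ses),
    ci_high = unname(coefs + qnorm(0.975) * ses),
    pvalue = unname(2 * pnorm(-abs(z))),
    strength_q = vapply(strength, `[[`, numeric(1), "q"),
    strength_q_pvalue = vapply(strength, `[[`, numeric(1), "pvalue"),
    stringsAsFactors = FALSE
  )
  structure(list(estimates = est, n_variants = k,
                 q = q,
                 q_pvalue = pchisq(q, df = k - m_active, lower.tail = FALSE),
                 outcome_id = attr(data, "outcome_id")),
            class = "mvmr_result")
}

#' Conditional instrument-strength Q statistic
#'
#' Measures whether the instrument set predicts `target_exposure` beyond
#' what it predicts of the other exposures: a precision-weighted regression
#' (weights 1/se_x(target)^2, with intercept) of the target exposure's
#' variant effects on the other exposures' effects, whose weighted residual
#' sum is referred to chi-square with k - m degrees of freedom. A large Q
#' (small p) indicates strong conditional instruments; residuals near zero
#' flag conditionally weak instruments.
#'
#' @param data Multi-exposure `mr_dataset`.
#' @param target_exposure Exposure id to assess.
#' @return List with `q`, `pvalue` and `df`.
#' @export
instrument_strength_q <- function(data, target_exposure) {
  em <- exposure_matrices(data)
  if (!(target_exposure %in% em$ids)) {
    stop_mr("unknown exposure: ", target_exposure, class = "mrkit_usage_error")
  }
  k <- nrow(em$beta); m <- length(em$ids)
  y <- em$beta[, target_exposure]
  w <- 1 / em$se[, target_exposure]^2
  others <- em$beta[, setdiff(em$ids, target_exposure), drop = FALSE]
  others <- others[, colSums(others != 0) > 0L, drop = FALSE]
  X <- cbind(1, others)
  A <- t(X * w) %*% X
  if (kappa(A) > 1e10) {
    stop_mr("exposure effect columns are nearly collinear",
            class = "mrkit_collinear_exposures")
  }
  coefs <- drop(solve(A, t(X * w) %*% y))
  resid <- y - drop(X %*% coefs)
  q <- sum(w * resid^2)
  df <- k - m
  list(q = q, pvalue = pchisq(q, df = df, lower.tail = FALSE), df = df)
}

#' @export
print.mvmr_result <- function(x, digits = 4, ...) {
  cat("<mvmr_result>", x$n_variants, "variants, outcome:",
      x$outcome_id %||% "?", "\n")
  print(format(x$estimates, digits = digits), row.names = FALSE)
  cat(sprintf("  residual Q = %.*g (p = %.*g)\n", digits, x$q, digits,
              x$q_pvalue))
  invisible(x)
}
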