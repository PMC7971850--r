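# Instrument selection: genome-wide-significance filtering, greedy LD plus
# distance clumping, and instrument-strength / variance-explained diagnostics.

#' Filter candidate instruments by association p-value
#'
#' @param stats Summary-statistic table.
#' @param p_threshold Retain rows with `pvalue < p_threshold` (the
#'   genome-wide-significance convention is 5e-8).
#' @return The subset of `stats` passing the threshold, order preserved.
#' @export
select_candidates <- function(stats, p_threshold = 5e-8) {
  stopifnot(is_scalar_number(p_threshold), p_threshold > 0, p_threshold <= 1)
  keep <- !is.na(stats$pvalue) & stats$pvalue < p_threshold
  out <- stats[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-variant instrument F-statistic
#'
#' The squared z-score `(beta/se)^2`; F < 10 conventionally flags a weak
#' instrument.
#'
#' @param v Summary-statistic table (or any data frame with `beta` and `se`).
#' @return Numeric vector of F-statistics.
#' @export
f_statistic <- function(v) {
  if (any(is.na(v$se) | v$se <= 0)) {
    stop_mr("se must be > 0 to compute the F-statistic",
            class = "mrkit_validation_error")
  }
  (v$beta / v$se)^2
}

#' Variance explained by one variant in a continuous trait
#'
#' Inverts the association p-value to the F quantile on (1, n - 2) degrees of
#' freedom and returns r2 = F / (F + n - 2), the coefficient of determination
#' implied by the test statistic.
#'
#' @param pvalue Association p-value(s) in (0, 1\].
#' @param n GWAS sample size(s), > 2.
#' @return Fraction(s) of trait variance explained, in \[0, 1).
#' @export
variance_explained_continuous <- function(pvalue, n) {
  if (any(is.na(n) | n <= 2)) {
    stop_mr("n must exceed 2", class = "mrkit_validation_error")
  }
  if (any(is.na(pvalue) | pvalue <= 0 | pvalue > 1)) {
    stop_mr("pvalue must lie in (0, 1]", class = "mrkit_validation_error")
  }
  f <- qf(pvalue, 1, n - 2, lower.tail = FALSE)
  f / (f + n - 2)
}

#' Liability-scale variance explained by one variant in a binary trait
#'
#' Uses the liability-threshold approximation: with prevalence K, threshold
#' t = qnorm(1 - K) and z = dnorm(t), the variant's effect on liability is
#' approximately `log_or * K * (1 - K) / z`, giving
#' r2 = 2 f (1 - f) (log_or K (1 - K) / z)^2 for effect-allele frequency f.
#'
#' @param log_or Per-allele log odds ratio(s).
#' @param eaf Effect-allele frequency in (0, 1).
#' @param n_case,n_control Case and control counts (used for the default
#'   prevalence).
#' @param prevalence Population prevalence in (0, 1); defaults to the sample
#'   case fraction.
#' @return Fraction(s) of liability variance explained, in \[0, 1).
#' @export
variance_explained_binary <- function(log_or, eaf, n_case, n_control,
                                      prevalence = n_case / (n_case + n_control)) {
  if (any(is.na(n_case) | is.na(n_control) | n_case <= 0 | n_control <= 0)) {
    stop_mr("n_case and n_control must be positive",
            class = "mrkit_validation_error")
  }
  if (any(is.na(eaf) | eaf <= 0 | eaf >= 1)) {
    stop_mr("eaf must lie strictly in (0, 1)", class = "mrkit_validation_error")
  }
  if (any(is.na(prevalence) | prevalence <= 0 | prevalence >= 1)) {
    stop_mr("prevalence must lie strictly in (0, 1)",
            class = "mrkit_validation_error")
  }
  thr <- qnorm(1 - prevalence)
  z <- dnorm(thr)
  beta_liab <- log_or * prevalence * (1 - prevalence) / z
  pmin(2 * eaf * (1 - eaf) * beta_liab^2, 1 - .Machine$double.eps)
}

#' Greedy LD and distance clumping of candidate instruments
#'
#' Sorts candidates by ascending p-value (ties broken by chromosome, position
#' and variant id for reproducibility), accepts the best remaining variant,
#' and discards every remaining variant either in LD above `r2_threshold`
#' with an accepted variant or on the same chromosome within `window_bp`
#' (center-to-center, half-open) of one. Variants absent from the LD source
#' are treated as unlinked (r2 = 0) with a warning, so pruning falls back to
#' the distance rule for them.
#'
#' @param candidates Summary-statistic table with `chrom` and `pos` set.
#' @param ld An `ld_source` (default: no LD information).
#' @param r2_threshold Prune pairs with r2 above this (default 0.01; use
#'   0.001 for a stricter sensitivity configuration).
#' @param window_bp Distance window in base pairs (default 1 Mb).
#' @param p_threshold Recorded selection threshold (metadata only; apply
#'   [select_candidates()] first).
#' @return An `instrument_set`: the retained variants with per-variant
#'   F-statistics and variance explained, plus the selection configuration.
#' @export
ld_clump <- function(candidates, ld = ld_source_empty(),
                     r2_threshold = 0.01, window_bp = 1e6,
                     p_threshold = 5e-8) {
  stopifnot(is_scalar_number(r2_threshold), r2_threshold >= 0,
            is_scalar_number(window_bp), window_bp >= 0)
  df <- as.data.frame(candidates)
  if (!nrow(df)) {
    return(new_instrument_set(candidates[0, , drop = FALSE], candidates,
                              r2_threshold, window_bp, p_threshold))
  }
  bad <- is.na(df$chrom) | is.na(df$pos)
  if (any(bad)) {
    stop_mr("candidate(s) missing chrom/pos: ",
            paste(df$variant_id[bad], collapse = ", "),
            class = "mrkit_validation_error")
  }
  if (!identical(ld$label, "empty")) {
    unknown <- setdiff(df$variant_id, ld$ids)
    if (length(unknown)) {
      warning(length(unknown), " candidate variant(s) absent from the LD ",
              "source; treated as unlinked (r2 = 0)", call. = FALSE)
    }
  }
  ord <- order(df$pvalue, df$chrom, df$pos, df$variant_id)
  df <- df[ord, , drop = FALSE]
  accepted <- integer()
  remaining <- seq_len(nrow(df))
  while (length(remaining)) {
    best <- remaining[1L]
    accepted <- c(accepted, best)
    remaining <- remaining[-1L]
    if (length(remaining)) {
      r2 <- ld_r2(ld, df$variant_id[remaining], df$variant_id[best])
      near <- df$chrom[remaining] == df$chrom[best] &
        abs(df$pos[remaining] - df$pos[best]) < window_bp
      remaining <- remaining[!(r2 > r2_threshold | near)]
    }
  }
  kept <- df[accepted, , drop = FALSE]
  rownames(kept) <- NULL
  new_instrument_set(kept, candidates, r2_threshold, window_bp, p_threshold)
}

new_instrument_set <- function(kept, source, r2_threshold, window_bp,
                               p_threshold) {
  meta <- attr(source, "trait_meta")
  f <- if (nrow(kept)) f_statistic(kept) else numeric()
  r2x <- rep(NA_real_, nrow(kept))
  if (nrow(kept)) {
    type <- meta$trait_type %||% "continuous"
    if (identical(type, "binary")) {
      ok <- !is.na(kept$eaf) & kept$eaf > 0 & kept$eaf < 1 &
        !is.na(kept$n_case) & !is.na(kept$n_control)
      if (any(ok)) {
        r2x[ok] <- variance_explained_binary(
          kept$beta[ok], kept$eaf[ok], kept$n_case[ok], kept$n_control[ok])
      }
    } else {
      ok <- !is.na(kept$n) & kept$n > 2
      if (any(ok)) {
        r2x[ok] <- variance_explained_continuous(kept$pvalue[ok], kept$n[ok])
      }
    }
  }
  structure(
    list(trait_id = meta$trait_id %||% unique(kept$trait_id)[1L],
         variants = kept,
         f_statistic = f,
         r2_explained = r2x,
         selection_config = list(p_threshold = p_threshold,
                                 r2_threshold = r2_threshold,
                                 window_bp = window_bp)),
    class = "instrument_set")
}

#' @export
print.instrument_set <- function(x, ...) {
  cat("<instrument_set> trait:", x$trait_id %||% "?",
      "-", nrow(x$variants), "instruments\n")
  if (nrow(x$variants)) {
    cat("  F-statistic: median", signif(stats::median(x$f_statistic), 3),
        "| weak (F < 10):", sum(x$f_statistic < 10), "\n")
    if (any(!is.na(x$r2_explained))) {
      cat("  variance explained (sum):",
          signif(sum(x$r2_explained, na.rm = TRUE), 3), "\n")
    }
  }
  invisible(x)
}
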