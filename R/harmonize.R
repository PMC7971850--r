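# Allele harmonization: align outcome records to the exposure's effect
# allele, resolving strand flips where possible and excluding ambiguous
# palindromic variants at intermediate allele frequency.

ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

complement_alleles <- function(a) {
  vapply(strsplit(a, ""), function(ch) {
    if (all(ch %in% names(ALLELE_COMPLEMENT))) {
      paste(ALLELE_COMPLEMENT[ch], collapse = "")
    } else {
      NA_character_
    }
  }, character(1))
}

#' Is an allele pair palindromic (strand-ambiguous)?
#'
#' A/T and C/G single-nucleotide pairs read the same on both strands, so the
#' two datasets' strands cannot be reconciled from alleles alone.
#'
#' @param a1,a2 Allele strings.
#' @return Logical vector.
#' @export
is_palindromic <- function(a1, a2) {
  nchar(a1) == 1L & nchar(a2) == 1L &
    !is.na(a1) & !is.na(a2) &
    unname(ALLELE_COMPLEMENT[a1] == a2)
}

new_harmonized_variant <- function(variant_id, status,
                                   beta_x = NA_real_, se_x = NA_real_,
                                   beta_y = NA_real_, se_y = NA_real_,
                                   eaf = NA_real_) {
  structure(list(variant_id = variant_id, beta_x = beta_x, se_x = se_x,
                 beta_y = beta_y, se_y = se_y, eaf = eaf, status = status),
            class = "harmonized_variant")
}

#' Harmonize one exposure/outcome variant pair
#'
#' Aligns the outcome record to the exposure's effect allele:
#' * identical allele pair (directly or after strand complement for
#'   non-palindromic SNPs) -> `aligned`;
#' * swapped alleles -> `flipped` (outcome beta negated, frequency
#'   complemented);
#' * palindromic pair with either dataset's effect-allele frequency inside
#'   `af_window` -> `excluded_palindromic` (frequency cannot resolve the
#'   strand); outside the window the pair is aligned by frequency matching,
#'   or excluded when either frequency is missing;
#' * irreconcilable alleles -> `excluded_mismatch`. Indels are compared as
#'   exact strings with no strand complement.
#'
#' @param x,y Single-row exposure and outcome association records (data frame
#'   rows or lists with the canonical fields) for the same `variant_id`.
#' @param af_window Ambiguity window `c(low, high)` on the allele frequency
#'   of palindromic variants (default `c(0.4, 0.6)`).
#' @param palindrome_filter Set `FALSE` to skip the palindromic exclusion and
#'   rely on frequency matching alone.
#' @return A `harmonized_variant`; excluded records carry no effect fields.
#' @export
harmonize_pair <- function(x, y, af_window = c(0.4, 0.6),
                           palindrome_filter = TRUE) {
  x <- as.list(x); y <- as.list(y)
  if (!identical(as.character(x$variant_id), as.character(y$variant_id))) {
    stop_mr("variant_id mismatch: ", x$variant_id, " vs ", y$variant_id,
            class = "mrkit_usage_error")
  }
  vid <- as.character(x$variant_id)
  xe <- toupper(x$effect_allele); xo <- toupper(x$other_allele)
  ye <- toupper(y$effect_allele); yo <- toupper(y$other_allele)
  pal <- is_palindromic(xe, xo)

  done <- function(status, flip = FALSE) {
    if (!(status %in% c("aligned", "flipped"))) {
      return(new_harmonized_variant(vid, status))
    }
    new_harmonized_variant(
      vid, status,
      beta_x = x$beta, se_x = x$se,
      beta_y = if (flip) -y$beta else y$beta,
      se_y = y$se,
      eaf = if (is.null(x$eaf)) NA_real_ else as.numeric(x$eaf))
  }

  if (isTRUE(pal)) {
    eaf_x <- as.numeric(x$eaf %||% NA)
    eaf_y <- as.numeric(y$eaf %||% NA)
    same <- ye == xe && yo == xo
    swapped <- ye == xo && yo == xe
    if (!same && !swapped) return(done("excluded_mismatch"))
    if (palindrome_filter) {
      inside <- function(f) !is.na(f) &&
        f >= af_window[1L] && f <= af_window[2L]
      if (inside(eaf_x) || inside(eaf_y)) return(done("excluded_palindromic"))
    }
    # Palindromic allele labels carry no strand information, so orientation
    # rests entirely on minor/major frequency matching: agreeing frequencies
    # mean the outcome's effect allele is the exposure's effect allele.
    if (is.na(eaf_x) || is.na(eaf_y)) return(done("excluded_palindromic"))
    freq_agree <- (eaf_x < 0.5) == (eaf_y < 0.5)
    return(done(if (freq_agree) "aligned" else "flipped", flip = !freq_agree))
  }

  if (ye == xe && yo == xo) return(done("aligned"))
  if (ye == xo && yo == xe) return(done("flipped", flip = TRUE))
  if (nchar(xe) == 1L && nchar(xo) == 1L) {
    yec <- complement_alleles(ye); yoc <- complement_alleles(yo)
    if (!is.na(yec) && !is.na(yoc)) {
      if (yec == xe && yoc == xo) return(done("aligned"))
      if (yec == xo && yoc == xe) return(done("flipped", flip = TRUE))
    }
  }
  done("excluded_mismatch")
}

#' Harmonize exposure and outcome summary statistics
#'
#' Intersects the two tables on `variant_id`, applies [harmonize_pair()] to
#' each shared variant, and returns the aligned effect pairs with an
#' exclusion log.
#'
#' @param exposure,outcome Summary-statistic tables (the exposure table is
#'   typically an instrument set's `variants`).
#' @inheritParams harmonize_pair
#' @return An `mr_dataset`: data frame with columns `variant_id`, `beta_x`,
#'   `se_x`, `beta_y`, `se_y`, `eaf`, `status`, carrying attributes
#'   `exposure_id`, `outcome_id` and `exclusion_log` (reason counts).
#' @export
harmonize_dataset <- function(exposure, outcome, af_window = c(0.4, 0.6),
                              palindrome_filter = TRUE) {
  if (inherits(exposure, "instrument_set")) exposure <- exposure$variants
  exposure <- as.data.frame(exposure)
  outcome_df <- as.data.frame(outcome)
  shared <- intersect(unique(exposure$variant_id), unique(outcome_df$variant_id))
  if (!length(shared)) {
    stop_mr("no shared variants between exposure and outcome",
            class = "mrkit_usage_error")
  }
  xi <- exposure[match(shared, exposure$variant_id), , drop = FALSE]
  yi <- outcome_df[match(shared, outcome_df$variant_id), , drop = FALSE]
  rows <- lapply(seq_along(shared), function(i) {
    harmonize_pair(xi[i, , drop = FALSE], yi[i, , drop = FALSE],
                   af_window = af_window,
                   palindrome_filter = palindrome_filter)
  })
  status <- vapply(rows, `[[`, character(1), "status")
  keep <- status %in% c("aligned", "flipped")
  out <- data.frame(
    variant_id = vapply(rows, `[[`, character(1), "variant_id")[keep],
    beta_x = vapply(rows, `[[`, numeric(1), "beta_x")[keep],
    se_x = vapply(rows, `[[`, numeric(1), "se_x")[keep],
    beta_y = vapply(rows, `[[`, numeric(1), "beta_y")[keep],
    se_y = vapply(rows, `[[`, numeric(1), "se_y")[keep],
    eaf = vapply(rows, `[[`, numeric(1), "eaf")[keep],
    status = status[keep],
    stringsAsFactors = FALSE
  )
  log_tab <- table(factor(status, levels = c("aligned", "flipped",
                                             "excluded_palindromic",
                                             "excluded_mismatch")))
  exclusion_log <- data.frame(reason = names(log_tab),
                              count = as.integer(log_tab),
                              stringsAsFactors = FALSE)
  xmeta <- attr(exposure, "trait_meta")
  ymeta <- attr(outcome, "trait_meta")
  structure(out,
            exposure_id = xmeta$trait_id %||% unique(exposure$trait_id)[1L],
            outcome_id = ymeta$trait_id %||% unique(outcome_df$trait_id)[1L],
            exclusion_log = exclusion_log,
            n_input = length(shared),
            class = c("mr_dataset", "data.frame"))
}

#' Exclusion log of a harmonized dataset
#' @param data An `mr_dataset`.
#' @return Data frame of per-reason variant counts.
#' @export
exclusion_log <- function(data) attr(data, "exclusion_log")

#' Construct an `mr_dataset` from aligned effect pairs
#'
#' Low-level constructor for already-harmonized per-variant effects (e.g.
#' simulated instruments).
#'
#' @param variant_id Variant identifiers.
#' @param beta_x,se_x Variant-exposure effects and standard errors.
#' @param beta_y,se_y Variant-outcome effects and standard errors.
#' @param eaf Optional effect-allele frequencies.
#' @param exposure_id,outcome_id Trait identifiers.
#' @return An `mr_dataset`.
#' @export
mr_dataset <- function(variant_id, beta_x, se_x, beta_y, se_y,
                       eaf = NA_real_, exposure_id = "exposure",
                       outcome_id = "outcome") {
  stopifnot(all(se_x > 0), all(se_y > 0))
  out <- data.frame(variant_id = as.character(variant_id),
                    beta_x = beta_x, se_x = se_x,
                    beta_y = beta_y, se_y = se_y,
                    eaf = eaf, status = "aligned",
                    stringsAsFactors = FALSE)
  structure(out, exposure_id = exposure_id, outcome_id = outcome_id,
            exclusion_log = data.frame(reason = character(),
                                       count = integer()),
            class = c("mr_dataset", "data.frame"))
}

check_mr_dataset <- function(data, min_variants = 1L, caller = "estimator") {
  need <- c("beta_x", "se_x", "beta_y", "se_y")
  if (!all(need %in% names(data))) {
    stop_mr(caller, " needs columns ", paste(need, collapse = ", "),
            class = "mrkit_usage_error")
  }
  if (nrow(data) < min_variants) {
    stop_mr(caller, " needs at least ", min_variants, " variants (got ",
            nrow(data), ")", class = "mrkit_insufficient_instruments")
  }
  invisible(data)
}
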