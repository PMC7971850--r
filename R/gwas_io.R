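# Reading, validating and writing GWAS summary statistics.
#
# A summary-statistic table is a data.frame with one row per variant and the
# canonical columns below; trait-level metadata (trait id, continuous/binary,
# unit label, sample sizes) travels as the "trait_meta" attribute.

CANONICAL_COLS <- c(
  "variant_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pvalue", "n", "n_case", "n_control"
)
REQUIRED_COLS <- c("variant_id", "effect_allele", "other_allele",
                   "beta", "se", "pvalue")
NUMERIC_COLS <- c("pos", "eaf", "beta", "se", "pvalue", "n",
                  "n_case", "n_control")

#' Default column dialect for summary-statistic files
#'
#' Maps canonical column names to the names used in a file. Override entries
#' to read other dialects, e.g. `default_dialect(beta = "b", pvalue = "p")`.
#'
#' @param ... Named overrides, `canonical = "file_column"`.
#' @return Named character vector mapping canonical names to file columns.
#' @export
#' @examples
#' default_dialect(beta = "b", se = "stderr")
default_dialect <- function(...) {
  d <- setNames(CANONICAL_COLS, CANONICAL_COLS)
  over <- c(...)
  if (length(over)) {
    bad <- setdiff(names(over), CANONICAL_COLS)
    if (length(bad)) {
      stop_mr("unknown dialect field(s): ", paste(bad, collapse = ", "),
              class = "mrkit_config_error")
    }
    d[names(over)] <- over
  }
  d
}

#' Attach trait metadata and validate a summary-statistic table
#'
#' @param df Data frame holding at least the required canonical columns
#'   (`variant_id`, `effect_allele`, `other_allele`, `beta`, `se`, `pvalue`).
#' @param trait_id Trait identifier.
#' @param trait_type `"continuous"` or `"binary"`. Binary traits must carry
#'   case/control counts (columns or the `n_case`/`n_control` arguments).
#' @param unit_label Unit of the per-allele effect (e.g. `"kg/m2"`,
#'   `"log-odds"`).
#' @param n,n_case,n_control Optional trait-level sample sizes used when the
#'   table has no per-variant columns.
#' @param on_invalid `"error"` to fail on rows violating record invariants,
#'   `"drop"` to remove them (the dropped rows stay available in the
#'   `"validation_log"` attribute).
#' @return The table with class `gwas_sumstats` and a `trait_meta` attribute.
#' @export
as_gwas_sumstats <- function(df, trait_id,
                             trait_type = c("continuous", "binary"),
                             unit_label = "unit",
                             n = NULL, n_case = NULL, n_control = NULL,
                             on_invalid = c("error", "drop")) {
  trait_type <- match.arg(trait_type)
  on_invalid <- match.arg(on_invalid)
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(REQUIRED_COLS, names(df))
  if (length(missing_cols)) {
    stop_mr("missing required column(s): ", paste(missing_cols, collapse = ", "),
            class = "mrkit_config_error")
  }
  for (col in setdiff(CANONICAL_COLS, names(df))) df[[col]] <- NA
  for (col in NUMERIC_COLS) df[[col]] <- as.numeric(df[[col]])
  if (!is.null(n)) df$n[is.na(df$n)] <- n
  if (!is.null(n_case)) df$n_case[is.na(df$n_case)] <- n_case
  if (!is.null(n_control)) df$n_control[is.na(df$n_control)] <- n_control
  df$variant_id <- as.character(df$variant_id)
  df$chrom <- as.character(df$chrom)
  df$effect_allele <- toupper(as.character(df$effect_allele))
  df$other_allele <- toupper(as.character(df$other_allele))
  df <- df[, CANONICAL_COLS]

  log <- validate_associations(df)
  if (nrow(log)) {
    if (on_invalid == "error") {
      stop_mr("invalid summary-statistic rows (first: line ", log$line[1L],
              ": ", log$message[1L], "); use on_invalid = \"drop\" to discard",
              class = "mrkit_validation_error")
    }
    df <- df[-unique(log$line), , drop = FALSE]
    rownames(df) <- NULL
  }
  if (trait_type == "binary" &&
      (all(is.na(df$n_case)) || all(is.na(df$n_control)))) {
    stop_mr("binary trait '", trait_id, "' requires n_case and n_control",
            class = "mrkit_config_error")
  }
  meta <- list(
    trait_id = trait_id, trait_type = trait_type, unit_label = unit_label,
    n = n %||% suppressWarnings(max(df$n, na.rm = TRUE)),
    n_case = n_case %||% suppressWarnings(max(df$n_case, na.rm = TRUE)),
    n_control = n_control %||% suppressWarnings(max(df$n_control, na.rm = TRUE))
  )
  meta[vapply(meta, function(x) is.numeric(x) && !is.finite(x), TRUE)] <- NA
  df$trait_id <- rep(trait_id, nrow(df))
  structure(df, trait_meta = meta, validation_log = log,
            class = c("gwas_sumstats", "data.frame"))
}

#' Check variant-association record invariants
#'
#' Applies the record-level rules (positive standard error, p-value in (0, 1],
#' distinct ACGT alleles, allele frequency in \[0, 1\], case + control = total
#' when all three are present) and reports violations row by row.
#'
#' @param df Summary-statistic table with canonical columns.
#' @return Data frame with columns `line` and `message` (empty when valid).
#' @export
validate_associations <- function(df) {
  problems <- list()
  note <- function(rows, msg) {
    rows <- which(rows)
    if (length(rows)) {
      problems[[length(problems) + 1L]] <<- data.frame(
        line = rows, message = msg, stringsAsFactors = FALSE)
    }
  }
  allele_ok <- function(a) !is.na(a) & grepl("^[ACGT]+$", a)
  note(is.na(df$beta), "beta is missing or non-numeric")
  note(!is.na(df$se) & df$se <= 0 | is.na(df$se),
       "se must be > 0 (positive standard error invariant)")
  note(is.na(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1,
       "pvalue must lie in (0, 1]")
  note(!allele_ok(df$effect_allele) | !allele_ok(df$other_allele),
       "alleles must be non-empty strings over {A,C,G,T}")
  note(allele_ok(df$effect_allele) & allele_ok(df$other_allele) &
         df$effect_allele == df$other_allele,
       "effect_allele must differ from other_allele")
  note(!is.na(df$eaf) & (df$eaf < 0 | df$eaf > 1),
       "eaf must lie in [0, 1]")
  note(!is.na(df$n) & !is.na(df$n_case) & !is.na(df$n_control) &
         df$n_case + df$n_control != df$n,
       "n_case + n_control must equal n when all are present")
  if (!length(problems)) {
    return(data.frame(line = integer(), message = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, problems)
  out[order(out$line), , drop = FALSE]
}

#' Read GWAS summary statistics from a delimited file
#'
#' @param path Path to a delimited text file with a header row.
#' @param dialect Column mapping from [default_dialect()]; canonical names not
#'   present in the file are left missing (the required set must resolve).
#' @param sep Field separator (default tab).
#' @inheritParams as_gwas_sumstats
#' @return A `gwas_sumstats` table (see [as_gwas_sumstats()]); rows failing
#'   validation are reported with their line numbers.
#' @export
read_summary_stats <- function(path, dialect = default_dialect(),
                               trait_id = basename(path),
                               trait_type = c("continuous", "binary"),
                               unit_label = "unit",
                               n = NULL, n_case = NULL, n_control = NULL,
                               sep = "\t",
                               on_invalid = c("error", "drop")) {
  if (!file.exists(path)) {
    stop_mr("file not found: ", path, class = "mrkit_io_error")
  }
  raw <- read.delim(path, sep = sep, header = TRUE,
                    colClasses = "character", check.names = FALSE,
                    stringsAsFactors = FALSE)
  missing_req <- REQUIRED_COLS[!(dialect[REQUIRED_COLS] %in% names(raw))]
  if (length(missing_req)) {
    stop_mr("required column(s) not found in ", path, ": ",
            paste(dialect[missing_req], collapse = ", "),
            " (canonical: ", paste(missing_req, collapse = ", "), ")",
            class = "mrkit_config_error")
  }
  df <- data.frame(row.names = seq_len(nrow(raw)))
  for (canon in CANONICAL_COLS) {
    src <- dialect[[canon]]
    df[[canon]] <- if (!is.null(src) && src %in% names(raw)) raw[[src]] else NA
  }
  as_gwas_sumstats(df, trait_id = trait_id, trait_type = trait_type,
                   unit_label = unit_label, n = n, n_case = n_case,
                   n_control = n_control, on_invalid = on_invalid)
}

# ---- result serialization ---------------------------------------------------

#' Convert an MR estimate to a one-row data frame
#' @param x An `mr_estimate`.
#' @param ... Unused.
#' @return One-row data frame with the estimate's numeric fields.
#' @export
as.data.frame.mr_estimate <- function(x, ...) {
  data.frame(
    method = x$method, beta = x$beta, se = x$se,
    ci_low = x$ci_low, ci_high = x$ci_high, pvalue = x$pvalue,
    n_variants = x$n_variants,
    q = x$q %||% NA_real_, q_pvalue = x$q_pvalue %||% NA_real_,
    intercept = x$intercept %||% NA_real_,
    intercept_se = x$intercept_se %||% NA_real_,
    intercept_pvalue = x$intercept_pvalue %||% NA_real_,
    stringsAsFactors = FALSE
  )
}

#' @export
as.data.frame.mr_presso_result <- function(x, ...) {
  k <- length(x$outlier_pvalues)
  data.frame(
    variant_id = names(x$outlier_pvalues),
    outlier_pvalue = unname(x$outlier_pvalues),
    is_outlier = names(x$outlier_pvalues) %in% x$outlier_ids,
    global_rss = x$global_rss, global_pvalue = x$global_pvalue,
    distortion_pvalue = x$distortion_pvalue %||% NA_real_,
    stringsAsFactors = FALSE
  )
}

#' @export
as.data.frame.mvmr_result <- function(x, ...) x$estimates

results_frame <- function(results) {
  if (is.data.frame(results)) return(as.data.frame(results))
  if (inherits(results, c("mr_estimate", "mr_presso_result", "mvmr_result"))) {
    return(as.data.frame(results))
  }
  if (is.list(results)) {
    return(do.call(rbind, lapply(results, results_frame)))
  }
  stop_mr("cannot serialize object of class ", paste(class(results), collapse = "/"),
          class = "mrkit_config_error")
}

#' Write MR results to disk
#'
#' Serializes estimates, MR-PRESSO results, multivariable fits or plain data
#' frames to TSV or JSON. Numeric fields survive a read-back round trip to at
#' least 12 significant digits.
#'
#' @param results A result object, data frame, or list of result objects.
#' @param path Output file path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  df <- results_frame(results)
  ok <- tryCatch({
    if (format == "tsv") {
      out <- df
      for (col in names(out)) {
        if (is.double(out[[col]])) {
          out[[col]] <- ifelse(is.na(out[[col]]), NA,
                               sprintf("%.15g", out[[col]]))
        }
      }
      write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                  na = "NA")
    } else {
      jsonlite::write_json(df, path, dataframe = "rows", digits = NA,
                           na = "null", auto_unbox = TRUE)
    }
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) {
    stop_mr("cannot write results to ", path, ": ", conditionMessage(ok),
            class = "mrkit_io_error")
  }
  invisible(path)
}
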