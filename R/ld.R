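# LD sources: a pairwise r-squared lookup contract used by clumping.
#
# A source answers r2(a, b) for any pair of variant ids: 1 when a == b, the
# stored value when the (unordered) pair is known, 0 otherwise. Known ids are
# tracked so clumping can warn when candidates fall outside the panel.

new_ld_source <- function(pairs, ids, label) {
  structure(list(pairs = pairs, ids = ids, label = label),
            class = "ld_source")
}

pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' LD source with no linkage information
#'
#' Every distinct pair has r-squared 0; appropriate for variant sets that are
#' independent by construction (e.g. simulated post-clumping instruments),
#' where pruning falls back to the distance rule alone.
#'
#' @return An `ld_source`.
#' @export
ld_source_empty <- function() {
  new_ld_source(new.env(parent = emptyenv()), character(), "empty")
}

#' LD source from a pairwise table
#'
#' @param table Data frame with columns `id_a`, `id_b`, `r2` (one row per
#'   variant pair; symmetry is implied).
#' @return An `ld_source`.
#' @export
ld_source_table <- function(table) {
  table <- as.data.frame(table)
  need <- c("id_a", "id_b", "r2")
  if (!all(need %in% names(table))) {
    stop_mr("LD table needs columns id_a, id_b, r2",
            class = "mrkit_config_error")
  }
  r2 <- as.numeric(table$r2)
  if (any(is.na(r2) | r2 < 0 | r2 > 1)) {
    stop_mr("LD r2 values must lie in [0, 1]", class = "mrkit_config_error")
  }
  env <- new.env(parent = emptyenv())
  keys <- pair_key(as.character(table$id_a), as.character(table$id_b))
  for (i in seq_along(keys)) assign(keys[i], r2[i], envir = env)
  new_ld_source(env, unique(c(table$id_a, table$id_b)), "table")
}

#' LD source from a square r-squared matrix
#'
#' @param mat Square numeric matrix with variant ids as dimnames (a header
#'   row of ids in file form); diagonal must be 1.
#' @return An `ld_source`.
#' @export
ld_source_matrix <- function(mat) {
  mat <- as.matrix(mat)
  ids <- colnames(mat)
  if (is.null(ids) || nrow(mat) != ncol(mat)) {
    stop_mr("LD matrix must be square with variant ids as column names",
            class = "mrkit_config_error")
  }
  rownames(mat) <- ids
  if (any(abs(diag(mat) - 1) > 1e-8)) {
    stop_mr("LD matrix diagonal must be 1", class = "mrkit_config_error")
  }
  if (any(is.na(mat) | mat < 0 | mat > 1)) {
    stop_mr("LD r2 values must lie in [0, 1]", class = "mrkit_config_error")
  }
  idx <- which(upper.tri(mat), arr.ind = TRUE)
  tab <- data.frame(id_a = ids[idx[, 1L]], id_b = ids[idx[, 2L]],
                    r2 = mat[idx], stringsAsFactors = FALSE)
  src <- ld_source_table(tab[tab$r2 > 0, , drop = FALSE])
  src$ids <- ids
  src
}

#' Read an LD source from a delimited file
#'
#' Accepts either a 3-column pair table (header `id_a  id_b  r2`) or a square
#' matrix with a header row of variant ids.
#'
#' @param path File path.
#' @param sep Field separator.
#' @return An `ld_source`.
#' @export
read_ld_source <- function(path, sep = "\t") {
  if (!file.exists(path)) {
    stop_mr("file not found: ", path, class = "mrkit_io_error")
  }
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (identical(names(df)[1:3], c("id_a", "id_b", "r2")) && ncol(df) == 3L) {
    return(ld_source_table(df))
  }
  ld_source_matrix(as.matrix(df))
}

#' Look up pairwise r-squared values
#'
#' Vectorized over `a`/`b`. Returns 1 when `a == b`, the stored value for
#' known pairs, 0 for absent pairs (symmetric by construction).
#'
#' @param ld An `ld_source`.
#' @param a,b Variant id vectors (recycled to common length).
#' @return Numeric vector of r-squared values in \[0, 1\].
#' @export
ld_r2 <- function(ld, a, b) {
  stopifnot(inherits(ld, "ld_source"))
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- numeric(n)
  same <- a == b
  out[same] <- 1
  if (any(!same)) {
    keys <- pair_key(a[!same], b[!same])
    out[!same] <- vapply(keys, function(k) {
      v <- get0(k, envir = ld$pairs, inherits = FALSE)
      if (is.null(v)) 0 else v
    }, numeric(1), USE.NAMES = FALSE)
  }
  out
}

#' @export
print.ld_source <- function(x, ...) {
  cat("<ld_source:", x$label, "-", length(x$ids), "known variants>\n")
  invisible(x)
}
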