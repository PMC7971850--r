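`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` after `set.seed(seed)`, then restores the caller's RNG state,
#' so seeded bootstrap/simulation helpers do not disturb the global stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive independent child seeds from one master seed (kept < 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stop_mr <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "mrkit_error")))
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
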