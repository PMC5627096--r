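# Internal helpers shared across modules.

#' @importFrom stats cor quantile rexp runif sd var
#' @importFrom utils head read.csv write.csv
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so seeded functions do not
#' perturb the global random stream. A NULL seed evaluates the expression
#' under the current stream.
#' @noRd
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)
  }
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage seed from a master seed
#'
#' Deterministic mixing of the master seed with a stage label so that
#' pipeline stages can be re-run in isolation. Result is in [1, 2^31 - 2].
#' @param seed master seed (integer-like) or NULL.
#' @param stage character stage label.
#' @return integer seed, or NULL if `seed` is NULL.
#' @export
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  stopifnot(is.character(stage), length(stage) == 1L)
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  # all arithmetic kept < 2^53 so doubles stay exact
  x <- (as.numeric(seed) %% 2147483647) * 69069 + h * 1013 + 1
  as.integer(x %% 2147483646 + 1)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)
warn_fmt <- function(...) warning(sprintf(...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 0 && x == floor(x)
}

is_pos_num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x > 0

upper_vec <- function(m) m[upper.tri(m)]
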