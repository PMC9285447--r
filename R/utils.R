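# Internal helpers shared across modules.

# Maximum phone-sequence length; longer words are truncated, shorter ones
# zero-padded and masked.
MAX_PHONES <- 15L

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the global random number generator seeded to `seed`,
#' restoring the previous RNG state afterwards so that library calls never
#' clobber the caller's random stream.
#'
#' @param seed single integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_fmt("`%s` must be a single non-missing number", name)
  if (integer && x != round(x))
    stop_fmt("`%s` must be an integer, got %s", name, format(x))
  if (x < lower || x > upper)
    stop_fmt("`%s` must be in [%s, %s], got %s", name,
             format(lower), format(upper), format(x))
  invisible(x)
}

# round-half-up, used for the train/test split size so that printed split
# sizes such as 1161 -> 929/232 are reproduced (floor would give 928).
round_half_up <- function(x) floor(x + 0.5)
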