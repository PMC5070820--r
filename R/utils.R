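#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so seeded operations do not
#' perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current stream unchanged.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# deterministic sub-seed for a (session, stage) pair; stays below 2^31
derive_seed <- function(base, session = 0L, stage = 0L) {
  if (is.null(base)) return(NULL)
  as.integer((as.double(base) + 1009 * session + 101 * stage) %% 2147483647)
}

stop_accelcal <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, ...) if (!isTRUE(ok)) stop_accelcal(...)

is_count <- function(x) length(x) >= 1 && is.numeric(x) && all(is.finite(x)) &&
  all(x >= 0) && all(x == round(x))

is_prob <- function(x) length(x) == 1 && is.numeric(x) && is.finite(x) &&
  x >= 0 && x <= 1
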