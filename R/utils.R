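#' @importFrom rlang abort warn %||%
#' @importFrom stats rnorm runif rbinom rpois rexp sd quantile median
#'   pnorm dnorm qnorm var t.test wilcox.test setNames complete.cases
#' @importFrom utils head tail
NULL

# Run `code` under a fixed RNG seed without disturbing the caller's stream.
# seed = NULL leaves the global stream untouched (still consumed).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream-specific child seed from a user seed; keeps values in
# 32-bit integer range so set.seed() never overflows.
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.double(seed) * 48271 + stream) %% 2147483647
}

stop_param <- function(msg, ...) abort(paste0(msg, ...), class = "ktrdyn_parameter_error")

check_number <- function(x, name, lower = -Inf, upper = Inf, strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_param(sprintf("`%s` must be a single finite number", name))
  }
  if (x < lower || (strict_lower && x <= lower) || x > upper) {
    stop_param(sprintf("`%s` = %g is outside its allowed range", name, x))
  }
  invisible(x)
}

check_fraction <- function(x, name) check_number(x, name, lower = 0, upper = 1)

# Maximum |ECDF - F| for a sorted numeric sample against model CDF values.
ks_statistic_cdf <- function(x_sorted, Fx) {
  n <- length(x_sorted)
  i <- seq_len(n)
  max(pmax(i / n - Fx, Fx - (i - 1) / n))
}
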