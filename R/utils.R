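#' @useDynLib rodletkin, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef lm median nls optim pchisq pt qchisq qnorm quantile
#'   rexp rnorm runif sd setNames
#' @importFrom utils head read.delim tail write.table packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

# signal an error with package condition classes so callers can distinguish
# validation problems from fit failures or degenerate inputs
stop_rk <- function(msg, ..., class = "validation") {
  if (...length() > 0L) msg <- sprintf(msg, ...)
  cnd <- structure(
    class = c(paste0("rodletkin_", class), "rodletkin_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cnd)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_lower = TRUE, allow_upper = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_rk("'%s' must be a single finite number", name)
  lo_ok <- if (allow_lower) x >= lower else x > lower
  hi_ok <- if (allow_upper) x <= upper else x < upper
  if (!lo_ok || !hi_ok)
    stop_rk("'%s' = %g is outside the allowed range %s%g, %g%s", name, x,
            if (allow_lower) "[" else "(", lower, upper,
            if (allow_upper) "]" else ")")
  x
}

check_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x))
    stop_rk("'%s' must be TRUE or FALSE", name)
  x
}

check_seed <- function(seed) {
  if (is.null(seed)) return(NULL)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed) || seed != round(seed))
    stop_rk("'seed' must be NULL or a single integer")
  as.integer(seed)
}

# Evaluate `code` under a given seed without disturbing the caller's RNG
# stream; seed = NULL uses (and advances) the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
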