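# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Stop with a formatted message
#' @noRd
abort_input <- function(...) stop(sprintf(...), call. = FALSE)

#' Check a scalar is a finite number
#' @noRd
check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    abort_input("`%s` must be a single finite number", name)
  if (x < min || x > max)
    abort_input("`%s` = %g is outside [%g, %g]", name, x, min, max)
  invisible(x)
}

#' Require columns in a data frame
#' @noRd
check_columns <- function(data, cols, where = "data") {
  missing <- setdiff(cols, names(data))
  if (length(missing))
    abort_input("%s is missing required column(s): %s",
                where, paste(missing, collapse = ", "))
  invisible(data)
}

#' Run an expression under a temporary seed, restoring the RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Derive a stream-specific child seed from a master seed
#'
#' Keeps derived seeds strictly below 2^31 so they remain valid R integers.
#' @noRd
child_seed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  (as.numeric(seed) * 1000003 + stream) %% 2147483629
}

#' Binary entropy in nats, safe at 0 and 1
#' @noRd
entropy_binary <- function(p) {
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  -(p * log(p) + (1 - p) * log(1 - p))
}
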