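# Group-level tests and design diagnostics: standardization, variance
# inflation factors, one-sample Wilcoxon signed-rank (exact null by dynamic
# programming, or normal approximation with continuity correction), and the
# Pearson correlation t-test. Statistic-only entry points are provided so
# printed statistics can be re-checked without raw data.

#' Standardize predictor columns
#'
#' Transforms each named column to mean 0, SD 1 and records the scaling so
#' coefficients can be mapped back to the raw scale. Interactions should be
#' built from standardized main effects (the model-fitting code does this).
#'
#' @param data A data frame.
#' @param columns Character vector of numeric columns to standardize.
#' @return List with `data` (transformed) and `scaling` (data frame of
#'   `column`, `center`, `scale`).
#' @export
standardize_predictors <- function(data, columns) {
  if (!length(columns))
    return(list(data = data,
                scaling = data.frame(column = character(0), center = numeric(0),
                                     scale = numeric(0))))
  check_columns(data, columns)
  scaling <- data.frame(column = columns, center = NA_real_, scale = NA_real_)
  for (i in seq_along(columns)) {
    x <- data[[columns[i]]]
    if (!is.numeric(x)) abort_input("column `%s` is not numeric", columns[i])
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0)
      abort_input("column `%s` has zero variance; cannot standardize", columns[i])
    scaling$center[i] <- mean(x)
    scaling$scale[i] <- s
    data[[columns[i]]] <- (x - mean(x)) / s
  }
  list(data = data, scaling = scaling)
}

#' Variance inflation factors
#'
#' `VIF_k = 1 / (1 - R^2_k)` from regressing design column `k` on all other
#' columns (with an intercept, which is itself excluded from scoring). A VIF
#' below 3 is conventionally read as collinearity not being an issue.
#'
#' @param design A numeric matrix or data frame of predictor columns
#'   (no intercept column), or a `mixed_fit` from [fit_glmm()].
#' @param ... Unused.
#' @return Named numeric vector of VIFs.
#' @export
vif <- function(design, ...) UseMethod("vif")

#' @export
vif.default <- function(design, ...) {
  X <- as.matrix(design)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- apply(X, 2, stats::sd) > 0
  X <- X[, keep, drop = FALSE]
  qrX <- qr(cbind(1, X))
  if (qrX$rank < ncol(X) + 1) {
    dep <- colnames(X)[qrX$pivot[seq(qrX$rank + 1, ncol(X) + 1)] - 1L]
    abort_input("design is rank deficient; dependent column(s): %s",
                paste(dep, collapse = ", "))
  }
  if (ncol(X) == 1L) return(stats::setNames(1, colnames(X)))
  vapply(seq_len(ncol(X)), function(k) {
    r2 <- summary(stats::lm(X[, k] ~ X[, -k, drop = FALSE]))$r.squared
    1 / (1 - r2)
  }, numeric(1)) -> v
  stats::setNames(v, colnames(X))
}

# --- Wilcoxon signed rank -------------------------------------------------

# Exact null distribution of the signed-rank statistic V for sample size n,
# by subset-sum dynamic programming over ranks 1..n. Returns the probability
# vector over support 0..n(n+1)/2.
signrank_null <- function(n) {
  maxv <- n * (n + 1) / 2
  f <- c(1, rep(0, maxv))
  for (k in seq_len(n)) {
    shifted <- c(rep(0, k), f[seq_len(maxv + 1 - k)])
    f <- (f + shifted) / 2
  }
  f
}

#' One-sample Wilcoxon signed-rank test
#'
#' Two-tailed test of symmetry about zero. Either raw `values` or the
#' statistic pair `(v, n)` may be supplied. `method = "exact"` builds the
#' full null distribution of V by dynamic programming over ranks (requires no
#' zeros and no tied absolute values when raw values are given) and doubles
#' the smaller tail, capped at 1. `method = "normal_cc"` uses the normal
#' approximation with a 0.5 continuity correction toward the null mean.
#'
#' @param values Numeric vector of (differences from zero), or `NULL` when
#'   `v` and `n` are given.
#' @param v,n Signed-rank statistic and sample size (statistic-only entry).
#' @param method `"exact"` or `"normal_cc"`.
#' @param tails 1 or 2 (default 2).
#' @return A `test_result` list: `statistic` (V), `n`, `p_value`, `method`,
#'   `tails`.
#' @export
wilcoxon_signed_rank <- function(values = NULL, v = NULL, n = NULL,
                                 method = c("exact", "normal_cc"), tails = 2) {
  method <- match.arg(method)
  if (!is.null(values)) {
    if (any(values == 0))
      abort_input("zeros present; drop them or use method = 'normal_cc'")
    a <- abs(values)
    if (method == "exact" && anyDuplicated(a))
      abort_input("tied absolute values; exact null invalid, use method = 'normal_cc'")
    n <- length(values)
    rk <- rank(a)
    v <- sum(rk[values > 0])
  }
  if (is.null(v) || is.null(n))
    abort_input("supply either `values` or both `v` and `n`")
  check_number(v, "v", min = 0, max = n * (n + 1) / 2)
  mu <- n * (n + 1) / 4
  if (method == "exact") {
    null <- signrank_null(n)
    lower <- sum(null[seq_len(v + 1)])          # P(V <= v)
    upper <- sum(null[seq(v + 1, length(null))]) # P(V >= v)
    p <- min(1, if (tails == 2) 2 * min(lower, upper)
             else if (v >= mu) upper else lower)
  } else {
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    z <- (v - mu - sign(v - mu) * 0.5) / sigma   # continuity correction
    p <- if (tails == 2) 2 * stats::pnorm(-abs(z)) else stats::pnorm(-abs(z))
  }
  structure(list(statistic = c(V = v), n = n, p_value = p,
                 method = paste0("wilcoxon-", sub("_", "-", method)),
                 tails = tails), class = "test_result")
}

#' Pearson correlation test
#'
#' Two-sided t-test of a Pearson correlation, `t = r sqrt(n-2)/sqrt(1-r^2)`
#' on `n - 2` df. Accepts raw vectors or the statistic pair `(r, n)`.
#'
#' @param x,y Numeric vectors, or `NULL` when `r` and `n` are given.
#' @param r,n Correlation and sample size (statistic-only entry).
#' @return A `test_result` with `statistic` (r), `n`, `p_value`, `method`.
#' @export
pearson_correlation_test <- function(x = NULL, y = NULL, r = NULL, n = NULL) {
  if (!is.null(x)) {
    ok <- stats::complete.cases(x, y)
    x <- x[ok]; y <- y[ok]
    n <- length(x)
    if (n < 3) abort_input("need n >= 3 for a correlation test")
    r <- stats::cor(x, y)
  }
  if (is.null(r) || is.null(n))
    abort_input("supply either `x`,`y` or both `r` and `n`")
  degenerate <- abs(r) >= 1 - 1e-12
  p <- if (degenerate) 0 else {
    t <- r * sqrt(n - 2) / sqrt(1 - r^2)
    2 * stats::pt(-abs(t), df = n - 2)
  }
  structure(list(statistic = c(r = r), n = n, p_value = p,
                 method = "pearson-t", tails = 2, degenerate = degenerate),
            class = "test_result")
}

#' Upper-tail chi-square p-value (likelihood-ratio test reporting)
#'
#' @param statistic Chi-square statistic.
#' @param df Degrees of freedom.
#' @return A `test_result`.
#' @export
chisq_tail_test <- function(statistic, df = 1) {
  structure(list(statistic = c(chisq = statistic), df = df,
                 p_value = stats::pchisq(statistic, df, lower.tail = FALSE),
                 method = "chi2-tail", tails = 1), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: %s = %.6g, %s, p = %.4g\n", x$method,
              names(x$statistic)[1], x$statistic[1],
              if (!is.null(x$df)) sprintf("df = %g", x$df)
              else sprintf("n = %g", x$n),
              x$p_value))
  invisible(x)
}
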