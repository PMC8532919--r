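#' Simple ordinary least-squares fit with F test and adjusted R-squared
#'
#' Closed-form simple linear regression `y ~ x` reporting the quantities
#' used throughout the package's trend analyses: slope, intercept, the
#' model F statistic on (1, n−2) degrees of freedom, R², adjusted R²
#' \eqn{1 - (1 - R^2)(n-1)/(n-2)}, and the two-sided p-value of the F test.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`; `x` must not be
#'   constant. Pairs with `NA` in either are dropped.
#' @return An object of class `ols_fit`: list with `slope`, `intercept`,
#'   `F`, `df` (`c(1, n - 2)`), `r2`, `adj_r2`, `p`, `n`.
#' @examples
#' f <- ols_fit(1:10, 2 * (1:10))
#' f$slope # 2
#' f$adj_r2 # 1
#' @export
ols_fit <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("OLS needs n >= 3", call. = FALSE)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("x is constant; slope undefined", call. = FALSE)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_mod <- ss_tot - ss_res
  df2 <- n - 2
  ms_res <- ss_res / df2
  f_stat <- if (ms_res == 0) Inf else ss_mod / ms_res
  r2 <- if (ss_tot == 0) 1 else ss_mod / ss_tot
  structure(
    list(
      slope = slope, intercept = intercept, F = f_stat, df = c(1, df2),
      r2 = r2, adj_r2 = 1 - (1 - r2) * (n - 1) / df2,
      p = stats::pf(f_stat, 1, df2, lower.tail = FALSE), n = n
    ),
    class = "ols_fit"
  )
}

#' @export
print.ols_fit <- function(x, ...) {
  cat(sprintf(
    "OLS fit: slope %.4g, intercept %.4g, F(1|%d) = %.4g, adj. R^2 = %.3f, p = %.3g\n",
    x$slope, x$intercept, x$df[2], x$F, x$adj_r2, x$p
  ))
  invisible(x)
}

#' Pearson correlation with Student t test
#'
#' Correlation coefficient from centered cross-moments, with the two-sided
#' test \eqn{t = r\sqrt{(n-2)/(1-r^2)}} on `n − 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, each with
#'   positive variance. Pairs with `NA` are dropped.
#' @return List of class `pearson_cor` with `r`, `t`, `df`, `p`, `n`.
#' @examples
#' pearson_cor(c(1, 2, 3, 4), c(2, 1, 4, 3))$r # 0.6
#' @export
pearson_cor <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(length(y) == n)
  if (n < 3) stop("correlation needs n >= 3", call. = FALSE)
  cx <- x - mean(x); cy <- y - mean(y)
  sxx <- sum(cx^2); syy <- sum(cy^2)
  if (sxx == 0 || syy == 0) stop("zero variance in input", call. = FALSE)
  r <- sum(cx * cy) / sqrt(sxx * syy)
  r <- max(-1, min(1, r))
  df <- n - 2
  t_stat <- if (abs(r) == 1) Inf * sign(r) else r * sqrt(df / (1 - r^2))
  structure(
    list(r = r, t = t_stat, df = df,
         p = 2 * stats::pt(abs(t_stat), df, lower.tail = FALSE), n = n),
    class = "pearson_cor"
  )
}

#' Coefficient of variation, in percent
#'
#' `100 * sd / mean`. Called either with a vector of values or with a
#' pre-computed mean and standard deviation (as when reproducing published
#' summary tables).
#'
#' @param x Numeric vector of values, or (when `sd` is given) the mean.
#' @param sd Optional standard deviation accompanying a scalar mean in `x`.
#' @return CV as a percentage.
#' @examples
#' cv(19.8, 0.7) # 3.535... -> 3.5% at one decimal
#' cv(c(2, 2, 2)) # 0
#' @export
cv <- function(x, sd = NULL) {
  if (is.null(sd)) {
    x <- x[!is.na(x)]
    m <- mean(x)
    s <- stats::sd(x)
  } else {
    stopifnot(length(x) == 1, length(sd) == 1)
    m <- x
    s <- sd
  }
  if (!is.finite(m) || m <= 0) stop("CV requires mean > 0", call. = FALSE)
  100 * s / m
}

#' Pairwise Pearson correlation report
#'
#' Computes all pairwise correlations among the numeric columns of a wide
#' per-animal table (e.g. cumulative roaming entropy at chosen dates, body
#' weight, behavior frequencies, resting metabolic rate). Raw p-values are
#' reported without multiple-testing correction; a cautionary flag column
#' marks nominal significance so that readers are reminded the design is
#' exploratory.
#'
#' @param data Data frame; one row per animal. Non-numeric columns are
#'   ignored. Pairs with fewer than 3 complete observations are skipped.
#' @param alpha Nominal level for the cautionary flag (default 0.05).
#' @return Tibble `var1, var2, n, r, t, p, flag` with `flag` equal to
#'   `"p < alpha (uncorrected)"` or `""`.
#' @export
correlation_matrix <- function(data, alpha = 0.05) {
  num <- vapply(data, is.numeric, TRUE)
  vars <- names(data)[num]
  if (length(vars) < 2) stop("need >= 2 numeric columns", call. = FALSE)
  pairs <- utils::combn(vars, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    v1 <- pairs[1, i]; v2 <- pairs[2, i]
    ok <- !is.na(data[[v1]]) & !is.na(data[[v2]])
    if (sum(ok) < 3) return(NULL)
    ct <- tryCatch(pearson_cor(data[[v1]][ok], data[[v2]][ok]),
                   error = function(e) NULL)
    if (is.null(ct)) return(NULL)
    tibble::tibble(
      var1 = v1, var2 = v2, n = ct$n, r = ct$r, t = ct$t, p = ct$p,
      flag = if (ct$p < alpha) sprintf("p < %g (uncorrected)", alpha) else ""
    )
  })
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}
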