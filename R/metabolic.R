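#' Cumulative frequency curve of an oxygen-consumption trace
#'
#' Sorts the measured V̇O₂ values and pairs each distinct value with the
#' percentage of observations at or below it: at rank `i` of `n`,
#' `y = 100 * i / n`; tied values share the highest rank's percentage, so
#' each distinct V̇O₂ appears once.
#'
#' @param vo2 Numeric vector of oxygen consumption rates
#'   (mL min\eqn{^{-1}} kg\eqn{^{-1}}), `n >= 2`, all positive.
#' @return Tibble with `x` (ascending distinct V̇O₂) and `y` (cumulative
#'   frequency, percent; last value 100).
#' @examples
#' cumulative_frequency(c(1, 2, 3, 4))$y # 25 50 75 100
#' @export
cumulative_frequency <- function(vo2) {
  vo2 <- vo2[!is.na(vo2)]
  if (length(vo2) == 0) stop("empty V̇O2 input", call. = FALSE)
  if (length(vo2) < 2) stop("need >= 2 values", call. = FALSE)
  if (any(vo2 <= 0)) stop("V̇O2 values must be positive", call. = FALSE)
  tab <- table(vo2)
  x <- as.numeric(names(tab))
  tibble::tibble(x = x, y = 100 * cumsum(as.numeric(tab)) / length(vo2))
}

two_segment_rss <- function(x, y, psi) {
  X <- cbind(1, x, pmax(x - psi, 0))
  fit <- stats::lm.fit(X, y)
  sum(fit$residuals^2)
}

#' Continuous two-segment linear fit with breakpoint search
#'
#' Fits the broken-line model `y = b0 + b1*x + b2*(x - psi)+` (two straight
#' segments joining continuously at the breakpoint `psi`), minimizing the
#' residual sum of squares over `psi`. The breakpoint is located by a grid
#' search over interior x-quantiles followed by golden-section refinement
#' between the neighbouring grid points; ties favour the smaller `psi`.
#' This search is deterministic and globally robust, and coincides with
#' iterative broken-line estimators when the breakpoint is well separated.
#'
#' @param x Sorted numeric predictor (`>= 6` points).
#' @param y Numeric response of the same length.
#' @param n_grid Number of grid candidates (default 200).
#' @param qrange Quantile range of `x` searched for the breakpoint
#'   (default `c(0.02, 0.98)`).
#' @param min_side Minimum number of points required on each side of an
#'   admissible breakpoint (default 3).
#' @return Object of class `segmented_fit`: list with `psi`, `slopes`
#'   (left and right segment slopes), `intercept`, `rss`, `rss_single`
#'   (best single straight line), `no_breakpoint` (`TRUE` when the RSS
#'   improvement over the single line is below 1%), `n_left`, `n_right`.
#' @examples
#' x <- 1:20
#' y <- ifelse(x <= 10, x, 10 + 3 * (x - 10))
#' segmented_fit(x, y)$psi # 10
#' @export
segmented_fit <- function(x, y, n_grid = 200, qrange = c(0.02, 0.98),
                          min_side = 3) {
  stopifnot(length(x) == length(y))
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 6) stop("segmented fit needs >= 6 points", call. = FALSE)
  if (is.unsorted(x)) stop("x must be sorted ascending", call. = FALSE)

  lo <- as.numeric(stats::quantile(x, qrange[1], names = FALSE))
  hi <- as.numeric(stats::quantile(x, qrange[2], names = FALSE))
  cand <- unique(seq(lo, hi, length.out = n_grid))
  admissible <- vapply(cand, function(p) {
    sum(x <= p) >= min_side && sum(x > p) >= min_side
  }, TRUE)
  cand <- cand[admissible]
  if (length(cand) == 0) stop("no admissible breakpoint", call. = FALSE)

  rss_grid <- vapply(cand, function(p) two_segment_rss(x, y, p), 0)
  best <- which(rss_grid == min(rss_grid))[1] # tie -> smaller psi
  # golden-section refinement between the neighbouring grid candidates
  a <- cand[max(1, best - 1)]
  b <- cand[min(length(cand), best + 1)]
  gr <- (sqrt(5) - 1) / 2
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- two_segment_rss(x, y, c1); f2 <- two_segment_rss(x, y, c2)
  while (b - a > 1e-9 * max(1, abs(hi))) {
    if (f1 <= f2) { # <= : ties move toward smaller psi
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- two_segment_rss(x, y, c1)
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- two_segment_rss(x, y, c2)
    }
  }
  psi <- (a + b) / 2
  refined <- two_segment_rss(x, y, psi)
  if (refined > rss_grid[best]) psi <- cand[best]
  if (sum(x <= psi) < min_side || sum(x > psi) < min_side) psi <- cand[best]

  X <- cbind(1, x, pmax(x - psi, 0))
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  single <- stats::lm.fit(cbind(1, x), y)
  rss_single <- sum(single$residuals^2)
  structure(
    list(
      psi = psi,
      slopes = c(left = unname(fit$coefficients[2]),
                 right = unname(fit$coefficients[2] + fit$coefficients[3])),
      intercept = unname(fit$coefficients[1]),
      rss = rss, rss_single = rss_single,
      no_breakpoint = rss_single <= 1e-12 * sum(y^2) ||
        (rss_single - rss) / rss_single < 0.01,
      n_left = sum(x <= psi), n_right = sum(x > psi), n = n
    ),
    class = "segmented_fit"
  )
}

#' @export
print.segmented_fit <- function(x, ...) {
  cat(sprintf(
    "Two-segment fit: psi = %.4g, slopes %.4g / %.4g, RSS %.4g (single line %.4g)%s\n",
    x$psi, x$slopes[1], x$slopes[2], x$rss, x$rss_single,
    if (x$no_breakpoint) " [no material breakpoint]" else ""
  ))
  invisible(x)
}

#' Resting metabolic rate from a V̇O₂ trace
#'
#' Implements the cumulative-frequency threshold procedure: the cumulative
#' frequency percentage is plotted against measured V̇O₂, a two-segment
#' linear regression locates the threshold between the resting and the
#' active metabolic regime, and the resting metabolic rate (RMR) is the
#' mean of all V̇O₂ samples strictly below that threshold.
#'
#' @param trace Numeric vector of V̇O₂ samples (mL min\eqn{^{-1}}
#'   kg\eqn{^{-1}}), or a data frame with a `vo2` column (e.g. from
#'   [read_vo2_trace()] or [simulate_vo2()]).
#' @param min_samples Minimum number of samples required (default 50);
#'   shorter traces cannot span a resting period reliably.
#' @param ... Passed to [segmented_fit()].
#' @return Object of class `rmr_result`: list with `threshold`, `rmr`,
#'   `n_below`, `degenerate` (`TRUE` when no material breakpoint exists,
#'   in which case `threshold` and `rmr` are `NA`) and the underlying
#'   `fit`.
#' @export
resting_metabolic_rate <- function(trace, min_samples = 50, ...) {
  vo2 <- if (is.data.frame(trace)) trace$vo2 else as.numeric(trace)
  vo2 <- vo2[!is.na(vo2)]
  if (length(vo2) < min_samples) {
    stop("trace has ", length(vo2), " samples; need >= ", min_samples,
         call. = FALSE)
  }
  cf <- cumulative_frequency(vo2)
  fit <- tryCatch(segmented_fit(cf$x, cf$y, ...), error = function(e) NULL)
  if (is.null(fit) || fit$no_breakpoint) {
    return(structure(
      list(threshold = NA_real_, rmr = NA_real_, n_below = NA_integer_,
           degenerate = TRUE, fit = fit),
      class = "rmr_result"
    ))
  }
  below <- vo2[vo2 < fit$psi]
  if (length(below) == 0) stop("no data below threshold", call. = FALSE)
  structure(
    list(threshold = fit$psi, rmr = mean(below),
         n_below = length(below), degenerate = FALSE, fit = fit),
    class = "rmr_result"
  )
}

#' @export
print.rmr_result <- function(x, ...) {
  if (x$degenerate) {
    cat("RMR: no material breakpoint in the cumulative-frequency curve\n")
  } else {
    cat(sprintf(
      "RMR = %.2f mL/min/kg (threshold %.2f, %d samples below)\n",
      x$rmr, x$threshold, x$n_below
    ))
  }
  invisible(x)
}

#' Read a calorimetry V̇O₂ trace from CSV
#'
#' Expects columns `time_s` and either `vo2_ml_min_kg` (mass-specific) or
#' `vo2_ml_min` (absolute flow, converted using the animal's body mass).
#'
#' @param path CSV file path.
#' @param mass_g Body mass in grams; required when only `vo2_ml_min` is
#'   present.
#' @return Tibble `time_s, vo2` with `vo2` in mL min\eqn{^{-1}}
#'   kg\eqn{^{-1}}, ordered by strictly increasing time.
#' @export
read_vo2_trace <- function(path, mass_g = NULL) {
  d <- utils::read.csv(path)
  stopifnot("time_s" %in% names(d))
  if ("vo2_ml_min_kg" %in% names(d)) {
    vo2 <- d$vo2_ml_min_kg
  } else if ("vo2_ml_min" %in% names(d)) {
    if (is.null(mass_g)) {
      stop("absolute flow trace: supply `mass_g` for conversion",
           call. = FALSE)
    }
    vo2 <- d$vo2_ml_min / (mass_g / 1000)
  } else {
    stop("no vo2_ml_min_kg or vo2_ml_min column", call. = FALSE)
  }
  o <- order(d$time_s)
  out <- tibble::tibble(time_s = d$time_s[o], vo2 = vo2[o])
  if (any(diff(out$time_s) <= 0)) {
    stop("sampling times must be strictly increasing", call. = FALSE)
  }
  if (any(out$vo2 <= 0)) stop("V̇O2 must be positive", call. = FALSE)
  out
}
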