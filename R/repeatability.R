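#' Sliding 4-week analysis windows
#'
#' Enumerates the overlapping windows over which repeatability is
#' estimated: windows of `width_weeks` consecutive weeks advancing by
#' `step_weeks` (week 1–4, week 2–5, ...). A 20-week series with the
#' defaults yields 17 windows.
#'
#' @param n_weeks Number of whole weeks available.
#' @param width_weeks Window width in weeks (default 4).
#' @param step_weeks Offset between consecutive windows (default 1).
#' @return Tibble `index, first_week, last_week`, one row per window.
#' @examples
#' nrow(sliding_windows(20)) # 17
#' @export
sliding_windows <- function(n_weeks, width_weeks = 4, step_weeks = 1) {
  stopifnot(width_weeks >= 1, step_weeks >= 1)
  if (n_weeks < width_weeks) {
    stop("series of ", n_weeks, " weeks shorter than window width ",
         width_weeks, call. = FALSE)
  }
  first <- seq(1L, n_weeks - width_weeks + 1L, by = step_weeks)
  tibble::tibble(
    index = seq_along(first),
    first_week = as.integer(first),
    last_week = as.integer(first + width_weeks - 1L)
  )
}

as_groups <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("animal_id", "value") %in% names(groups)))
    groups <- split(groups$value, groups$animal_id)
  }
  groups <- lapply(groups, function(g) g[!is.na(g)])
  groups[lengths(groups) > 0]
}

# core ANOVA variance-component computation on (value, group-index) vectors;
# shared by the estimator, bootstrap and permutation loops
icc_from_vectors <- function(values, gi, n_groups) {
  n_i <- tabulate(gi, nbins = n_groups)
  keep <- n_i > 0
  n_i <- n_i[keep]
  a <- length(n_i)
  n_total <- length(values)
  sums <- rowsum(values, gi)[, 1]
  means_i <- sums / n_i
  grand <- sum(values) / n_total
  ss_a <- sum(n_i * (means_i - grand)^2)
  ss_w <- sum(values^2) - sum(sums^2 / n_i)
  ms_a <- ss_a / (a - 1)
  ms_w <- ss_w / (n_total - a)
  n0 <- (n_total - sum(n_i^2) / n_total) / (a - 1)
  sigma2_a <- max(0, (ms_a - ms_w) / n0)
  r <- if (sigma2_a + ms_w == 0) 0 else sigma2_a / (sigma2_a + ms_w)
  list(R = r, sigma2_among = sigma2_a, sigma2_within = ms_w,
       ms_among = ms_a, n0 = n0, n_groups = a, n_obs = n_total)
}

#' Repeatability (intraclass correlation) of grouped observations
#'
#' One-way ANOVA variance-components estimate of the fraction of total
#' variance attributable to consistent between-individual differences:
#' \deqn{R = \sigma^2_{among} / (\sigma^2_{among} + \sigma^2_{within}),}
#' with \eqn{\sigma^2_{among} = (MS_A - MS_W)/n_0} and, for unbalanced
#' groups, \eqn{n_0 = (N - \sum n_i^2/N)/(a - 1)}. A negative among-group
#' component is truncated to 0, so `R` always lies in `[0, 1]`.
#'
#' @param groups Either a named list of per-animal numeric vectors (e.g.
#'   nightly RE values) or a data frame with columns `animal_id`, `value`.
#'   At least 2 groups, and at least one group with 2 observations.
#' @return Object of class `repeatability`: list with `R`, `sigma2_among`,
#'   `sigma2_within`, `n_groups`, `n_obs`.
#' @examples
#' estimate_repeatability(list(a = c(1, 1), b = c(2, 2), c = c(3, 3)))$R # 1
#' @export
estimate_repeatability <- function(groups) {
  groups <- as_groups(groups)
  if (length(groups) < 2) stop("need >= 2 groups (animals)", call. = FALSE)
  if (max(lengths(groups)) < 2) {
    stop("need >= 2 observations in at least one group", call. = FALSE)
  }
  values <- unlist(groups, use.names = FALSE)
  gi <- rep(seq_along(groups), lengths(groups))
  out <- icc_from_vectors(values, gi, length(groups))
  structure(out, class = "repeatability")
}

#' @export
print.repeatability <- function(x, ...) {
  cat(sprintf("Repeatability R = %.3f (%d groups, %d observations)\n",
              x$R, x$n_groups, x$n_obs))
  invisible(x)
}

#' Cluster bootstrap confidence interval for repeatability
#'
#' Resamples whole animals (groups) with replacement, re-estimates `R` on
#' each replicate, and returns the empirical 2.5% and 97.5% percentiles.
#' Resampling animals rather than observations respects the within-animal
#' dependence that the repeatability quantifies.
#'
#' @inheritParams estimate_repeatability
#' @param n_boot Number of bootstrap replicates (default 500).
#' @param seed Integer seed; required, so intervals are reproducible.
#' @return List with `ci` (`c(low, high)`), `replicates` (the bootstrap
#'   `R` values) and `n_boot`.
#' @export
bootstrap_ci <- function(groups, n_boot = 500, seed) {
  if (n_boot < 1) stop("n_boot must be >= 1", call. = FALSE)
  groups <- as_groups(groups)
  a <- length(groups)
  if (a < 2) stop("need >= 2 groups", call. = FALSE)
  reps <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    pick <- sample.int(a, a, replace = TRUE)
    g <- groups[pick]
    values <- unlist(g, use.names = FALSE)
    gi <- rep(seq_along(g), lengths(g))
    icc_from_vectors(values, gi, a)$R
  }, 0))
  list(ci = stats::quantile(reps, c(0.025, 0.975), names = FALSE),
       replicates = reps, n_boot = n_boot)
}

#' Permutation p-value for repeatability
#'
#' Shuffles observations across animals (preserving group sizes), giving
#' the null distribution of `R` under exchangeability; the p-value uses the
#' add-one correction \eqn{p = (1 + \#\{R_{perm} \ge R_{obs}\})/(1 + n_{perm})}
#' so that finite permutation runs never report exactly zero.
#'
#' @inheritParams estimate_repeatability
#' @param n_perm Number of permutations (default 100).
#' @param seed Integer seed; required.
#' @return List with `p`, `R_obs`, `replicates`, `n_perm`.
#' @export
permutation_pvalue <- function(groups, n_perm = 100, seed) {
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  groups <- as_groups(groups)
  if (length(groups) < 2) stop("need >= 2 groups", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  gi <- rep(seq_along(groups), lengths(groups))
  r_obs <- icc_from_vectors(values, gi, length(groups))$R
  reps <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
    icc_from_vectors(sample(values), gi, length(groups))$R
  }, 0))
  list(p = (1 + sum(reps >= r_obs)) / (1 + n_perm),
       R_obs = r_obs, replicates = reps, n_perm = n_perm)
}

#' Sliding-window repeatability of nightly roaming entropy
#'
#' Splits a nightly RE series into whole weeks (anchored to the first
#' night; a trailing partial week is dropped), forms 4-week windows
#' advancing by 1 week, and estimates repeatability with bootstrap CI and
#' permutation p per window.
#'
#' @param re_data Tibble as returned by [roaming_series()] (columns
#'   `animal_id, date, re`); missing nights are dropped per animal.
#' @param width_weeks,step_weeks Window geometry (defaults 4 and 1).
#' @param n_boot,n_perm Resampling effort per window.
#' @param seed Integer root seed; each window derives its own stream.
#' @return Tibble `window_index, week_start, week_end, R, ci_low, ci_high,
#'   p_perm, n_groups, n_obs`.
#' @export
repeatability_windows <- function(re_data, width_weeks = 4, step_weeks = 1,
                                  n_boot = 500, n_perm = 100, seed) {
  stopifnot(all(c("animal_id", "date", "re") %in% names(re_data)))
  dates <- as.Date(re_data$date)
  d0 <- min(dates)
  week <- as.integer(floor(as.numeric(dates - d0) / 7)) + 1L
  # whole weeks anchored at the first night; a trailing partial week is dropped
  n_weeks <- as.integer((as.numeric(max(dates) - d0) + 1) %/% 7)
  wins <- sliding_windows(n_weeks, width_weeks, step_weeks)
  rows <- lapply(seq_len(nrow(wins)), function(i) {
    sel <- week >= wins$first_week[i] & week <= wins$last_week[i] &
      !is.na(re_data$re)
    grp <- data.frame(animal_id = re_data$animal_id[sel],
                      value = re_data$re[sel])
    est <- estimate_repeatability(grp)
    ci <- bootstrap_ci(grp, n_boot = n_boot, seed = seed + 1000L + i)
    pp <- permutation_pvalue(grp, n_perm = n_perm, seed = seed + 2000L + i)
    tibble::tibble(
      window_index = wins$index[i],
      week_start = wins$first_week[i], week_end = wins$last_week[i],
      R = est$R, ci_low = ci$ci[1], ci_high = ci$ci[2], p_perm = pp$p,
      n_groups = est$n_groups, n_obs = est$n_obs
    )
  })
  do.call(rbind, rows)
}

#' Trend of repeatability across windows
#'
#' OLS of the window repeatability estimates on window index, quantifying
#' whether individual activity patterns stabilize (positive slope) over
#' the observation period.
#'
#' @param results Tibble from [repeatability_windows()] (needs columns
#'   `window_index`, `R`), or a numeric vector of `R` values in window
#'   order. At least 3 windows.
#' @return An [ols_fit()].
#' @export
repeatability_trend <- function(results) {
  if (is.data.frame(results)) {
    r <- results$R[order(results$window_index)]
  } else {
    r <- as.numeric(results)
  }
  if (length(r) < 3) stop("trend needs >= 3 windows", call. = FALSE)
  ols_fit(seq_along(r), r)
}
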