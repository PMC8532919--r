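#' Per-animal antenna contact distribution for one period
#'
#' Tallies how often an animal was read at each of the `k` installed
#' antennas during one observation period (typically one nightly dark
#' phase) and normalizes the tally to a probability vector `p`. A period in
#' which the animal was never read yields an "empty" distribution, for
#' which roaming entropy is undefined.
#'
#' @param night_log An `event_log` already sliced to the period of interest
#'   (and, if desired, deduplicated — whether contact probabilities are
#'   computed from raw reads or debounced contacts is a user choice exposed
#'   through [deduplicate_events()]).
#' @param animal_id Animal whose events to tally.
#' @param k Number of installed antennas; must be at least the largest
#'   observed antenna id. Defaults to the log's layout.
#' @return A `contact_distribution`: list with `animal_id`, `period_label`
#'   (the log's night attribute, if any), integer `counts` of length `k`,
#'   probability vector `p`, `k`, and logical `empty`.
#' @examples
#' log <- parse_event_log(c(
#'   "2019-06-01T21:00:00,5,M01",
#'   "2019-06-01T21:05:00,5,M01",
#'   "2019-06-01T21:10:00,7,M01"
#' ), k = 27)
#' d <- contact_distribution(log, "M01")
#' d$p[c(5, 7)] # 2/3, 1/3
#' @export
contact_distribution <- function(night_log, animal_id, k = layout_k(night_log)) {
  stopifnot(inherits(night_log, "event_log"))
  ants <- night_log$antenna_id[night_log$animal_id == animal_id]
  if (length(ants) > 0 && max(ants) > k) {
    stop("k = ", k, " smaller than max observed antenna id ", max(ants),
         call. = FALSE)
  }
  counts <- tabulate(ants, nbins = k)
  total <- sum(counts)
  structure(
    list(
      animal_id = animal_id,
      period_label = attr(night_log, "night"),
      counts = counts,
      p = if (total > 0) counts / total else rep(NA_real_, k),
      k = as.integer(k),
      empty = total == 0L
    ),
    class = "contact_distribution"
  )
}

#' Roaming entropy of a contact distribution
#'
#' Normalized Shannon entropy of the antenna contact probabilities:
#' \deqn{RE = -\sum_{j=1}^{k} p_j \log p_j / \log k,}
#' with the convention \eqn{0 \log 0 = 0}. RE is 0 when all contacts fall
#' on one antenna and 1 when all `k` antennas are used uniformly; it does
#' not depend on the logarithm base (natural log is used internally). An
#' empty distribution has no defined entropy and returns `NA`.
#'
#' @param x A `contact_distribution`, or a numeric vector of probabilities
#'   (summing to 1) or non-negative counts over the `k` antennas.
#' @param k Number of installed antennas; defaults to the distribution's
#'   `k` or `length(x)` for a bare vector. Must exceed 1.
#' @return RE in `[0, 1]`, or `NA_real_` for an empty distribution.
#' @examples
#' roaming_entropy(rep(1 / 27, 27)) # 1
#' roaming_entropy(c(1, rep(0, 26))) # 0
#' @export
roaming_entropy <- function(x, k = NULL) {
  if (inherits(x, "contact_distribution")) {
    if (is.null(k)) k <- x$k
    if (x$empty) return(NA_real_)
    p <- x$p
  } else {
    if (is.null(k)) k <- length(x)
    if (any(x < 0) || all(x == 0)) {
      stop("probabilities/counts must be non-negative with positive sum",
           call. = FALSE)
    }
    p <- x / sum(x)
  }
  if (k <= 1) stop("roaming entropy requires k > 1 (log(k) = 0)", call. = FALSE)
  nz <- p > 0
  # + 0 normalizes IEEE negative zero on one-hot distributions
  -sum(p[nz] * log(p[nz])) / log(k) + 0
}

#' Cumulative roaming entropy
#'
#' Running sum of per-period RE values:
#' \eqn{cRE_t = RE_1 + RE_2 + \dots + RE_t}. Periods with no contacts carry
#' a missing RE; under the default `"skip"` policy they contribute 0 to the
#' running sum and are flagged in the `missing` attribute.
#'
#' @param re Numeric vector of RE values in `[0, 1]`, possibly with `NA`.
#' @param missing_policy Only `"skip"` is defined: missing periods add 0.
#' @return Numeric vector of the same length, non-decreasing, with a
#'   logical attribute `missing` marking skipped periods.
#' @export
cumulative_re <- function(re, missing_policy = "skip") {
  missing_policy <- match.arg(missing_policy, "skip")
  ok <- !is.na(re)
  if (any(re[ok] < 0 | re[ok] > 1)) {
    stop("RE values must lie in [0, 1]", call. = FALSE)
  }
  contrib <- ifelse(ok, re, 0)
  structure(cumsum(contrib), missing = !ok)
}

#' Nightly roaming-entropy series for a colony
#'
#' End-to-end driver: for each requested night, slices the dark phase from
#' the log, tallies each animal's contact distribution, and computes RE and
#' the running cumulative cRE.
#'
#' @param log An `event_log` for the whole study span.
#' @param sched A `light_schedule` covering all nights.
#' @param nights Vector of lights-off dates; defaults to every date from
#'   the first to the last event date for which the following morning is
#'   still covered by the log span.
#' @param animals Animal ids to include; defaults to all ids in the log.
#' @param refractory_s Refractory window for [deduplicate_events()] applied
#'   before tallying; 0 (default) uses raw reads.
#' @return A tibble `animal_id, date, re, cre, missing, n_contacts`, ordered
#'   by animal then date. `re` is `NA` and `missing` is `TRUE` on nights
#'   the animal produced no contact.
#' @export
roaming_series <- function(log, sched, nights = NULL, animals = NULL,
                           refractory_s = 0) {
  stopifnot(inherits(log, "event_log"))
  if (refractory_s > 0) log <- deduplicate_events(log, refractory_s)
  if (is.null(animals)) animals <- sort(unique(log$animal_id))
  if (is.null(nights)) {
    dates <- as.Date(log$timestamp, tz = "UTC")
    nights <- seq(min(dates), max(dates) - 1, by = "day")
  }
  nights <- as.Date(nights)
  k <- layout_k(log)
  per_night <- lapply(nights, function(nd) {
    nl <- extract_dark_phase(log, sched, nd)
    vapply(animals, function(a) {
      d <- contact_distribution(nl, a, k)
      c(re = roaming_entropy(d), n = sum(d$counts))
    }, c(re = 0, n = 0))
  })
  re_mat <- matrix(unlist(lapply(per_night, function(m) m["re", ])),
                   nrow = length(nights), byrow = TRUE)
  n_mat <- matrix(unlist(lapply(per_night, function(m) m["n", ])),
                  nrow = length(nights), byrow = TRUE)
  out <- lapply(seq_along(animals), function(j) {
    re <- re_mat[, j]
    cre <- cumulative_re(re)
    tibble::tibble(
      animal_id = animals[j], date = nights, re = re,
      cre = as.numeric(cre), missing = is.na(re),
      n_contacts = as.integer(n_mat[, j])
    )
  })
  do.call(rbind, out)
}

#' Descriptive summary: mean, sd, CV%, extremes
#'
#' The reporting convention for group values: mean ± sample standard
#' deviation with the coefficient of variation (100·sd/mean, in percent),
#' maximum, minimum and the number of non-missing values.
#'
#' @param values Numeric vector; `NA`s are dropped. At least 2 non-missing
#'   values are required.
#' @return One-row tibble `mean, sd, cv_percent, max, min, n`.
#' @examples
#' group_summary(c(1, 2, 3)) # mean 2, sd 1, CV 50%
#' @export
group_summary <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("all values missing", call. = FALSE)
  if (length(values) < 2) stop("need >= 2 non-missing values", call. = FALSE)
  m <- mean(values)
  s <- stats::sd(values)
  tibble::tibble(
    mean = m, sd = s,
    cv_percent = if (s == 0) 0 else cv(m, s),
    max = max(values), min = min(values), n = length(values)
  )
}

#' Cross-animal variance of nightly RE and its trend over nights
#'
#' Computes, for each night, the between-animal variance of RE (sample,
#' n−1 denominator) and fits an ordinary least-squares trend of that
#' variance on night index.
#'
#' @param re_matrix Numeric matrix, animals × nights (`NA` allowed; each
#'   night needs at least 2 non-missing animals).
#' @return List with `variance` (per-night vector) and `trend` (an
#'   [ols_fit()] of variance on night index 1..n).
#' @export
variance_trajectory <- function(re_matrix) {
  stopifnot(is.matrix(re_matrix))
  n_ok <- colSums(!is.na(re_matrix))
  if (any(n_ok < 2)) {
    stop("every night needs >= 2 animals with non-missing RE", call. = FALSE)
  }
  v <- apply(re_matrix, 2, stats::var, na.rm = TRUE)
  if (length(v) < 3) stop("trend needs >= 3 nights", call. = FALSE)
  list(variance = v, trend = ols_fit(seq_along(v), v))
}
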