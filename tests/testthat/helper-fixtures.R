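# Small programmatic fixtures shared across test files.

summer_schedule <- function(from = "2019-05-01", to = "2019-09-30") {
  light_schedule(data.frame(
    start_date = from, end_date = to,
    lights_on = "08:00", lights_off = "20:00"
  ))
}

seasonal_schedule <- function() {
  light_schedule(data.frame(
    start_date = c("2019-04-01", "2019-10-27"),
    end_date = c("2019-10-26", "2020-03-28"),
    lights_on = c("08:00", "07:00"),
    lights_off = c("20:00", "19:00")
  ))
}

# build an event_log from "animal antenna time-string" triplets
make_log <- function(animal, antenna, when, k = 27) {
  event_log(
    tibble::tibble(
      timestamp = as.POSIXct(when, tz = "UTC"),
      antenna_id = as.integer(antenna),
      animal_id = animal
    ),
    k = k
  )
}

# brute-force one-way variance components: explicit group means and pooled
# residuals, no shared code with estimate_repeatability()
icc_brute_force <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  a <- length(groups)
  n_i <- lengths(groups)
  N <- sum(n_i)
  grand <- mean(unlist(groups))
  m_i <- vapply(groups, mean, 0)
  ms_a <- sum(n_i * (m_i - grand)^2) / (a - 1)
  ms_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0)) / (N - a)
  n0 <- (N - sum(n_i^2) / N) / (a - 1)
  s_a <- max(0, (ms_a - ms_w) / n0)
  s_a / (s_a + ms_w)
}
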