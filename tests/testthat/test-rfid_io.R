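test_that("well-formed records parse into a sorted event log", {
  log <- parse_event_log("2019-01-01T21:00:00,5,M01", k = 27)
  expect_equal(n_events(log), 1L)
  expect_equal(log$antenna_id, 5L)
  expect_equal(log$animal_id, "M01")
  expect_equal(layout_k(log), 27L)

  # out-of-order input is stably sorted by timestamp
  shuffled <- parse_event_log(c(
    "2019-01-01T22:00:00,3,M02",
    "2019-01-01T21:00:00,5,M01",
    "2019-01-01T21:30:00,7,M01"
  ), k = 27)
  expect_equal(shuffled$antenna_id, c(5L, 7L, 3L))

  expect_equal(n_events(parse_event_log(character(), k = 27)), 0L)
  expect_equal(n_events(parse_event_log("", k = 27)), 0L)
})

test_that("validation errors name offending lines; non-strict mode collects them", {
  bad_ant <- c("2019-01-01T21:00:00,5,M01", "2019-01-01T21:01:00,28,M01")
  expect_error(parse_event_log(bad_ant, k = 27), "line 2.*antenna_id outside 1\\.\\.27")
  expect_error(parse_event_log("2019-01-01 25:99:00,5,M01", k = 27),
               "unparseable timestamp")
  expect_error(parse_event_log("not,a,log,line", k = 27), "3 fields")

  log <- parse_event_log(bad_ant, k = 27, strict = FALSE)
  expect_equal(n_events(log), 1L)
  rep <- parse_errors(log)
  expect_equal(rep$line, 2L)
  expect_match(rep$problem, "antenna_id")
})

test_that("event-log CSV round-trips byte-equivalently", {
  log <- make_log(
    c("M01", "M02", "M01"), c(5, 3, 7),
    c("2019-06-01 21:00:00", "2019-06-01 21:00:00", "2019-06-01 22:30:05")
  )
  path <- withr::local_tempfile(fileext = ".csv")
  write_event_log(log, path)
  first <- readLines(path)
  log2 <- read_event_log(path, k = 27)
  path2 <- withr::local_tempfile(fileext = ".csv")
  write_event_log(log2, path2)
  expect_identical(readLines(path2), first)
  expect_equal(log2$timestamp, log$timestamp)
})

test_that("deduplication collapses same-antenna repeats only, and is idempotent", {
  t0 <- as.POSIXct("2019-06-01 21:00:00", tz = "UTC")
  same <- event_log(tibble::tibble(
    timestamp = t0 + c(0, 0.5), antenna_id = c(5L, 5L),
    animal_id = c("M01", "M01")
  ), k = 27)
  expect_equal(n_events(deduplicate_events(same, 1)), 1L)

  different <- event_log(tibble::tibble(
    timestamp = t0 + c(0, 0.5), antenna_id = c(5L, 7L),
    animal_id = c("M01", "M01")
  ), k = 27)
  expect_equal(n_events(deduplicate_events(different, 1)), 2L)

  # refractory 0 is the identity
  expect_equal(nrow(deduplicate_events(same, 0)), 2L)

  # idempotence on a busy log with interleaved animals and antennas
  set.seed(42)
  busy <- event_log(tibble::tibble(
    timestamp = t0 + cumsum(runif(200, 0, 0.8)),
    antenna_id = sample(1:3, 200, replace = TRUE),
    animal_id = sample(c("A", "B"), 200, replace = TRUE)
  ), k = 27)
  once <- deduplicate_events(busy, 1)
  twice <- deduplicate_events(once, 1)
  expect_equal(as.data.frame(twice), as.data.frame(once))
  # chain case: t = 0, 0.5, 1.5 -> the middle read is inside the window of
  # the first retained event; the third is outside it and survives
  chain <- event_log(tibble::tibble(
    timestamp = t0 + c(0, 0.5, 1.5), antenna_id = c(5L, 5L, 5L),
    animal_id = "M01"
  ), k = 27)
  expect_equal(as.numeric(deduplicate_events(chain, 1)$timestamp - t0),
               c(0, 1.5))
})

test_that("dark phase slicing uses half-open lights-off to next lights-on", {
  sched <- seasonal_schedule()
  iv <- dark_phase_interval(sched, "2019-06-01")
  expect_equal(iv$start, as.POSIXct("2019-06-01 20:00:00", tz = "UTC"))
  expect_equal(iv$end, as.POSIXct("2019-06-02 08:00:00", tz = "UTC"))

  log <- make_log(
    rep("M01", 4), c(1, 2, 3, 4),
    c("2019-06-01 19:59:59", "2019-06-01 20:00:00",
      "2019-06-02 07:59:59", "2019-06-02 08:00:00")
  )
  night <- extract_dark_phase(log, sched, "2019-06-01")
  expect_equal(night$antenna_id, c(2L, 3L)) # boundaries: start in, end out
  expect_equal(attr(night, "night"), as.Date("2019-06-01"))

  empty <- extract_dark_phase(make_log("M01", 1, "2019-06-01 10:00:00"),
                              sched, "2019-06-02")
  expect_equal(n_events(empty), 0L)

  expect_error(extract_dark_phase(log, sched, "2021-01-01"), "not covered")

  # seasonal switch: the night of the regime change ends at the NEW lights-on
  iv2 <- dark_phase_interval(sched, "2019-10-26")
  expect_equal(iv2$start, as.POSIXct("2019-10-26 20:00:00", tz = "UTC"))
  expect_equal(iv2$end, as.POSIXct("2019-10-27 07:00:00", tz = "UTC"))
})

test_that("dark and light slices partition the log with no loss or duplication", {
  sched <- summer_schedule()
  set.seed(7)
  t0 <- as.POSIXct("2019-06-01 08:00:00", tz = "UTC")
  log <- event_log(tibble::tibble(
    timestamp = t0 + sort(runif(500, 0, 3 * 86400 - 1)),
    antenna_id = sample(1:27, 500, replace = TRUE),
    animal_id = sample(c("A", "B", "C"), 500, replace = TRUE)
  ), k = 27)
  pieces <- c(
    lapply(c("2019-06-01", "2019-06-02", "2019-06-03"), function(d) {
      extract_light_phase(log, sched, d)
    }),
    lapply(c("2019-06-01", "2019-06-02", "2019-06-03"), function(d) {
      extract_dark_phase(log, sched, d)
    })
  )
  expect_equal(sum(vapply(pieces, n_events, 0L)), n_events(log))
  recombined <- do.call(rbind, lapply(pieces, as.data.frame))
  recombined <- recombined[order(recombined$timestamp), ]
  expect_equal(recombined$antenna_id, log$antenna_id)
})

test_that("light schedules validate coverage and overlap", {
  expect_error(light_schedule(data.frame(
    start_date = c("2019-01-01", "2019-06-01"),
    end_date = c("2019-07-01", "2019-12-31"),
    lights_on = "08:00", lights_off = "20:00"
  )), "overlap")
  sched <- read_light_schedule(
    withr::local_tempfile(lines = c(
      "start_date,end_date,lights_on,lights_off",
      "2019-04-01,2019-10-26,08:00,20:00"
    ), fileext = ".csv")
  )
  expect_s3_class(sched, "light_schedule")
  expect_equal(sched$lights_off - sched$lights_on, 12 * 3600)
})
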