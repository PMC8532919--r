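#' @title RFID event logs
#'
#' @description An `event_log` holds timestamped antenna detections for a
#' colony: one row per transponder read, plus the number of installed
#' antennas `k`. Timestamps are naive local clock time (stored as POSIXct in
#' UTC so that no daylight-saving arithmetic is ever applied); events are
#' kept stably sorted by timestamp.
#'
#' @param events A data frame with columns `timestamp` (POSIXct),
#'   `antenna_id` (integer) and `animal_id` (character).
#' @param k Number of installed antennas; antenna ids must lie in `1..k`.
#' @return An object of class `event_log`: a tibble of events with
#'   attributes `k` and (after parsing in non-strict mode) `errors`.
#' @examples
#' ev <- tibble::tibble(
#'   timestamp = as.POSIXct("2019-01-01 21:00:00", tz = "UTC"),
#'   antenna_id = 5L, animal_id = "M01"
#' )
#' log <- event_log(ev, k = 27)
#' n_events(log)
#' @export
event_log <- function(events, k) {
  stopifnot(is.data.frame(events), length(k) == 1L, k >= 1)
  events <- tibble::as_tibble(events)[, c("timestamp", "antenna_id", "animal_id")]
  if (nrow(events) > 0) {
    if (!inherits(events$timestamp, "POSIXct")) {
      stop("`timestamp` must be POSIXct", call. = FALSE)
    }
    bad <- which(events$antenna_id < 1 | events$antenna_id > k |
                   events$antenna_id != as.integer(events$antenna_id))
    if (length(bad) > 0) {
      stop("antenna_id outside 1..", k, " at row(s) ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    events$antenna_id <- as.integer(events$antenna_id)
    events$animal_id <- as.character(events$animal_id)
    # stable sort: ties keep input order, so re-parsing is byte-faithful
    events <- events[order(events$timestamp, method = "radix"), , drop = FALSE]
  }
  structure(events, k = as.integer(k), class = c("event_log", class(events)))
}

#' Number of events and antenna count of an event log
#' @param log An `event_log`.
#' @return `n_events()` the number of rows; `layout_k()` the antenna count.
#' @export
n_events <- function(log) nrow(log)

#' @rdname n_events
#' @export
layout_k <- function(log) attr(log, "k")

#' Parse an RFID event log from delimited text
#'
#' Records are comma-separated `timestamp,antenna_id,animal_id` with
#' ISO-8601 timestamps (`2019-01-01T21:00:00`; a space separator is also
#' accepted). A header line is detected and skipped.
#'
#' @param text Character vector of lines, or a single string with newlines.
#' @param k Number of installed antennas.
#' @param strict If `TRUE` (default) any malformed line — wrong field count,
#'   unparseable timestamp, or antenna outside `1..k` — aborts with an error
#'   naming the offending line numbers. If `FALSE`, offending lines are
#'   collected into an error report retrievable with [parse_errors()] and
#'   the remaining lines are parsed.
#' @return An `event_log`, sorted by timestamp.
#' @examples
#' log <- parse_event_log("2019-01-01T21:00:00,5,M01", k = 27)
#' n_events(log)
#' @export
parse_event_log <- function(text, k, strict = TRUE) {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    text <- strsplit(text, "\n", fixed = TRUE)[[1]]
  }
  lines <- text[nzchar(trimws(text))]
  line_no <- seq_along(text)[nzchar(trimws(text))]
  if (length(lines) > 0 && grepl("^timestamp", lines[[1]])) {
    lines <- lines[-1]
    line_no <- line_no[-1]
  }
  if (length(lines) == 0L) {
    return(event_log(empty_events(), k = k))
  }
  parts <- strsplit(lines, ",", fixed = TRUE)
  nf <- lengths(parts)
  ts_raw <- vapply(parts, function(p) if (length(p) >= 1) trimws(p[[1]]) else NA_character_, "")
  ts <- parse_iso_timestamp(ts_raw)
  ant_raw <- vapply(parts, function(p) if (length(p) >= 2) trimws(p[[2]]) else NA_character_, "")
  ant <- suppressWarnings(as.integer(ant_raw))
  ant[!grepl("^[0-9]+$", ant_raw)] <- NA_integer_
  ani <- vapply(parts, function(p) if (length(p) >= 3) trimws(p[[3]]) else NA_character_, "")

  problem <- character(length(lines))
  problem[nf != 3L] <- "expected 3 fields"
  problem[nf == 3L & is.na(ts)] <- "unparseable timestamp"
  problem[nf == 3L & !is.na(ts) & (is.na(ant) | ant < 1 | ant > k)] <-
    paste0("antenna_id outside 1..", k)
  bad <- which(nzchar(problem))
  if (length(bad) > 0 && strict) {
    stop("invalid event log: ",
         paste(sprintf("line %d (%s)", line_no[bad], problem[bad]),
               collapse = "; "), call. = FALSE)
  }
  keep <- setdiff(seq_along(lines), bad)
  events <- tibble::tibble(
    timestamp = ts[keep], antenna_id = ant[keep], animal_id = ani[keep]
  )
  log <- event_log(events, k = k)
  attr(log, "errors") <- tibble::tibble(
    line = line_no[bad], text = lines[bad], problem = problem[bad]
  )
  log
}

#' Error report from non-strict parsing
#' @param log An `event_log` produced by [parse_event_log()].
#' @return A tibble with columns `line`, `text`, `problem` (zero rows if the
#'   input was clean or the log was built directly).
#' @export
parse_errors <- function(log) {
  err <- attr(log, "errors")
  if (is.null(err)) tibble::tibble(line = integer(), text = character(),
                                   problem = character()) else err
}

#' Read / write event-log CSV files
#'
#' The on-disk dialect is a CSV with header `timestamp,antenna_id,animal_id`
#' and ISO-8601 `T`-separated timestamps. `write_event_log()` followed by
#' `read_event_log()` round-trips byte-equivalently for well-formed logs.
#'
#' @param path File path.
#' @param k Number of installed antennas.
#' @param strict Passed to [parse_event_log()].
#' @param log An `event_log`.
#' @return `read_event_log()` an `event_log`; `write_event_log()` the path,
#'   invisibly.
#' @export
read_event_log <- function(path, k, strict = TRUE) {
  parse_event_log(readLines(path, warn = FALSE), k = k, strict = strict)
}

#' @rdname read_event_log
#' @export
write_event_log <- function(log, path) {
  lines <- c("timestamp,antenna_id,animal_id",
             sprintf("%s,%d,%s", format_iso_timestamp(log$timestamp),
                     log$antenna_id, log$animal_id))
  writeLines(lines, path)
  invisible(path)
}

empty_events <- function() {
  tibble::tibble(
    timestamp = as.POSIXct(character(), tz = "UTC"),
    antenna_id = integer(), animal_id = character()
  )
}

parse_iso_timestamp <- function(x) {
  x <- sub("T", " ", x, fixed = TRUE)
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  # reject trailing garbage that strptime would silently ignore
  out[!grepl("^\\d{4}-\\d{2}-\\d{2} \\d{2}:\\d{2}:\\d{2}$", x)] <- NA
  out
}

format_iso_timestamp <- function(x) {
  format(x, "%Y-%m-%dT%H:%M:%S", tz = "UTC")
}

#' Collapse antenna re-reads within a refractory window
#'
#' RFID ring antennas re-read a stationary animal every few hundred
#' milliseconds. For each (animal, antenna) stream, consecutive events
#' closer than `refractory_s` seconds to the last retained event collapse to
#' that first event; events at different antennas are never merged.
#' `refractory_s = 0` returns the log unchanged (raw-count mode). The
#' operation is idempotent.
#'
#' @param log An `event_log`, sorted by time (as constructed).
#' @param refractory_s Refractory window in seconds, `>= 0`. Default 1.
#' @return A deduplicated `event_log`.
#' @export
deduplicate_events <- function(log, refractory_s = 1) {
  stopifnot(inherits(log, "event_log"), refractory_s >= 0)
  if (refractory_s == 0 || nrow(log) < 2) return(log)
  key <- paste(log$animal_id, log$antenna_id, sep = "\r")
  t <- as.numeric(log$timestamp)
  keep <- logical(nrow(log))
  last_kept <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(log))) {
    prev <- last_kept[[key[i]]]
    if (is.null(prev) || t[i] - prev >= refractory_s) {
      keep[i] <- TRUE
      last_kept[[key[i]]] <- t[i]
    }
  }
  out <- log[keep, , drop = FALSE]
  event_log(out, k = layout_k(log))
}

#' Light schedules
#'
#' A light schedule is a table of regimes, each a date range with fixed
#' lights-on and lights-off clock times defining a 12 h light / 12 h dark
#' cycle (e.g. summertime 08:00--20:00, wintertime 07:00--19:00). Regime
#' switches take effect per calendar date; date ranges must not overlap.
#'
#' @param regimes Data frame with columns `start_date`, `end_date` (Dates or
#'   `"YYYY-MM-DD"` strings, inclusive) and `lights_on`, `lights_off`
#'   (`"HH:MM"` or `"HH:MM:SS"` clock times).
#' @return A `light_schedule` object.
#' @examples
#' sched <- light_schedule(data.frame(
#'   start_date = c("2019-04-01", "2019-10-27"),
#'   end_date   = c("2019-10-26", "2020-03-28"),
#'   lights_on  = c("08:00", "07:00"),
#'   lights_off = c("20:00", "19:00")
#' ))
#' @export
light_schedule <- function(regimes) {
  regimes <- tibble::as_tibble(regimes)
  stopifnot(all(c("start_date", "end_date", "lights_on", "lights_off") %in%
                  names(regimes)), nrow(regimes) >= 1)
  regimes$start_date <- as.Date(regimes$start_date)
  regimes$end_date <- as.Date(regimes$end_date)
  regimes$lights_on <- vapply(regimes$lights_on, parse_clock_s, 0,
                              USE.NAMES = FALSE)
  regimes$lights_off <- vapply(regimes$lights_off, parse_clock_s, 0,
                               USE.NAMES = FALSE)
  if (any(regimes$end_date < regimes$start_date)) {
    stop("regime end_date before start_date", call. = FALSE)
  }
  o <- order(regimes$start_date)
  regimes <- regimes[o, , drop = FALSE]
  if (nrow(regimes) > 1 &&
      any(regimes$start_date[-1] <= regimes$end_date[-nrow(regimes)])) {
    stop("light-schedule regimes overlap", call. = FALSE)
  }
  structure(regimes, class = c("light_schedule", class(regimes)))
}

#' @rdname light_schedule
#' @param path CSV file with header `start_date,end_date,lights_on,lights_off`.
#' @export
read_light_schedule <- function(path) {
  light_schedule(utils::read.csv(path, colClasses = "character"))
}

parse_clock_s <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  p <- as.numeric(strsplit(x, ":", fixed = TRUE)[[1]])
  if (length(p) == 2) p <- c(p, 0)
  stopifnot(length(p) == 3)
  p[1] * 3600 + p[2] * 60 + p[3]
}

schedule_regime <- function(sched, date) {
  i <- which(sched$start_date <= date & date <= sched$end_date)
  if (length(i) != 1) {
    stop("date ", format(date), " not covered by the light schedule",
         call. = FALSE)
  }
  sched[i, , drop = FALSE]
}

#' Clock boundaries of one night's dark phase
#'
#' A "night" is labeled by the calendar date on which lights go off; it
#' spans the half-open interval from lights-off on that date to lights-on on
#' the following date (under that date's regime, so a seasonal switch takes
#' effect at the following morning).
#'
#' @param sched A `light_schedule`.
#' @param night_date The lights-off calendar date (Date or string).
#' @return List with POSIXct `start` (lights-off, included) and `end`
#'   (next lights-on, excluded).
#' @export
dark_phase_interval <- function(sched, night_date) {
  night_date <- as.Date(night_date)
  reg_off <- schedule_regime(sched, night_date)
  reg_on <- schedule_regime(sched, night_date + 1)
  list(
    start = as.POSIXct(night_date, tz = "UTC") + reg_off$lights_off,
    end = as.POSIXct(night_date + 1, tz = "UTC") + reg_on$lights_on
  )
}

#' Slice an event log to one night's dark phase
#'
#' @param log An `event_log`.
#' @param sched A `light_schedule` covering `night_date` and the next day.
#' @param night_date Lights-off date labeling the night.
#' @return An `event_log` restricted to `[lights_off, next lights_on)`, with
#'   attribute `night` set to `night_date`.
#' @export
extract_dark_phase <- function(log, sched, night_date) {
  iv <- dark_phase_interval(sched, night_date)
  out <- log[log$timestamp >= iv$start & log$timestamp < iv$end, , drop = FALSE]
  out <- event_log(out, k = layout_k(log))
  attr(out, "night") <- as.Date(night_date)
  out
}

#' Slice an event log to one day's light phase
#'
#' Complement of [extract_dark_phase()]: events from lights-on to lights-off
#' on `day_date`, half-open. Together the nightly dark slices and the daily
#' light slices partition the full log.
#'
#' @inheritParams extract_dark_phase
#' @param day_date Calendar date of the light phase.
#' @return An `event_log`.
#' @export
extract_light_phase <- function(log, sched, day_date) {
  day_date <- as.Date(day_date)
  reg <- schedule_regime(sched, day_date)
  start <- as.POSIXct(day_date, tz = "UTC") + reg$lights_on
  end <- as.POSIXct(day_date, tz = "UTC") + reg$lights_off
  out <- log[log$timestamp >= start & log$timestamp < end, , drop = FALSE]
  event_log(out, k = layout_k(log))
}
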