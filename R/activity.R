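#' Quarter-hour activity matrix
#'
#' Bins events into clock-aligned 15-minute windows (96 per day, half-open
#' `[00:00, 00:15)`, ...) and applies the activity rule: an animal is
#' active in a bin when it contacted at least two *different* antennas
#' within that bin. Repeated reads at one antenna never count as activity,
#' so the rule is insensitive to whether the log was debounced.
#'
#' @param log An `event_log`.
#' @param animals Animal ids defining the rows; defaults to all ids in the
#'   log. Animals without events simply stay inactive.
#' @param days Ordered vector of dates defining the day axis; defaults to
#'   the full date range of the log (every calendar day, even if empty).
#' @return An `activity_matrix`: list with `animals`, `days`, `bin_start`
#'   (seconds since midnight, length 96) and logical array `active` of
#'   dimension animals × days × 96.
#' @export
activity_matrix <- function(log, animals = NULL, days = NULL) {
  stopifnot(inherits(log, "event_log"))
  if (is.null(animals)) animals <- sort(unique(log$animal_id))
  if (is.null(days)) {
    if (nrow(log) == 0) stop("empty log: supply `days` explicitly", call. = FALSE)
    d <- as.Date(log$timestamp, tz = "UTC")
    days <- seq(min(d), max(d), by = "day")
  }
  days <- as.Date(days)
  n_bins <- 96L
  active <- array(FALSE, dim = c(length(animals), length(days), n_bins),
                  dimnames = list(animals, format(days), NULL))
  if (nrow(log) > 0) {
    ev_day <- as.Date(log$timestamp, tz = "UTC")
    secs <- as.numeric(log$timestamp) - as.numeric(as.POSIXct(ev_day, tz = "UTC"))
    bin <- pmin(floor(secs / 900), n_bins - 1) + 1L
    ai <- match(log$animal_id, animals)
    di <- match(ev_day, days)
    keep <- !is.na(ai) & !is.na(di)
    if (any(keep)) {
      key <- paste(ai[keep], di[keep], bin[keep])
      n_distinct <- tapply(log$antenna_id[keep], key,
                           function(a) length(unique(a)))
      hit <- names(n_distinct)[n_distinct >= 2]
      if (length(hit) > 0) {
        idx <- do.call(rbind, lapply(strsplit(hit, " "), as.integer))
        active[idx] <- TRUE
      }
    }
  }
  structure(
    list(animals = animals, days = days,
         bin_start = seq(0, by = 900, length.out = n_bins), active = active),
    class = "activity_matrix"
  )
}

#' Colony activity heatmap counts
#'
#' Number of active animals per (day, 15-minute bin): the column sums of
#' the boolean activity matrix over animals. The brighter a cell in the
#' resulting raster, the more animals were active in that quarter hour.
#'
#' @param matrix An `activity_matrix`.
#' @return Integer matrix, days × 96 bins, values in `0..n_animals`, with
#'   day labels as row names.
#' @export
active_count_heatmap <- function(matrix) {
  stopifnot(inherits(matrix, "activity_matrix"))
  counts <- apply(matrix$active, c(2, 3), sum)
  storage.mode(counts) <- "integer"
  rownames(counts) <- format(matrix$days)
  counts
}

#' Long-format activity counts
#'
#' @param matrix An `activity_matrix`.
#' @return Tibble `date, bin_start, active_count` with `bin_start` in
#'   `"HH:MM"` clock time, ordered by date then bin.
#' @export
activity_long <- function(matrix) {
  counts <- active_count_heatmap(matrix)
  hm <- sprintf("%02d:%02d", matrix$bin_start %/% 3600,
                (matrix$bin_start %% 3600) %/% 60)
  tibble::tibble(
    date = rep(matrix$days, each = length(hm)),
    bin_start = rep(hm, times = length(matrix$days)),
    active_count = as.integer(t(counts))
  )
}

#' Thin raster plot of the colony activity heatmap
#'
#' Minimal wrapper around [graphics::image()]: days on the y axis, time of
#' day on the x axis, brightness proportional to the number of active
#' animals.
#'
#' @param matrix An `activity_matrix`.
#' @param ... Passed on to [graphics::image()].
#' @return Invisibly, the count matrix plotted.
#' @export
plot_activity_heatmap <- function(matrix, ...) {
  counts <- active_count_heatmap(matrix)
  graphics::image(
    x = (matrix$bin_start + 450) / 3600, y = seq_along(matrix$days),
    z = t(counts), xlab = "time of day [h]", ylab = "day",
    col = grDevices::gray.colors(64, start = 0, end = 1), ...
  )
  invisible(counts)
}
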