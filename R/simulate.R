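#' Antenna layout graph
#'
#' Abstracts the enclosure's antenna layout as a connected graph: `k` ring
#' antennas distributed over `n_levels` levels, antennas within a level
#' arranged in a ring (adjacent positions reachable without passing a third
#' antenna), and consecutive levels joined by a single "tube" edge. The
#' default (27 antennas on 5 levels) mirrors the study system's scale; it
#' is a documented approximation of such an enclosure, not a wiring
#' diagram of any particular one. A custom adjacency can be supplied
#' instead.
#'
#' @param k Number of antennas (default 27).
#' @param n_levels Number of enclosure levels (default 5).
#' @param adjacency Optional symmetric logical/0-1 matrix (`k` × `k`)
#'   overriding the default topology; must be connected.
#' @return Object of class `antenna_graph`: list with `k`, `level_of`
#'   (integer vector) and `adj` (logical adjacency matrix, no self loops).
#' @export
antenna_graph <- function(k = 27, n_levels = 5, adjacency = NULL) {
  stopifnot(k >= 2, n_levels >= 1, n_levels <= k)
  sizes <- rep(k %/% n_levels, n_levels)
  extra <- k - sum(sizes)
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  level_of <- rep(seq_len(n_levels), sizes)
  if (is.null(adjacency)) {
    adj <- matrix(FALSE, k, k)
    offset <- c(0L, cumsum(sizes))
    for (lv in seq_len(n_levels)) {
      ids <- offset[lv] + seq_len(sizes[lv])
      m <- length(ids)
      if (m > 1) {
        for (i in seq_len(m)) {
          j <- ids[i %% m + 1L]
          adj[ids[i], j] <- TRUE
          adj[j, ids[i]] <- TRUE
        }
      }
      if (lv < n_levels) { # one tube between consecutive levels
        a <- ids[m]
        b <- offset[lv + 1L] + 1L
        adj[a, b] <- TRUE
        adj[b, a] <- TRUE
      }
    }
  } else {
    adj <- adjacency != 0
    stopifnot(nrow(adj) == k, ncol(adj) == k, isTRUE(all(adj == t(adj))))
    diag(adj) <- FALSE
  }
  g <- structure(list(k = as.integer(k), level_of = level_of, adj = adj),
                 class = "antenna_graph")
  if (!graph_connected(g)) stop("antenna graph is not connected", call. = FALSE)
  g
}

graph_connected <- function(graph) {
  k <- graph$k
  seen <- logical(k)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    nb <- which(graph$adj[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

#' Default circadian rate profile
#'
#' Per-hour multipliers of the event rate over the 24 h clock, relative to
#' a light schedule: sustained high activity through the dark phase with
#' pronounced peaks in the first and last dark hour (activity crests at
#' the phase transitions), and low activity during the light phase with a
#' slight ramp in the hours before lights-off.
#'
#' @param lights_on_h,lights_off_h Clock hours of the transitions
#'   (defaults 8 and 20, the summertime regime).
#' @param dark_level,light_level Baseline multipliers for dark and light
#'   hours (defaults 1 and 0.15).
#' @param peak Multiplier applied to the first and last dark hour
#'   (default 1.6).
#' @return Numeric vector of length 24 (multiplier for clock hour 0..23).
#' @export
circadian_profile <- function(lights_on_h = 8, lights_off_h = 20,
                              dark_level = 1, light_level = 0.15,
                              peak = 1.6) {
  h <- 0:23
  dark <- !(h >= lights_on_h & h < lights_off_h)
  prof <- ifelse(dark, dark_level, light_level)
  prof[(lights_off_h %% 24) + 1] <- dark_level * peak
  prof[((lights_on_h - 1) %% 24) + 1] <- dark_level * peak
  # slight anticipatory ramp in the two hours before lights-off
  ramp <- ((lights_off_h - c(2, 1)) %% 24) + 1
  prof[ramp] <- pmax(prof[ramp], light_level * c(2, 3))
  prof
}

#' Simulation configuration for a synthetic RFID colony
#'
#' Bundles and validates the generator settings. Defaults describe the
#' study conditions the package targets: 20 mice on a 27-antenna,
#' five-level layout under a 12/12 h light cycle, strongly home-biased
#' individual antenna preferences (nightly roaming entropy of the order
#' 0.05–0.1), moderate night-to-night variability, and a slow age-related
#' decline of activity and roaming.
#'
#' @param n_mice Number of animals (default 20).
#' @param n_days Number of simulated days.
#' @param graph An [antenna_graph()] (default `antenna_graph()`).
#' @param schedule A [light_schedule()]; the default covers the simulated
#'   span with the summertime 08:00/20:00 regime.
#' @param start_date First simulated date (default `"2019-06-01"`).
#' @param base_rate_mean,base_rate_cv Mean events per dark-phase hour per
#'   mouse and its between-mouse coefficient of variation (defaults 40
#'   and 0.25).
#' @param home_weight_mean,home_weight_sd Mean and between-mouse sd of the
#'   preference weight on each mouse's home antenna (defaults 0.75 and
#'   0.02, which put the implied asymptotic nightly RE near 0.08 ± 0.015,
#'   the scale reported for aged mice in such enclosures); the complement
#'   is spread over the remaining antennas with mild Dirichlet jitter.
#'   Larger `home_weight_sd` means more between-mouse heterogeneity in
#'   roaming breadth.
#' @param consistency Between-night lognormal sd of each mouse's rate
#'   (default 0.3); smaller values mean more consistent individuals.
#' @param aging_decline Per-day multiplicative decline (`0 <` value
#'   `<= 1`) applied to the event rate and to the odds of leaving the home
#'   antenna (default 1, no aging).
#' @param circadian Per-hour multipliers (length 24); default
#'   [circadian_profile()].
#' @param seed Mandatory integer seed.
#' @return Validated list of class `sim_config`.
#' @export
sim_config <- function(n_mice = 20, n_days = 14, graph = antenna_graph(),
                       schedule = NULL, start_date = "2019-06-01",
                       base_rate_mean = 40, base_rate_cv = 0.25,
                       home_weight_mean = 0.75, home_weight_sd = 0.02,
                       consistency = 0.3, aging_decline = 1,
                       circadian = circadian_profile(), seed) {
  if (missing(seed)) stop("sim_config requires a seed", call. = FALSE)
  start_date <- as.Date(start_date)
  if (is.null(schedule)) {
    schedule <- light_schedule(data.frame(
      start_date = format(start_date - 1),
      end_date = format(start_date + n_days + 1),
      lights_on = "08:00", lights_off = "20:00"
    ))
  }
  stopifnot(
    n_mice >= 1, n_days >= 1, inherits(graph, "antenna_graph"),
    inherits(schedule, "light_schedule"), base_rate_mean > 0,
    base_rate_cv >= 0, home_weight_mean > 0, home_weight_mean < 1,
    home_weight_sd >= 0, consistency >= 0, aging_decline > 0,
    aging_decline <= 1, length(circadian) == 24, all(circadian >= 0)
  )
  structure(
    list(n_mice = n_mice, n_days = n_days, graph = graph,
         schedule = schedule, start_date = start_date,
         base_rate_mean = base_rate_mean, base_rate_cv = base_rate_cv,
         home_weight_mean = home_weight_mean,
         home_weight_sd = home_weight_sd, consistency = consistency,
         aging_decline = aging_decline, circadian = circadian,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

# preference-biased one-step transition matrix and its stationary law
walk_kernel <- function(graph, pref) {
  k <- graph$k
  P <- matrix(0, k, k)
  for (a in seq_len(k)) {
    nb <- c(a, which(graph$adj[a, ]))
    w <- pref[nb]
    if (sum(w) == 0) w <- rep(1, length(nb))
    P[a, nb] <- w / sum(w)
  }
  P
}

stationary_distribution <- function(P) {
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

#' Simulate an RFID colony on the antenna graph
#'
#' Generates a synthetic event log with the statistical structure the
#' analysis pipeline assumes. Per mouse, event times arise from an
#' inhomogeneous Poisson process with piecewise-constant hourly rate
#' `base_i * circadian(hour) * aging^day * night_effect`; each event's
#' antenna is a one-step move on the antenna graph biased by the mouse's
#' preference vector, whose non-home odds shrink with the aging
#' multiplier so that roaming breadth (and hence nightly RE) declines
#' with age.
#'
#' @param config A [sim_config()].
#' @return List of class `colony_sim` with
#'   \describe{
#'     \item{log}{an [event_log()] in the standard CSV dialect;}
#'     \item{truth}{per-mouse ground truth: profiles (base rate, home
#'       antenna, preference vector), each mouse's day-1 walk stationary
#'       distribution and its implied asymptotic RE, and the generating
#'       between/within-night rate variance components;}
#'     \item{config}{the configuration, echoed for provenance.}
#'   }
#' @export
simulate_colony <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  g <- config$graph
  k <- g$k
  with_seed(config$seed, {
    ids <- sprintf("M%02d", seq_len(config$n_mice))
    # individual profiles
    base <- config$base_rate_mean *
      exp(stats::rnorm(config$n_mice, 0, config$base_rate_cv) -
            config$base_rate_cv^2 / 2)
    home <- sample.int(k, config$n_mice, replace = TRUE)
    hw <- pmin(0.995, pmax(
      0.02, stats::rnorm(config$n_mice, config$home_weight_mean,
                         config$home_weight_sd)
    ))
    pref <- lapply(seq_len(config$n_mice), function(i) {
      other <- stats::rgamma(k - 1, shape = 2, rate = 1)
      p <- numeric(k)
      p[-home[i]] <- (1 - hw[i]) * other / sum(other)
      p[home[i]] <- hw[i]
      p
    })
    truth_stationary <- vector("list", config$n_mice)
    asymptotic_re <- numeric(config$n_mice)

    all_events <- vector("list", config$n_mice)
    day0 <- as.POSIXct(config$start_date, tz = "UTC")
    for (i in seq_len(config$n_mice)) {
      P1 <- walk_kernel(g, pref[[i]])
      pi1 <- stationary_distribution(P1)
      truth_stationary[[i]] <- pi1
      asymptotic_re[i] <- roaming_entropy(pi1, k = k)

      times <- numeric(0)
      for (d in seq_len(config$n_days)) {
        aging <- config$aging_decline^(d - 1)
        night_effect <- exp(stats::rnorm(1, 0, config$consistency) -
                              config$consistency^2 / 2)
        hourly <- base[i] * config$circadian * aging * night_effect
        n_h <- stats::rpois(24, hourly)
        if (sum(n_h) == 0) next
        t_h <- unlist(lapply(which(n_h > 0), function(h) {
          (d - 1) * 86400 + (h - 1) * 3600 + sort(stats::runif(n_h[h], 0, 3600))
        }))
        times <- c(times, t_h)
      }
      if (length(times) == 0) {
        all_events[[i]] <- empty_events()
        next
      }
      # antenna sequence: one-step preference-biased walk; aging shrinks
      # the odds of non-home antennas so exploration narrows with age
      day_of <- floor(times / 86400) + 1
      ant <- integer(length(times))
      cur <- home[i]
      Pd <- P1
      last_day <- 1L
      for (e in seq_along(times)) {
        d <- day_of[e]
        if (d != last_day || e == 1L) {
          aging <- config$aging_decline^(d - 1)
          pd <- pref[[i]]
          pd[-home[i]] <- pd[-home[i]] * aging
          pd <- pd / sum(pd)
          Pd <- walk_kernel(g, pd)
          Pd <- t(apply(Pd, 1, cumsum))
          last_day <- d
        }
        cur <- findInterval(stats::runif(1), Pd[cur, ]) + 1L
        ant[e] <- cur
      }
      all_events[[i]] <- tibble::tibble(
        timestamp = day0 + times, antenna_id = ant, animal_id = ids[i]
      )
    }
    events <- do.call(rbind, all_events)
    log <- event_log(events, k = k)
    truth <- list(
      animal_id = ids,
      profiles = tibble::tibble(
        animal_id = ids, base_rate = base, home_antenna = home,
        home_weight = hw
      ),
      preference = pref,
      stationary = truth_stationary,
      asymptotic_re = asymptotic_re,
      variance_components = list(
        between_night_log_rate_sd = config$consistency,
        between_mouse_log_rate_sd = config$base_rate_cv,
        between_mouse_home_weight_sd = config$home_weight_sd
      )
    )
    structure(list(log = log, truth = truth, config = config),
              class = "colony_sim")
  })
}

#' Write a colony simulation with provenance sidecars
#'
#' Emits the event log in the standard CSV dialect plus a ground-truth CSV
#' (per-mouse profiles and asymptotic RE) and a YAML metadata sidecar
#' recording the generating configuration and seed.
#'
#' @param sim A `colony_sim` from [simulate_colony()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_colony_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "colony_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    events = file.path(dir, "events.csv"),
    truth = file.path(dir, "ground_truth.csv"),
    meta = file.path(dir, "metadata.yml")
  )
  write_event_log(sim$log, paths["events"])
  gt <- sim$truth$profiles
  gt$asymptotic_re <- sim$truth$asymptotic_re
  utils::write.csv(gt, paths["truth"], row.names = FALSE)
  cfg <- sim$config
  meta <- list(
    generator = "roamr::simulate_colony",
    seed = cfg$seed, n_mice = cfg$n_mice, n_days = cfg$n_days,
    k = cfg$graph$k, start_date = format(cfg$start_date),
    base_rate_mean = cfg$base_rate_mean, base_rate_cv = cfg$base_rate_cv,
    home_weight_mean = cfg$home_weight_mean,
    home_weight_sd = cfg$home_weight_sd, consistency = cfg$consistency,
    aging_decline = cfg$aging_decline
  )
  writeLines(yaml::as.yaml(meta), paths["meta"])
  invisible(paths)
}

#' Parametric nightly-RE series with a known intraclass correlation
#'
#' Draws per-animal nightly RE values from the Gaussian variance-components
#' model `re = mean + animal_effect + noise` with
#' `var(animal_effect) = icc * total_sd^2` and
#' `var(noise) = (1 - icc) * total_sd^2`, then clips to `[0, 1]` (at the
#' default scale the clip is never active). This is the direct generative
#' counterpart of the one-way ANOVA repeatability estimator and is used
#' for parameter-recovery testing at the study scale (19 animals × 28
#' nights).
#'
#' @param n_animals,n_nights Design size.
#' @param icc True intraclass correlation in `[0, 1)`.
#' @param mean_re Grand mean nightly RE (default 0.08).
#' @param total_sd Total standard deviation (default 0.015).
#' @param seed Mandatory integer seed.
#' @return Tibble `animal_id, night, re` with attribute `truth` (list with
#'   the generating `icc`, variances, and the realized animal effects).
#' @export
simulate_re_series <- function(n_animals, n_nights, icc, mean_re = 0.08,
                               total_sd = 0.015, seed) {
  stopifnot(icc >= 0, icc < 1, total_sd > 0)
  with_seed(seed, {
    u <- stats::rnorm(n_animals, 0, sqrt(icc) * total_sd)
    e <- stats::rnorm(n_animals * n_nights, 0, sqrt(1 - icc) * total_sd)
    re <- pmin(1, pmax(0, mean_re + rep(u, each = n_nights) + e))
    out <- tibble::tibble(
      animal_id = rep(sprintf("M%02d", seq_len(n_animals)), each = n_nights),
      night = rep(seq_len(n_nights), n_animals),
      re = re
    )
    attr(out, "truth") <- list(
      icc = icc, sigma2_among = icc * total_sd^2,
      sigma2_within = (1 - icc) * total_sd^2, animal_effects = u
    )
    out
  })
}

#' Two-state Markov-modulated V̇O₂ trace
#'
#' Emulates an indirect-calorimetry recording: the animal alternates
#' between a resting and an active metabolic state following a two-state
#' Markov chain with stationary resting probability `p_rest` and mean
#' dwell `dwell` samples, and V̇O₂ is Gaussian around the state mean.
#'
#' @param rest_mean,active_mean State means in mL min\eqn{^{-1}}
#'   kg\eqn{^{-1}} (`rest_mean < active_mean`; defaults 40 and 80).
#' @param sd_within Within-state standard deviation (default 2).
#' @param p_rest Stationary probability of the resting state, in (0, 1)
#'   (default 0.8).
#' @param n Number of samples (default 600, one per minute over 10 h).
#' @param dwell Mean sojourn (in samples) of the resting state
#'   (default 30).
#' @param seed Mandatory integer seed.
#' @return List of class `vo2_sim`: `trace` (tibble `time_s, vo2`, 60 s
#'   sampling), `state` (`"rest"`/`"active"` per sample), and `truth`
#'   (list with the generating parameters and `rest_mean_realized`, the
#'   mean of the samples actually emitted in the resting state).
#' @export
simulate_vo2 <- function(rest_mean = 40, active_mean = 80, sd_within = 2,
                         p_rest = 0.8, n = 600, dwell = 30, seed) {
  if (!(rest_mean < active_mean)) {
    stop("rest_mean must be below active_mean", call. = FALSE)
  }
  if (p_rest <= 0 || p_rest > 1) stop("p_rest must be in (0, 1]", call. = FALSE)
  stopifnot(sd_within > 0, n >= 2, dwell > 1)
  if (p_rest < 1) {
    # stay probabilities giving stationary P(rest) = p_rest
    p_rr <- 1 - 1 / dwell
    p_aa <- 1 - (1 - p_rr) * p_rest / (1 - p_rest)
    if (p_aa < 0) {
      stop("p_rest too high for the requested dwell: the active state ",
           "would have a mean sojourn below one sample", call. = FALSE)
    }
  }
  with_seed(seed, {
    state <- integer(n) # 1 = rest, 2 = active
    if (p_rest == 1) {
      state[] <- 1L
    } else {
      state[1] <- if (stats::runif(1) < p_rest) 1L else 2L
      for (t in 2:n) {
        stay <- if (state[t - 1] == 1L) p_rr else p_aa
        state[t] <- if (stats::runif(1) < stay) state[t - 1] else 3L - state[t - 1]
      }
    }
    mu <- ifelse(state == 1L, rest_mean, active_mean)
    vo2 <- stats::rnorm(n, mu, sd_within)
    vo2 <- pmax(vo2, 0.1) # physical positivity guard
    structure(
      list(
        trace = tibble::tibble(time_s = 60 * (seq_len(n) - 1) + 60, vo2 = vo2),
        state = c("rest", "active")[state],
        truth = list(
          rest_mean = rest_mean, active_mean = active_mean,
          sd_within = sd_within, p_rest = p_rest,
          rest_mean_realized = mean(vo2[state == 1L])
        )
      ),
      class = "vo2_sim"
    )
  })
}
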