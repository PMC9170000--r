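#' Category level constructors for the simulated study design
#'
#' The default design mirrors a six-week personal-monitoring campaign on a
#' single underground line: a `Station` factor whose last level is `Tunnel`
#' (records collected while travelling between two adjacent stations), an
#' `Environment` factor whose reference level is the `sampling_room` where
#' every shift starts and ends, and an `Event` factor of short incidents
#' (door openings, heater use, passing trains, ...).
#'
#' @param n number of category levels.
#' @return character vector of level names; the first element is the
#'   reference category.
#' @keywords internal
#' @name sim-levels
NULL

station_levels <- function(n) {
  if (n == 1L) return("S01")
  c(sprintf("S%02d", seq_len(n - 1L)), "Tunnel")
}

environment_levels <- function(n) {
  base <- c("sampling_room", "cloakroom", "ticket_counter",
            "underground_corridor", "platform", "cabin", "train", "outdoor")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("env_%02d", seq.int(length(base) + 1L, n)))
}

event_levels <- function(n) {
  base <- c("cabin_door_opening", "heater_on", "train_passing",
            "passenger_entry", "window_opening", "ticket_counter_door",
            "tobacco_smoke", "platform_cleaning",
            "ticket_machine_intervention", "radio_check")
  if (n == 0L) return(character(0))
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("event_%02d", seq.int(length(base) + 1L, n)))
}

job_levels <- function(n) {
  base <- c("station_agent", "locomotive_operator", "security_guard")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("job_%02d", seq.int(length(base) + 1L, n)))
}

#' Simulation configuration for a synthetic personal-exposure study
#'
#' Defines the full data-generating design: 3 occupations monitored for 8
#' work days each (24 day-series), 6-hour shifts sampled every 5 minutes for
#' mass concentrations and every 6 seconds for number concentrations, and a
#' categorical design of 45 stations (including `Tunnel`), 8 environments and
#' 10 event types. Concentrations are generated on the log10 scale as
#'
#' \deqn{\log_{10} Y = \mu_i + \alpha_{station} + \beta_{environment} +
#'   \gamma^T event + \zeta_i^T b(t) + offset_{fraction} + \varepsilon,\quad
#'   \varepsilon \sim N(0, \sigma^2_i)}
#'
#' with day-specific intercepts \eqn{\mu_i \sim N(m_{job}, \tau^2_{job})},
#' day-specific residual variances, and a per-day smooth trend built from a
#' cubic B-spline basis with coefficients \eqn{\zeta_i \sim N(0,
#' \code{trend_amplitude}^2)}.
#'
#' Unsupplied effect vectors are drawn once, deterministically from `seed`:
#' station effects are small (SD 0.03 log10 units, i.e. mostly under a 10%
#' fold change), environment effects are larger and mostly positive relative
#' to the clean `sampling_room` reference, and event effects are small
#' positive bumps. The default fraction offsets place PM0.3 about 1.1
#' decades below PM10, with PM1 and PM2.5 slightly below PM10, matching
#' typical underground mass size distributions.
#'
#' @param n_jobs number of occupations (default 3).
#' @param days_per_job monitored work days per occupation (default 8).
#' @param shift_minutes shift duration in minutes (default 360).
#' @param mass_dt mass-concentration recording interval, seconds (default 300).
#' @param number_dt number-concentration recording interval, seconds (default 6).
#' @param n_stations,n_environments,n_events category counts (defaults 45/8/10).
#' @param true_alpha,true_beta,true_gamma named log10-scale effect vectors;
#'   the reference (first) category must be exactly 0. Drawn from `seed` when
#'   `NULL`.
#' @param mu_job job-level mean intercepts, log10 ug/m3.
#' @param tau2_job job-level intercept variances (log10 scale).
#' @param sigma2_day_range range from which per-day residual variances are
#'   drawn uniformly.
#' @param trend_amplitude SD of the per-day spline trend coefficients, log10
#'   units.
#' @param trend_knots number of interior knots of the generating cubic
#'   B-spline trend.
#' @param fraction_offsets named log10 offsets for PM0.3, PM1, PM2.5, PM10.
#' @param number_factor ratio of total wide-range-counter number
#'   concentration to the optical counter's 0.25-0.7 um band (default 1e3).
#' @param number_log10_baseline log10 total number concentration (#/cm3) of
#'   the optical counter's full range at the reference category.
#' @param seed integer seed controlling every random draw derived from this
#'   configuration.
#' @return an object of class `sim_config` (a validated list).
#' @export
#' @examples
#' cfg <- sim_config(n_stations = 5, n_environments = 3, n_events = 2)
#' cfg$station_levels
sim_config <- function(n_jobs = 3,
                       days_per_job = 8,
                       shift_minutes = 360,
                       mass_dt = 300,
                       number_dt = 6,
                       n_stations = 45,
                       n_environments = 8,
                       n_events = 10,
                       true_alpha = NULL,
                       true_beta = NULL,
                       true_gamma = NULL,
                       mu_job = NULL,
                       tau2_job = NULL,
                       sigma2_day_range = c(0.02, 0.08),
                       trend_amplitude = 0.15,
                       trend_knots = 8,
                       fraction_offsets = c(PM0.3 = -1.10, PM1 = -0.16,
                                            PM2.5 = -0.07, PM10 = 0),
                       number_factor = 1e3,
                       number_log10_baseline = 1.5,
                       seed = 1L) {
  n_jobs <- stopifnot_scalar_count(n_jobs, "n_jobs")
  days_per_job <- stopifnot_scalar_count(days_per_job, "days_per_job")
  n_stations <- stopifnot_scalar_count(n_stations, "n_stations")
  n_environments <- stopifnot_scalar_count(n_environments, "n_environments")
  if (!is.numeric(n_events) || n_events < 0 || n_events != round(n_events)) {
    abort("`n_events` must be a non-negative integer.",
          class = "subwaypm_config_error")
  }
  n_events <- as.integer(n_events)
  assert_positive(shift_minutes, "shift_minutes")
  if (shift_minutes < 360 || shift_minutes > 480) {
    abort("`shift_minutes` must lie in [360, 480] (a 6-8 hour shift).",
          class = "subwaypm_config_error")
  }
  assert_positive(mass_dt, "mass_dt")
  assert_positive(number_dt, "number_dt")
  if ((shift_minutes * 60) %% mass_dt != 0) {
    abort("`mass_dt` must divide the shift duration evenly.",
          class = "subwaypm_config_error")
  }
  if (length(sigma2_day_range) != 2 || any(sigma2_day_range <= 0) ||
      diff(sigma2_day_range) < 0) {
    abort("`sigma2_day_range` must be an increasing positive interval.",
          class = "subwaypm_config_error")
  }
  assert_positive(trend_amplitude, "trend_amplitude")
  assert_positive(number_factor, "number_factor")
  if (length(fraction_offsets) != 4 ||
      !setequal(names(fraction_offsets), c("PM0.3", "PM1", "PM2.5", "PM10"))) {
    abort("`fraction_offsets` must be named PM0.3, PM1, PM2.5, PM10.",
          class = "subwaypm_config_error")
  }

  st <- station_levels(n_stations)
  en <- environment_levels(n_environments)
  ev <- event_levels(n_events)
  jb <- job_levels(n_jobs)

  if (is.null(mu_job)) mu_job <- stats::setNames(
    rep_len(c(0.55, 0.65, 0.60), n_jobs), jb)
  if (is.null(names(mu_job))) names(mu_job) <- jb
  if (is.null(tau2_job)) tau2_job <- stats::setNames(
    rep_len(c(0.010, 0.020, 0.015), n_jobs), jb)
  if (is.null(names(tau2_job))) names(tau2_job) <- jb
  assert_positive(tau2_job, "tau2_job")

  draw_effects <- is.null(true_alpha) || is.null(true_beta) || is.null(true_gamma)
  if (draw_effects) {
    with_seed(seed_mod(as.numeric(seed) * 13 + 7), {
      if (is.null(true_alpha)) {
        true_alpha <- stats::setNames(c(0, stats::rnorm(n_stations - 1, 0, 0.03)), st)
        if ("Tunnel" %in% st) true_alpha[["Tunnel"]] <- abs(true_alpha[["Tunnel"]]) + 0.05
      }
      if (is.null(true_beta)) {
        true_beta <- stats::setNames(
          c(0, stats::rnorm(n_environments - 1, 0.25, 0.15)), en)
        if ("cloakroom" %in% en) true_beta[["cloakroom"]] <- -0.05
      }
      if (is.null(true_gamma)) {
        true_gamma <- stats::setNames(stats::rnorm(n_events, 0.08, 0.05), ev)
      }
    })
  }
  if (is.null(names(true_alpha))) names(true_alpha) <- st
  if (is.null(names(true_beta))) names(true_beta) <- en
  if (n_events > 0 && is.null(names(true_gamma))) names(true_gamma) <- ev
  if (length(true_alpha) != n_stations || length(true_beta) != n_environments ||
      length(true_gamma) != n_events) {
    abort("effect vector lengths must match the category counts.",
          class = "subwaypm_config_error")
  }
  if (true_alpha[[1L]] != 0 || true_beta[[1L]] != 0) {
    abort("reference category effects (first element of true_alpha/true_beta) must be exactly 0.",
          class = "subwaypm_config_error")
  }

  cfg <- structure(list(
    n_jobs = n_jobs, days_per_job = days_per_job, n_days = n_jobs * days_per_job,
    shift_minutes = shift_minutes, mass_dt = mass_dt, number_dt = number_dt,
    n_stations = n_stations, n_environments = n_environments, n_events = n_events,
    station_levels = st, environment_levels = en, event_levels = ev,
    job_levels = jb,
    reference_station = st[1L], reference_environment = en[1L],
    true_alpha = true_alpha, true_beta = true_beta, true_gamma = true_gamma,
    mu_job = mu_job, tau2_job = tau2_job,
    sigma2_day_range = as.numeric(sigma2_day_range),
    trend_amplitude = trend_amplitude, trend_knots = as.integer(trend_knots),
    fraction_offsets = fraction_offsets[c("PM0.3", "PM1", "PM2.5", "PM10")],
    number_factor = number_factor,
    number_log10_baseline = number_log10_baseline,
    seed = as.integer(seed)
  ), class = "sim_config")
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d jobs x %d days, %g-min shifts; mass dt %gs, number dt %gs\n",
              x$n_jobs, x$days_per_job, x$shift_minutes, x$mass_dt, x$number_dt))
  cat(sprintf("  design: %d stations / %d environments / %d events; seed %d\n",
              x$n_stations, x$n_environments, x$n_events, x$seed))
  invisible(x)
}

job_of_day <- function(cfg, day_index) {
  cfg$job_levels[[((day_index - 1L) %/% cfg$days_per_job) + 1L]]
}

shift_start_time <- function(cfg, day_index) {
  as.POSIXct("2019-10-07 08:00:00", tz = "UTC") + (day_index - 1) * 86400
}

#' Realise the latent ground truth of a simulated study
#'
#' Draws, deterministically from the configuration seed, the per-day
#' intercepts, per-day residual variances and per-day spline-trend
#' coefficients actually used by the series generators, and stores them with
#' the effect vectors. Keeping the realised values alongside every generated
#' dataset is what makes parameter-recovery experiments possible.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `ground_truth`: a list with elements `mu_day`,
#'   `sigma2_day`, `zeta` (days x basis-coefficients matrix), `alpha`,
#'   `beta`, `gamma`, `fraction_offsets`, `trend_basis` (degree, interior
#'   knot count, domain) and the day -> job assignment.
#' @export
simulate_ground_truth <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  d <- cfg$n_days
  k <- cfg$trend_knots + 3L + 1L          # cubic basis dimension
  jobs <- vapply(seq_len(d), function(i) job_of_day(cfg, i), character(1))
  with_seed(seed_mod(as.numeric(cfg$seed) * 31 + 11), {
    mu_day <- stats::rnorm(d, cfg$mu_job[jobs], sqrt(cfg$tau2_job[jobs]))
    sigma2_day <- stats::runif(d, cfg$sigma2_day_range[1], cfg$sigma2_day_range[2])
    zeta <- matrix(stats::rnorm(d * k, 0, cfg$trend_amplitude), nrow = d)
  })
  day_ids <- sprintf("day%02d", seq_len(d))
  rownames(zeta) <- day_ids
  structure(list(
    day_id = day_ids,
    job = jobs,
    mu_day = stats::setNames(mu_day, day_ids),
    sigma2_day = stats::setNames(sigma2_day, day_ids),
    zeta = zeta,
    alpha = cfg$true_alpha,
    beta = cfg$true_beta,
    gamma = cfg$true_gamma,
    fraction_offsets = cfg$fraction_offsets,
    trend_basis = list(degree = 3L, n_knots = cfg$trend_knots,
                       domain = c(0, cfg$shift_minutes))
  ), class = "ground_truth")
}

#' Serialise / restore ground truth
#'
#' Ground truth round-trips losslessly through JSON (doubles are written at
#' full precision).
#'
#' @param gt a `ground_truth` object.
#' @param path file path.
#' @return `read_ground_truth()` returns the restored `ground_truth`.
#' @export
write_ground_truth <- function(gt, path) {
  stopifnot(inherits(gt, "ground_truth"))
  # doubles as %.17g strings: JSON number formatting is lossy in the last
  # bit, while 17 significant digits round-trip IEEE doubles exactly
  pack <- function(x) list(names = names(x), values = sprintf("%.17g", x))
  out <- list(
    day_id = gt$day_id, job = gt$job,
    mu_day = pack(gt$mu_day), sigma2_day = pack(gt$sigma2_day),
    alpha = pack(gt$alpha), beta = pack(gt$beta), gamma = pack(gt$gamma),
    fraction_offsets = pack(gt$fraction_offsets),
    zeta = list(values = sprintf("%.17g", as.numeric(gt$zeta)),
                nrow = nrow(gt$zeta), rownames = rownames(gt$zeta)),
    trend_basis = gt$trend_basis)
  jsonlite::write_json(out, path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  unpack <- function(p) stats::setNames(as.numeric(p$values), p$names)
  z <- matrix(as.numeric(raw$zeta$values), nrow = raw$zeta$nrow)
  rownames(z) <- raw$zeta$rownames
  structure(list(
    day_id = raw$day_id, job = raw$job,
    mu_day = unpack(raw$mu_day), sigma2_day = unpack(raw$sigma2_day),
    zeta = z,
    alpha = unpack(raw$alpha), beta = unpack(raw$beta),
    gamma = unpack(raw$gamma),
    fraction_offsets = unpack(raw$fraction_offsets),
    trend_basis = list(degree = as.integer(raw$trend_basis$degree),
                       n_knots = as.integer(raw$trend_basis$n_knots),
                       domain = as.numeric(raw$trend_basis$domain))
  ), class = "ground_truth")
}

# ---- activity logbooks -----------------------------------------------------

# build interval rows for a walk between station indices, Tunnel in between;
# `env_move` is the environment used while moving (train or cabin).
# Hop durations are jittered around their means: without jitter the hop
# period can divide the recording interval exactly and alias the sampling
# grid onto a fixed subset of stations.
walk_segments <- function(cfg, from, to, t0, env_move,
                          hop_tunnel = 1.5, hop_station = 0.5) {
  if (from == to || cfg$n_stations < 3L) {
    return(list(rows = NULL, t = t0, at = from))
  }
  step <- sign(to - from)
  idx <- seq(from, to, by = step)
  rows <- list(); t <- t0
  for (i in seq_along(idx)[-1]) {
    tun <- hop_tunnel * stats::runif(1, 0.75, 1.25)
    rows[[length(rows) + 1L]] <- list(start = t, end = t + tun,
                                      station = "Tunnel", environment = env_move)
    t <- t + tun
    dwell <- if (i == length(idx)) 0 else hop_station * stats::runif(1, 0.6, 1.4)
    if (dwell > 0) {
      rows[[length(rows) + 1L]] <- list(start = t, end = t + dwell,
                                        station = cfg$station_levels[idx[i]],
                                        environment = env_move)
      t <- t + dwell
    }
  }
  list(rows = rows, t = t, at = to)
}

env_or_ref <- function(cfg, env) {
  if (env %in% cfg$environment_levels) env else cfg$reference_environment
}

#' Simulate one day's activity logbook
#'
#' Produces the interval-annotated `Station`/`Environment` schedule and the
#' point-or-interval `Event` annotations for one monitored work day. Every
#' shift starts and ends in the reference environment (the sampling room at
#' the reference station); the station sequence is a walk along the line,
#' with records between two adjacent stations labelled `Tunnel`. Schedules
#' follow one of three occupation templates: a station agent travelling to a
#' ticket counter and staying there, a locomotive operator traversing the
#' line in the cabin, and a security guard patrolling a mix of environments
#' near the terminus.
#'
#' @param cfg a [sim_config()].
#' @param day_index day number in `1:cfg$n_days`.
#' @return a tibble with one row per interval: `day_id`, `job`, `type`
#'   (`"interval"` or `"event"`), `start`, `end` (POSIXct), `station`,
#'   `environment` (NA on event rows), `event` (NA on interval rows).
#' @export
#' @examples
#' lb <- simulate_logbook(sim_config(n_stations = 6, n_events = 2), 1)
#' head(lb)
simulate_logbook <- function(cfg, day_index) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.numeric(day_index) || day_index < 1 || day_index > cfg$n_days) {
    abort("`day_index` must lie in 1:cfg$n_days.",
          class = "subwaypm_config_error")
  }
  day_index <- as.integer(day_index)
  job <- job_of_day(cfg, day_index)
  template <- switch(((match(job, cfg$job_levels) - 1L) %% 3L) + 1L,
                     "station_agent", "locomotive_operator", "security_guard")
  S <- cfg$shift_minutes
  n_real <- max(cfg$n_stations - 1L, 1L)     # stations excluding Tunnel
  rows <- list()
  add <- function(start, end, station, environment) {
    rows[[length(rows) + 1L]] <<- list(start = start, end = end,
                                       station = station,
                                       environment = environment)
  }

  with_seed(seed_mod(as.numeric(cfg$seed) * 101 + day_index), {
    ref_st <- cfg$reference_station
    ref_env <- cfg$reference_environment
    t <- 0
    add(0, 10, ref_st, ref_env); t <- 10

    if (template == "station_agent" && cfg$n_stations >= 3L) {
      target <- 2L + (day_index * 5L) %% (n_real - 1L)
      add(t, t + 3, ref_st, env_or_ref(cfg, "underground_corridor")); t <- t + 3
      add(t, t + 2, ref_st, env_or_ref(cfg, "platform")); t <- t + 2
      w <- walk_segments(cfg, 1L, target, t, env_or_ref(cfg, "train"))
      for (r in w$rows) add(r$start, r$end, r$station, r$environment)
      t <- w$t
      travel_back <- 2.6 * abs(target - 1L) + 5 + 10
      counter_env <- env_or_ref(cfg, "ticket_counter")
      add(t, S - travel_back, cfg$station_levels[target], counter_env)
      t <- S - travel_back
      w <- walk_segments(cfg, target, 1L, t, env_or_ref(cfg, "train"))
      for (r in w$rows) add(r$start, r$end, r$station, r$environment)
      t <- w$t
    } else if (template == "locomotive_operator" && cfg$n_stations >= 3L) {
      add(t, t + 3, ref_st, env_or_ref(cfg, "underground_corridor")); t <- t + 3
      add(t, t + 2, ref_st, env_or_ref(cfg, "platform")); t <- t + 2
      at <- 1L
      # repeated full-line traversals with ~1-min station stops, leaving
      # room to return to the terminus at the end of the shift
      while (t < S - 15 - 3.25 * (n_real - 1L) - 3) {
        dest <- if (at == 1L) n_real else 1L
        w <- walk_segments(cfg, at, dest, t, env_or_ref(cfg, "cabin"),
                           hop_station = 1)
        for (r in w$rows) add(r$start, r$end, r$station, r$environment)
        t <- w$t; at <- dest
        dwell <- min(3, S - 15 - t)
        if (dwell > 0.5) {
          add(t, t + dwell, cfg$station_levels[at], env_or_ref(cfg, "platform"))
          t <- t + dwell
        }
      }
      if (at != 1L) {
        w <- walk_segments(cfg, at, 1L, t, env_or_ref(cfg, "cabin"),
                           hop_station = 1)
        for (r in w$rows) add(r$start, r$end, r$station, r$environment)
        t <- w$t
      }
    } else {
      # security guard: patrol within reach of the terminus, rotating through
      # the remaining environment pool so every category gets visited
      pool <- setdiff(cfg$environment_levels,
                      c(ref_env, "ticket_counter", "cabin"))
      if (length(pool) == 0L) pool <- ref_env
      reach <- min(n_real, 8L)
      at <- 1L; block <- day_index  # offset rotation across days
      while (t < S - 10 - 2.6 * reach - 5) {
        env <- pool[((block - 1L) %% length(pool)) + 1L]; block <- block + 1L
        dur <- stats::runif(1, 8, 20)
        dur <- min(dur, S - 10 - 2.6 * abs(at - 1L) - 5 - t)
        if (dur < 2) break
        add(t, t + dur, cfg$station_levels[at], env); t <- t + dur
        if (n_real >= 2L) {
          dest <- at + sample(c(-1L, 1L), 1L)
          dest <- max(1L, min(reach, dest))
          if (dest != at) {
            w <- walk_segments(cfg, at, dest, t, env_or_ref(cfg, "train"))
            for (r in w$rows) add(r$start, r$end, r$station, r$environment)
            t <- w$t; at <- dest
          }
        }
      }
      if (at != 1L) {
        w <- walk_segments(cfg, at, 1L, t, env_or_ref(cfg, "train"))
        for (r in w$rows) add(r$start, r$end, r$station, r$environment)
        t <- w$t
      }
    }
    # close the shift: corridor filler (jittered walks shift the end time),
    # then the sampling room until the end of the shift
    t_end <- min(max(t, S - 10), S - 2)
    if (t < t_end) {
      add(t, t_end, ref_st, env_or_ref(cfg, "underground_corridor"))
    }
    add(t_end, S, ref_st, ref_env)

    # events: cycle the type list across days (coverage), plus random extras
    ev_rows <- list()
    if (cfg$n_events > 0L) {
      n_ev <- 2L + stats::rpois(1L, 1)
      types <- cfg$event_levels[((day_index - 1L) %% cfg$n_events) + 1L]
      if (n_ev > 1L) {
        types <- c(types, sample(cfg$event_levels, n_ev - 1L, replace = TRUE))
      }
      starts <- sort(stats::runif(n_ev, 30, S - 40))
      durs <- stats::runif(n_ev, 2, 10)
      for (i in seq_len(n_ev)) {
        ev_rows[[i]] <- list(start = starts[i], end = starts[i] + durs[i],
                             event = types[i])
      }
    }
    NULL
  })

  t0 <- shift_start_time(cfg, day_index)
  ints <- dplyr::bind_rows(lapply(rows, as_tibble))
  ints <- dplyr::mutate(ints, type = "interval", event = NA_character_)
  out <- ints
  if (exists("ev_rows") && length(ev_rows)) {
    evs <- dplyr::bind_rows(lapply(ev_rows, as_tibble))
    evs <- dplyr::mutate(evs, type = "event",
                         station = NA_character_, environment = NA_character_)
    out <- dplyr::bind_rows(ints, evs)
  }
  dplyr::transmute(out,
                   day_id = sprintf("day%02d", day_index),
                   job = job,
                   type = .data$type,
                   start = t0 + .data$start * 60,
                   end = t0 + .data$end * 60,
                   station = .data$station,
                   environment = .data$environment,
                   event = .data$event) |>
    dplyr::arrange(.data$type, .data$start)
}

# environment/station/event lookup at given times (half-open [start, end))
lookup_logbook <- function(logbook_day, times, event_lvls) {
  ints <- dplyr::filter(logbook_day, .data$type == "interval") |>
    dplyr::arrange(.data$start)
  pos <- findInterval(as.numeric(times), as.numeric(ints$start))
  inside <- pos >= 1L & as.numeric(times) < as.numeric(ints$end)[pmax(pos, 1L)]
  station <- ifelse(inside, ints$station[pmax(pos, 1L)], NA_character_)
  environment <- ifelse(inside, ints$environment[pmax(pos, 1L)], NA_character_)
  flags <- matrix(0L, nrow = length(times), ncol = length(event_lvls),
                  dimnames = list(NULL, event_lvls))
  evs <- dplyr::filter(logbook_day, .data$type == "event")
  if (nrow(evs)) {
    for (i in seq_len(nrow(evs))) {
      on <- times >= evs$start[i] & times < evs$end[i]
      flags[on, evs$event[i]] <- 1L
    }
  }
  list(station = station, environment = environment, flags = flags,
       covered = inside)
}

# log10 mean surface of the generating model at given times
latent_mean <- function(cfg, gt, lk, day_index, t_min) {
  day <- sprintf("day%02d", day_index)
  B <- spline_basis(t_min, domain = gt$trend_basis$domain,
                    n_knots = gt$trend_basis$n_knots,
                    degree = gt$trend_basis$degree)
  trend <- as.numeric(B %*% gt$zeta[day, ])
  ev <- if (length(cfg$event_levels)) {
    as.numeric(lk$flags[, cfg$event_levels, drop = FALSE] %*%
                 gt$gamma[cfg$event_levels])
  } else 0
  gt$mu_day[[day]] + unname(gt$alpha[lk$station]) +
    unname(gt$beta[lk$environment]) + ev + trend
}

#' Simulate a mass-concentration shift series
#'
#' Generates one complete shift of optical-particle-counter mass records for
#' one PM size fraction from the generating model (see [sim_config()]).
#' Concentrations are strictly positive by construction; the default
#' fraction offsets put PM0.3 more than an order of magnitude below PM10.
#' Temperature and relative humidity channels with mild diurnal structure
#' are included for calibration exercises.
#'
#' @param cfg a [sim_config()].
#' @param logbook the day's logbook from [simulate_logbook()].
#' @param ground_truth from [simulate_ground_truth()].
#' @param fraction one of `"PM0.3"`, `"PM1"`, `"PM2.5"`, `"PM10"`.
#' @return a tibble (`day_id`, `job`, `timestamp`, `fraction`, `value`,
#'   `temperature`, `rh`), one row per `mass_dt`-second window start.
#' @export
simulate_mass_series <- function(cfg, logbook, ground_truth,
                                 fraction = c("PM10", "PM2.5", "PM1", "PM0.3")) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ground_truth, "ground_truth"))
  fraction <- match.arg(fraction)
  day_id <- unique(logbook$day_id)
  stopifnot(length(day_id) == 1L)
  day_index <- as.integer(sub("day", "", day_id))
  t0 <- min(logbook$start[logbook$type == "interval"])
  n <- (cfg$shift_minutes * 60) %/% cfg$mass_dt
  times <- t0 + (seq_len(n) - 1L) * cfg$mass_dt
  t_min <- as.numeric(difftime(times, t0, units = "mins"))
  lk <- lookup_logbook(logbook, times, cfg$event_levels)
  mean_log10 <- latent_mean(cfg, ground_truth, lk, day_index, t_min) +
    cfg$fraction_offsets[[fraction]]
  sig <- sqrt(ground_truth$sigma2_day[[day_id]])
  frac_idx <- match(fraction, names(cfg$fraction_offsets))
  with_seed(seed_mod(as.numeric(cfg$seed) * 479 + day_index * 7 + frac_idx), {
    y <- 10^(mean_log10 + stats::rnorm(n, 0, sig))
    temperature <- 20 + 3 * sin(2 * pi * t_min / cfg$shift_minutes) +
      stats::rnorm(n, 0, 0.3)
    rh <- 45 + 8 * sin(2 * pi * (t_min + 60) / cfg$shift_minutes) +
      stats::rnorm(n, 0, 1)
  })
  tibble(day_id = day_id, job = unique(logbook$job)[1],
         timestamp = times, fraction = fraction, value = y,
         temperature = temperature, rh = rh)
}

#' Simulate paired number-concentration series
#'
#' Generates (a) a channelised optical-particle-counter series (31 log-spaced
#' size channels spanning 0.25-20 um, recorded every `mass_dt` seconds) and
#' (b) a wide-range diffusion-charger counter series (10-700 nm totals,
#' recorded every `number_dt` seconds). Both are driven by the same latent
#' within-shift trend, so their smoothed correlation is positive; the counter
#' totals exceed the optical counter's 0.25-0.7 um band totals by
#' `cfg$number_factor` (default three orders of magnitude), reflecting the
#' dominance of ultrafine particles in number concentration.
#'
#' @inheritParams simulate_mass_series
#' @param channel_edges strictly increasing channel boundaries in um; must
#'   start at 0.25 and end at 20 (length 32 for 31 channels).
#' @param noise_sd multiplicative (log10) noise SD for both instruments; set
#'   0 for noise-free output.
#' @return a list with `opc` (tibble: `day_id`, `job`, `timestamp`, then one
#'   column per channel `ch_01`..`ch_31`, in #/cm3, with the channel edges in
#'   attribute `"channel_edges"`) and `counter` (tibble: `day_id`, `job`,
#'   `timestamp`, `value`).
#' @export
simulate_number_series <- function(cfg, logbook, ground_truth,
                                   channel_edges = NULL, noise_sd = 0.05) {
  stopifnot(inherits(cfg, "sim_config"), inherits(ground_truth, "ground_truth"))
  if (is.null(channel_edges)) {
    channel_edges <- exp(seq(log(0.25), log(20), length.out = 32L))
    channel_edges[1] <- 0.25; channel_edges[32] <- 20
  }
  if (any(diff(channel_edges) <= 0) || abs(channel_edges[1] - 0.25) > 1e-9 ||
      abs(channel_edges[length(channel_edges)] - 20) > 1e-9) {
    abort("`channel_edges` must increase strictly from 0.25 to 20 um.",
          class = "subwaypm_config_error")
  }
  day_id <- unique(logbook$day_id)
  day_index <- as.integer(sub("day", "", day_id))
  job <- unique(logbook$job)[1]
  t0 <- min(logbook$start[logbook$type == "interval"])
  n_ch <- length(channel_edges) - 1L

  # fixed lognormal number-size spectrum over the optical range
  w <- diff(stats::plnorm(channel_edges, meanlog = log(0.35), sdlog = log(2.2)))
  w <- w / sum(w)

  make_grid <- function(dt) {
    n <- floor(cfg$shift_minutes * 60 / dt)
    t0 + (seq_len(n) - 1L) * dt
  }
  latent_at <- function(times) {
    t_min <- as.numeric(difftime(times, t0, units = "mins"))
    lk <- lookup_logbook(logbook, times, cfg$event_levels)
    latent_mean(cfg, ground_truth, lk, day_index, t_min) -
      ground_truth$mu_day[[day_id]] + cfg$number_log10_baseline
  }

  times_opc <- make_grid(cfg$mass_dt)
  times_ctr <- make_grid(cfg$number_dt)
  L_opc <- latent_at(times_opc)
  L_ctr <- latent_at(times_ctr)
  with_seed(seed_mod(as.numeric(cfg$seed) * 881 + day_index * 3), {
    eps_opc <- stats::rnorm(length(times_opc), 0, noise_sd)
    eps_ctr <- stats::rnorm(length(times_ctr), 0, noise_sd)
  })
  total_opc <- 10^(L_opc + eps_opc)
  ch <- outer(total_opc, w)
  colnames(ch) <- sprintf("ch_%02d", seq_len(n_ch))
  opc <- dplyr::bind_cols(
    tibble(day_id = day_id, job = job, timestamp = times_opc),
    as_tibble(ch))
  attr(opc, "channel_edges") <- channel_edges

  # fraction of the spectrum inside the counter's overlap band (0.25-0.7 um)
  band_w <- band_weights(channel_edges, 0.25, 0.7, mode = "prorata")
  w_band <- sum(w * band_w)
  counter <- tibble(day_id = day_id, job = job, timestamp = times_ctr,
                    value = cfg$number_factor * w_band * 10^(L_ctr + eps_ctr))
  list(opc = opc, counter = counter)
}

#' Simulate shift-level gravimetric filter results
#'
#' Emulates the reference filter measurement that accompanies each shift:
#' the gravimetric value is a power function of the shift's time-weighted
#' mean raw concentration, `a * mean(raw)^b`, with multiplicative lognormal
#' noise. With `a > 1` the raw optical series under-reads relative to
#' gravimetry, the situation the calibration module corrects.
#'
#' @param series mass series (possibly several days) as returned by
#'   [simulate_mass_series()]; fractions PM2.5/PM10 only.
#' @param true_calibration numeric `c(a, b)` of the generating power law.
#' @param noise_sd SD of the multiplicative log-normal noise (natural log
#'   scale); 0 gives exact power-law values.
#' @param seed integer seed.
#' @return tibble (`day_id`, `fraction`, `raw_mean`, `gravimetric`), one row
#'   per shift per fraction.
#' @export
simulate_gravimetric <- function(series, true_calibration = c(a = 1.8, b = 0.9),
                                 noise_sd = 0.1, seed = 1L) {
  stopifnot(all(series$value > 0))
  bad <- setdiff(unique(series$fraction), c("PM2.5", "PM10"))
  if (length(bad)) {
    abort(sprintf("gravimetric sampling is defined for PM2.5/PM10 only (got %s).",
                  paste(bad, collapse = ", ")),
          class = "subwaypm_config_error")
  }
  a <- true_calibration[[1]]; b <- true_calibration[[2]]
  out <- series |>
    dplyr::group_by(.data$day_id, .data$fraction) |>
    dplyr::summarise(raw_mean = mean(.data$value), .groups = "drop")
  with_seed(seed_mod(as.numeric(seed) * 9973), {
    noise <- exp(stats::rnorm(nrow(out), 0, noise_sd))
  })
  dplyr::mutate(out, gravimetric = a * .data$raw_mean^b * noise)
}

#' Simulate station metadata
#'
#' Covariates mirroring what a transport operator records per station:
#' opening/renovation years, annual ridership, ventilation equipment,
#' entrances, correspondence concourses, platform/track counts, a design
#' type (A-G) and the minimum altitude of the station. Values are synthetic
#' and drawn from the configuration seed.
#'
#' @param cfg a [sim_config()].
#' @return tibble with one row per station (the `Tunnel` pseudo-station is
#'   excluded).
#' @export
simulate_station_metadata <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  st <- setdiff(cfg$station_levels, "Tunnel")
  n <- length(st)
  with_seed(seed_mod(as.numeric(cfg$seed) * 211 + 5), {
    tibble(
      station = st,
      year_opened = sample(1900:1985, n, replace = TRUE),
      year_renovated = sample(1990:2019, n, replace = TRUE),
      annual_passengers = round(stats::rlnorm(n, log(3e6), 0.6)),
      n_ventilators = stats::rpois(n, 2),
      n_entrances = 1L + stats::rpois(n, 2),
      n_correspondence_concourses = stats::rpois(n, 1),
      n_platforms_tracks = sample(2:4, n, replace = TRUE),
      design_type = sample(LETTERS[1:7], n, replace = TRUE),
      min_altitude = round(stats::rnorm(n, 35, 8), 1)
    )
  })
}

#' Simulate a complete monitoring campaign
#'
#' Orchestrates the per-day generators into a full synthetic study:
#' logbooks, mass series for the four PM fractions, optional number series,
#' gravimetric shift values, station metadata and the realised ground truth.
#' The schedule is resampled (bounded retries, by advancing the seed) until
#' every station, environment and event category appears in at least one
#' record, so that all model coefficients are informed by data.
#'
#' @param cfg a [sim_config()].
#' @param fractions which mass fractions to generate.
#' @param number_series generate the paired number-concentration series for
#'   each day? (Slower; off by default.)
#' @param missing_days optional integer day indices whose instrument series
#'   are dropped (the logbook is kept), emulating instrument failure days.
#' @param max_retries resampling attempts for design completeness.
#' @return a list of class `sim_study`: `cfg`, `ground_truth`, `logbook`
#'   (all days), `mass` (all fractions), `gravimetric`, `metadata`, and
#'   `number` (when requested).
#' @export
simulate_study <- function(cfg,
                           fractions = c("PM10", "PM2.5", "PM1", "PM0.3"),
                           number_series = FALSE,
                           missing_days = NULL,
                           max_retries = 20L) {
  stopifnot(inherits(cfg, "sim_config"))
  attempt_cfg <- cfg
  for (attempt in seq_len(max_retries)) {
    logbook <- dplyr::bind_rows(
      lapply(seq_len(attempt_cfg$n_days),
             function(i) simulate_logbook(attempt_cfg, i)))
    # completeness is judged on the records the mass grid will actually see,
    # not on the logbook intervals (short dwells can fall between grid points)
    seen <- lapply(seq_len(attempt_cfg$n_days), function(i) {
      lb <- dplyr::filter(logbook, .data$day_id == sprintf("day%02d", i))
      t0 <- min(lb$start[lb$type == "interval"])
      nrec <- (attempt_cfg$shift_minutes * 60) %/% attempt_cfg$mass_dt
      times <- t0 + (seq_len(nrec) - 1L) * attempt_cfg$mass_dt
      lk <- lookup_logbook(lb, times, attempt_cfg$event_levels)
      list(st = unique(lk$station), en = unique(lk$environment),
           ev = colnames(lk$flags)[colSums(lk$flags) > 0])
    })
    complete <-
      all(attempt_cfg$station_levels %in% unlist(lapply(seen, `[[`, "st"))) &&
      all(attempt_cfg$environment_levels %in% unlist(lapply(seen, `[[`, "en"))) &&
      (attempt_cfg$n_events == 0L ||
         all(attempt_cfg$event_levels %in% unlist(lapply(seen, `[[`, "ev"))))
    if (complete) break
    if (attempt == max_retries) {
      abort("could not realise a schedule covering every design category.",
            class = "subwaypm_simulation_error")
    }
    attempt_cfg$seed <- attempt_cfg$seed + 1000003L
  }
  gt <- simulate_ground_truth(attempt_cfg)
  keep_days <- setdiff(seq_len(attempt_cfg$n_days), missing_days)
  mass <- dplyr::bind_rows(lapply(keep_days, function(i) {
    lb <- dplyr::filter(logbook, .data$day_id == sprintf("day%02d", i))
    dplyr::bind_rows(lapply(fractions, function(fr)
      simulate_mass_series(attempt_cfg, lb, gt, fr)))
  }))
  grav <- NULL
  grav_fracs <- intersect(fractions, c("PM2.5", "PM10"))
  if (length(grav_fracs)) {
    grav <- simulate_gravimetric(
      dplyr::filter(mass, .data$fraction %in% grav_fracs),
      seed = attempt_cfg$seed)
  }
  number <- NULL
  if (number_series) {
    number <- lapply(keep_days, function(i) {
      lb <- dplyr::filter(logbook, .data$day_id == sprintf("day%02d", i))
      simulate_number_series(attempt_cfg, lb, gt)
    })
    names(number) <- sprintf("day%02d", keep_days)
  }
  structure(list(cfg = attempt_cfg, ground_truth = gt, logbook = logbook,
                 mass = mass, gravimetric = grav,
                 metadata = simulate_station_metadata(attempt_cfg),
                 number = number),
            class = "sim_study")
}
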