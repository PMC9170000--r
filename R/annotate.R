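#' Clean an instrument series before log-transforming
#'
#' Drops missing and non-positive records (the model works on the log10
#' scale) and anything below a detection floor, preserving record order.
#' The number of dropped records is reported and attached as attribute
#' `"n_dropped"`.
#'
#' @param series tibble with at least a `value` column.
#' @param floor strictly positive detection floor in the series' units;
#'   records with `value < floor` are removed.
#' @return the cleaned tibble.
#' @export
#' @examples
#' clean_series(tibble::tibble(value = c(1, 0, 2)), floor = 1e-3)
clean_series <- function(series, floor = 1e-3) {
  assert_positive(floor, "floor")
  keep <- !is.na(series$value) & series$value >= floor
  n_dropped <- sum(!keep)
  if (all(!keep)) {
    abort("all records removed by cleaning; nothing left to analyse.",
          class = "subwaypm_empty_series_error")
  }
  if (n_dropped > 0) {
    inform(sprintf("clean_series: dropped %d record(s) below %g or missing.",
                   n_dropped, floor))
  }
  out <- series[keep, , drop = FALSE]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Join instrument records to activity-logbook annotations
#'
#' Attaches to every record the `Station` and `Environment` active at its
#' timestamp and a 0/1 flag per event type, and computes the log10
#' concentration and the within-shift time in minutes (origin = the shift's
#' first record). Logbook intervals are half-open `[start, end)`: a record
#' at a boundary belongs to the later interval. Overlapping events are
#' allowed (several flags can be 1 on one record). Records falling outside
#' logbook coverage are dropped with a reported count.
#'
#' @param series instrument records: tibble with `day_id`, `timestamp`,
#'   `value` (and optionally `job`, `fraction`); multiple days allowed.
#' @param logbook logbook tibble as produced by [simulate_logbook()] (rows of
#'   `type` `"interval"` and `"event"`).
#' @param event_levels event dictionary defining the flag columns; defaults
#'   to the sorted event types present in `logbook`.
#' @return tibble of annotated records: `day_id`, `job`, `fraction` (if
#'   present), `timestamp`, `t_min`, `log10_value`, `station`,
#'   `environment`, and one integer column `event_<type>` per event level.
#'   Attribute `"n_dropped"` counts records outside logbook coverage.
#' @export
annotate <- function(series, logbook, event_levels = NULL) {
  stopifnot(all(c("day_id", "timestamp", "value") %in% names(series)))
  if (is.null(event_levels)) {
    event_levels <- sort(unique(stats::na.omit(logbook$event)))
  }
  days <- unique(series$day_id)
  pieces <- lapply(days, function(d) {
    s <- series[series$day_id == d, , drop = FALSE]
    lb <- logbook[logbook$day_id == d, , drop = FALSE]
    if (nrow(lb) == 0L) {
      return(dplyr::mutate(s, station = NA_character_,
                           environment = NA_character_))
    }
    lk <- lookup_logbook(lb, s$timestamp, event_levels)
    s$station <- lk$station
    s$environment <- lk$environment
    if (length(event_levels)) {
      colnames(lk$flags) <- paste0("event_", event_levels)
      s <- dplyr::bind_cols(s, as_tibble(lk$flags))
    }
    t0 <- min(s$timestamp)
    s$t_min <- as.numeric(difftime(s$timestamp, t0, units = "mins"))
    s
  })
  out <- dplyr::bind_rows(pieces)
  keep <- !is.na(out$station) & !is.na(out$environment)
  n_dropped <- sum(!keep)
  if (all(!keep)) {
    abort("no record falls inside the logbook's coverage.",
          class = "subwaypm_annotation_error")
  }
  if (n_dropped > 0) {
    inform(sprintf("annotate: dropped %d record(s) outside logbook coverage.",
                   n_dropped))
  }
  out <- out[keep, , drop = FALSE]
  out$log10_value <- log10(out$value)
  ev_cols <- if (length(event_levels)) paste0("event_", event_levels) else character(0)
  cols <- c("day_id", intersect(c("job", "fraction"), names(out)),
            "timestamp", "t_min", "log10_value", "station", "environment",
            ev_cols)
  out <- out[, cols]
  attr(out, "n_dropped") <- n_dropped
  out
}

#' Build reference-coded design matrices from annotated records
#'
#' Encodes `Station` and `Environment` as one-hot blocks with the reference
#' category's column omitted (its rows are all-zero), keeps the event flags
#' as-is, and indexes days and jobs. Columns are ordered lexicographically
#' by category id, and rows are sorted by `(day_id, timestamp)` so the
#' result is invariant to the input row order.
#'
#' @param records annotated records from [annotate()].
#' @param reference_station,reference_environment reference category ids;
#'   must be present among the observed categories.
#' @return an object of class `pm_design`: a list with matrices `X_station`,
#'   `X_environment`, `X_event`, vectors `day` (integer index), `t_min`, `y`
#'   (log10 values), `job_of_day`, and the category dictionaries
#'   (`stations`, `environments`, `events`, `days`, `jobs`; reference
#'   first, remaining levels sorted).
#' @export
build_design <- function(records, reference_station, reference_environment) {
  stopifnot(all(c("day_id", "timestamp", "log10_value", "station",
                  "environment") %in% names(records)))
  records <- dplyr::arrange(records, .data$day_id, .data$timestamp)
  st_obs <- sort(unique(records$station))
  en_obs <- sort(unique(records$environment))
  if (!reference_station %in% st_obs) {
    abort(sprintf("reference station '%s' not among observed stations.",
                  reference_station), class = "subwaypm_config_error")
  }
  if (!reference_environment %in% en_obs) {
    abort(sprintf("reference environment '%s' not among observed environments.",
                  reference_environment), class = "subwaypm_config_error")
  }
  stations <- c(reference_station, setdiff(st_obs, reference_station))
  environments <- c(reference_environment, setdiff(en_obs, reference_environment))
  one_hot <- function(x, levels) {
    # reference (first level) omitted -> all-zero row
    m <- matrix(0, nrow = length(x), ncol = length(levels) - 1L,
                dimnames = list(NULL, levels[-1L]))
    j <- match(x, levels) - 1L
    hit <- which(j >= 1L)
    m[cbind(hit, j[hit])] <- 1
    m
  }
  ev_cols <- grep("^event_", names(records), value = TRUE)
  events <- sub("^event_", "", ev_cols)
  ord <- order(events)
  events <- events[ord]
  X_event <- as.matrix(records[, ev_cols[ord], drop = FALSE])
  colnames(X_event) <- events
  storage.mode(X_event) <- "double"
  days <- sort(unique(records$day_id))
  day <- match(records$day_id, days)
  job_of_day <- if ("job" %in% names(records)) {
    vapply(days, function(d) records$job[match(d, records$day_id)], character(1))
  } else {
    stats::setNames(rep("job_01", length(days)), days)
  }
  jobs <- sort(unique(unname(job_of_day)))
  structure(list(
    X_station = one_hot(records$station, stations),
    X_environment = one_hot(records$environment, environments),
    X_event = X_event,
    day = day,
    t_min = records$t_min,
    y = records$log10_value,
    station_of_record = records$station,
    environment_of_record = records$environment,
    day_id_of_record = records$day_id,
    stations = stations,
    environments = environments,
    events = events,
    days = days,
    jobs = jobs,
    job_of_day = match(unname(job_of_day), jobs),
    n_records = nrow(records)
  ), class = "pm_design")
}

#' @export
print.pm_design <- function(x, ...) {
  cat("<pm_design>\n")
  cat(sprintf("  %d records, %d days, %d jobs\n",
              x$n_records, length(x$days), length(x$jobs)))
  cat(sprintf("  %d stations (ref %s), %d environments (ref %s), %d events\n",
              length(x$stations), x$stations[1],
              length(x$environments), x$environments[1], length(x$events)))
  invisible(x)
}

#' Read / write the tabular interchange formats
#'
#' Series and logbooks travel as plain CSV with ISO-8601 timestamps;
#' category dictionaries as JSON.
#'
#' @param x tibble to write.
#' @param path file path.
#' @name pm-io
#' @export
write_series_csv <- function(x, path) {
  out <- x
  for (cl in names(out)) {
    if (inherits(out[[cl]], "POSIXct")) {
      out[[cl]] <- format(out[[cl]], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
    }
  }
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname pm-io
#' @export
read_series_csv <- function(path) {
  out <- as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  for (cl in intersect(c("timestamp", "start", "end"), names(out))) {
    out[[cl]] <- as.POSIXct(out[[cl]], format = "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")
  }
  out
}

#' @rdname pm-io
#' @param design a `pm_design`.
#' @export
write_dictionaries_json <- function(design, path) {
  stopifnot(inherits(design, "pm_design"))
  jsonlite::write_json(
    list(stations = design$stations, environments = design$environments,
         events = design$events, days = design$days, jobs = design$jobs),
    path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname pm-io
#' @export
read_dictionaries_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
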