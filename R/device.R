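# channel weights for a diameter band, by overlap with each channel
# (pro-rata in log-diameter, since aerosol channels are log-spaced; the
# "nearest" mode includes a channel fully iff more than half its log-width
# lies inside the band)
band_weights <- function(edges, lo, hi, mode = c("prorata", "nearest")) {
  mode <- match.arg(mode)
  le <- log(edges)
  llo <- log(lo); lhi <- log(hi)
  w_full <- diff(le)
  overlap <- pmin(lhi, le[-1L]) - pmax(llo, le[-length(le)])
  f <- pmin(pmax(overlap / w_full, 0), 1)
  if (mode == "nearest") f <- as.numeric(f > 0.5)
  f
}

#' Integrate a channelised number-concentration series over a size band
#'
#' Sums the per-channel number concentrations of an optical particle
#' counter over a diameter band, e.g. 0.25-0.7 um (the overlap with a
#' 10-700 nm diffusion-charger counter). Channels fully inside the band
#' contribute entirely; a channel straddling a band edge contributes
#' pro-rata by the fraction of its log-diameter width inside the band
#' (channels are log-spaced). `edge_mode = "nearest"` instead includes a
#' straddling channel fully when more than half its log-width is inside.
#'
#' @param cs channel series: tibble with `timestamp` plus one column per
#'   channel (names starting with `ch_`), and the channel boundaries (um)
#'   in attribute `"channel_edges"` or supplied via `edges`.
#' @param lo,hi band boundaries in um; must overlap the channel span.
#' @param edges optional explicit channel boundaries.
#' @param edge_mode `"prorata"` (default) or `"nearest"`.
#' @return tibble (`day_id`/`job` if present, `timestamp`, `value`) with
#'   the band total per timestamp.
#' @export
integrate_band <- function(cs, lo, hi, edges = NULL,
                           edge_mode = c("prorata", "nearest")) {
  edge_mode <- match.arg(edge_mode)
  edges <- edges %||% attr(cs, "channel_edges")
  if (is.null(edges)) {
    abort("channel edges missing: supply `edges` or a series with a 'channel_edges' attribute.",
          class = "subwaypm_config_error")
  }
  ch_cols <- grep("^ch_", names(cs), value = TRUE)
  if (length(ch_cols) != length(edges) - 1L) {
    abort("number of channel columns does not match the channel edges.",
          class = "subwaypm_config_error")
  }
  if (hi <= lo || hi <= edges[1L] || lo >= edges[length(edges)]) {
    abort("band does not overlap the channel span.",
          class = "subwaypm_config_error")
  }
  w <- band_weights(edges, lo, hi, mode = edge_mode)
  vals <- as.matrix(cs[, ch_cols, drop = FALSE]) %*% w
  keep <- intersect(c("day_id", "job", "timestamp"), names(cs))
  out <- cs[, keep, drop = FALSE]
  out$value <- as.numeric(vals)
  as_tibble(out)
}

#' Align two series recorded at different resolutions
#'
#' Averages the finer-resolution series into the coarser grid's half-open
#' windows `[t, t + dt)` and pairs the result with the coarser series.
#' Windows in which either member is missing are dropped and counted
#' (attribute `"n_dropped"`). Identical grids pair records one-to-one.
#'
#' @param a,b tibbles with `timestamp` and `value`; their spans must
#'   overlap.
#' @return tibble (`timestamp`, `value_a`, `value_b`) on the coarser grid.
#' @export
align_series <- function(a, b) {
  dt_a <- stats::median(diff(as.numeric(a$timestamp)))
  dt_b <- stats::median(diff(as.numeric(b$timestamp)))
  if (max(a$timestamp) < min(b$timestamp) ||
      max(b$timestamp) < min(a$timestamp)) {
    abort("the two series do not overlap in time.",
          class = "subwaypm_config_error")
  }
  a_coarse <- dt_a >= dt_b
  coarse <- if (a_coarse) a else b
  fine <- if (a_coarse) b else a
  dt <- max(dt_a, dt_b)
  grid <- as.numeric(coarse$timestamp)
  win <- findInterval(as.numeric(fine$timestamp), grid)
  ok <- win >= 1L & as.numeric(fine$timestamp) < grid[pmin(win, length(grid))] + dt
  means <- tapply(fine$value[ok], win[ok], mean)
  fine_on_grid <- rep(NA_real_, length(grid))
  fine_on_grid[as.integer(names(means))] <- as.numeric(means)
  out <- tibble(timestamp = coarse$timestamp,
                value_a = if (a_coarse) coarse$value else fine_on_grid,
                value_b = if (a_coarse) fine_on_grid else coarse$value)
  n_all <- nrow(out)
  out <- dplyr::filter(out, !is.na(.data$value_a) & !is.na(.data$value_b))
  if (nrow(out) == 0L) {
    abort("no complete pairs after alignment.",
          class = "subwaypm_config_error")
  }
  attr(out, "n_dropped") <- n_all - nrow(out)
  out
}

#' Compare two aligned number-concentration series
#'
#' Summarises the agreement between a wide-range counter and an optical
#' counter band total: the ratio of totals (`sum(b) / sum(a)`), the Pearson
#' correlation of the log10 values (concentrations span decades), and the
#' fraction of paired first differences that agree in sign. With the
#' default generator the counter runs about three orders of magnitude above
#' the optical 0.25-0.7 um band while following the same temporal pattern.
#'
#' @param paired output of [align_series()]; at least 3 pairs.
#' @return one-row tibble (`n`, `ratio_of_totals`, `log10_pearson_r`,
#'   `sign_agreement`), with the paired table in attribute `"paired"`.
#' @export
compare_devices <- function(paired) {
  if (nrow(paired) < 3L) {
    abort("need at least 3 aligned pairs.", class = "subwaypm_config_error")
  }
  r <- if (stats::sd(paired$value_a) > 0 && stats::sd(paired$value_b) > 0 &&
           all(paired$value_a > 0) && all(paired$value_b > 0)) {
    stats::cor(log10(paired$value_a), log10(paired$value_b))
  } else NA_real_
  da <- diff(paired$value_a); db <- diff(paired$value_b)
  out <- tibble(n = nrow(paired),
                ratio_of_totals = sum(paired$value_b) / sum(paired$value_a),
                log10_pearson_r = r,
                sign_agreement = mean(sign(da) == sign(db)))
  attr(out, "paired") <- paired
  out
}

#' Overlay plot of two aligned series
#'
#' Both series on a log10 axis against time, the standard display for an
#' optical-counter band total against a wide-range counter.
#'
#' @param paired output of [align_series()].
#' @param labels length-2 labels for series a and b.
#' @return a ggplot.
#' @export
plot_device_comparison <- function(paired, labels = c("series a", "series b")) {
  long <- tidyr::pivot_longer(paired, c("value_a", "value_b"),
                              names_to = "series", values_to = "value")
  long$series <- labels[match(long$series, c("value_a", "value_b"))]
  ggplot2::ggplot(long, ggplot2::aes(x = .data$timestamp, y = .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "number concentration (#/cm3)") +
    ggplot2::theme_minimal()
}
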