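#' Posterior fold-change summaries per category
#'
#' Transforms the posterior draws of one categorical block into fold
#' changes, `10^coefficient`: the multiplicative concentration change
#' relative to the block's reference category. Reported per category are
#' the posterior median and the central 95% credible interval; the
#' reference category is exactly `(1, 1, 1)`. A category is `elevated`
#' when its credible interval lies entirely above 1.
#'
#' @param draws a `pm_draws`.
#' @param block `"station"`, `"environment"` or `"event"`.
#' @param level credible level (default 0.95).
#' @param fraction optional size-fraction label carried into the output.
#' @return tibble of class `pm_effect_summary`: `category`, `fraction`,
#'   `fold_change_median`, `ci_low`, `ci_high`, `elevated`.
#' @export
fold_change_summary <- function(draws,
                                block = c("station", "environment", "event"),
                                level = 0.95, fraction = NA_character_) {
  stopifnot(inherits(draws, "pm_draws"))
  block <- match.arg(block)
  lay_name <- c(station = "alpha", environment = "beta", event = "gamma")[[block]]
  idx <- draws$layout[[lay_name]]
  if (length(idx) == 0L) {
    abort(sprintf("the draws contain no '%s' block.", block),
          class = "subwaypm_summary_error")
  }
  cats <- switch(block, station = draws$stations,
                 environment = draws$environments, event = draws$events)
  dm <- dim(draws$draws)
  flat <- matrix(draws$draws[, , idx, drop = FALSE], nrow = dm[1] * dm[2])
  a2 <- (1 - level) / 2
  q <- t(apply(flat, 2, stats::quantile, probs = c(a2, 0.5, 1 - a2),
               names = FALSE))
  out <- tibble(category = cats,
                fraction = fraction,
                fold_change_median = 10^q[, 2],
                ci_low = 10^q[, 1],
                ci_high = 10^q[, 3])
  out$elevated <- out$ci_low > 1
  class(out) <- c("pm_effect_summary", class(out))
  out
}

#' Flag categories with elevated concentrations
#'
#' A category is flagged `elevated` when the lower bound of its 95%
#' fold-change credible interval exceeds 1, and `borderline` when the lower
#' bound falls in `(1 - delta, 1]` - an increase with borderline
#' credibility.
#'
#' @param summaries a `pm_effect_summary` (or compatible tibble with
#'   `ci_low`).
#' @param delta borderline width below 1 (default 0.02).
#' @param include optional subset of category ids to consider (e.g. real
#'   stations only, excluding the `Tunnel` pseudo-station).
#' @return the elevated and borderline rows, with a `status` column.
#' @export
flag_elevated <- function(summaries, delta = 0.02, include = NULL) {
  out <- summaries
  if (!is.null(include)) out <- dplyr::filter(out, .data$category %in% include)
  out <- dplyr::mutate(out, status = dplyr::case_when(
    .data$ci_low > 1 ~ "elevated",
    .data$ci_low > 1 - delta ~ "borderline",
    TRUE ~ "none"))
  dplyr::filter(out, .data$status != "none")
}

#' Geometric mean / geometric standard deviation tables
#'
#' The natural summaries of lognormal exposure data:
#' `GM = exp(mean(ln y))`, `GSD = exp(sd(ln y))`, per group and size
#' fraction. Groups with fewer than two records get `GSD = NA`.
#'
#' @param series tibble with `value` (> 0), `fraction`, and the grouping
#'   column.
#' @param grouping `"day"` (groups by `day_id`) or `"job"`.
#' @return tibble with one row per group x fraction: group id, `fraction`,
#'   `n`, `gm`, `gsd`.
#' @export
#' @examples
#' gm_gsd(tibble::tibble(day_id = "d1", job = "a", fraction = "PM10",
#'                       value = c(1, 10, 100)), "day")
gm_gsd <- function(series, grouping = c("day", "job")) {
  grouping <- match.arg(grouping)
  if (any(series$value <= 0, na.rm = TRUE)) {
    abort("geometric summaries need strictly positive values.",
          class = "subwaypm_summary_error")
  }
  key <- if (grouping == "day") "day_id" else "job"
  series |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(key, "fraction")))) |>
    dplyr::summarise(
      n = dplyr::n(),
      gm = exp(mean(log(.data$value))),
      gsd = if (dplyr::n() >= 2L) exp(stats::sd(log(.data$value))) else NA_real_,
      .groups = "drop")
}

#' Correlate station coefficients with station characteristics
#'
#' Pearson correlation between the posterior point estimates of the
#' log10-scale station coefficients and each numeric station covariate,
#' computed pairwise on stations with both values. No multiple-testing
#' correction is applied - this is an exploratory screen, not a
#' hypothesis-driven analysis. Covariates with zero variance yield `NA`.
#'
#' @param summaries a `pm_effect_summary` for the station block (one or
#'   more fractions stacked).
#' @param metadata station metadata table (see
#'   [simulate_station_metadata()]); character/factor columns other than
#'   `station` are ignored.
#' @param estimate `"median"` (default) or `"mean"` point estimate of the
#'   coefficient; with `"median"` the log10 coefficient is
#'   `log10(fold_change_median)`.
#' @return tibble (`fraction`, `covariate`, `r`, `n`).
#' @export
station_correlations <- function(summaries, metadata,
                                 estimate = c("median", "mean")) {
  estimate <- match.arg(estimate)
  stopifnot("station" %in% names(metadata))
  num_cols <- names(metadata)[vapply(metadata, is.numeric, logical(1))]
  if (length(num_cols) == 0L) {
    abort("metadata has no numeric covariates.",
          class = "subwaypm_summary_error")
  }
  df <- dplyr::inner_join(summaries, metadata,
                          by = c(category = "station"))
  if (nrow(df) < 3L) {
    abort("need at least 3 stations with both a coefficient and covariates.",
          class = "subwaypm_summary_error")
  }
  df$coef_log10 <- log10(df$fold_change_median)
  purrr::map_dfr(split(df, df$fraction), function(dd) {
    purrr::map_dfr(num_cols, function(cv) {
      ok <- stats::complete.cases(dd$coef_log10, dd[[cv]])
      r <- if (sum(ok) >= 3L && stats::sd(dd[[cv]][ok]) > 0 &&
               stats::sd(dd$coef_log10[ok]) > 0) {
        stats::cor(dd$coef_log10[ok], dd[[cv]][ok])
      } else NA_real_
      tibble(fraction = dd$fraction[1], covariate = cv, r = r, n = sum(ok))
    })
  })
}

#' Mean fold change per station design type
#'
#' Summarises station fold changes by the architectural design type (A-G)
#' as a per-type mean, the qualitative companion to
#' [station_correlations()].
#'
#' @inheritParams station_correlations
#' @return tibble (`fraction`, `design_type`, `n`, `mean_fold_change`).
#' @export
design_type_summary <- function(summaries, metadata) {
  stopifnot(all(c("station", "design_type") %in% names(metadata)))
  dplyr::inner_join(summaries, metadata, by = c(category = "station")) |>
    dplyr::group_by(.data$fraction, .data$design_type) |>
    dplyr::summarise(n = dplyr::n(),
                     mean_fold_change = mean(.data$fold_change_median),
                     .groups = "drop")
}

#' Forest plot of fold changes
#'
#' Posterior median fold change with its credible interval per category,
#' the standard display for station/environment/event effects.
#'
#' @param object a `pm_effect_summary`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pm_effect_summary <- function(object, ...) {
  df <- dplyr::mutate(object,
                      category = stats::reorder(.data$category,
                                                .data$fold_change_median))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$fold_change_median,
                                        y = .data$category,
                                        colour = .data$elevated)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high)) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey30",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "fold change (10^coefficient)", y = NULL) +
    ggplot2::theme_minimal()
  if (!all(is.na(object$fraction))) p <- p + ggplot2::facet_wrap(~fraction)
  p
}
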