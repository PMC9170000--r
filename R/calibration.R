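#' Calibrate optical-counter mass concentrations against gravimetric values
#'
#' Optical particle counters convert scattered-light signals to mass under
#' assumptions (density, refractive index, shape) that rarely hold for
#' underground aerosols, so shift-average readings are regressed on
#' co-located gravimetric filter values. Three candidate families are
#' supported, with the power family — the best-fitting one for underground
#' PM2.5/PM10 in practice — fitted by ordinary least squares on the log-log
#' scale:
#' \describe{
#'   \item{power}{`gravimetric = a * raw^b` (optionally with additive
#'     log-temperature / log-RH terms on the log scale)}
#'   \item{linear}{`gravimetric = a * raw + c`}
#'   \item{exponential}{`gravimetric = a * exp(b * raw)`}
#' }
#' R-squared is always computed on the original (untransformed) scale so
#' that families are comparable.
#'
#' Only PM2.5 and PM10 can be calibrated: no gravimetric measurement
#' standard exists for PM1 or PM0.3, and the API refuses them.
#'
#' @param pairs tibble with columns `raw_mean` (shift time-weighted mean raw
#'   concentration), `gravimetric`, and optionally `mean_temperature`,
#'   `mean_rh`.
#' @param family one of `"power"`, `"linear"`, `"exponential"`.
#' @param fraction the size fraction being calibrated (`"PM2.5"` or
#'   `"PM10"`).
#' @param use_covariates include additive log-T and log-RH terms in the
#'   power model (off by default; the exact covariate functional form is a
#'   modelling choice, not a standard).
#' @return an object of class `pm_calibration`: family, named `parameters`,
#'   `r_squared` (original scale), `n_shifts`, `fraction`, and the fitting
#'   data.
#' @export
#' @examples
#' pairs <- tibble::tibble(raw_mean = c(2, 4, 8, 16),
#'                         gravimetric = 2 * c(2, 4, 8, 16)^0.8)
#' fit_calibration(pairs, family = "power")
fit_calibration <- function(pairs,
                            family = c("power", "linear", "exponential"),
                            fraction = "PM10",
                            use_covariates = FALSE) {
  family <- match.arg(family)
  check_calibratable(fraction)
  stopifnot(all(c("raw_mean", "gravimetric") %in% names(pairs)))
  if (nrow(pairs) < 3L) {
    abort("calibration needs at least 3 shift-level pairs.",
          class = "subwaypm_calibration_error")
  }
  if (any(pairs$raw_mean <= 0) || any(pairs$gravimetric <= 0)) {
    abort("raw and gravimetric values must be strictly positive.",
          class = "subwaypm_calibration_error")
  }
  if (stats::var(pairs$raw_mean) == 0) {
    abort("raw shift means have zero variance; calibration is degenerate.",
          class = "subwaypm_calibration_error")
  }
  x <- pairs$raw_mean
  g <- pairs$gravimetric

  if (family == "power") {
    df <- data.frame(lg = log(g), lx = log(x))
    fml <- lg ~ lx
    if (use_covariates) {
      if (!all(c("mean_temperature", "mean_rh") %in% names(pairs))) {
        abort("covariate calibration needs mean_temperature and mean_rh.",
              class = "subwaypm_calibration_error")
      }
      df$lt <- log(pairs$mean_temperature)
      df$lrh <- log(pairs$mean_rh)
      fml <- lg ~ lx + lt + lrh
    }
    m <- stats::lm(fml, data = df)
    cf <- stats::coef(m)
    parameters <- c(a = unname(exp(cf[["(Intercept)"]])), b = unname(cf[["lx"]]))
    if (use_covariates) {
      parameters <- c(parameters, c_T = unname(cf[["lt"]]),
                      c_RH = unname(cf[["lrh"]]))
    }
    fitted_g <- exp(stats::fitted(m))
  } else if (family == "linear") {
    m <- stats::lm(g ~ x)
    cf <- stats::coef(m)
    parameters <- c(a = unname(cf[["x"]]), c = unname(cf[["(Intercept)"]]))
    fitted_g <- stats::fitted(m)
  } else {
    m <- stats::lm(log(g) ~ x)
    cf <- stats::coef(m)
    parameters <- c(a = unname(exp(cf[["(Intercept)"]])), b = unname(cf[["x"]]))
    fitted_g <- exp(stats::fitted(m))
  }
  r2 <- 1 - sum((g - fitted_g)^2) / sum((g - mean(g))^2)
  structure(list(family = family, parameters = parameters,
                 r_squared = r2, n_shifts = nrow(pairs),
                 fraction = fraction, use_covariates = use_covariates,
                 pairs = as_tibble(pairs)),
            class = "pm_calibration")
}

check_calibratable <- function(fraction) {
  if (!fraction %in% c("PM2.5", "PM10")) {
    abort(sprintf(paste0("fraction '%s' cannot be calibrated: gravimetric ",
                         "measurement standards exist only for PM2.5 and PM10."),
                  fraction),
          class = "subwaypm_calibration_error")
  }
  invisible(fraction)
}

#' Fit all calibration families and select the best by R-squared
#'
#' Fits the power, linear and exponential families and returns the fit with
#' the highest original-scale R-squared. Ties are broken by preferring the
#' power family (the established choice for underground PM), then the
#' family with fewest parameters.
#'
#' @inheritParams fit_calibration
#' @return the winning `pm_calibration`; all candidate fits are attached as
#'   attribute `"candidates"`.
#' @export
select_family <- function(pairs, fraction = "PM10", use_covariates = FALSE) {
  fams <- c("power", "linear", "exponential")
  fits <- lapply(fams, function(f) {
    tryCatch(fit_calibration(pairs, family = f, fraction = fraction,
                             use_covariates = use_covariates && f == "power"),
             error = function(e) NULL)
  })
  names(fits) <- fams
  ok <- !vapply(fits, is.null, logical(1))
  if (!any(ok)) {
    abort("all calibration families failed to fit.",
          class = "subwaypm_calibration_error")
  }
  r2 <- vapply(fits[ok], function(f) f$r_squared, numeric(1))
  npar <- vapply(fits[ok], function(f) length(f$parameters), numeric(1))
  pref <- as.integer(names(fits[ok]) != "power")   # 0 for power: wins ties
  best <- order(-r2, pref, npar)[1L]
  out <- fits[ok][[best]]
  attr(out, "candidates") <- fits[ok]
  out
}

#' Apply a fitted calibration to a time-series
#'
#' Transforms every record of a raw series through the fitted calibration
#' function. For the power family with `b > 0` the transform is monotone
#' increasing, so record ordering by concentration is preserved. Records
#' whose transformed value is non-positive (possible under the linear
#' family) are dropped with a reported count. Timestamps are untouched and
#' the calibration provenance is recorded in attribute `"calibration"`.
#'
#' @param series tibble with `fraction` and `value` columns.
#' @param fit a `pm_calibration`.
#' @return the calibrated series.
#' @export
apply_calibration <- function(series, fit) {
  stopifnot(inherits(fit, "pm_calibration"))
  frs <- unique(series$fraction)
  if (length(frs) != 1L || frs != fit$fraction) {
    abort(sprintf("series fraction (%s) does not match the calibration's (%s).",
                  paste(frs, collapse = ","), fit$fraction),
          class = "subwaypm_calibration_error")
  }
  p <- fit$parameters
  v <- switch(fit$family,
              power = p[["a"]] * series$value^p[["b"]],
              linear = p[["a"]] * series$value + p[["c"]],
              exponential = p[["a"]] * exp(p[["b"]] * series$value))
  keep <- v > 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    inform(sprintf("apply_calibration: dropped %d record(s) with non-positive calibrated value.",
                   n_dropped))
  }
  out <- series[keep, , drop = FALSE]
  out$value <- v[keep]
  attr(out, "calibration") <- list(family = fit$family, parameters = p,
                                   r_squared = fit$r_squared)
  attr(out, "n_dropped") <- n_dropped
  out
}

#' @export
print.pm_calibration <- function(x, ...) {
  cat(sprintf("<pm_calibration> %s fit for %s on %d shifts\n",
              x$family, x$fraction, x$n_shifts))
  cat("  parameters:",
      paste(sprintf("%s = %.4g", names(x$parameters), x$parameters),
            collapse = ", "), "\n")
  cat(sprintf("  R^2 (original scale): %.4f\n", x$r_squared))
  if (x$r_squared <= 0) cat("  NOTE: R^2 <= 0 - fit is uninformative.\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pm_calibration <- function(x, ...) {
  tibble(term = names(x$parameters), estimate = unname(x$parameters))
}

#' @exportS3Method generics::glance
glance.pm_calibration <- function(x, ...) {
  tibble(family = x$family, fraction = x$fraction,
         r_squared = x$r_squared, n_shifts = x$n_shifts,
         uninformative = x$r_squared <= 0)
}

#' Diagnostic plot of a calibration fit
#'
#' Shift-level gravimetric values against raw optical shift means, with the
#' fitted calibration curve.
#'
#' @param object a `pm_calibration`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.pm_calibration <- function(object, ...) {
  p <- object$parameters
  grid <- tibble(raw_mean = seq(min(object$pairs$raw_mean),
                                max(object$pairs$raw_mean), length.out = 200))
  grid$fitted <- switch(object$family,
                        power = p[["a"]] * grid$raw_mean^p[["b"]],
                        linear = p[["a"]] * grid$raw_mean + p[["c"]],
                        exponential = p[["a"]] * exp(p[["b"]] * grid$raw_mean))
  ggplot2::ggplot(object$pairs,
                  ggplot2::aes(x = .data$raw_mean, y = .data$gravimetric)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid,
                       ggplot2::aes(y = .data$fitted), colour = "firebrick") +
    ggplot2::labs(x = "raw shift mean (ug/m3)", y = "gravimetric (ug/m3)",
                  title = sprintf("%s calibration, %s (R² = %.3f)",
                                  object$family, object$fraction,
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}
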