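#' Gelman-Rubin potential scale reduction factor
#'
#' Classic between/within-chain diagnostic (the 1992 variant with the
#' `(n-1)/n` correction, not split-R-hat): with `m` chains of length `n`,
#' chain means \eqn{\bar x_j} and chain variances \eqn{s^2_j},
#' \deqn{B = n \,\mathrm{Var}(\bar x_j), \quad W = \tfrac1m \sum s^2_j,
#'   \quad \hat R = \sqrt{\frac{(n-1)/n\, W + B/n}{W}}.}
#' Values near 1 indicate convergence; the conventional pass threshold is
#' 1.1.
#'
#' @param x either a matrix (iterations x chains, >= 2 chains of length >=
#'   4) or a `pm_draws` object (then every monitored parameter is
#'   diagnosed).
#' @param ... unused.
#' @return for a matrix, the scalar R-hat; for `pm_draws`, a tibble with
#'   `parameter` and `rhat` (`NA` for degenerate parameters held constant,
#'   e.g. the reference-category coefficients fixed at zero, which are
#'   converged by construction).
#' @export
#' @examples
#' chains <- cbind(rnorm(500), rnorm(500))
#' gelman_rubin(chains)
gelman_rubin <- function(x, ...) UseMethod("gelman_rubin")

#' @export
gelman_rubin.default <- function(x, ...) {
  x <- as.matrix(x)
  m <- ncol(x); n <- nrow(x)
  if (m < 2L) abort("need at least 2 chains.", class = "subwaypm_diag_error")
  if (n < 4L) abort("chains must have length >= 4.",
                    class = "subwaypm_diag_error")
  W <- mean(apply(x, 2, stats::var))
  if (W == 0) {
    abort("zero within-chain variance in all chains; R-hat is undefined.",
          class = "subwaypm_degenerate_chain_error")
  }
  B <- n * stats::var(colMeans(x))
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' @export
gelman_rubin.pm_draws <- function(x, ...) {
  rhat <- vapply(x$monitored, function(p) {
    mat <- draws_matrix(x, p)
    if (is.null(dim(mat))) return(NA_real_)
    if (all(apply(mat, 2, stats::var) == 0)) return(NA_real_)
    gelman_rubin.default(mat)
  }, numeric(1))
  tibble(parameter = x$monitored, rhat = unname(rhat))
}

#' Sample autocorrelation function of a Markov chain
#'
#' Standard sample ACF at lags 1 to `max_lag` (lag 0, identically 1, is
#' omitted).
#'
#' @param samples numeric vector, longer than `max_lag`.
#' @param max_lag maximum lag (default 20).
#' @return numeric vector of length `max_lag`, named by lag.
#' @export
#' @examples
#' mcmc_acf(as.numeric(arima.sim(list(ar = 0.9), 2000)), max_lag = 5)
mcmc_acf <- function(samples, max_lag = 20L) {
  if (length(samples) <= max_lag) {
    abort("series must be longer than `max_lag`.",
          class = "subwaypm_diag_error")
  }
  if (stats::sd(samples) == 0) {
    abort("constant series: autocorrelation is undefined.",
          class = "subwaypm_diag_error")
  }
  a <- stats::acf(samples, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf
  stats::setNames(as.numeric(a)[-1L], paste0("lag", seq_len(max_lag)))
}

#' Prior-sensitivity analysis on the effect coefficients
#'
#' Refits the model with the effect-prior SD set to each value in
#' `s_values` (the conventional perturbations around the default 5 are 3
#' and 10) and reports, per station/environment/event coefficient, the
#' shift of the posterior median expressed in units of the baseline
#' posterior SD. Parameters whose shift exceeds `threshold` are flagged as
#' prior-dominated: on well-informed data no flags are expected, whereas
#' categories never observed in the records stay at their prior and will be
#' flagged.
#'
#' @param model a `pm_model`.
#' @param draws baseline `pm_draws` fitted with the spec's prior SD.
#' @param s_values alternative prior SDs (default `c(3, 10)`).
#' @param threshold flag threshold in baseline posterior-SD units (default
#'   0.5).
#' @param chains,iterations,burnin,seed sampler settings for the refits
#'   (defaults: the baseline's).
#' @return tibble with one row per effect coefficient and prior SD:
#'   `parameter`, `prior_sd`, `delta_median_sd` and `flagged`.
#' @export
prior_sensitivity <- function(model, draws, s_values = c(3, 10),
                              threshold = 0.5,
                              chains = NULL, iterations = NULL,
                              burnin = NULL, seed = NULL) {
  stopifnot(inherits(model, "pm_model"), inherits(draws, "pm_draws"))
  lay <- draws$layout
  eff_idx <- c(lay$alpha, lay$beta, lay$gamma)
  eff <- draws$par_names[eff_idx]
  dm <- dim(draws$draws)
  base_flat <- matrix(draws$draws[, , eff_idx, drop = FALSE],
                      nrow = dm[1] * dm[2])
  base_med <- apply(base_flat, 2, stats::median)
  base_sd <- apply(base_flat, 2, stats::sd)
  out <- purrr::map_dfr(s_values, function(s) {
    spec2 <- model$spec
    spec2$prior_sd_effects <- s
    model2 <- build_model(model$design, spec2)
    d2 <- fit_spline_model(model2,
                           chains = chains %||% dim(draws$draws)[2],
                           iterations = iterations %||% dim(draws$draws)[1],
                           burnin = burnin %||% model$spec$burnin,
                           seed = seed %||% draws$seed)
    flat2 <- matrix(d2$draws[, , eff_idx, drop = FALSE],
                    nrow = dim(d2$draws)[1] * dim(d2$draws)[2])
    med2 <- apply(flat2, 2, stats::median)
    delta <- abs(med2 - base_med) / ifelse(base_sd > 0, base_sd, NA_real_)
    tibble(parameter = eff, prior_sd = s, delta_median_sd = delta,
           flagged = !is.na(delta) & delta > threshold)
  })
  out
}

#' Posterior predictive check
#'
#' Draws replicate series from the fitted model and reports the fraction of
#' observed records falling inside the central predictive interval,
#' together with the paired observed/predicted table for plotting. Data
#' actually generated by the fitted model should achieve coverage close to
#' the nominal level.
#'
#' @param model a `pm_model`.
#' @param draws a `pm_draws`.
#' @param observed observed log10 values aligned with the model's design
#'   (default: the design's own response).
#' @param level predictive-interval level (default 0.95).
#' @param max_draws posterior draws used for the predictive distribution.
#' @return a list of class `pm_ppc`: `coverage`, `level`, `n`, and the
#'   per-record `table` (tibble).
#' @export
posterior_predictive_check <- function(model, draws, observed = NULL,
                                       level = 0.95, max_draws = 400L) {
  observed <- observed %||% model$design$y
  if (length(observed) == 0L) {
    abort("`observed` is empty.", class = "subwaypm_diag_error")
  }
  if (length(observed) != model$design$n_records) {
    abort(sprintf("observed records (%d) do not align with the design (%d).",
                  length(observed), model$design$n_records),
          class = "subwaypm_diag_error")
  }
  pp <- predict(model, draws, level = level, max_draws = max_draws)
  pp$observed <- observed
  inside <- observed >= pp$pred_lwr_log10 & observed <= pp$pred_upr_log10
  structure(list(coverage = mean(inside), level = level,
                 n = length(observed), table = pp),
            class = "pm_ppc")
}

#' @export
print.pm_ppc <- function(x, ...) {
  cat(sprintf("<pm_ppc> %.1f%% of %d observed records inside the %g%% predictive interval\n",
              100 * x$coverage, x$n, 100 * x$level))
  invisible(x)
}

#' Full WAMBS-style validation report
#'
#' Bundles the numeric parts of the WAMBS checklist for a fitted model:
#' per-parameter Gelman-Rubin R-hat and autocorrelations at lags 1-20, the
#' posterior predictive coverage, and overall pass flags. Trace/density
#' material is exported as a tidy table (see [trace_data()]) rather than as
#' an interactive display. The report is deterministic given the draws.
#'
#' @param model a `pm_model`.
#' @param draws a `pm_draws`.
#' @param rhat_threshold convergence threshold (default 1.1).
#' @param acf_lag lag range for autocorrelation (default 20).
#' @param acf_threshold flag threshold for the lag-1 autocorrelation.
#' @param ppc run the posterior predictive check (default TRUE).
#' @return a list of class `pm_diagnostics`: `parameters` (tibble with
#'   `rhat`, `acf_lag1`, `acf_max`), `ppc_coverage`, and `pass` flags.
#' @export
diagnose_fit <- function(model, draws, rhat_threshold = 1.1, acf_lag = 20L,
                         acf_threshold = 0.9, ppc = TRUE) {
  rh <- gelman_rubin(draws)
  acfs <- purrr::map(draws$monitored, function(p) {
    mat <- draws_matrix(draws, p)
    v <- as.numeric(mat)
    if (stats::sd(v) == 0) return(rep(NA_real_, acf_lag))
    mcmc_acf(as.numeric(mat[, 1]), max_lag = acf_lag)
  })
  params <- dplyr::mutate(rh,
                          acf_lag1 = vapply(acfs, function(a) a[[1]], numeric(1)),
                          acf_max = vapply(acfs, function(a)
                            if (all(is.na(a))) NA_real_ else max(abs(a), na.rm = TRUE),
                            numeric(1)))
  cov <- NA_real_
  if (ppc) cov <- posterior_predictive_check(model, draws)$coverage
  pass <- list(
    convergence = all(params$rhat < rhat_threshold, na.rm = TRUE),
    autocorrelation = all(params$acf_lag1 < acf_threshold, na.rm = TRUE),
    posterior_predictive = if (ppc) abs(cov - 0.95) <= 0.05 else NA
  )
  structure(list(parameters = params, ppc_coverage = cov, pass = pass,
                 rhat_threshold = rhat_threshold),
            class = "pm_diagnostics")
}

#' @export
print.pm_diagnostics <- function(x, ...) {
  cat("<pm_diagnostics>\n")
  cat(sprintf("  max R-hat: %.4f (threshold %.2f) - %s\n",
              suppressWarnings(max(x$parameters$rhat, na.rm = TRUE)),
              x$rhat_threshold,
              if (isTRUE(x$pass$convergence)) "PASS" else "FAIL"))
  if (!is.na(x$ppc_coverage)) {
    cat(sprintf("  posterior predictive coverage: %.3f\n", x$ppc_coverage))
  }
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.pm_diagnostics <- function(x, ...) x$parameters

#' @exportS3Method generics::glance
glance.pm_diagnostics <- function(x, ...) {
  tibble(max_rhat = suppressWarnings(max(x$parameters$rhat, na.rm = TRUE)),
         n_above_threshold = sum(x$parameters$rhat >= x$rhat_threshold,
                                 na.rm = TRUE),
         ppc_coverage = x$ppc_coverage,
         converged = isTRUE(x$pass$convergence))
}

#' Tidy trace data for visual inspection
#'
#' Long-format draws for selected parameters, suitable for trace and
#' density plots with ggplot2.
#'
#' @param draws a `pm_draws`.
#' @param parameters parameter names (default: the monitored set).
#' @return tibble (`parameter`, `chain`, `iteration`, `value`).
#' @export
trace_data <- function(draws, parameters = NULL) {
  parameters <- parameters %||% draws$monitored
  purrr::map_dfr(parameters, function(p) {
    mat <- draws_matrix(draws, p)
    if (is.null(dim(mat))) mat <- matrix(mat, ncol = 1)
    tidyr::pivot_longer(
      dplyr::mutate(as_tibble(mat, .name_repair = ~ paste0("chain", seq_along(.x))),
                    iteration = dplyr::row_number()),
      -"iteration", names_to = "chain", values_to = "value") |>
      dplyr::mutate(parameter = p, .before = 1)
  })
}

#' Trace plot
#'
#' @param draws a `pm_draws`.
#' @param parameters parameters to display (default: first 6 monitored).
#' @return a ggplot.
#' @export
plot_trace <- function(draws, parameters = NULL) {
  parameters <- parameters %||% utils::head(draws$monitored, 6L)
  td <- trace_data(draws, parameters)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   colour = .data$chain)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "iteration", y = "draw")
}

#' Posterior-predictive overlay plot
#'
#' Observed log10 series with the posterior predictive mean and interval,
#' one panel per day.
#'
#' @param ppc a `pm_ppc` from [posterior_predictive_check()].
#' @param days subset of day ids to display (default: first 3).
#' @return a ggplot.
#' @export
plot_posterior_predictive <- function(ppc, days = NULL) {
  tb <- ppc$table
  days <- days %||% utils::head(unique(tb$day_id), 3L)
  tb <- dplyr::filter(tb, .data$day_id %in% days)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$t_min)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$pred_lwr_log10,
                                      ymax = .data$pred_upr_log10),
                         fill = "grey80") +
    ggplot2::geom_line(ggplot2::aes(y = .data$pred_mean_log10),
                       colour = "firebrick") +
    ggplot2::geom_point(ggplot2::aes(y = .data$observed), size = 0.4) +
    ggplot2::facet_wrap(~day_id) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "within-shift minutes", y = "log10 concentration")
}
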