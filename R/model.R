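#' Specification of the hierarchical Bayesian spline model
#'
#' Collects every tunable of the model
#' \deqn{Y_{ir} \sim N\{\mu_i + X^{Station}_{ir}{}^T\alpha +
#'   X^{Environment}_{ir}{}^T\beta + X^{Event}_{ir}{}^T\gamma +
#'   \zeta_i^T b(t_{ir}),\ \sigma^2(Day_i)\}}
#' where \eqn{Y_{ir}} is the log10 concentration of record \eqn{r} on day
#' \eqn{i}, the categorical effects use reference coding (reference
#' coefficients fixed at exactly 0), \eqn{b(t)} is a cubic B-spline basis on
#' within-shift minutes with day-specific coefficients \eqn{\zeta_i}, the
#' residual variance is day-specific, and the day intercepts absorb a job
#' random effect, \eqn{\mu_i \sim N(m_{job(i)}, \tau^2_{job(i)})}.
#'
#' Priors: effects \eqn{\alpha, \beta, \gamma \sim N(0, s^2)} with
#' `prior_sd_effects` \eqn{s \in \{3, 5, 10\}} (default 5; the other two
#' values are the standard sensitivity settings); job means
#' \eqn{m_j \sim N(0, s_m^2)}; variances \eqn{\sigma^2_i, \tau^2_j} and the
#' spline-coefficient variance \eqn{\sigma^2_\zeta} get weakly-informative
#' Inverse-Gamma priors in the BUGS tradition.
#'
#' @param n_knots interior knots of the cubic trend basis (default 8).
#' @param degree spline degree (default 3).
#' @param prior_sd_effects prior SD `s` of the categorical effects.
#' @param prior_sd_job_mean prior SD of the job-level mean intercepts.
#' @param var_prior `c(shape, rate)` of the Inverse-Gamma prior for
#'   \eqn{\sigma^2_i} and \eqn{\tau^2_j}.
#' @param zeta_var_prior `c(shape, rate)` of the Inverse-Gamma prior for
#'   \eqn{\sigma^2_\zeta}.
#' @param chains,iterations,burnin,thin MCMC defaults used by
#'   [fit_spline_model()]: `iterations` are post-burn-in kept draws per
#'   chain.
#' @param seed integer seed.
#' @return an object of class `pm_model_spec`.
#' @export
pm_model_spec <- function(n_knots = 8L, degree = 3L,
                          prior_sd_effects = 5,
                          prior_sd_job_mean = 5,
                          var_prior = c(shape = 0.01, rate = 0.01),
                          zeta_var_prior = c(shape = 0.01, rate = 0.01),
                          chains = 3L, iterations = 10000L, burnin = 5000L,
                          thin = 1L, seed = 1L) {
  assert_positive(prior_sd_effects, "prior_sd_effects")
  assert_positive(prior_sd_job_mean, "prior_sd_job_mean")
  assert_positive(var_prior, "var_prior")
  assert_positive(zeta_var_prior, "zeta_var_prior")
  stopifnot_scalar_count(n_knots, "n_knots")
  stopifnot_scalar_count(chains, "chains")
  stopifnot_scalar_count(iterations, "iterations")
  stopifnot_scalar_count(thin, "thin")
  if (burnin < 0) abort("`burnin` must be >= 0.", class = "subwaypm_config_error")
  structure(list(n_knots = as.integer(n_knots), degree = as.integer(degree),
                 prior_sd_effects = prior_sd_effects,
                 prior_sd_job_mean = prior_sd_job_mean,
                 var_prior = c(shape = var_prior[[1]], rate = var_prior[[2]]),
                 zeta_var_prior = c(shape = zeta_var_prior[[1]],
                                    rate = zeta_var_prior[[2]]),
                 chains = as.integer(chains), iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "pm_model_spec")
}

#' Assemble the model object from design matrices and a specification
#'
#' Pre-computes the spline basis and the per-day sufficient blocks used by
#' both the log-posterior callable and the Gibbs sampler, and fixes the
#' parameter layout.
#'
#' The returned object exposes `log_lik(pars)` and `log_posterior(pars)`
#' callables, where `pars` is a named list with elements `mu` (day
#' intercepts), `alpha`, `beta`, `gamma` (full named effect vectors, the
#' reference entries exactly 0), `zeta` (days x basis matrix), `sigma2`
#' (day variances), `m`, `tau2` (job-level), and `sigma2_zeta`.
#'
#' @param design a `pm_design` from [build_design()].
#' @param spec a `pm_model_spec`.
#' @return an object of class `pm_model`.
#' @export
build_model <- function(design, spec = pm_model_spec()) {
  stopifnot(inherits(design, "pm_design"), inherits(spec, "pm_model_spec"))
  n <- design$n_records
  d <- length(design$days)
  if (length(design$job_of_day) != d) {
    abort("design day/job dimensions are inconsistent.",
          class = "subwaypm_model_error")
  }
  domain <- c(0, max(design$t_min))
  B <- spline_basis(design$t_min, domain = domain,
                    n_knots = spec$n_knots, degree = spec$degree)
  K <- ncol(B)
  X <- cbind(design$X_station, design$X_environment, design$X_event)
  if (nrow(X) != n || length(design$y) != n) {
    abort("design matrix blocks have mismatched row counts.",
          class = "subwaypm_model_error")
  }
  blocks <- list(
    station = seq_len(ncol(design$X_station)),
    environment = ncol(design$X_station) + seq_len(ncol(design$X_environment)),
    event = ncol(design$X_station) + ncol(design$X_environment) +
      seq_len(ncol(design$X_event))
  )
  idx_day <- lapply(seq_len(d), function(i) which(design$day == i))
  structure(list(design = design, spec = spec, B = B, X = X,
                 blocks = blocks, domain = domain, n_basis = K,
                 idx_day = idx_day,
                 log_lik = NULL, log_posterior = NULL),
            class = "pm_model") -> model
  model$log_lik <- function(pars) model_log_lik(model, pars)
  model$log_posterior <- function(pars) {
    model_log_lik(model, pars) + model_log_prior(model, pars)
  }
  model
}

# per-record mean of the model for a full parameter list
model_mean <- function(model, pars) {
  des <- model$design
  day <- des$day
  # effects through the design matrices so reference coding is explicit
  theta <- c(pars$alpha[des$stations[-1L]],
             pars$beta[des$environments[-1L]],
             if (length(des$events)) pars$gamma[des$events] else numeric(0))
  trend <- rowSums(model$B * pars$zeta[day, , drop = FALSE])
  pars$mu[day] + as.numeric(model$X %*% theta) + trend
}

model_log_lik <- function(model, pars) {
  check_pars(model, pars)
  mu_r <- model_mean(model, pars)
  sd_r <- sqrt(pars$sigma2[model$design$day])
  sum(stats::dnorm(model$design$y, mu_r, sd_r, log = TRUE))
}

model_log_prior <- function(model, pars) {
  spec <- model$spec
  des <- model$design
  s <- spec$prior_sd_effects
  eff <- c(pars$alpha[des$stations[-1L]], pars$beta[des$environments[-1L]],
           if (length(des$events)) pars$gamma[des$events] else numeric(0))
  a0 <- spec$var_prior[["shape"]]; b0 <- spec$var_prior[["rate"]]
  az <- spec$zeta_var_prior[["shape"]]; bz <- spec$zeta_var_prior[["rate"]]
  dinvgamma_log <- function(x, shape, rate) {
    shape * log(rate) - lgamma(shape) - (shape + 1) * log(x) - rate / x
  }
  sum(stats::dnorm(eff, 0, s, log = TRUE)) +
    sum(stats::dnorm(pars$mu, pars$m[des$job_of_day],
                     sqrt(pars$tau2[des$job_of_day]), log = TRUE)) +
    sum(stats::dnorm(pars$m, 0, spec$prior_sd_job_mean, log = TRUE)) +
    sum(dinvgamma_log(pars$sigma2, a0, b0)) +
    sum(dinvgamma_log(pars$tau2, a0, b0)) +
    dinvgamma_log(pars$sigma2_zeta, az, bz) +
    sum(stats::dnorm(as.numeric(pars$zeta), 0, sqrt(pars$sigma2_zeta),
                     log = TRUE))
}

check_pars <- function(model, pars) {
  des <- model$design
  need <- c("mu", "alpha", "beta", "gamma", "zeta", "sigma2", "m", "tau2",
            "sigma2_zeta")
  missing <- setdiff(need, names(pars))
  if (length(missing)) {
    abort(paste0("parameter list lacks: ", paste(missing, collapse = ", ")),
          class = "subwaypm_model_error")
  }
  d <- length(des$days)
  if (length(pars$mu) != d || length(pars$sigma2) != d ||
      nrow(pars$zeta) != d || ncol(pars$zeta) != model$n_basis ||
      length(pars$alpha) < length(des$stations) ||
      length(pars$beta) < length(des$environments)) {
    abort("parameter dimensions do not match the design.",
          class = "subwaypm_model_error")
  }
  if (any(pars$sigma2 <= 0) || any(pars$tau2 <= 0) || pars$sigma2_zeta <= 0) {
    abort("variance parameters must be strictly positive.",
          class = "subwaypm_model_error")
  }
  invisible(TRUE)
}

#' @export
print.pm_model <- function(x, ...) {
  cat("<pm_model> hierarchical Bayesian spline regression\n")
  cat(sprintf("  %d records, %d days; %d effect columns (+%d-dim trend basis per day)\n",
              x$design$n_records, length(x$design$days), ncol(x$X), x$n_basis))
  cat(sprintf("  monitored parameters: %d\n", count_monitored_parameters(x)))
  invisible(x)
}

#' Count the monitored parameters of a model
#'
#' The monitored set comprises every station, environment and event
#' coefficient (the reference coefficients counted as explicit, degenerate
#' zeros), one intercept and one residual variance per day, and one mean and
#' one variance per job; the many spline coefficients \eqn{\zeta} are
#' excluded. For a design of 45 stations, 8 environments, 10 events, 24
#' days and 3 jobs this gives 117.
#'
#' @param x a `pm_design`, a `pm_model`, or the number of station
#'   categories.
#' @param ... for the default method: `n_environments`, `n_events`,
#'   `n_days`, `n_jobs`.
#' @return integer count.
#' @export
#' @examples
#' count_monitored_parameters(45, 8, 10, 24, 3)  # 117
count_monitored_parameters <- function(x, ...) UseMethod("count_monitored_parameters")

#' @export
count_monitored_parameters.pm_design <- function(x, ...) {
  count_monitored_parameters.default(length(x$stations), length(x$environments),
                                     length(x$events), length(x$days),
                                     length(x$jobs))
}

#' @export
count_monitored_parameters.pm_model <- function(x, ...) {
  count_monitored_parameters.pm_design(x$design)
}

#' @rdname count_monitored_parameters
#' @param n_environments,n_events,n_days,n_jobs design dimensions.
#' @export
count_monitored_parameters.default <- function(x, n_environments, n_events,
                                               n_days, n_jobs, ...) {
  n_stations <- stopifnot_scalar_count(x, "n_stations")
  if (n_events < 0) abort("`n_events` must be >= 0.",
                          class = "subwaypm_config_error")
  as.integer(n_stations + n_environments + n_events + 2L * n_days + 2L * n_jobs)
}
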