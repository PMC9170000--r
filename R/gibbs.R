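#' Fit the spline model by blocked Gibbs sampling
#'
#' All full conditionals of the model are conjugate, so the sampler is a
#' pure Gibbs scheme with the following blocks per sweep:
#' \enumerate{
#'   \item the joint vector of station/environment/event effects (a
#'     multivariate Normal draw with heteroscedastic weights),
#'   \item per day, the intercept \eqn{\mu_i} jointly with the spline
#'     coefficients \eqn{\zeta_i} (multivariate Normal),
#'   \item per day, the residual variance \eqn{\sigma^2_i} (Inverse-Gamma),
#'   \item per job, the mean \eqn{m_j} (Normal) and variance
#'     \eqn{\tau^2_j} (Inverse-Gamma),
#'   \item the spline-coefficient variance \eqn{\sigma^2_\zeta}
#'     (Inverse-Gamma).
#' }
#' Chains are initialised over-dispersed around data-driven starting values.
#' Runs are exactly reproducible: the same seed yields identical draws.
#'
#' @param model a `pm_model` from [build_model()].
#' @param chains number of chains (>= 2 recommended for diagnosability;
#'   default from the model spec).
#' @param iterations kept draws per chain (after burn-in, before thinning).
#' @param burnin discarded warm-up sweeps per chain.
#' @param thin keep every `thin`-th sweep.
#' @param seed integer seed.
#' @return an object of class `pm_draws`: array `draws` of dimension
#'   `iterations x chains x parameters` (dimnames carry parameter names),
#'   the monitored-parameter names (effects, day intercepts and variances,
#'   job means and variances - the spline coefficients are stored but not
#'   monitored), the layout, spec and seed.
#' @export
fit_spline_model <- function(model, chains = NULL, iterations = NULL,
                             burnin = NULL, thin = NULL, seed = NULL) {
  stopifnot(inherits(model, "pm_model"))
  spec <- model$spec
  chains <- chains %||% spec$chains
  iterations <- iterations %||% spec$iterations
  burnin <- burnin %||% spec$burnin
  thin <- thin %||% spec$thin
  seed <- seed %||% spec$seed
  if (chains < 2L) {
    warn("fewer than 2 chains: convergence diagnostics will be unavailable.")
  }

  des <- model$design
  X <- model$X; B <- model$B
  n <- des$n_records
  p <- ncol(X)
  d <- length(des$days)
  K <- model$n_basis
  J <- length(des$jobs)
  G <- length(des$events)
  s2_eff <- spec$prior_sd_effects^2
  s2_m <- spec$prior_sd_job_mean^2
  a0 <- spec$var_prior[["shape"]]; b0 <- spec$var_prior[["rate"]]
  az <- spec$zeta_var_prior[["shape"]]; bz <- spec$zeta_var_prior[["rate"]]

  idx <- model$idx_day
  n_i <- lengths(idx)
  XtX_i <- lapply(idx, function(ii) crossprod(X[ii, , drop = FALSE]))
  D_i <- lapply(idx, function(ii) cbind(1, B[ii, , drop = FALSE]))
  DtD_i <- lapply(D_i, crossprod)
  y <- des$y
  day <- des$day
  job <- des$job_of_day                    # length d, integer in 1..J
  days_in_job <- lapply(seq_len(J), function(j) which(job == j))

  # parameter layout (stored draws)
  par_names <- c(
    paste0("alpha[", des$stations, "]"),
    paste0("beta[", des$environments, "]"),
    if (G) paste0("gamma[", des$events, "]") else character(0),
    paste0("mu[", des$days, "]"),
    paste0("sigma2[", des$days, "]"),
    paste0("m[", des$jobs, "]"),
    paste0("tau2[", des$jobs, "]"),
    "sigma2_zeta",
    paste0("zeta[", rep(des$days, each = K), ".",
           rep(seq_len(K), times = d), "]"))
  S <- length(des$stations); E <- length(des$environments)
  off <- 0L
  layout <- list()
  for (nm in list(c("alpha", S), c("beta", E), c("gamma", G), c("mu", d),
                  c("sigma2", d), c("m", J), c("tau2", J),
                  c("sigma2_zeta", 1L), c("zeta", d * K))) {
    len <- as.integer(nm[2])
    layout[[nm[1]]] <- if (len > 0) off + seq_len(len) else integer(0)
    off <- off + len
  }
  monitored <- par_names[c(layout$alpha, layout$beta, layout$gamma,
                           layout$mu, layout$sigma2, layout$m, layout$tau2)]

  n_total <- burnin + iterations * thin
  draws <- array(NA_real_, dim = c(iterations, chains, length(par_names)),
                 dimnames = list(NULL, paste0("chain", seq_len(chains)),
                                 par_names))

  day_means <- vapply(idx, function(ii) mean(y[ii]), numeric(1))
  day_vars <- vapply(idx, function(ii) max(stats::var(y[ii]), 1e-3), numeric(1))

  set.seed(seed)
  for (ch in seq_len(chains)) {
    # over-dispersed, data-informed initial values
    mu <- day_means + stats::rnorm(d, 0, 0.3)
    theta <- stats::rnorm(p, 0, 0.2)
    zeta <- matrix(stats::rnorm(d * K, 0, 0.05), d, K)
    sigma2 <- day_vars * stats::runif(d, 0.5, 2)
    m <- vapply(days_in_job, function(ii) mean(mu[ii]), numeric(1)) +
      stats::rnorm(J, 0, 0.2)
    tau2 <- stats::runif(J, 0.01, 0.1)
    s2z <- stats::runif(1, 0.01, 0.1)
    keep <- 0L

    for (it in seq_len(n_total)) {
      # (1) joint effect vector (absent in a pure reference-category design)
      if (p > 0L) {
        trend <- rowSums(B * zeta[day, , drop = FALSE])
        r1 <- y - mu[day] - trend
        A <- diag(1 / s2_eff, p)
        for (i in seq_len(d)) A <- A + XtX_i[[i]] / sigma2[i]
        bvec <- crossprod(X, r1 / sigma2[day])
        R <- chol(A)
        mean_theta <- backsolve(R, backsolve(R, bvec, transpose = TRUE))
        theta <- as.numeric(mean_theta + backsolve(R, stats::rnorm(p)))
        fe <- as.numeric(X %*% theta)
      } else {
        fe <- numeric(n)
      }

      # (2)+(3) per-day intercept + spline coefficients, then variance
      for (i in seq_len(d)) {
        ii <- idx[[i]]
        r2 <- y[ii] - fe[ii]
        prior_prec <- c(1 / tau2[job[i]], rep(1 / s2z, K))
        Ai <- DtD_i[[i]] / sigma2[i] + diag(prior_prec)
        bi <- crossprod(D_i[[i]], r2) / sigma2[i]
        bi[1] <- bi[1] + m[job[i]] / tau2[job[i]]
        Ri <- chol(Ai)
        mean_i <- backsolve(Ri, backsolve(Ri, bi, transpose = TRUE))
        phi <- as.numeric(mean_i + backsolve(Ri, stats::rnorm(K + 1L)))
        mu[i] <- phi[1]
        zeta[i, ] <- phi[-1]
        resid <- r2 - as.numeric(D_i[[i]] %*% phi)
        sigma2[i] <- rinvgamma1(a0 + n_i[i] / 2, b0 + sum(resid^2) / 2)
      }

      # (4) job-level mean and variance
      for (j in seq_len(J)) {
        ii <- days_in_job[[j]]
        dj <- length(ii)
        prec <- dj / tau2[j] + 1 / s2_m
        mean_m <- (sum(mu[ii]) / tau2[j]) / prec
        m[j] <- stats::rnorm(1, mean_m, sqrt(1 / prec))
        tau2[j] <- rinvgamma1(a0 + dj / 2, b0 + sum((mu[ii] - m[j])^2) / 2)
      }

      # (5) spline-coefficient variance
      s2z <- rinvgamma1(az + d * K / 2, bz + sum(zeta^2) / 2)

      if (it > burnin && (it - burnin) %% thin == 0L) {
        keep <- keep + 1L
        draws[keep, ch, ] <- c(0, theta[model$blocks$station],
                               0, theta[model$blocks$environment],
                               theta[model$blocks$event],
                               mu, sigma2, m, tau2, s2z, as.numeric(t(zeta)))
      }
    }
  }

  structure(list(draws = draws, par_names = par_names, monitored = monitored,
                 layout = layout, spec = spec, seed = seed,
                 stations = des$stations, environments = des$environments,
                 events = des$events, days = des$days, jobs = des$jobs,
                 n_basis = K),
            class = "pm_draws")
}

#' @export
print.pm_draws <- function(x, ...) {
  dm <- dim(x$draws)
  cat(sprintf("<pm_draws> %d kept draws x %d chains x %d parameters (%d monitored)\n",
              dm[1], dm[2], dm[3], length(x$monitored)))
  invisible(x)
}

# iterations x chains matrix for one parameter
draws_matrix <- function(draws, parameter) {
  j <- match(parameter, draws$par_names)
  if (is.na(j)) {
    abort(sprintf("unknown parameter '%s'.", parameter),
          class = "subwaypm_model_error")
  }
  draws$draws[, , j, drop = TRUE]
}

# pooled vector across chains
pooled_draws <- function(draws, parameter) as.numeric(draws_matrix(draws, parameter))

#' Tidy posterior summaries
#'
#' One row per stored parameter with posterior mean, median, SD and 95%
#' credible bounds, pooled across chains.
#'
#' @param x a `pm_draws`.
#' @param monitored_only restrict to the monitored set (default `TRUE`).
#' @param ... unused.
#' @return a tibble.
#' @exportS3Method generics::tidy
tidy.pm_draws <- function(x, monitored_only = TRUE, ...) {
  pars <- if (monitored_only) x$monitored else x$par_names
  jj <- match(pars, x$par_names)
  flat <- matrix(x$draws[, , jj, drop = FALSE],
                 nrow = dim(x$draws)[1] * dim(x$draws)[2])
  q <- t(apply(flat, 2, stats::quantile, probs = c(0.025, 0.5, 0.975),
               names = FALSE))
  tibble(parameter = pars,
         mean = colMeans(flat),
         sd = apply(flat, 2, stats::sd),
         q2.5 = q[, 1], median = q[, 2], q97.5 = q[, 3])
}

#' @exportS3Method generics::glance
glance.pm_draws <- function(x, ...) {
  dm <- dim(x$draws)
  diag <- tryCatch(gelman_rubin(x), error = function(e) NULL)
  tibble(chains = dm[2], iterations = dm[1],
         parameters = dm[3], monitored = length(x$monitored),
         max_rhat = if (is.null(diag)) NA_real_ else
           suppressWarnings(max(diag$rhat, na.rm = TRUE)))
}

#' Posterior predictive summaries per record
#'
#' For each record of the design, draws from the posterior predictive
#' distribution (model mean plus day-specific residual noise, using a
#' thinned subset of the posterior draws) and summarises it on the log10 and
#' natural concentration scales.
#'
#' @param object a `pm_model`.
#' @param draws a `pm_draws` fitted from it.
#' @param design optionally a different `pm_design`; its categories must all
#'   have been seen by the fitted model, otherwise an error lists the
#'   offending categories.
#' @param max_draws posterior draws used (thinned evenly; default 400).
#' @param level credible level of the predictive interval.
#' @param ... unused.
#' @return tibble with one row per record: `day_id`, `t_min`, `observed`
#'   (log10), `pred_mean_log10`, `pred_lwr_log10`, `pred_upr_log10`, and the
#'   natural-scale `pred_mean`, `pred_lwr`, `pred_upr`.
#' @export
predict.pm_model <- function(object, draws, design = NULL, max_draws = 400L,
                             level = 0.95, ...) {
  stopifnot(inherits(draws, "pm_draws"))
  model <- object
  des <- design %||% model$design
  new_st <- setdiff(unique(des$station_of_record), draws$stations)
  new_en <- setdiff(unique(des$environment_of_record), draws$environments)
  new_ev <- setdiff(des$events, draws$events)
  if (length(c(new_st, new_en, new_ev))) {
    abort(paste0("categories unseen by the fitted model: ",
                 paste(c(new_st, new_en, new_ev), collapse = ", ")),
          class = "subwaypm_prediction_error")
  }
  new_day <- setdiff(des$days, draws$days)
  if (length(new_day)) {
    abort(paste0("days unseen by the fitted model: ",
                 paste(new_day, collapse = ", ")),
          class = "subwaypm_prediction_error")
  }

  dm <- dim(draws$draws)
  flat <- matrix(draws$draws, nrow = dm[1] * dm[2])  # (iter*chain) x par
  take <- unique(round(seq(1, nrow(flat), length.out = min(max_draws, nrow(flat)))))
  flat <- flat[take, , drop = FALSE]
  nd <- nrow(flat)
  n <- des$n_records
  lay <- draws$layout
  K <- draws$n_basis

  st_idx <- lay$alpha[match(des$station_of_record, draws$stations)]
  en_idx <- lay$beta[match(des$environment_of_record, draws$environments)]
  day_of_rec <- match(des$day_id_of_record, draws$days)
  mu_idx <- lay$mu[day_of_rec]
  s2_idx <- lay$sigma2[day_of_rec]

  B <- spline_basis(des$t_min, domain = model$domain,
                    n_knots = model$spec$n_knots, degree = model$spec$degree)
  gamma_part <- if (length(des$events) && length(draws$events)) {
    Xev <- matrix(0, n, length(draws$events),
                  dimnames = list(NULL, draws$events))
    common <- intersect(des$events, draws$events)
    Xev[, common] <- des$X_event[, common, drop = FALSE]
    Xev %*% t(flat[, lay$gamma, drop = FALSE])     # n x nd
  } else {
    matrix(0, n, nd)
  }
  M <- t(flat[, mu_idx, drop = FALSE]) + t(flat[, st_idx, drop = FALSE]) +
    t(flat[, en_idx, drop = FALSE]) + gamma_part
  for (s in seq_len(nd)) {
    Z <- matrix(flat[s, lay$zeta], nrow = length(draws$days), ncol = K,
                byrow = TRUE)
    M[, s] <- M[, s] + rowSums(B * Z[day_of_rec, , drop = FALSE])
  }
  sd_mat <- sqrt(t(flat[, s2_idx, drop = FALSE]))   # n x nd
  yrep <- M + matrix(stats::rnorm(n * nd), n, nd) * sd_mat
  alpha2 <- (1 - level) / 2
  qs <- t(apply(yrep, 1, stats::quantile, probs = c(alpha2, 1 - alpha2),
                names = FALSE))
  tibble(day_id = des$day_id_of_record,
         t_min = des$t_min,
         observed = des$y,
         pred_mean_log10 = rowMeans(M),
         pred_lwr_log10 = qs[, 1],
         pred_upr_log10 = qs[, 2],
         pred_mean = rowMeans(10^yrep),
         pred_lwr = 10^qs[, 1],
         pred_upr = 10^qs[, 2])
}
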