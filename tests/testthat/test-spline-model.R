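test_that("the B-spline basis is a non-negative partition of unity", {
  B <- spline_basis(seq(0, 360, by = 7.3), domain = c(0, 360))
  expect_true(all(B >= 0))
  expect_equal(rowSums(B), rep(1, nrow(B)), tolerance = 1e-12)
  expect_identical(ncol(B), 8L + 3L + 1L)
  # continuity at a knot
  knot <- 360 / 9
  left <- spline_basis(knot - 1e-9, domain = c(0, 360))
  right <- spline_basis(knot + 1e-9, domain = c(0, 360))
  expect_equal(as.numeric(left), as.numeric(right), tolerance = 1e-6)
  expect_error(spline_basis(400, domain = c(0, 360)),
               class = "subwaypm_extrapolation_error")
})

test_that("the basis matches an independent Cox-de Boor recursion", {
  withr::local_seed(17)
  for (case in list(list(n_knots = 8L, degree = 3L, domain = c(0, 360)),
                    list(n_knots = 4L, degree = 2L, domain = c(0, 100)))) {
    x <- runif(100, case$domain[1], case$domain[2])
    B <- spline_basis(x, domain = case$domain, n_knots = case$n_knots,
                      degree = case$degree)
    O <- coxdeboor_matrix(x, case$domain, case$n_knots, case$degree)
    expect_lt(max(abs(B - O)), 1e-10)
  }
})

test_that("monitored-parameter counting matches the reference design and is linear in days", {
  expect_identical(count_monitored_parameters(45, 8, 10, 24, 3), 117L)
  expect_identical(count_monitored_parameters(1, 1, 0, 1, 1), 6L)
  base <- count_monitored_parameters(45, 8, 10, 24, 3)
  expect_identical(count_monitored_parameters(45, 8, 10, 24 + 5, 3),
                   base + 2L * 5L)
  des <- small_design()
  expect_identical(count_monitored_parameters(des),
                   count_monitored_parameters(
                     length(des$stations), length(des$environments),
                     length(des$events), length(des$days), length(des$jobs)))
})

zero_pars <- function(model, mu = 0.5, sigma2 = 0.04) {
  des <- model$design
  d <- length(des$days)
  list(mu = rep(mu, d),
       alpha = stats::setNames(rep(0, length(des$stations)), des$stations),
       beta = stats::setNames(rep(0, length(des$environments)), des$environments),
       gamma = stats::setNames(rep(0, length(des$events)), des$events),
       zeta = matrix(0, d, model$n_basis),
       sigma2 = rep(sigma2, d),
       m = rep(mu, length(des$jobs)),
       tau2 = rep(0.01, length(des$jobs)),
       sigma2_zeta = 0.02)
}

test_that("the log-likelihood equals a brute-force Normal density sum", {
  des <- small_design()
  model <- build_model(des, pm_model_spec())
  pars <- zero_pars(model)
  # brute force: per-record dnorm, written out longhand
  brute <- 0
  for (r in seq_len(des$n_records)) {
    brute <- brute + stats::dnorm(des$y[r], 0.5, sqrt(0.04), log = TRUE)
  }
  expect_lt(abs(model$log_lik(pars) - brute), 1e-10)
  # with non-zero effects the mean follows the design matrices
  pars2 <- pars
  pars2$alpha[des$stations[2]] <- 0.3
  mean_r <- 0.5 + 0.3 * des$X_station[, des$stations[2]]
  brute2 <- sum(stats::dnorm(des$y, mean_r, sqrt(0.04), log = TRUE))
  expect_lt(abs(model$log_lik(pars2) - brute2), 1e-10)
  expect_true(is.finite(model$log_posterior(pars)))
})

test_that("the log-posterior is invariant to record permutation", {
  st <- small_study()
  ann <- suppressMessages(
    annotate(dplyr::filter(st$mass, fraction == "PM10"), st$logbook,
             event_levels = st$cfg$event_levels))
  des1 <- build_design(ann, st$cfg$reference_station,
                       st$cfg$reference_environment)
  des2 <- build_design(ann[sample.int(nrow(ann)), ],
                       st$cfg$reference_station, st$cfg$reference_environment)
  m1 <- build_model(des1, pm_model_spec())
  m2 <- build_model(des2, pm_model_spec())
  pars <- zero_pars(m1)
  expect_equal(m1$log_posterior(pars), m2$log_posterior(pars),
               tolerance = 1e-12)
})

test_that("model construction validates dimensions and parameter lists", {
  des <- small_design()
  model <- build_model(des, pm_model_spec())
  pars <- zero_pars(model)
  bad <- pars; bad$sigma2 <- bad$sigma2[-1]
  expect_error(model$log_lik(bad), class = "subwaypm_model_error")
  bad2 <- pars; bad2$sigma2[1] <- -1
  expect_error(model$log_lik(bad2), class = "subwaypm_model_error")
  bad3 <- pars; bad3$mu <- NULL
  expect_error(model$log_lik(bad3), class = "subwaypm_model_error")
})

test_that("two fits with the same seed give identical draws", {
  des <- small_design()
  model <- build_model(des, pm_model_spec(iterations = 50, burnin = 20,
                                          chains = 2))
  d1 <- fit_spline_model(model, seed = 99)
  d2 <- fit_spline_model(model, seed = 99)
  expect_identical(d1$draws, d2$draws)
  d3 <- fit_spline_model(model, seed = 100)
  expect_false(identical(d1$draws, d3$draws))
})

test_that("a conjugate reduction recovers the closed-form posterior mean", {
  # single day, single category, variance pinned by a concentrated prior,
  # trend suppressed: the posterior for mu approaches the Normal-Normal
  # update, which for a diffuse prior is ybar +/- sigma/sqrt(n)
  withr::local_seed(55)
  n <- 200; sigma <- 0.2; mu_true <- 0.6
  t0 <- as.POSIXct("2019-10-07 08:00:00", tz = "UTC")
  rec <- tibble::tibble(
    day_id = "day01", job = "station_agent",
    timestamp = t0 + (seq_len(n) - 1) * 60,
    t_min = (seq_len(n) - 1), log10_value = rnorm(n, mu_true, sigma),
    station = "S01", environment = "sampling_room")
  des <- build_design(rec, "S01", "sampling_room")
  a_conc <- 5000
  spec <- pm_model_spec(iterations = 1500, burnin = 300, chains = 2,
                        var_prior = c(shape = a_conc,
                                      rate = (a_conc - 1) * sigma^2),
                        zeta_var_prior = c(shape = 5000, rate = 5000 * 1e-8))
  model <- build_model(des, spec)
  draws <- fit_spline_model(model, seed = 3)
  mu_hat <- mean(draws$draws[, , grep("^mu\\[", draws$par_names)])
  ybar <- mean(rec$log10_value)
  expect_lt(abs(mu_hat - ybar), 3 * sigma / sqrt(n))
})

test_that("predictions recover a nearly noise-free truth and respect day variances", {
  cfg <- small_cfg(sigma2_day_range = c(1e-6, 2e-6), trend_amplitude = 0.05)
  st <- simulate_study(cfg)
  ann <- suppressMessages(
    annotate(dplyr::filter(st$mass, fraction == "PM10"), st$logbook,
             event_levels = cfg$event_levels))
  des <- build_design(ann, cfg$reference_station, cfg$reference_environment)
  model <- build_model(des, pm_model_spec(iterations = 800, burnin = 300,
                                          chains = 2))
  draws <- fit_spline_model(model, seed = 4)
  pp <- predict(model, draws, max_draws = 200)
  close <- mean(abs(pp$pred_mean_log10 - des$y) <= 0.05)
  expect_gte(close, 0.95)
})

test_that("predictive interval width tracks the day's residual variance", {
  # two days with very different noise, all else equal
  cfg <- sim_config(n_stations = 1, n_environments = 1, n_events = 0,
                    n_jobs = 1, days_per_job = 2,
                    true_alpha = c(S01 = 0), true_beta = c(sampling_room = 0),
                    true_gamma = numeric(0),
                    trend_amplitude = 1e-6, seed = 8L)
  gt <- simulate_ground_truth(cfg)
  gt$sigma2_day <- c(day01 = 0.005, day02 = 0.15)
  lbs <- dplyr::bind_rows(simulate_logbook(cfg, 1), simulate_logbook(cfg, 2))
  mass <- dplyr::bind_rows(
    simulate_mass_series(cfg, dplyr::filter(lbs, day_id == "day01"), gt, "PM10"),
    simulate_mass_series(cfg, dplyr::filter(lbs, day_id == "day02"), gt, "PM10"))
  ann <- suppressMessages(annotate(mass, lbs))
  des <- build_design(ann, "S01", "sampling_room")
  model <- build_model(des, pm_model_spec(iterations = 600, burnin = 200,
                                          chains = 2))
  draws <- fit_spline_model(model, seed = 5)
  pp <- predict(model, draws, max_draws = 200)
  width <- tapply(pp$pred_upr_log10 - pp$pred_lwr_log10, pp$day_id, mean)
  expect_lt(width[["day01"]], width[["day02"]])
})

test_that("prediction refuses categories the model has not seen", {
  des <- small_design()
  model <- build_model(des, pm_model_spec(iterations = 30, burnin = 10,
                                          chains = 2))
  draws <- fit_spline_model(model, seed = 1)
  des2 <- des
  des2$station_of_record <- replace(des2$station_of_record, 1, "S99")
  expect_error(predict(model, draws, design = des2),
               class = "subwaypm_prediction_error")
})
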