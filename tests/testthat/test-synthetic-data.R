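test_that("configuration validation rejects inconsistent designs", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(mass_dt = 299), class = "subwaypm_config_error")
  expect_error(sim_config(shift_minutes = 200), class = "subwaypm_config_error")
  expect_error(sim_config(sigma2_day_range = c(0.1, 0.01)),
               class = "subwaypm_config_error")
  expect_error(sim_config(true_alpha = c(0.5, rep(0, 44))),
               class = "subwaypm_config_error")  # reference must be 0
  expect_error(simulate_logbook(sim_config(), 99),
               class = "subwaypm_config_error")
})

test_that("logbooks cover the shift contiguously and start/end in the reference environment", {
  cfg <- sim_config(seed = 7L)
  for (day in c(1L, 9L, 17L)) {  # one day per occupation template
    lb <- simulate_logbook(cfg, day)
    ints <- dplyr::arrange(dplyr::filter(lb, type == "interval"), start)
    # contiguous, non-overlapping, exact coverage of the shift
    expect_true(all(abs(as.numeric(ints$start[-1]) -
                          as.numeric(ints$end[-nrow(ints)])) < 1e-6))
    expect_equal(sum(as.numeric(ints$end - ints$start, units = "mins")),
                 cfg$shift_minutes, tolerance = 1e-9)
    expect_identical(ints$environment[1], cfg$reference_environment)
    expect_identical(ints$environment[nrow(ints)], cfg$reference_environment)
    expect_identical(ints$station[1], cfg$reference_station)
  }
})

test_that("travel between stations is labelled Tunnel and the walk stays on the line", {
  cfg <- sim_config(seed = 3L)
  lb <- simulate_logbook(cfg, 9)  # locomotive operator traverses the line
  ints <- dplyr::arrange(dplyr::filter(lb, type == "interval"), start)
  sts <- ints$station
  expect_true("Tunnel" %in% sts)
  # between any two distinct real stations there is always a Tunnel row
  real <- which(sts != "Tunnel")
  idx <- match(sts[real], cfg$station_levels)
  changes <- which(diff(idx) != 0)
  expect_true(all(real[changes + 1] - real[changes] > 1))
  # the walk is along the line: consecutive real stations are adjacent
  expect_true(all(abs(diff(idx)) <= 1))
})

test_that("a single-environment design annotates every record with that environment", {
  cfg <- sim_config(n_environments = 1, n_stations = 6, n_events = 2, seed = 5L)
  lb <- simulate_logbook(cfg, 1)
  ints <- dplyr::filter(lb, type == "interval")
  expect_true(all(ints$environment == cfg$reference_environment))
})

test_that("identical configuration and seed give byte-identical studies", {
  s1 <- simulate_study(small_cfg())
  s2 <- simulate_study(small_cfg())
  expect_identical(s1$mass, s2$mass)
  expect_identical(s1$logbook, s2$logbook)
  expect_identical(s1$ground_truth, s2$ground_truth)
  expect_identical(s1$gravimetric, s2$gravimetric)
})

test_that("every design category appears in the generated records", {
  st <- small_study()
  ann <- suppressMessages(
    annotate(dplyr::filter(st$mass, fraction == "PM10"), st$logbook,
             event_levels = st$cfg$event_levels))
  expect_setequal(unique(ann$station), st$cfg$station_levels)
  expect_setequal(unique(ann$environment), st$cfg$environment_levels)
  ev_cols <- paste0("event_", st$cfg$event_levels)
  expect_true(all(colSums(ann[ev_cols]) > 0))
})

test_that("the noise-free limit gives a constant series at 10^(mu + offset)", {
  cfg <- sim_config(n_stations = 1, n_environments = 1, n_events = 0,
                    true_alpha = c(S01 = 0), true_beta = c(sampling_room = 0),
                    true_gamma = numeric(0),
                    mu_job = c(0.5, 0.5, 0.5), tau2_job = rep(1e-18, 3),
                    sigma2_day_range = c(1e-18, 2e-18),
                    trend_amplitude = 1e-12, seed = 2L)
  gt <- simulate_ground_truth(cfg)
  lb <- simulate_logbook(cfg, 1)
  s <- simulate_mass_series(cfg, lb, gt, "PM10")
  expect_equal(s$value, rep(10^gt$mu_day[["day01"]], nrow(s)), tolerance = 1e-6)
  s03 <- simulate_mass_series(cfg, lb, gt, "PM0.3")
  expect_equal(log10(s03$value[1]) - log10(s$value[1]), -1.10, tolerance = 1e-6)
})

test_that("PM0.3 sits more than an order of magnitude below PM10", {
  st <- small_study()
  med <- tapply(st$mass$value, st$mass$fraction, stats::median)
  expect_lt(med[["PM0.3"]] * 10, med[["PM10"]])
})

test_that("per-day log10 residual variance matches the generating value at large n", {
  cfg <- sim_config(n_stations = 1, n_environments = 1, n_events = 0,
                    true_alpha = c(S01 = 0), true_beta = c(sampling_room = 0),
                    true_gamma = numeric(0),
                    mass_dt = 4,  # 5400 records per shift
                    trend_amplitude = 1e-12, seed = 11L)
  gt <- simulate_ground_truth(cfg)
  lb <- simulate_logbook(cfg, 1)
  s <- simulate_mass_series(cfg, lb, gt, "PM10")
  expect_gte(nrow(s), 5000)
  v <- stats::var(log10(s$value))
  expect_lt(abs(v - gt$sigma2_day[["day01"]]) / gt$sigma2_day[["day01"]], 0.10)
})

test_that("gravimetric simulation reduces to the shift mean under the identity calibration", {
  st <- small_study()
  s <- dplyr::filter(st$mass, fraction == "PM10")
  g_id <- simulate_gravimetric(s, true_calibration = c(1, 1), noise_sd = 0)
  expect_equal(g_id$gravimetric, g_id$raw_mean, tolerance = 1e-12)
  g_hi <- simulate_gravimetric(s, true_calibration = c(2, 1), noise_sd = 0)
  expect_true(all(g_hi$gravimetric > g_hi$raw_mean))
  expect_error(simulate_gravimetric(dplyr::mutate(s, fraction = "PM1")),
               class = "subwaypm_config_error")
})

test_that("fitting a calibration to noise-free gravimetric output recovers the generating law", {
  st <- small_study()
  s <- dplyr::filter(st$mass, fraction == "PM10")
  g <- simulate_gravimetric(s, true_calibration = c(a = 1.7, b = 0.85),
                            noise_sd = 0)
  fit <- fit_calibration(dplyr::rename(g, raw_mean = raw_mean),
                         family = "power", fraction = "PM10")
  expect_equal(unname(fit$parameters[["a"]]), 1.7, tolerance = 1e-6)
  expect_equal(unname(fit$parameters[["b"]]), 0.85, tolerance = 1e-6)
})

test_that("ground truth serialises losslessly", {
  gt <- simulate_ground_truth(small_cfg())
  path <- withr::local_tempfile(fileext = ".json")
  write_ground_truth(gt, path)
  expect_identical(read_ground_truth(path), gt)
})

test_that("number series honour the counter/optical factor and share the latent trend", {
  cfg <- small_cfg()
  gt <- simulate_ground_truth(cfg)
  lb <- simulate_logbook(cfg, 3)
  ns <- simulate_number_series(cfg, lb, gt)
  band <- integrate_band(ns$opc, 0.25, 0.7)
  paired <- align_series(band, ns$counter)
  cmp <- compare_devices(paired)
  expect_gt(cmp$ratio_of_totals, 500)
  expect_lt(cmp$ratio_of_totals, 2000)
  expect_gt(cmp$log10_pearson_r, 0)
  # factor 1, same grid, no noise: equal after band integration
  cfg1 <- small_cfg(number_factor = 1)
  cfg1$number_dt <- cfg1$mass_dt
  gt1 <- simulate_ground_truth(cfg1)
  ns1 <- simulate_number_series(cfg1, simulate_logbook(cfg1, 3), gt1,
                                noise_sd = 0)
  band1 <- integrate_band(ns1$opc, 0.25, 0.7)
  expect_equal(band1$value, ns1$counter$value, tolerance = 1e-12)
  # invalid channel grid
  expect_error(simulate_number_series(cfg, lb, gt, channel_edges = c(0.25, 0.2, 20)),
               class = "subwaypm_config_error")
})
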