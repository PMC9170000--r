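# shared fixtures, built in code; kept small so the suite stays fast

small_cfg <- function(seed = 42L, ...) {
  sim_config(n_stations = 6, n_environments = 4, n_events = 2,
             days_per_job = 2, seed = seed, ...)
}

# one small complete study, computed once per test run
small_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_study(small_cfg())
    cache
  }
})

small_design <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      st <- small_study()
      ann <- suppressMessages(
        annotate(dplyr::filter(st$mass, fraction == "PM10"), st$logbook,
                 event_levels = st$cfg$event_levels))
      cache <<- build_design(ann, st$cfg$reference_station,
                             st$cfg$reference_environment)
    }
    cache
  }
})

# hand-built posterior container for summary-level tests: `blocks` is a
# named list (stations/environments/events -> category names) and `values`
# a function(category) returning that category's draws
fake_draws <- function(stations = c("S01", "S02"),
                       environments = c("sampling_room", "platform"),
                       events = character(0),
                       n_iter = 50L, n_chain = 2L,
                       value_fun = function(cat, block) 0) {
  days <- "day01"; jobs <- "job_01"; K <- 2L
  par_names <- c(paste0("alpha[", stations, "]"),
                 paste0("beta[", environments, "]"),
                 if (length(events)) paste0("gamma[", events, "]"),
                 paste0("mu[", days, "]"), paste0("sigma2[", days, "]"),
                 paste0("m[", jobs, "]"), paste0("tau2[", jobs, "]"),
                 "sigma2_zeta",
                 paste0("zeta[", rep(days, each = K), ".", 1:K, "]"))
  lens <- c(alpha = length(stations), beta = length(environments),
            gamma = length(events), mu = 1, sigma2 = 1, m = 1, tau2 = 1,
            sigma2_zeta = 1, zeta = K)
  layout <- list(); off <- 0L
  for (nm in names(lens)) {
    layout[[nm]] <- if (lens[[nm]] > 0) off + seq_len(lens[[nm]]) else integer(0)
    off <- off + lens[[nm]]
  }
  draws <- array(0, dim = c(n_iter, n_chain, length(par_names)),
                 dimnames = list(NULL, paste0("chain", 1:n_chain), par_names))
  fill <- function(block, cats) {
    for (i in seq_along(cats)) {
      draws[, , layout[[block]][i]] <<- value_fun(cats[i], block)
    }
  }
  fill("alpha", stations); fill("beta", environments)
  if (length(events)) fill("gamma", events)
  draws[, , layout$sigma2] <- 0.04
  draws[, , layout$tau2] <- 0.01
  draws[, , layout$sigma2_zeta] <- 0.01
  monitored <- par_names[c(layout$alpha, layout$beta, layout$gamma,
                           layout$mu, layout$sigma2, layout$m, layout$tau2)]
  structure(list(draws = draws, par_names = par_names, monitored = monitored,
                 layout = layout, spec = pm_model_spec(), seed = 1L,
                 stations = stations, environments = environments,
                 events = events, days = days, jobs = jobs, n_basis = K),
            class = "pm_draws")
}
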