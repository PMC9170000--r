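Package: subwaypm
Title: Bayesian Spline Analysis of Personal Particulate-Matter Exposure
    Time-Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing real-time personal particulate-matter (PM)
    exposure time-series collected in underground transport workplaces.
    Covers the full pipeline: simulation of activity-logbook-annotated
    instrument series with known ground truth, joining of instrument records
    to logbook annotations, gravimetric calibration of optical particle
    counter mass concentrations, a hierarchical Bayesian spline regression of
    log10 concentrations on station, environment and event categories fitted
    by a blocked Gibbs sampler, MCMC validation following the WAMBS checklist
    (Gelman-Rubin diagnostics, autocorrelation, prior sensitivity, posterior
    predictive checks), posterior fold-change summaries with credible
    intervals, geometric mean and geometric standard deviation exposure
    tables, and comparison of channelised optical particle counter number
    concentrations with a wide-range diffusion-charger counter.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    splines,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
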