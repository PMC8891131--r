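# Synthetic surveillance-series generator: forward model runs emitted in
# the national yearly-table schema, for end-to-end pipeline tests.

#' Configuration for the synthetic surveillance generator
#'
#' @param true_params generating [ioud_params()] (its delta schedule is
#'   the generating death-rate trend)
#' @param init initial state at the first year
#' @param years calendar years to emit (at least 3)
#' @param us_population_base national population in the first year
#' @param us_population_growth linear yearly growth (persons/year)
#' @param city_size reference city population the model lives at
#' @param noise_cv coefficient of variation of multiplicative lognormal
#'   observation noise per cell (0 = noiseless)
#' @param hud_fraction,averaging_factor,specialty_fraction the reporting
#'   constants embedded in the emitted table (defaults 0.8, 0.903, 0.6874)
#' @param seed RNG seed for the noise
#' @return an `ioud_synth_config`
#' @export
synthetic_config <- function(true_params = ioud_params(delta = delta_fit_paper()),
                             init = baseline_init(), years = 2002:2019,
                             us_population_base = 287.3e6,
                             us_population_growth = 2.3e6,
                             city_size = 200000, noise_cv = 0,
                             hud_fraction = 0.8, averaging_factor = 0.903,
                             specialty_fraction = 0.6874, seed = 1) {
  stopifnot(inherits(true_params, "ioud_params"), length(years) >= 3,
            noise_cv >= 0, us_population_base > 0, city_size > 0)
  structure(list(true_params = true_params, init = init, years = sort(years),
                 us_population_base = us_population_base,
                 us_population_growth = us_population_growth,
                 city_size = city_size, noise_cv = noise_cv,
                 hud_fraction = hud_fraction,
                 averaging_factor = averaging_factor,
                 specialty_fraction = specialty_fraction, seed = seed),
            class = "ioud_synth_config")
}

#' Generate a synthetic yearly surveillance series
#'
#' Simulates the model over the configured years, converts the disorder
#' and treatment classes to past-year counts via the leave/return
#' corrections, up-scales the city-level quantities to a linearly growing
#' national population (the inverse of [scale_to_city()]), applies
#' independent multiplicative lognormal noise per cell, and emits records
#' in the national yearly-table schema. With zero noise,
#' [delta_from_data()] applied to the output recovers the generating
#' death-rate schedule up to the past-year averaging approximation.
#'
#' @param config an [synthetic_config()]
#' @return data.frame in the [load_surveillance()] schema, with the
#'   generating truth attached as `attr(, "truth")`
#' @export
generate_series <- function(config) {
  stopifnot(inherits(config, "ioud_synth_config"))
  y0 <- config$years[1]
  y1 <- config$years[length(config$years)] + 1
  tr <- simulate_ioud(config$true_params, init = config$init,
                      t0 = y0, t1 = y1, dt_out = 0.5)
  pyI <- past_year_prevalence(tr, "I")
  pyT <- past_year_prevalence(tr, "T")
  tal <- yearly_flow_tallies(tr)
  idx <- match(config$years, tal$year)
  pop <- config$us_population_base +
    config$us_population_growth * (config$years - y0)
  up <- pop / config$city_size
  deaths_heroin <- tal$overdose_deaths[idx] / config$hud_fraction * up
  hud <- pyI$past_year[idx] * up
  treat_hud <- pyT$past_year[idx] * up
  # synthetic-opioid deaths are schema plumbing, not consumed downstream:
  # emit a smooth growing series at the scale of the heroin column
  deaths_synth <- 0.5 * deaths_heroin * (1 + (config$years - y0) / 10)

  noisy <- function(x) {
    if (config$noise_cv == 0) return(x)
    sdl <- sqrt(log(1 + config$noise_cv^2))
    x * stats::rlnorm(length(x), meanlog = -sdl^2 / 2, sdlog = sdl)
  }
  set.seed(config$seed)
  out <- data.frame(year = config$years,
                    deaths_synthetic = noisy(deaths_synth),
                    deaths_heroin = noisy(deaths_heroin),
                    us_population = pop,
                    hud_past_year = noisy(hud),
                    treatment_past_year = noisy(treat_hud) / config$specialty_fraction,
                    treatment_from_hud = NA_real_,
                    treatment_is_scaled = FALSE)
  truth <- list(beta = config$true_params$beta, rho = config$true_params$rho,
                epsilon = config$true_params$epsilon,
                omega = config$true_params$omega,
                params = config$true_params, config = config)
  # the from-HUD split is left for the loader to reconstruct via the
  # specialty fraction, mirroring the national table's starred years
  attr(out, "truth") <- truth
  out
}

#' Write a synthetic series plus its generating truth
#'
#' @param series output of [generate_series()]
#' @param csv_path CSV destination (surveillance schema)
#' @param truth_path optional JSON sidecar with the generating parameter
#'   values
#' @return invisibly, `series`
#' @export
write_synthetic <- function(series, csv_path, truth_path = NULL) {
  utils::write.csv(series, csv_path, row.names = FALSE, na = "")
  if (!is.null(truth_path)) {
    tr <- attr(series, "truth")
    jsonlite::write_json(tr[c("beta", "rho", "epsilon", "omega")],
                         truth_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(series)
}
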