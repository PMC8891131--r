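# Conversion of instantaneous model output to survey-comparable
# "in class in the past year" counts, and parameter estimation.

#' Past-year prevalence with leave/return corrections
#'
#' Annual surveys count anyone who was in a class at any time during the
#' past year, which exceeds the instantaneous compartment size. The model
#' analogue is assembled per calendar year from three components, each a
#' yearly average of an instantaneous quantity: the compartment itself
#' (`average_instantaneous`), the year-to-date count of individuals who
#' left the class during the year (`left_class`), and a small discount for
#' leavers who already returned (`return_correction`). For the disorder
#' class I the return flow is `kappa*T_I + alpha1*R_I`; for the treatment
#' class T it is `I_T * (eta1 + eta3*S/N) / (1 + epsilon*T)`, where `T_I`,
#' `R_I`, `I_T` are the within-year sub-compartments tracked by
#' [simulate_ioud()].
#'
#' @param trajectory an `ioud_trajectory` covering at least one whole
#'   calendar year
#' @param target which class to convert: `"I"` or `"T"`
#' @return data.frame with columns `year`, `past_year`,
#'   `average_instantaneous`, `left_class`, `return_correction`; the first
#'   equals the sum of the second and third minus the fourth
#' @export
past_year_prevalence <- function(trajectory, target = c("I", "T")) {
  target <- match.arg(target)
  tal <- yearly_flow_tallies(trajectory)
  if (nrow(tal) == 0) stop("trajectory carries no whole-year tallies")
  if (target == "I") {
    out <- data.frame(year = tal$year,
                      past_year = tal$mean_I + tal$avg_left_I - tal$avg_ret_I,
                      average_instantaneous = tal$mean_I,
                      left_class = tal$avg_left_I,
                      return_correction = tal$avg_ret_I)
  } else {
    out <- data.frame(year = tal$year,
                      past_year = tal$mean_T + tal$avg_left_T - tal$avg_ret_T,
                      average_instantaneous = tal$mean_T,
                      left_class = tal$avg_left_T,
                      return_correction = tal$avg_ret_T)
  }
  out
}

#' Average past-year-to-mean ratio
#'
#' The per-year ratio of the yearly mean of I to the model past-year I
#' count, averaged over all whole years of the trajectory. On the baseline
#' 2002--2019 run this is the 0.903 conversion factor used to turn survey
#' past-year counts into average-during-year counts.
#'
#' @param trajectory an `ioud_trajectory` covering at least two whole years
#' @return the average ratio (dimensionless, in (0, 1] when leavers
#'   outnumber returns)
#' @export
average_past_year_ratio <- function(trajectory) {
  py <- past_year_prevalence(trajectory, "I")
  if (nrow(py) < 2) stop("need at least two whole years")
  keep <- py$past_year > 0
  if (any(!keep)) warning("years with zero past-year count excluded: ",
                          paste(py$year[!keep], collapse = ", "))
  mean(py$average_instantaneous[keep] / py$past_year[keep])
}

# Model series against which data are compared: past-year I, past-year T
# and yearly overdose deaths, at the city scale.
.model_series <- function(params, init, t0, t1) {
  tr <- simulate_ioud(params, init = init, t0 = t0, t1 = t1, dt_out = 0.5)
  tal <- yearly_flow_tallies(tr)
  data.frame(year = tal$year,
             past_year_I = tal$mean_I + tal$avg_left_I - tal$avg_ret_I,
             past_year_T = tal$mean_T + tal$avg_left_T - tal$avg_ret_T,
             deaths = tal$overdose_deaths)
}

# Scale an observed national series to the city and assemble the three
# comparison columns (NA allowed where data are missing).
.observed_series <- function(series, city_size = 200000, hud_fraction = 0.8,
                             specialty_fraction = 0.6874) {
  if (is.null(series$treatment_from_hud)) series$treatment_from_hud <- NA_real_
  fill <- is.na(series$treatment_from_hud) & !is.na(series$treatment_past_year)
  series$treatment_from_hud[fill] <-
    series$treatment_past_year[fill] * specialty_fraction
  f <- city_size / series$us_population
  data.frame(year = series$year,
             past_year_I = series$hud_past_year * f,
             past_year_T = series$treatment_from_hud * f,
             deaths = series$deaths_heroin * hud_fraction * f)
}

#' Estimate transmission, completion, saturation and self-recovery rates
#'
#' Minimizes the sum of squared residuals between the model's city-scale
#' yearly series (past-year I, past-year T, overdose deaths) and an
#' observed national series scaled to the city. Each of the three series
#' is normalized by its own data mean so that counts of different
#' magnitude contribute comparably. The initial state is fixed at the 2002
#' baseline; only (beta, rho, epsilon, omega) move, within bounds.
#'
#' @param series a surveillance data.frame as returned by
#'   [load_surveillance()] or [generate_series()]
#' @param delta an `ioud_delta_fit` or `ioud_delta_schedule` providing the
#'   overdose death-rate schedule used during fitting
#' @param fixed an [ioud_params()] object supplying every parameter not
#'   being estimated
#' @param start named start values for `beta`, `rho`, `epsilon`, `omega`
#'   (defaults: the `fixed` values)
#' @param lower,upper named bounds; defaults beta in (0, 1],
#'   rho in \[0.1, 0.4\], omega in \[0.01, 0.2\] (literature ranges),
#'   epsilon in \[0, 1\]
#' @param n_starts number of Latin-hypercube multistart points (in
#'   addition to `start`); 0 runs a single local fit from `start`
#' @param seed RNG seed for the multistart design
#' @param t0,t1 simulation window (default 2002--2020)
#' @param init initial state at `t0`
#' @param maxit iteration budget per local fit; 0 returns the start point
#'   with its objective
#' @return an `ioud_fit`: list with `estimates`, `rss`, `convergence`,
#'   `bounds`, `residuals` (per-year, per-series), `objective` function
#' @export
estimate_parameters <- function(series, delta = delta_fit_paper(),
                                fixed = ioud_params(),
                                start = NULL,
                                lower = c(beta = 1e-4, rho = 0.1, epsilon = 0, omega = 0.01),
                                upper = c(beta = 1, rho = 0.4, epsilon = 1, omega = 0.2),
                                n_starts = 15, seed = 1, t0 = 2002, t1 = 2020,
                                init = baseline_init(), maxit = 200) {
  if (inherits(delta, "ioud_delta_fit")) delta <- as_delta_schedule(delta)
  free <- c("beta", "rho", "epsilon", "omega")
  if (is.null(start)) start <- unlist(fixed[free])
  start <- pmin(pmax(start[free], lower[free]), upper[free])
  obs <- .observed_series(series)
  obs <- obs[obs$year >= t0 & obs$year < t1, , drop = FALSE]
  usable <- rowSums(!is.na(obs[, c("past_year_I", "past_year_T", "deaths")])) > 0
  if (sum(usable) < 4) stop("need at least 4 usable years of data")
  obs <- obs[usable, , drop = FALSE]
  norm <- vapply(c("past_year_I", "past_year_T", "deaths"),
                 function(cn) mean(obs[[cn]], na.rm = TRUE), 0)
  if (any(!is.finite(norm) | norm <= 0)) stop("cannot normalize: empty data series")

  residual_fn <- function(theta) {
    pars <- update_params(fixed, beta = theta[["beta"]], rho = theta[["rho"]],
                          epsilon = theta[["epsilon"]], omega = theta[["omega"]],
                          delta = delta)
    mod <- .model_series(pars, init, t0, t1)
    m <- merge(obs, mod, by = "year", suffixes = c(".obs", ".mod"))
    unlist(lapply(c("past_year_I", "past_year_T", "deaths"), function(cn) {
      r <- (m[[paste0(cn, ".mod")]] - m[[paste0(cn, ".obs")]]) / norm[[cn]]
      r[!is.na(r)]
    }))
  }
  objective <- function(theta) {
    r <- try(residual_fn(theta), silent = TRUE)
    if (inherits(r, "try-error")) return(1e10) # candidate rejected
    sum(r^2)
  }

  starts <- list(start)
  if (n_starts > 0) {
    set.seed(seed)
    lat <- lhs_matrix(n_starts, length(free))
    for (i in seq_len(n_starts)) {
      th <- lower[free] + lat[i, ] * (upper[free] - lower[free])
      names(th) <- free
      starts[[i + 1]] <- th
    }
  }

  best <- NULL
  for (th in starts) {
    if (maxit == 0) {
      cand <- list(par = th, value = objective(th), convergence = 0L)
    } else {
      cand <- stats::optim(th, objective, method = "L-BFGS-B",
                           lower = lower[free], upper = upper[free],
                           control = list(maxit = maxit,
                                          parscale = pmax(abs(th), 1e-3)))
    }
    if (is.null(best) || cand$value < best$value) best <- cand
  }
  res <- if (maxit == 0) NULL else residual_fn(best$par)
  structure(list(estimates = stats::setNames(as.numeric(best$par), free),
                 rss = best$value,
                 convergence = best$convergence,
                 bounds = list(lower = lower[free], upper = upper[free]),
                 residuals = res, objective = objective),
            class = "ioud_fit")
}

#' @export
print.ioud_fit <- function(x, ...) {
  cat("IOUD parameter fit (beta, rho, epsilon, omega):\n")
  print(x$estimates)
  cat(sprintf("residual sum of squares: %.6g (convergence flag %d)\n",
              x$rss, x$convergence))
  invisible(x)
}
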