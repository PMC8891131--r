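# Core dynamics: right-hand side, saturating treatment entry, simulation
# with per-calendar-year flow tallies.

#' Treatment saturation factor
#'
#' `b(T) = 1 / (1 + epsilon * T)`: the multiplier throttling entry into
#' specialty treatment as treatment occupancy `T` grows. Equals 1 when
#' either argument is zero and decreases towards 0 as `epsilon * T` grows.
#'
#' @param T_count treatment occupancy (persons, >= 0), vectorized
#' @param epsilon saturation coefficient (1/person, >= 0)
#' @return factor in (0, 1]
#' @export
#' @examples
#' treatment_saturation(95, 0.0313)
treatment_saturation <- function(T_count, epsilon) {
  if (any(T_count < 0) || any(epsilon < 0))
    stop("treatment_saturation: arguments must be nonnegative")
  1 / (1 + epsilon * T_count)
}

#' Model right-hand side
#'
#' Time derivatives of the four compartments. The sum of the four
#' derivatives equals `Lambda - mu * N - delta * I` (the population law).
#'
#' @param state numeric vector (S, I, T, R), all nonnegative with positive
#'   total
#' @param params an [ioud_params()] object
#' @param t calendar time (years), used to evaluate a time-varying delta
#' @return named numeric vector of derivatives (persons/year)
#' @export
ioud_rhs <- function(state, params, t = 0) {
  stopifnot(inherits(params, "ioud_params"))
  delta <- param_delta(params, t)
  d <- .ioud_rhs_raw(state, params, delta)
  if (!is.finite(sum(d))) stop("non-finite derivative")
  d
}

# unvalidated core used by Jacobians and equilibrium residuals; `delta` is
# a number and `state` may carry small negative perturbations
.ioud_rhs_raw <- function(state, params, delta) {
  S <- state[[1]]; I <- state[[2]]; T_ <- state[[3]]; R <- state[[4]]
  N <- S + I + T_ + R
  if (!(N > 0)) stop("degenerate state: N must be positive")
  bT <- 1 / (1 + params$epsilon * T_)
  inc <- params$beta * S * I / N
  treat_in <- bT * (params$eta1 * I + params$eta2 * I * R / N +
                      params$eta3 * I * S / N)
  relT <- params$kappa * T_
  relR <- params$alpha1 * R + params$alpha2 * R * I / N
  c(S = params$Lambda - inc - params$mu * S,
    I = inc + relR + relT - treat_in - params$omega * I -
      (params$mu + delta) * I,
    T = treat_in - relT - params$rho * T_ - params$mu * T_,
    R = params$omega * I + params$rho * T_ - relR - params$mu * R)
}

#' Simulate the IOUD model
#'
#' Integrates the model with a Dormand-Prince 5(4) adaptive step
#' (rtol = atol = 1e-9 by default), restarting at calendar-year boundaries
#' and at breakpoints of the death-rate schedule. Cumulative flows (new
#' entries to the disorder class, relapses, overdose deaths, class
#' leavers) and the within-year sub-compartments feeding the past-year
#' corrections are integrated as additional coordinates alongside the
#' state, and reset at year boundaries; their per-year values are returned
#' as tallies.
#'
#' @param params an [ioud_params()] object
#' @param init initial state, named or ordered (S, I, T, R)
#' @param t0,t1 start and end calendar times (years), `t1 > t0`
#' @param dt_out spacing of the trajectory output grid (years)
#' @param rtol,atol integrator tolerances
#' @return an `ioud_trajectory`: list with `times`, `states` (data.frame
#'   time, S, I, T, R, N), `tallies` (see [yearly_flow_tallies()]),
#'   `params`, `init`, `t0`, `t1`
#' @export
simulate_ioud <- function(params, init = baseline_init(), t0 = 2002,
                          t1 = 2020, dt_out = 1 / 12,
                          rtol = 1e-9, atol = 1e-9) {
  stopifnot(inherits(params, "ioud_params"))
  if (t1 <= t0) stop("t1 must exceed t0")
  init <- as.numeric(init[c(1, 2, 3, 4)])
  if (any(is.na(init)) || any(init < 0)) stop("init must be 4 nonnegative numbers")
  tout <- seq(t0, t1, by = dt_out)
  if (tout[length(tout)] < t1) tout <- c(tout, t1)
  res <- .ioud_integrate_cpp(init, t0, t1, .flat_params(params),
                             params$delta$pieces, tout, rtol, atol,
                             ri_rho = 1L)
  st <- res$states
  states <- data.frame(time = res$times, S = st[, 1], I = st[, 2],
                       T = st[, 3], R = st[, 4])
  states$N <- states$S + states$I + states$T + states$R
  tal <- as.data.frame(res$tallies)
  tal <- tal[tal$full > 0.5, , drop = FALSE]
  tal$full <- NULL
  names(tal)[names(tal) == "int_I"] <- "mean_I"
  names(tal)[names(tal) == "int_T"] <- "mean_T"
  rownames(tal) <- NULL
  structure(list(times = res$times, states = states, tallies = tal,
                 final = res$final, params = params,
                 init = stats::setNames(init, c("S", "I", "T", "R")),
                 t0 = t0, t1 = t1),
            class = "ioud_trajectory")
}

.flat_params <- function(params) {
  unlist(params[c("Lambda", "mu", "beta", "eta1", "eta2", "eta3", "omega",
                  "rho", "kappa", "alpha1", "alpha2", "epsilon")])
}

#' @export
print.ioud_trajectory <- function(x, ...) {
  cat(sprintf("IOUD trajectory %s -> %s (%d output points, %d tallied years)\n",
              format(x$t0), format(x$t1), length(x$times), nrow(x$tallies)))
  print(utils::head(x$states, 3))
  invisible(x)
}

#' Per-year flow tallies of a trajectory
#'
#' One row per whole calendar year covered by the trajectory, with the
#' year's mean compartment sizes (`mean_I`, `mean_T`), cumulative flows
#' (`new_to_I` integrates the incidence beta*S*I/N; `relapse_from_T`
#' integrates kappa*T; `relapse_from_R` integrates alpha1*R +
#' alpha2*R*I/N; `overdose_deaths` integrates delta*I; `left_I` and
#' `left_T` the non-death outflows of I and T), and the year-scoped return
#' flows used by the past-year corrections (`ret_I_from_T`,
#' `ret_I_from_R`, `ret_T_from_I`).
#'
#' @param trajectory an `ioud_trajectory`
#' @return data.frame of tallies; empty (with a warning) if the
#'   trajectory spans less than one whole calendar year
#' @export
yearly_flow_tallies <- function(trajectory) {
  stopifnot(inherits(trajectory, "ioud_trajectory"))
  tal <- trajectory$tallies
  if (nrow(tal) == 0)
    warning("trajectory spans less than one whole calendar year; no tallies")
  tal
}

#' Trajectory and tally export
#'
#' Writes the state trajectory and the yearly tallies as CSV files.
#' @param trajectory an `ioud_trajectory`
#' @param states_path,tallies_path output CSV paths (either may be NULL to
#'   skip)
#' @return invisibly, the trajectory
#' @export
write_trajectory <- function(trajectory, states_path = NULL, tallies_path = NULL) {
  stopifnot(inherits(trajectory, "ioud_trajectory"))
  if (!is.null(states_path))
    utils::write.csv(trajectory$states, states_path, row.names = FALSE)
  if (!is.null(tallies_path))
    utils::write.csv(trajectory$tallies, tallies_path, row.names = FALSE)
  invisible(trajectory)
}
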