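# Overdose death-rate trend: data derivation, piecewise-linear fit,
# evaluation and extrapolation.

# Canonical fitted constants for the 2002-2019 national series (the sloped
# branch is delta(t) = M0 * t - B0; the early branch is the constant C0NST).
.DELTA_M0 <- 0.002307120199666
.DELTA_B0 <- 4.630363924326326
.DELTA_CONST0 <- 0.0080891345
.DELTA_BREAK0 <- 2010.4947542468
.DELTA_SHIFT0 <- 0.006483049602509 # 1 - (M0/B0)*2020, times B0 gives delta(2020)

#' Constant overdose death-rate schedule
#' @param delta rate in 1/year
#' @return an `ioud_delta_schedule`
#' @export
delta_constant <- function(delta) {
  stopifnot(is.numeric(delta), length(delta) == 1L, !is.na(delta), delta >= 0)
  structure(list(pieces = matrix(c(-Inf, 0, delta), nrow = 1,
                                 dimnames = list(NULL, c("t_start", "slope", "intercept")))),
            class = "ioud_delta_schedule")
}

#' @export
print.ioud_delta_schedule <- function(x, ...) {
  cat("piecewise-linear delta schedule (delta = slope * t + intercept):\n")
  print(x$pieces)
  invisible(x)
}

#' Evaluate a delta schedule
#' @param schedule an `ioud_delta_schedule`
#' @param t calendar times (years)
#' @return delta(t), vectorized
#' @export
delta_schedule_at <- function(schedule, t) {
  stopifnot(inherits(schedule, "ioud_delta_schedule"))
  p <- schedule$pieces
  idx <- vapply(t, function(ti) max(1L, sum(p[, "t_start"] <= ti)), 1L)
  unname(p[idx, "slope"] * t + p[idx, "intercept"])
}

#' Piecewise-linear overdose death-rate fit
#'
#' Container for a two-branch trend: an early constant level followed by a
#' rising line `delta(t) = m * t - b`, joined at the breakpoint where the
#' branches intersect.
#'
#' @param constant early-period level (1/year)
#' @param m slope of the late branch (1/year^2)
#' @param b intercept of the late branch, sign convention `delta = m*t - b`
#' @param breakpoint branch intersection; computed as `(constant + b)/m`
#'   when omitted
#' @return an object of class `ioud_delta_fit`
#' @export
delta_fit <- function(constant, m, b, breakpoint = NULL) {
  stopifnot(is.numeric(constant), is.numeric(m), is.numeric(b), m != 0)
  if (is.null(breakpoint)) breakpoint <- (constant + b) / m
  if (abs(m * breakpoint - b - constant) > 1e-6 * max(abs(constant), 1e-12))
    stop("branches do not intersect at the breakpoint (continuity violated)")
  structure(list(constant = constant, m = m, b = b, breakpoint = breakpoint),
            class = "ioud_delta_fit")
}

#' @export
print.ioud_delta_fit <- function(x, ...) {
  cat(sprintf("delta(t) = %.10g for t < %.6f;  %.10g * t - %.10g afterwards\n",
              x$constant, x$breakpoint, x$m, x$b))
  invisible(x)
}

#' The canonical published piecewise delta fit
#'
#' Constant 0.0080891345 up to the breakpoint 2010.4947542468, then
#' `0.002307120199666 * t - 4.630363924326326`. Extrapolating the sloped
#' branch past 2020 gives the projected death-rate trend used by the
#' bifurcation and sensitivity analyses.
#' @return an `ioud_delta_fit`
#' @export
delta_fit_paper <- function() {
  delta_fit(.DELTA_CONST0, .DELTA_M0, .DELTA_B0, .DELTA_BREAK0)
}

#' Evaluate a piecewise delta fit
#' @param fit an `ioud_delta_fit`
#' @param t calendar times (years), vectorized
#' @return delta(t) in 1/year
#' @export
delta_at <- function(fit, t) {
  stopifnot(inherits(fit, "ioud_delta_fit"))
  ifelse(t < fit$breakpoint, fit$constant, fit$m * t - fit$b)
}

#' Convert a delta fit to an integrable schedule
#' @param fit an `ioud_delta_fit`
#' @return an `ioud_delta_schedule` with two pieces (the sloped branch is
#'   extrapolated indefinitely)
#' @export
as_delta_schedule <- function(fit) {
  stopifnot(inherits(fit, "ioud_delta_fit"))
  pieces <- rbind(c(-Inf, 0, fit$constant),
                  c(fit$breakpoint, fit$m, -fit$b))
  colnames(pieces) <- c("t_start", "slope", "intercept")
  structure(list(pieces = pieces), class = "ioud_delta_schedule")
}

#' Scale a national count to the reference city
#'
#' @param national_count count at national level (persons)
#' @param us_population national population (persons)
#' @param city_size reference city population, default 200000 (persons)
#' @return the count scaled by `city_size / us_population`
#' @export
#' @examples
#' scale_to_city(214000, 287.3e6) # 148.97
scale_to_city <- function(national_count, us_population, city_size = 200000) {
  if (any(us_population <= 0)) stop("us_population must be positive")
  national_count * city_size / us_population
}

#' Data-derived yearly overdose death rate
#'
#' The yearly rate is estimated as the heroin overdose deaths attributed to
#' the heroin-use-disorder (HUD) class (a fraction `hud_fraction` of all
#' heroin overdose deaths) divided by the average number with HUD during
#' the year (the past-year HUD count times `averaging_factor`). The ratio
#' is invariant to simultaneous population scaling of both counts, so
#' national and city-scaled inputs give the same rate.
#'
#' @param deaths_heroin total overdose deaths due to heroin in the year
#' @param hud_past_year past-year HUD count
#' @param hud_fraction fraction of heroin overdose deaths occurring in the
#'   HUD class (default 0.8)
#' @param averaging_factor past-year-to-average conversion factor
#'   (default 0.903, see [average_past_year_ratio()])
#' @return death rate in 1/year, vectorized
#' @export
delta_from_data <- function(deaths_heroin, hud_past_year,
                            hud_fraction = 0.8, averaging_factor = 0.903) {
  if (any(hud_past_year <= 0, na.rm = TRUE)) stop("hud_past_year must be positive")
  if (any(deaths_heroin < 0, na.rm = TRUE)) stop("deaths_heroin must be nonnegative")
  deaths_heroin * hud_fraction / (hud_past_year * averaging_factor)
}

#' Least-squares piecewise-linear fit of the death-rate trend
#'
#' Fits a constant level to the early years (ordinary least squares, i.e.
#' the mean) and a straight line to the late years, and returns the
#' two-branch trend joined at the intersection of the branches.
#'
#' @param year calendar years of the series
#' @param delta data-derived death rates (1/year), same length
#' @param early_years years belonging to the constant branch
#'   (default 2002:2010)
#' @param late_years years belonging to the sloped branch
#'   (default 2011:2019)
#' @return an `ioud_delta_fit`
#' @export
fit_piecewise_delta <- function(year, delta, early_years = 2002:2010,
                                late_years = 2011:2019) {
  stopifnot(length(year) == length(delta))
  e <- year %in% early_years & !is.na(delta)
  l <- year %in% late_years & !is.na(delta)
  if (sum(e) < 1) stop("need at least one early-branch year")
  if (sum(l) < 2) stop("need at least two late-branch years")
  if (length(unique(year[l])) < 2) stop("degenerate late set: all points share a year")
  const <- mean(delta[e])
  fit <- stats::lm.fit(cbind(1, year[l]), delta[l])
  m <- unname(fit$coefficients[2])
  b <- -unname(fit$coefficients[1])
  if (m == 0) stop("late branch has zero slope; breakpoint undefined")
  delta_fit(const, m, b)
}

#' Extrapolated death rate with perturbable slope and level
#'
#' Reparameterized extrapolation of the fitted sloped branch for
#' `t >= 2020`: `delta(t) = m * (t - 2020) + b * 0.006483049602509` with
#' baseline `m = 0.002307120199666` and `b = 4.630363924326326`. Scaling
#' `b` by a factor shifts delta(2020) by the same factor; scaling `m`
#' scales the slope by the same factor.
#'
#' @param m_factor multiplicative perturbation of the slope
#' @param b_factor multiplicative perturbation of the 2020 level
#' @param t calendar time, must be >= 2020 (vectorized)
#' @return delta(t) in 1/year
#' @export
perturbed_extrapolation <- function(m_factor = 1, b_factor = 1, t) {
  if (any(t < 2020)) stop("the perturbed extrapolation is defined for t >= 2020")
  m_factor * .DELTA_M0 * (t - 2020) + b_factor * .DELTA_B0 * .DELTA_SHIFT0
}

#' Schedule form of the perturbed extrapolation
#' @inheritParams perturbed_extrapolation
#' @return an `ioud_delta_schedule` with a single linear piece valid from
#'   2020 on (and applied at all earlier times fed to it)
#' @export
delta_extrapolation_schedule <- function(m_factor = 1, b_factor = 1) {
  m <- m_factor * .DELTA_M0
  icpt <- b_factor * .DELTA_B0 * .DELTA_SHIFT0 - 2020 * m
  pieces <- matrix(c(-Inf, m, icpt), nrow = 1,
                   dimnames = list(NULL, c("t_start", "slope", "intercept")))
  structure(list(pieces = pieces), class = "ioud_delta_schedule")
}

#' Load a yearly surveillance series
#'
#' Reads a CSV with columns `year, deaths_synthetic, deaths_heroin,
#' us_population, hud_past_year, treatment_past_year, treatment_from_hud`
#' (missing values as empty fields). Years lacking a direct
#' treatment-from-HUD count have it imputed as
#' `treatment_past_year * specialty_fraction` and are flagged in
#' `treatment_is_scaled`.
#'
#' @param path CSV path
#' @param specialty_fraction fraction of specialty-treatment counts
#'   attributable to the HUD class (default 0.6874)
#' @return a data.frame with the input columns plus `treatment_is_scaled`
#' @export
load_surveillance <- function(path, specialty_fraction = 0.6874) {
  if (!file.exists(path)) stop("surveillance file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("year", "deaths_synthetic", "deaths_heroin", "us_population",
            "hud_past_year", "treatment_past_year", "treatment_from_hud")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  if (any(d$us_population <= 0, na.rm = TRUE)) stop("us_population must be positive")
  num <- setdiff(need, "year")
  bad <- vapply(num, function(nm) any(d[[nm]] < 0, na.rm = TRUE), TRUE)
  if (any(bad)) stop("negative counts in columns: ", paste(num[bad], collapse = ", "))
  if (is.null(d$treatment_is_scaled)) d$treatment_is_scaled <- FALSE
  fill <- is.na(d$treatment_from_hud) & !is.na(d$treatment_past_year)
  d$treatment_from_hud[fill] <- d$treatment_past_year[fill] * specialty_fraction
  d$treatment_is_scaled <- as.logical(d$treatment_is_scaled) | fill
  d
}

#' The packaged 2002--2020 national surveillance table
#'
#' Yearly national overdose deaths (synthetics; heroin), population,
#' past-year HUD counts and past-year specialty-treatment-from-HUD counts.
#' Treatment values flagged `treatment_is_scaled` were derived from total
#' specialty-treatment counts via the 0.6874 factor (the from-HUD split
#' was only surveyed 2014--2017).
#'
#' @return a data.frame, one row per year 2002--2020
#' @export
ioud_table2 <- function() {
  load_surveillance(system.file("extdata", "usa_surveillance_2002_2020.csv",
                                package = "ioud", mustWork = TRUE))
}
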