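# Latin hypercube sampling, PRCC and significance banding for the four
# derived yearly outcomes.

#' Latin hypercube sample on the unit cube
#'
#' One stratum per sample and factor; within-stratum positions are
#' uniform and strata are independently permuted per column.
#'
#' @param n number of samples
#' @param k number of factors
#' @return n x k matrix in (0, 1)
#' @export
lhs_matrix <- function(n, k) {
  m <- vapply(seq_len(k), function(j) (sample(n) - stats::runif(n)) / n,
              numeric(n))
  if (!is.matrix(m)) m <- matrix(m, nrow = n)
  m
}

#' Sensitivity design around the 2020 baseline
#'
#' Builds the factor table for the two death-rate scenarios: every model
#' rate and the four 2020 initial conditions vary uniformly within
#' +/- 10% of baseline. Under `constant_delta` the death rate delta (at
#' its extrapolated 2020 value 0.03002) is itself a factor; under
#' `variable_delta` the extrapolation's slope `m` and level parameter `b`
#' replace it.
#'
#' @param scenario "constant_delta" or "variable_delta"
#' @param n_samples design size (default 1000)
#' @param seed sampling seed
#' @param params baseline parameters
#' @param init2020 the 2020 state used as initial-condition baseline; by
#'   default the final state of the baseline 2002--2020 run under the
#'   fitted death-rate trend
#' @param horizon output year: outcomes are the flow tallies of the year
#'   ending at the horizon (default 2030)
#' @param span half-width of the factor ranges relative to baseline
#'   (default 0.1)
#' @return an `ioud_sensitivity_design`
#' @export
sensitivity_design <- function(scenario = c("constant_delta", "variable_delta"),
                               n_samples = 1000, seed = 20202030,
                               params = ioud_params(),
                               init2020 = NULL, horizon = 2030, span = 0.1) {
  scenario <- match.arg(scenario)
  if (is.null(init2020)) {
    tr <- simulate_ioud(update_params(params, delta = delta_fit_paper()),
                        init = baseline_init(), t0 = 2002, t1 = 2020, dt_out = 1)
    init2020 <- tr$final[1:4]
  }
  base <- c(S0 = unname(init2020[1]), I0 = unname(init2020[2]),
            T0 = unname(init2020[3]), R0 = unname(init2020[4]),
            Lambda = params$Lambda, mu = params$mu, beta = params$beta,
            eta1 = params$eta1, eta2 = params$eta2, eta3 = params$eta3,
            rho = params$rho, kappa = params$kappa, alpha1 = params$alpha1,
            alpha2 = params$alpha2, delta = 0.03002,
            m = .DELTA_M0, b = .DELTA_B0,
            omega = params$omega, epsilon = params$epsilon)
  drop <- if (scenario == "constant_delta") c("m", "b") else "delta"
  base <- base[setdiff(names(base), drop)]
  n_min <- length(base) + 2
  if (n_samples < n_min) stop("n_samples must be at least ", n_min)
  structure(list(scenario = scenario, n_samples = n_samples, seed = seed,
                 baseline = base,
                 lower = base * (1 - span), upper = base * (1 + span),
                 horizon = horizon, params = params),
            class = "ioud_sensitivity_design")
}

#' Draw the Latin hypercube factor matrix of a design
#' @param design an [sensitivity_design()]
#' @return n x k matrix, columns named by factor, each within its range
#' @export
lhs_sample <- function(design) {
  stopifnot(inherits(design, "ioud_sensitivity_design"))
  set.seed(design$seed)
  u <- lhs_matrix(design$n_samples, length(design$baseline))
  X <- sweep(sweep(u, 2, design$upper - design$lower, `*`), 2, design$lower, `+`)
  colnames(X) <- names(design$baseline)
  X
}

# simulate one factor row from 2020 to the horizon and return the final
# year's tallies (and optionally every year's)
.row_outcomes <- function(x, design, all_years = FALSE) {
  pars <- ioud_params(Lambda = x[["Lambda"]], mu = x[["mu"]], beta = x[["beta"]],
                      eta1 = x[["eta1"]], eta2 = x[["eta2"]], eta3 = x[["eta3"]],
                      omega = x[["omega"]], rho = x[["rho"]], kappa = x[["kappa"]],
                      alpha1 = x[["alpha1"]], alpha2 = x[["alpha2"]],
                      epsilon = x[["epsilon"]],
                      delta = if (design$scenario == "constant_delta")
                        delta_constant(x[["delta"]])
                      else delta_extrapolation_schedule(
                        m_factor = x[["m"]] / .DELTA_M0,
                        b_factor = x[["b"]] / .DELTA_B0))
  tr <- simulate_ioud(pars, init = c(x[["S0"]], x[["I0"]], x[["T0"]], x[["R0"]]),
                      t0 = 2020, t1 = design$horizon, dt_out = design$horizon - 2020)
  tal <- tr$tallies
  keep <- c("new_to_I", "relapse_from_T", "relapse_from_R", "overdose_deaths")
  if (all_years) as.matrix(tal[, c("year", keep)])
  else unlist(tal[nrow(tal), keep])
}

#' Evaluate the outcome matrix of a sensitivity design
#'
#' Runs the model from 2020 to the design horizon for every factor row
#' and collects the four derived yearly outcomes of the final year (new
#' entries to the disorder class, relapses from treatment, relapses from
#' recovered, overdose deaths).
#'
#' @param X factor matrix from [lhs_sample()]
#' @param design the matching design
#' @return matrix n x 4; failed rows are NA with a warning
#' @export
evaluate_outcomes <- function(X, design) {
  out <- matrix(NA_real_, nrow(X), 4,
                dimnames = list(NULL, c("new_to_I", "relapse_from_T",
                                        "relapse_from_R", "overdose_deaths")))
  fail <- 0L
  for (i in seq_len(nrow(X))) {
    v <- try(.row_outcomes(X[i, ], design), silent = TRUE)
    if (inherits(v, "try-error")) fail <- fail + 1L else out[i, ] <- v
  }
  if (fail > 0) warning(fail, " simulation row(s) failed and were excluded")
  out
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms every column (ties by average rank); for each factor,
#' correlates the residuals of the factor-on-other-factors and
#' outcome-on-other-factors linear regressions in rank space.
#'
#' @param X factor matrix (no constant columns)
#' @param y outcome vector
#' @return named vector of PRCC values in \[-1, 1\]; NA for factors whose
#'   rank regression is degenerate
#' @export
prcc <- function(X, y) {
  ok <- stats::complete.cases(X) & !is.na(y)
  X <- X[ok, , drop = FALSE]; y <- y[ok]
  if (nrow(X) < ncol(X) + 2) stop("need at least ", ncol(X) + 2, " complete rows")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) stop("constant factor column(s): ",
                          paste(colnames(X)[sds == 0], collapse = ", "))
  R <- apply(X, 2, rank, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  out <- stats::setNames(numeric(ncol(X)), colnames(X))
  for (j in seq_len(ncol(X))) {
    Z <- cbind(1, R[, -j, drop = FALSE])
    qz <- qr(Z)
    if (qz$rank < ncol(Z)) { out[j] <- NA_real_; next }
    rx <- stats::setNames(qr.resid(qz, R[, j]), NULL)
    rr <- qr.resid(qz, ry)
    out[j] <- stats::cor(rx, rr)
  }
  out
}

#' Significance band of a PRCC value
#'
#' Magnitude bands: at least 0.85 "highly significant"; 0.70 up to 0.85
#' "significant"; 0.55 up to 0.70 "somewhat significant"; 0.45 up to 0.55
#' "slightly significant"; 0.40 up to 0.45 "borderline significant";
#' below 0.40 "not significant". The sign is reported separately.
#'
#' @param prcc PRCC value(s) in \[-1, 1\]
#' @return character vector of band labels
#' @export
significance_band <- function(prcc) {
  if (any(abs(prcc) > 1 + 1e-12, na.rm = TRUE)) stop("|prcc| must be <= 1")
  a <- abs(prcc)
  cut(a, breaks = c(-Inf, 0.40, 0.45, 0.55, 0.70, 0.85, Inf),
      labels = c("not significant", "borderline significant",
                 "slightly significant", "somewhat significant",
                 "significant", "highly significant"),
      right = FALSE) |> as.character()
}

#' Full PRCC analysis for one scenario
#'
#' Convenience wrapper: builds the design, samples, simulates, and
#' returns the factor-by-outcome PRCC table with significance bands.
#' Factors that cannot be acted upon (`mu`) or that are absent from the
#' basic reproduction number (`Lambda`, `eta2`, `alpha2`, `epsilon`) are
#' flagged.
#'
#' @inheritParams sensitivity_design
#' @return list with `design`, `X`, `outcomes`, and `table` (long
#'   data.frame: factor, outcome, prcc, band, actionable, in_r0)
#' @export
prcc_analysis <- function(scenario = c("constant_delta", "variable_delta"),
                          n_samples = 1000, seed = 20202030,
                          params = ioud_params(), horizon = 2030) {
  scenario <- match.arg(scenario)
  design <- sensitivity_design(scenario, n_samples = n_samples, seed = seed,
                               params = params, horizon = horizon)
  X <- lhs_sample(design)
  Y <- evaluate_outcomes(X, design)
  tabs <- lapply(colnames(Y), function(oc) {
    pr <- prcc(X, Y[, oc])
    data.frame(factor = names(pr), outcome = oc, prcc = unname(pr),
               band = significance_band(pr),
               actionable = names(pr) != "mu",
               in_r0 = !names(pr) %in% c("Lambda", "eta2", "alpha2", "epsilon",
                                         "S0", "I0", "T0", "R0"),
               row.names = NULL)
  })
  list(design = design, X = X, outcomes = Y, table = do.call(rbind, tabs))
}
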