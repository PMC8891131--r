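# Shared fixtures and independent oracles for the test suite.

# baseline parameters with the fitted piecewise death-rate trend
pars_fit <- function(...) {
  update_params(ioud_params(delta = delta_fit_paper()), ...)
}

# random nonnegative parameter draws with mu > 0 (rates at plausible scales)
rand_params <- function() {
  ioud_params(Lambda = runif(1, 500, 5000), mu = runif(1, 0.005, 0.05),
              beta = runif(1, 0.01, 0.5), eta1 = runif(1, 0, 1),
              eta2 = runif(1, 0, 0.5), eta3 = runif(1, 0, 0.5),
              omega = runif(1, 0, 0.3), rho = runif(1, 0.01, 0.5),
              kappa = runif(1, 0, 1), alpha1 = runif(1, 0, 0.5),
              alpha2 = runif(1, 0, 0.1), epsilon = runif(1, 0, 0.1),
              delta = runif(1, 0, 0.1))
}

# Fixed-step explicit-Euler integration of the full bookkeeping system,
# written independently of the package integrator. delta_fun maps time to
# the death rate. Returns the final 22-coordinate vector (year-scoped
# coordinates are NOT reset: use within a single calendar year).
euler_bookkeeping <- function(params, delta_fun, init, t0, t1, h = 1e-4) {
  y <- c(init[1:4], numeric(18))
  t <- t0
  nstep <- round((t1 - t0) / h)
  for (k in seq_len(nstep)) {
    S <- y[1]; I <- y[2]; TT <- y[3]; R <- y[4]
    N <- S + I + TT + R
    dl <- delta_fun(t)
    b <- 1 / (1 + params$epsilon * TT)
    inc <- params$beta * S * I / N
    tin <- b * I * (params$eta1 + params$eta2 * R / N + params$eta3 * S / N)
    relT <- params$kappa * TT
    relR <- params$alpha1 * R + params$alpha2 * R * I / N
    outI_pc <- b * (params$eta1 + params$eta2 * R / N + params$eta3 * S / N) +
      params$omega + params$mu + dl
    d <- c(params$Lambda - inc - params$mu * S,
           inc + relR + relT - tin - (params$omega + params$mu + dl) * I,
           tin - relT - (params$rho + params$mu) * TT,
           params$omega * I + params$rho * TT - relR - params$mu * R,
           inc, relT, relR, dl * I,
           tin + params$omega * I, relT + params$rho * TT,
           tin - (params$kappa + params$rho + params$mu) * y[11],
           params$omega * I + params$rho * y[11] -
             (params$alpha1 + params$mu + params$alpha2 * I / N) * y[12],
           relT - outI_pc * y[13],
           params$kappa * y[11], params$alpha1 * y[12],
           y[13] * (params$eta1 + params$eta3 * S / N) * b,
           I, TT, y[9], y[14] + y[15], y[10], y[16])
    y <- y + h * d
    t <- t + h
  }
  names(y) <- c("S", "I", "T", "R", "new_to_I", "relapse_from_T",
                "relapse_from_R", "overdose_deaths", "left_I", "left_T",
                "T_I", "R_I", "I_T", "ret_I_from_T", "ret_I_from_R",
                "ret_T_from_I", "int_I", "int_T", "avg_left_I", "avg_ret_I",
                "avg_left_T", "avg_ret_T")
  y
}

# printed national yearly table, death-rate column (2002-2019)
printed_delta_data <- c(0.008648, 0.009750, 0.006162, 0.007841, 0.005709,
                        0.009932, 0.009520, 0.007870, 0.007451, 0.009144,
                        0.011240, 0.014149, 0.015986, 0.019471, 0.021892,
                        0.021037, 0.025258, 0.028356)
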