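test_that("treatment saturation factor matches its closed form and bounds", {
  expect_identical(treatment_saturation(0, 0.0313), 1)
  expect_identical(treatment_saturation(95, 0), 1)
  expect_equal(treatment_saturation(95, 0.0313), 1 / (1 + 0.0313 * 95))
  # strictly decreasing in both arguments
  expect_true(all(diff(treatment_saturation(seq(0, 500, by = 50), 0.03)) < 0))
  expect_true(all(diff(treatment_saturation(95, seq(0.01, 0.2, by = 0.01))) < 0))
  expect_error(treatment_saturation(-1, 0.03), "nonnegative")
  expect_error(treatment_saturation(5, -0.1), "nonnegative")
})

test_that("right-hand side vanishes at the DFE and satisfies the population law", {
  p <- ioud_params(delta = 0.0080891345)
  dfe <- c(p$Lambda / p$mu, 0, 0, 0)
  expect_equal(unname(ioud_rhs(dfe, p)), rep(0, 4))

  st <- c(199500, 102, 95, 100)
  d <- ioud_rhs(st, p)
  N <- sum(st)
  expect_equal(sum(d), p$Lambda - p$mu * N - 0.0080891345 * st[2],
               tolerance = 1e-12)
  # arithmetic oracle for the identity at this state
  expect_equal(sum(d), 2500 - 0.0125 * 199797 - 0.0080891345 * 102,
               tolerance = 1e-12)

  # with no transmission and empty T, R every remaining I-term is outflow
  p0 <- ioud_params(beta = 0)
  expect_lt(ioud_rhs(c(1000, 50, 0, 0), p0)[["I"]], 0)

  expect_error(ioud_rhs(c(0, 0, 0, 0), p0), "N must be positive")
})

test_that("simulation holds the DFE and matches a fixed-step Euler oracle", {
  p <- pars_fit()
  dfe <- c(p$Lambda / p$mu, 0, 0, 0)
  tr <- simulate_ioud(p, init = dfe, t0 = 2002, t1 = 2007)
  expect_true(all(abs(tr$states$S - p$Lambda / p$mu) < 1e-6))
  expect_true(all(tr$states$I == 0))

  tr1 <- simulate_ioud(p, t0 = 2002, t1 = 2003)
  oracle <- euler_bookkeeping(p, function(t) param_delta(p, t),
                              baseline_init(), 2002, 2003, h = 1e-4)
  expect_equal(tr1$final[2], oracle[["I"]], tolerance = 1e-3)
  expect_equal(tr1$final[1], oracle[["S"]], tolerance = 1e-3)
})

test_that("yearly tallies equal an independent fine-step quadrature", {
  p <- pars_fit()
  tr <- simulate_ioud(p, t0 = 2002, t1 = 2003)
  tal <- yearly_flow_tallies(tr)
  oracle <- euler_bookkeeping(p, function(t) param_delta(p, t),
                              baseline_init(), 2002, 2003, h = 1e-4)
  for (cn in c("new_to_I", "relapse_from_T", "relapse_from_R",
               "overdose_deaths", "left_I", "left_T", "ret_I_from_T",
               "ret_I_from_R", "ret_T_from_I", "avg_left_I", "avg_ret_I",
               "avg_left_T", "avg_ret_T")) {
    expect_equal(tal[[cn]][1], oracle[[cn]], tolerance = 1e-3,
                 label = paste("tally", cn))
  }
  expect_equal(tal$mean_I[1], oracle[["int_I"]], tolerance = 1e-3)
})

test_that("trajectories stay nonnegative and respect the population law", {
  p <- pars_fit()
  set.seed(42)
  for (k in 1:6) {
    init <- runif(4, 0, 1000) * c(200, 1, 1, 1)
    tr <- simulate_ioud(p, init = init, t0 = 2002, t1 = 2012, dt_out = 0.1)
    expect_true(all(tr$states[, c("S", "I", "T", "R")] >= 0))
  }
  # d/dt N = Lambda - mu N - delta I along a finely sampled trajectory
  tr <- simulate_ioud(ioud_params(delta = 0.02), t0 = 2002, t1 = 2003,
                      dt_out = 1e-3)
  st <- tr$states
  n <- nrow(st)
  dN <- (st$N[3:n] - st$N[1:(n - 2)]) / (st$time[3:n] - st$time[1:(n - 2)])
  rhsN <- 2500 - 0.0125 * st$N[2:(n - 1)] - 0.02 * st$I[2:(n - 1)]
  expect_lt(max(abs(dN - rhsN)), 1e-4)
})

test_that("with no disorder the susceptible class relaxes monotonically to Lambda/mu", {
  p <- ioud_params(delta = 0)
  tr <- simulate_ioud(p, init = c(150000, 0, 0, 0), t0 = 0, t1 = 800, dt_out = 10)
  s <- tr$states$S
  expect_true(all(diff(s) > 0))
  expect_equal(s[length(s)], p$Lambda / p$mu, tolerance = 1e-3)
  tr2 <- simulate_ioud(p, init = c(250000, 0, 0, 0), t0 = 0, t1 = 800, dt_out = 10)
  expect_true(all(diff(tr2$states$S) < 0))
})

test_that("raising the saturation coefficient never increases treatment occupancy", {
  base <- simulate_ioud(pars_fit(), t0 = 2002, t1 = 2012, dt_out = 0.25)
  high <- simulate_ioud(pars_fit(epsilon = 0.05), t0 = 2002, t1 = 2012,
                        dt_out = 0.25)
  expect_true(all(high$states$T <= base$states$T + 1e-9))
})

test_that("short trajectories yield empty tallies with a warning", {
  tr <- simulate_ioud(pars_fit(), t0 = 2002.2, t1 = 2002.9)
  expect_warning(tal <- yearly_flow_tallies(tr), "less than one whole")
  expect_equal(nrow(tal), 0)
})

test_that("time-varying delta switches branch at the breakpoint", {
  p <- pars_fit()
  expect_equal(param_delta(p, 2005), 0.0080891345)
  expect_equal(param_delta(p, 2015), 0.0023071201997 * 2015 - 4.63036392433,
               tolerance = 1e-6)
})
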