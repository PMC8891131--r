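test_that("the disorder-free equilibrium is Lambda/mu and flips stability at R0 = 1", {
  p <- ioud_params()
  dfe <- disorder_free_equilibrium(p, delta = 0.0577)
  expect_equal(unname(dfe$state), c(200000, 0, 0, 0))
  expect_equal(dfe$stability, "stable") # R0 < 1 there
  expect_lt(r0_closed_form(p, delta = 0.0577), 1)

  dfe2 <- disorder_free_equilibrium(p, delta = 0.03002)
  expect_equal(dfe2$stability, "unstable") # R0 > 1

  d2 <- disorder_free_equilibrium(update_params(p, Lambda = 5000), delta = 0.06)
  expect_equal(d2$state[["S"]], 400000)

  # eigenvalue crossing located at the R0 = 1 transmission rate
  bstar <- p$beta / r0_closed_form(p, delta = 0.03002)
  lo <- disorder_free_equilibrium(update_params(p, beta = bstar - 1e-4),
                                  delta = 0.03002)
  hi <- disorder_free_equilibrium(update_params(p, beta = bstar + 1e-4),
                                  delta = 0.03002)
  expect_equal(lo$stability, "stable")
  expect_equal(hi$stability, "unstable")
})

test_that("endemic equilibria are genuine fixed points with consistent stability", {
  p <- ioud_params()
  ee <- endemic_equilibria(p, delta = 0.03002)
  expect_length(ee, 1)
  expect_equal(ee[[1]]$stability, "stable")
  resid <- ioud:::.ioud_rhs_raw(ee[[1]]$state, p, 0.03002)
  expect_lt(max(abs(resid)), 1e-8)

  # independent 4-d Newton oracle lands on the same point
  set.seed(3)
  st <- ee[[1]]$state * runif(4, 0.5, 1.5)
  nz <- ioud:::.newton_equilibrium(st, p, 0.03002)
  expect_false(is.null(nz))
  expect_equal(unname(nz), unname(ee[[1]]$state), tolerance = 1e-6)

  ee2 <- endemic_equilibria(p, delta = 0.0531)
  expect_length(ee2, 2)
  expect_setequal(vapply(ee2, function(e) e$stability, ""),
                  c("unstable", "stable"))
  for (e in ee2)
    expect_lt(max(abs(ioud:::.ioud_rhs_raw(e$state, p, 0.0531))), 1e-8)

  # beyond the fold only the disorder-free state remains
  expect_length(endemic_equilibria(p, delta = 0.09), 0)
})

test_that("the bi-stable window shows two attractors in simulation", {
  p <- ioud_params(delta = 0.0531)
  ee <- endemic_equilibria(p, delta = 0.0531)
  stable_I <- ee[[which(vapply(ee, function(e) e$stability, "") == "stable")]]$state[["I"]]
  # small seeding collapses to the disorder-free state (the leading DFE
  # eigenvalue is tiny here, so the horizon is long)
  lo <- simulate_ioud(p, init = c(199999, 1, 0, 0), t0 = 0, t1 = 6000,
                      dt_out = 500)
  expect_lt(lo$final[2], 0.05)
  # large seeding is attracted to the endemic state
  hi <- simulate_ioud(p, init = c(150000, 30000, 1000, 5000), t0 = 0, t1 = 600,
                      dt_out = 50)
  expect_equal(hi$final[2], stable_I, tolerance = 1e-3)
})

test_that("stability labels agree with perturbed long-horizon simulation", {
  p <- ioud_params()
  set.seed(11)
  checked <- 0
  for (dlt in c(0.02, 0.03002, 0.045)) {
    for (e in endemic_equilibria(p, delta = dlt)) {
      pd <- update_params(p, delta = dlt)
      init <- pmax(e$state * (1 + 1e-3 * runif(4, -1, 1)), 0)
      tr <- simulate_ioud(pd, init = init, t0 = 0, t1 = 300, dt_out = 100)
      back <- abs(tr$final[2] - e$state[["I"]]) < 1e-2 * max(1, e$state[["I"]])
      expect_equal(back, e$stability == "stable",
                   label = paste("delta", dlt, "I*", round(e$state[["I"]])))
      checked <- checked + 1
    }
  }
  expect_gte(checked, 3)
})

test_that("the no-saturation cubic reduction matches its printed structure", {
  p0 <- ioud_params(epsilon = 0, eta2 = 0)
  cc <- cubic_coefficients_no_saturation(update_params(p0, alpha2 = 0), delta = 0.06)
  expect_identical(cc$a, 0) # a carries the alpha2 factor
  expect_lt(cubic_coefficients_no_saturation(p0, delta = 0.06)$a, 0)
  # sign(c) follows sign(R0 - 1)
  expect_lt(cubic_coefficients_no_saturation(p0, delta = 0.06)$c, 0)
  expect_gt(cubic_coefficients_no_saturation(p0, delta = 0.02)$c, 0)
  expect_error(cubic_coefficients_no_saturation(ioud_params(), delta = 0.06),
               "epsilon = 0")

  # printed example: delta = 0.06, alpha2 = 2000 gives b > 0 and two
  # positive roots of the quadratic factor
  big <- cubic_coefficients_no_saturation(update_params(p0, alpha2 = 2000),
                                          delta = 0.06)
  expect_gt(big$b_coeff, 0)
  expect_true(ioud:::.quad_two_positive(big$quadratic))

  # the quadratic's roots coincide with the reduced-equation roots
  q <- big$quadratic
  r <- sort(Re(polyroot(q)))
  pr <- update_params(p0, alpha2 = 2000)
  resid <- equilibrium_residual(r, pr, delta = 0.06)
  expect_lt(max(abs(resid) / r), 1e-6)
})

test_that("the backward-bifurcation threshold in alpha2 is sharp", {
  p0 <- ioud_params(epsilon = 0, eta2 = 0)
  a2c <- critical_alpha2(p0, delta = 0.06)
  expect_equal(a2c, 1200, tolerance = 0.05)
  below <- cubic_coefficients_no_saturation(update_params(p0, alpha2 = 0.99 * a2c),
                                            delta = 0.06)$quadratic
  above <- cubic_coefficients_no_saturation(update_params(p0, alpha2 = 1.01 * a2c),
                                            delta = 0.06)$quadratic
  expect_false(ioud:::.quad_two_positive(below))
  expect_true(ioud:::.quad_two_positive(above))
  expect_error(critical_alpha2(p0, delta = 0.02), "R0 >= 1")
})

test_that("quintic elimination agrees with interpolation and the root scan", {
  p <- ioud_params()
  qc <- quintic_coefficients(0.0531, 0.0313, 0.09, p)
  expect_lt(qc$interp_max_rel_diff, 1e-8)

  roots <- quintic_admissible_roots(0.0531, 0.0313, 0.09, p)
  direct <- endemic_equilibria(p, delta = 0.0531, classify = FALSE)
  expect_equal(length(roots), length(direct))
  expect_equal(sort(roots), sort(direct), tolerance = 1e-6)

  # degree collapse without saturation, contact relapse or recovered-contact
  # entry: the quintic nests the cubic reduction. The leading coefficient
  # vanishes, every root of the cubic's effective quadratic annihilates
  # the quintic (the quintic's remaining roots are the known elimination
  # artifacts at the population boundary x = 1 and the S-denominator
  # root, both inadmissible), and the admissible-root sets coincide.
  p0 <- ioud_params(epsilon = 0, eta2 = 0, alpha2 = 0)
  qc0 <- quintic_coefficients(0.06, 0, 0.09, p0)
  scale0 <- max(abs(qc0$nu_scaled))
  expect_lt(abs(qc0$nu_scaled[["nu6"]]), 1e-6 * scale0)
  qr_cubic <- cubic_coefficients_no_saturation(p0, delta = 0.06)$quadratic
  for (r in Re(polyroot(qr_cubic)))
    expect_lt(abs(ioud:::.peval(qc0$nu_scaled, r / qc0$scale)), 1e-6 * scale0)
  expect_length(quintic_admissible_roots(0.06, 0, 0.09, p0), 0)

  # ... and with a supercritical contact-relapse rate both reductions
  # report the same two admissible endemic levels
  pbb <- ioud_params(epsilon = 0, eta2 = 0, alpha2 = 2000)
  q_bb <- quintic_admissible_roots(0.06, 0, 0.09, pbb)
  c_bb <- sort(Re(polyroot(cubic_coefficients_no_saturation(pbb, delta = 0.06)$quadratic)))
  c_bb <- c_bb[c_bb > 0 & c_bb < 2500 / 0.06]
  expect_equal(q_bb, c_bb, tolerance = 1e-6)

  # constant term changes sign exactly where R0 crosses 1 in beta
  bstar <- 0.09 / r0_closed_form(p, delta = 0.0531)
  lo <- quintic_coefficients(0.0531, 0.0313, bstar * 0.99, p)$nu[["nu1"]]
  hi <- quintic_coefficients(0.0531, 0.0313, bstar * 1.01, p)$nu[["nu1"]]
  expect_lt(lo * hi, 0)
})

test_that("critical saturation for bi-stability behaves as a threshold", {
  p <- ioud_params()
  ec <- critical_epsilon(0.0531, 0.09, p)
  expect_true(is.finite(ec) && ec > 0)
  expect_lt(ec, 0.0313) # the baseline saturation sits inside the bi-stable region
  expect_length(endemic_equilibria(update_params(p, epsilon = 1.1 * ec),
                                   delta = 0.0531, classify = FALSE), 2)
  expect_length(endemic_equilibria(update_params(p, epsilon = 0.5 * ec),
                                   delta = 0.0531, classify = FALSE), 0)
  expect_error(critical_epsilon(0.03, 0.09, p), "R0 >= 1")

  # nonincreasing in the transmission rate
  ecs <- vapply(c(0.08, 0.085, 0.09), function(b) {
    critical_epsilon(0.0531, b, p)
  }, 0)
  expect_true(all(diff(ecs) <= 1e-6 + 0.02 * ecs[-3]))

  # finite threshold even without contact-driven relapse
  ec0 <- critical_epsilon(0.0531, 0.09, update_params(p, alpha2 = 0))
  expect_true(is.finite(ec0) && ec0 > 0)
})

test_that("no fold is reported when saturation is varied below the critical death rate", {
  p <- ioud_params()
  f <- saddle_node_locus("epsilon", p, delta = 0.03002, bracket = c(0, 0.05))
  expect_false(f$found)
})

test_that("stability regions partition the delta-beta plane as expected", {
  rg <- stability_regions("delta-beta", c(0.04, 0.09), c(0.07, 0.1),
                          fixed = 0.0313, n = 6)
  expect_setequal(unique(rg$label), c("EE", "BI", "DFE"))
  # the bi-stable cells all sit on the R0 < 1 side
  expect_true(all(rg$R0[rg$label == "BI"] < 1))
  expect_true(all(rg$R0[rg$label == "EE"] > 1))
})
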