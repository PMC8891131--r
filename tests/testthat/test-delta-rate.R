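test_that("city scaling matches the worked examples", {
  expect_equal(round(scale_to_city(214000, 287.3e6, 200000), 2), 148.97)
  expect_identical(scale_to_city(1234, 5e6, 5e6), 1234)
  expect_equal(scale_to_city(626000, 323.0e6, 200000), 626000 / 323.0e6 * 200000)
  expect_error(scale_to_city(10, 0), "positive")
})

test_that("the data-derived death-rate column reproduces every printed entry", {
  d <- ioud_table2()
  obs <- d[d$year <= 2019, ]
  dd <- delta_from_data(obs$deaths_heroin, obs$hud_past_year)
  expect_equal(round(dd, 6), printed_delta_data)
  # ratio invariance under joint population scaling
  sc <- scale_to_city(cbind(obs$deaths_heroin, obs$hud_past_year),
                      obs$us_population)
  expect_equal(delta_from_data(sc[, 1], sc[, 2]), dd, tolerance = 1e-12)
  expect_equal(delta_from_data(0, 1000), 0)
  expect_error(delta_from_data(10, 0), "positive")
})

test_that("piecewise fitting recovers exact synthetic trends to machine precision", {
  # branches genuinely intersect at 2010.5 so the data lie on the curve
  const <- 0.008; m <- 0.002; b <- m * 2010.5 - const
  yrs <- 2002:2019
  dd <- ifelse(yrs <= 2010, const, m * yrs - b)
  fit <- fit_piecewise_delta(yrs, dd)
  expect_equal(fit$constant, const, tolerance = 1e-12)
  expect_equal(fit$m, m, tolerance = 1e-9)
  expect_equal(fit$b, b, tolerance = 1e-6)
  expect_equal(fit$breakpoint, (const + b) / m, tolerance = 1e-9)
  # evaluation residuals on the fitting years match the direct fit exactly
  expect_equal(delta_at(fit, yrs), dd, tolerance = 1e-9)

  # a two-point late branch is interpolated exactly
  f2 <- fit_piecewise_delta(c(2005, 2011, 2012), c(0.008, 0.010, 0.013),
                            early_years = 2005, late_years = 2011:2012)
  expect_equal(delta_at(f2, c(2011, 2012)), c(0.010, 0.013))
  expect_error(fit_piecewise_delta(c(2005, 2011, 2011), c(1, 2, 3) / 100,
                                   early_years = 2005, late_years = 2011),
               "late")
})

test_that("fitting the printed column approximates the canonical constants", {
  d <- ioud_table2()
  dd <- delta_from_data(d$deaths_heroin[d$year <= 2019],
                        d$hud_past_year[d$year <= 2019])
  fit <- fit_piecewise_delta(2002:2019, dd)
  can <- delta_fit_paper()
  expect_equal(fit$constant, can$constant, tolerance = 0.02)
  expect_equal(fit$m, can$m, tolerance = 0.02)
  expect_equal(fit$breakpoint, can$breakpoint, tolerance = 0.001)
})

test_that("the canonical fit evaluates to the printed values", {
  fit <- delta_fit_paper()
  expect_equal(delta_at(fit, 2005), 0.0080891345)
  expect_equal(round(delta_at(fit, 2015), 5), 0.01848)
  expect_equal(round(delta_at(fit, 2020), 5), 0.03002)
  expect_equal(round(delta_at(fit, 2032), 4), 0.0577)
  # continuity at the breakpoint
  eps <- 1e-9
  expect_equal(delta_at(fit, fit$breakpoint - eps),
               delta_at(fit, fit$breakpoint + eps), tolerance = 1e-6)
  # printed fitted-column entries for the sloped years
  expect_equal(round(delta_at(fit, 2011), 6), 0.009255)
  expect_equal(round(delta_at(fit, 2019), 5), 0.02771)
})

test_that("the perturbable extrapolation behaves linearly in its factors", {
  expect_equal(round(perturbed_extrapolation(1, 1, 2020), 5), 0.03002)
  expect_equal(perturbed_extrapolation(1.1, 1, 2020),
               perturbed_extrapolation(1, 1, 2020))
  expect_equal(perturbed_extrapolation(1, 1.1, 2020),
               1.1 * perturbed_extrapolation(1, 1, 2020))
  expect_error(perturbed_extrapolation(1, 1, 2019), ">= 2020")
  # schedule form agrees with the closed form
  sch <- delta_extrapolation_schedule(1.05, 0.95)
  expect_equal(delta_schedule_at(sch, 2025),
               perturbed_extrapolation(1.05, 0.95, 2025), tolerance = 1e-12)
})

test_that("the surveillance loader validates and imputes the treatment split", {
  d <- ioud_table2()
  expect_equal(nrow(d), 19)
  expect_true(all(c("treatment_from_hud", "treatment_is_scaled") %in% names(d)))
  expect_true(d$treatment_is_scaled[d$year == 2011])
  expect_false(d$treatment_is_scaled[d$year == 2014])

  tmp <- tempfile(fileext = ".csv")
  write.csv(data.frame(year = 2010:2014, deaths_synthetic = 1,
                       deaths_heroin = 100, us_population = 3e8,
                       hud_past_year = 1e5, treatment_past_year = 1e4,
                       treatment_from_hud = NA),
            tmp, row.names = FALSE, na = "")
  d2 <- load_surveillance(tmp)
  expect_equal(d2$treatment_from_hud, rep(1e4 * 0.6874, 5))
  expect_true(all(d2$treatment_is_scaled))
  writeLines("year,deaths_heroin\n2002,5", tmp)
  expect_error(load_surveillance(tmp), "missing columns")
})
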