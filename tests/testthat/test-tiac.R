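ga <- ga68_decay_data()
lam <- ga$decay_constant_per_min

test_that("closed-form TIAC matches hand-derived limiting cases", {
  # no biological clearance: all decays happen in place, 1/lambda
  m0 <- retention_model(data.frame(amplitude = 1, rate_per_min = 0))
  expect_equal(tiac_from_model(m0, ga), 1 / lam / 60, tolerance = 1e-12)
  expect_equal(tiac_from_model(m0, ga), 1.628, tolerance = 1e-3)
  # biological rate equal to physical: exactly half
  m1 <- retention_model(data.frame(amplitude = 1, rate_per_min = lam))
  expect_equal(tiac_from_model(m1, ga), tiac_from_model(m0, ga) / 2)
  # reported blood clearance lands near the published blood TIAC
  expect_equal(tiac_from_model(blood_truth_model(), ga), 0.27,
               tolerance = 0.15)
  expect_error(
    tiac_from_model(data.frame(amplitude = 1, rate_per_min = -0.1), ga),
    class = "psmadosim_domain_error")
})

test_that("trapezoid TIAC reproduces the analytic pure-decay integral", {
  t <- seq(0, 240, by = 5)
  pts <- data.frame(time_min = t, value = exp(-lam * t))
  expect_equal(tiac_trapezoid(pts, ga), 1 / lam / 60, tolerance = 5e-3)
  # converges to the closed form at dense sampling
  t1 <- seq(0, 600, by = 1)
  pts1 <- data.frame(time_min = t1, value = exp(-lam * t1))
  expect_equal(tiac_trapezoid(pts1, ga), 1 / lam / 60, tolerance = 5e-4)
})

test_that("trapezoid TIAC handles edge cases and refuses corrected data", {
  expect_equal(tiac_trapezoid(data.frame(time_min = c(10, 60),
                                         value = c(0, 0)), ga), 0)
  # single point: triangle to t plus pure-decay tail
  got <- tiac_trapezoid(data.frame(time_min = 60, value = 0.5), ga)
  expect_equal(got, (0.5 / 2 * 60 + 0.5 / lam) / 60, tolerance = 1e-12)
  expect_equal(got, 1.064, tolerance = 1e-3)
  expect_error(
    tiac_trapezoid(data.frame(time_min = 60, value = 0.5,
                              decay_corrected = TRUE), ga),
    "decay_uncorrect")
  expect_error(
    tiac_trapezoid(data.frame(time_min = c(60, 60), value = c(0.5, 0.5)), ga),
    class = "psmadosim_domain_error")
})

test_that("trapezoid converges to the model TIAC for identical kinetics", {
  # same biokinetics, 1-min sampling: relative error below 0.5%
  m <- retention_model(data.frame(amplitude = c(0.6, 0.4),
                                  rate_per_min = c(0.05, 0.002)))
  t <- seq(0, 1500, by = 1)
  u_measured <- predict(m, t) * exp(-lam * t)
  trap <- tiac_trapezoid(data.frame(time_min = t, value = u_measured), ga)
  expect_equal(trap, tiac_from_model(m, ga), tolerance = 5e-3)
})

test_that("bladder cumulated activity matches closed forms and a brute-force oracle", {
  # constant inflow k per hour, negligible decay, single void at 3.5 h
  k <- 0.08
  inflow <- function(t_min) k * t_min / 60
  got <- bladder_cumulated_activity(inflow, void_times_h = 3.5,
                                    nuclide = no_decay_nuclide(),
                                    horizon_h = 3.5)
  expect_equal(got, k * 3.5^2 / 2, tolerance = 1e-4)
  # zero inflow
  expect_equal(bladder_cumulated_activity(function(t) 0 * t,
                                          nuclide = ga), 0)
  # bi-exponential excretion versus a fine-grid numerical integral
  f <- function(t) 0.2 * (1 - exp(-log(2) / 60 * t)) +
    0.05 * (1 - exp(-log(2) / 300 * t))
  got <- bladder_cumulated_activity(f, void_times_h = c(3.5, 7), nuclide = ga)
  tg <- seq(0, 3000, by = 0.01)
  reset <- ifelse(tg >= 420, f(420), ifelse(tg >= 210, f(210), 0))
  content <- (f(tg) - reset) * exp(-lam * tg)
  oracle <- sum((head(content, -1) + tail(content, -1)) / 2 * diff(tg)) / 60
  expect_equal(got, oracle, tolerance = 0.01)
})

test_that("bladder schedule validation rejects misconfigured voids", {
  expect_error(bladder_cumulated_activity(function(t) t, void_times_h = c(7, 3.5)),
               class = "psmadosim_config_error")
  df <- data.frame(time_min = c(300, 400), value = c(0.1, 0.2))
  expect_error(bladder_cumulated_activity(df, void_times_h = 3.5),
               class = "psmadosim_config_error")
})

test_that("remainder bookkeeping conserves, clips, and rejects inconsistency", {
  expect_equal(remainder_retention(organs = 0.6, blood = 0.2,
                                   bladder_content = 0.1, urine = 0.1), 0)
  expect_equal(remainder_retention(organs = 0), 1)
  expect_warning(out <- remainder_retention(organs = 0.9, blood = 0.14),
                 "clipped")
  expect_equal(out, 0)
  expect_error(remainder_retention(organs = 0.9, blood = 0.2),
               class = "psmadosim_domain_error")
  # vectorised over time points
  expect_equal(remainder_retention(organs = c(0.2, 0.3), blood = c(0.1, 0)),
               c(0.7, 0.7))
})

test_that("TIAC mass rescaling follows the equal-concentration assumption", {
  expect_equal(scale_tiac_to_mass(0.23, 2360, 1000), 0.0975, tolerance = 1e-3)
  expect_equal(round(scale_tiac_to_mass(0.23, 2360, 1000), 2), 0.10)
  expect_error(scale_tiac_to_mass(0.23, 0, 1000),
               class = "psmadosim_domain_error")
})
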