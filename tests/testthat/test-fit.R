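test_that("noiseless constrained bi-exponential recovers the blood half-lives", {
  m <- blood_truth_model()
  pts <- data.frame(time_min = blood_schedule_min,
                    value = predict(m, blood_schedule_min))
  fit <- fit_retention(pts, n_components = 2, constrain_unity = TRUE)
  hl <- sort(fit$components$half_life_min)
  expect_equal(hl[1], 6.5, tolerance = 1e-3)
  expect_equal(hl[2] / 60, 4.4, tolerance = 1e-3)
  amps <- fit$components$amplitude[order(fit$components$half_life_min)]
  expect_equal(amps, c(0.91, 0.09), tolerance = 1e-3)
  expect_equal(sum(fit$components$amplitude), 1, tolerance = 1e-9)
})

test_that("noiseless mono-exponential is recovered exactly", {
  t <- c(0, 15, 30, 60, 120, 240)
  pts <- data.frame(time_min = t, value = 0.2 * exp(-log(2) / 60 * t))
  fit <- fit_retention(pts, n_components = 1)
  expect_equal(fit$components$amplitude, 0.2, tolerance = 1e-6)
  expect_equal(fit$components$rate_per_min, log(2) / 60, tolerance = 1e-6)
})

test_that("constant data degenerate to a zero-rate single component", {
  pts <- data.frame(time_min = c(0, 60, 120, 240), value = 0.35)
  fit <- fit_retention(pts, n_components = 1)
  expect_equal(fit$components$rate_per_min, 0, tolerance = 1e-8)
  expect_equal(fit$components$amplitude, 0.35, tolerance = 1e-8)
})

test_that("uptake-washout pairs are recovered from noiseless organ curves", {
  lu <- log(2) / 5; lw <- log(2) / 300
  t <- c(0, 10, 20, 30, 90, 180, 255)
  pts <- data.frame(time_min = t, value = 0.08 * (exp(-lw * t) - exp(-lu * t)))
  fit <- fit_retention(pts, n_components = 2, washin = TRUE)
  expect_true(fit$washin)
  expect_equal(sum(fit$components$amplitude), 0, tolerance = 1e-9)
  expect_equal(sort(fit$components$rate_per_min), sort(c(lu, lw)),
               tolerance = 1e-4)
  # noiseless TIAC round trip through the closed form
  truth <- 0.08 * (1 / (lw + decay_constant(67.71)) -
                     1 / (lu + decay_constant(67.71))) / 60
  expect_equal(tiac_from_model(fit), truth, tolerance = 1e-4)
})

test_that("model order is chosen by F-test when unspecified", {
  t <- c(2, 5, 10, 20, 30, 45, 85, 175, 245)
  bi <- 0.9 * exp(-0.1 * t) + 0.1 * exp(-0.002 * t)
  fit_bi <- fit_retention(data.frame(time_min = t, value = bi))
  expect_equal(fit_bi$n_components, 2)

  mono <- 0.5 * exp(-0.01 * t)
  set.seed(42)
  mono_noisy <- mono * (1 + rnorm(length(t), 0, 0.02))
  fit_mono <- fit_retention(data.frame(time_min = t, value = mono_noisy))
  expect_equal(fit_mono$n_components, 1)
})

test_that("underdetermined and invalid fits fail loudly", {
  expect_error(
    fit_retention(data.frame(time_min = c(0, 10, 20), value = c(1, 0.5, 0.3)),
                  n_components = 2),
    class = "psmadosim_fit_failure")
  expect_error(
    fit_retention(data.frame(time_min = c(0, 10), value = c(1, -0.5)),
                  n_components = 1),
    class = "psmadosim_domain_error")
})

test_that("fit accessors expose tidy components and fit summary", {
  m <- blood_truth_model()
  pts <- data.frame(time_min = blood_schedule_min,
                    value = predict(m, blood_schedule_min))
  fit <- fit_retention(pts, 2, constrain_unity = TRUE, organ = "blood")
  td <- tidy(fit)
  expect_named(td, c("term", "organ", "amplitude", "rate_per_min",
                     "half_life_min"))
  gl <- glance(fit)
  expect_equal(gl$n, length(blood_schedule_min))
  expect_true(gl$converged)
  expect_lt(gl$sse, 1e-12)
  expect_s3_class(autoplot(fit), "ggplot")
})
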