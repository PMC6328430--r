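ga <- ga68_decay_data()

test_that("sphere geometry derives the radius and validates inputs", {
  s <- sphere_spec(0.7)
  expect_equal(s$radius_cm, (3 * 0.7 / (4 * pi))^(1 / 3))
  expect_error(sphere_spec(0), class = "psmadosim_domain_error")
  expect_error(sphere_spec(1, density_g_per_cm3 = -1),
               class = "psmadosim_domain_error")
  expect_error(sphere_self_dose(s, ga, n_histories = 100),
               class = "psmadosim_domain_error")
})

test_that("unit conversions between per-decay and per-MBq.h are exact", {
  expect_equal(per_decay_to_per_mbq_h(1.19e-10), 428.4)
  expect_equal(round(per_decay_to_per_mbq_h(1.19e-10)), 428)
  expect_equal(per_decay_to_per_mbq_h(0), 0)
  expect_equal(per_decay_to_per_mbq_h(1 / 3.6e9), 1000)
  expect_error(per_decay_to_per_mbq_h(-1), class = "psmadosim_domain_error")
})

test_that("lacrimal coefficient splits the pair TIAC over two glands", {
  expect_equal(lacrimal_dose_coefficient(0.00053, 428), 0.113, tolerance = 1e-2)
  expect_equal(round(lacrimal_dose_coefficient(0.00053, 428), 2), 0.11)
  expect_equal(lacrimal_dose_coefficient(0, 428), 0)
  # highest-TIAC patient lands at the top of the published range
  expect_equal(lacrimal_dose_coefficient(0.00093, 428), 0.199, tolerance = 1e-2)
  expect_lte(lacrimal_dose_coefficient(0.00093, 428), 0.2)
  expect_error(lacrimal_dose_coefficient(-0.001, 428),
               class = "psmadosim_domain_error")
})

test_that("self-dose Monte Carlo is seed-reproducible and conserves energy", {
  a <- sphere_self_dose(sphere_spec(0.7), ga, n_histories = 2e4, seed = 99)
  b <- sphere_self_dose(sphere_spec(0.7), ga, n_histories = 2e4, seed = 99)
  expect_identical(a, b)
  expect_lte(a$max_history_excess_MeV, 0)
  expect_lte(a$deposited_MeV_per_decay, a$emitted_MeV_per_decay)
  c <- sphere_self_dose(sphere_spec(0.7), ga, n_histories = 2e4, seed = 100)
  expect_false(identical(a$dose_per_decay_Gy, c$dose_per_decay_Gy))
})

test_that("electron absorbed fraction approaches 1 for body-scale spheres", {
  big <- sphere_self_dose(sphere_spec(7e4), ga, n_histories = 5e4, seed = 3)
  expect_gt(big$electron_af, 0.99)
})

test_that("electron absorbed fraction decreases monotonically with mass", {
  masses <- c(100, 10, 1, 0.1)
  afs <- vapply(masses, function(m)
    sphere_self_dose(sphere_spec(m), ga, n_histories = 5e4,
                     seed = 7)$electron_af, numeric(1))
  expect_true(all(diff(afs) < 0))
})

test_that("the 0.7-g gland sphere reproduces the published dose factor", {
  res <- sphere_self_dose(sphere_spec(0.7), ga, n_histories = 2e5, seed = 1)
  expect_equal(res$dose_per_decay_Gy, 1.19e-10, tolerance = 0.15)
  expect_true(res$converged)
  td <- tidy(res)
  expect_equal(td$dose_rate_mGy_per_MBq_h,
               per_decay_to_per_mbq_h(res$dose_per_decay_Gy))
})

test_that("gland-lens geometry rejects overlapping spheres", {
  expect_error(gland_lens_geometry(center_separation_mm = 5),
               class = "psmadosim_geometry_error")
  g <- gland_lens_geometry()
  expect_equal(g$center_separation_mm, 24)
})

test_that("positrons cannot reach the lens across a gap beyond their range", {
  # default geometry: surface gap ~14.9 mm > 9.2 mm maximum positron range
  res <- lens_dose_from_gland(gland_lens_geometry(), ga, n_histories = 5e4,
                              seed = 5)
  expect_identical(res$electron_af, 0)
  expect_gt(res$dose_per_decay_Gy, 0)
})

test_that("lens dose is photon-dominated with a 511-keV share above 90%", {
  res <- lens_dose_from_gland(gland_lens_geometry(), ga, n_histories = 2e5,
                              seed = 6)
  expect_gte(res$photon_share, 0.90)
  # order of magnitude of the published lens dose factor
  expect_gt(res$dose_per_decay_Gy, 5.37e-15)
  expect_lt(res$dose_per_decay_Gy, 5.37e-13)
})

test_that("lens dose decreases when the separation doubles", {
  near <- lens_dose_from_gland(gland_lens_geometry(), ga,
                               n_histories = 1e5, seed = 8)
  far <- lens_dose_from_gland(
    gland_lens_geometry(center_separation_mm = 48), ga,
    n_histories = 1e5, seed = 8)
  expect_lt(far$dose_per_decay_Gy, near$dose_per_decay_Gy)
})

test_that("gland self-dose dwarfs its cross-dose to the lens", {
  self <- sphere_self_dose(sphere_spec(0.7), ga, n_histories = 5e4, seed = 12)
  cross <- lens_dose_from_gland(gland_lens_geometry(), ga,
                                n_histories = 5e4, seed = 12)
  lac <- lacrimal_dose_coefficient(
    0.00053, per_decay_to_per_mbq_h(self$dose_per_decay_Gy))
  lens_from_gland <- 0.00053 *
    per_decay_to_per_mbq_h(cross$dose_per_decay_Gy)
  # the lens receives its 0.0051 mGy/MBq almost entirely from elsewhere
  expect_gt(0.0051 / lens_from_gland, 10)
  expect_gt(lac / lens_from_gland, 10)
})
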