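ga <- ga68_decay_data()

test_that("s_value is the yield-energy-SAF contraction with unit conversion", {
  # zero SAF -> zero S
  nuc <- new_nuclide("P1", 60, tibble::tibble(kind = "photon", yield = 1,
                                              energy_MeV = 0.5))
  safs0 <- tibble::tibble(source = "a", target = "a", particle = "photon",
                          energy_MeV = 0.5, saf_per_kg = c(1e-9, 0))
  safs0 <- safs0[2, ]
  # keep the validator happy with a positive self-SAF elsewhere
  expect_equal(s_value("a", "a", nuc, safs0), 0)

  # 1 MeV electron, yield 1, SAF 1/kg -> 1 MeV/kg per decay
  nuc_e <- new_nuclide("E1", 60, tibble::tibble(kind = "electron", yield = 1,
                                                energy_MeV = 1))
  safs1 <- tibble::tibble(source = "m", target = "m", particle = "electron",
                          energy_MeV = 1, saf_per_kg = 1)
  expect_equal(s_value("m", "m", nuc_e, safs1), 1.602e-13, tolerance = 1e-3)

  # 68Ga electrons only in a 422-g region with SAF = 1/m
  safs2 <- dplyr::bind_rows(
    tibble::tibble(source = "kidneys", target = "kidneys",
                   particle = "electron", energy_MeV = 0.836,
                   saf_per_kg = 1 / 0.422),
    tibble::tibble(source = "kidneys", target = "kidneys",
                   particle = "photon", energy_MeV = c(0.511, 1.0772),
                   saf_per_kg = 0))
  expect_equal(s_value("kidneys", "kidneys", ga, safs2), 2.82e-13,
               tolerance = 0.005)
})

test_that("missing SAF pairs raise a lookup error naming the pair", {
  safs <- tibble::tibble(source = "a", target = "a", particle = "electron",
                         energy_MeV = 1, saf_per_kg = 1)
  nuc_e <- new_nuclide("E1", 60, tibble::tibble(kind = "electron", yield = 1,
                                                energy_MeV = 1))
  expect_error(s_value("a", "b", nuc_e, safs), "a -> b",
               class = "psmadosim_lookup_error")
  nuc_p <- new_nuclide("P1", 60, tibble::tibble(kind = "photon", yield = 1,
                                                energy_MeV = 0.5))
  expect_error(s_value("a", "a", nuc_p, safs), "photon",
               class = "psmadosim_lookup_error")
})

test_that("simplified SAFs behave physically", {
  masses <- tibble::tibble(
    organ = c("small", "mid", "kidneys", "total_body"),
    mass_g = c(0.7, 50, 422, 70000))
  safs <- simplified_saf(masses, ga, n_histories = 2e4, seed = 11)
  expect_silent(validate_saf_table(safs))

  # electron self-SAF of the whole body approaches 1/mass
  tb <- safs$saf_per_kg[safs$source == "total_body" &
                          safs$target == "total_body" &
                          safs$particle == "electron"]
  expect_equal(tb, 1 / 70, tolerance = 0.02)

  # lacrimal-scale absorbed fraction ~0.7
  small <- safs$saf_per_kg[safs$source == "small" & safs$target == "small" &
                             safs$particle == "electron"]
  expect_equal(small * 0.0007, 0.7, tolerance = 0.1)

  # photon self-SAF times mass (the absorbed fraction) grows with organ mass
  photon_self <- safs |>
    dplyr::filter(.data$source == .data$target, .data$particle == "photon",
                  .data$energy_MeV < 0.6) |>
    dplyr::left_join(masses, by = c(source = "organ")) |>
    dplyr::arrange(.data$mass_g)
  expect_true(all(diff(photon_self$saf_per_kg * photon_self$mass_g / 1000) > 0))

  # electron cross-fire is explicitly zero
  cross_e <- safs$saf_per_kg[safs$source != safs$target &
                               safs$particle == "electron"]
  expect_true(all(cross_e == 0))
})

test_that("absorbed dose is the MIRD matrix-vector product", {
  # unit identity: 1 h of TIAC at S = 1e-13 Gy/Bq.s -> 0.36 mGy/MBq
  tiacs <- tibble::tibble(patient_id = "P1", organ = "kidneys", tiac_h = 1)
  sv <- tibble::tibble(source = "kidneys", target = "kidneys",
                       gy_per_bq_s = 1e-13)
  rep <- absorbed_dose(tiacs, sv)
  expect_equal(rep$per_patient$dose_mGy_per_MBq, 0.36)
  # zero TIAC -> zero everywhere
  rep0 <- absorbed_dose(dplyr::mutate(tiacs, tiac_h = 0), sv)
  expect_equal(rep0$per_patient$dose_mGy_per_MBq, 0)
  # unknown source region is a named error
  expect_error(absorbed_dose(dplyr::mutate(tiacs, organ = "pancreas"), sv),
               "pancreas", class = "psmadosim_lookup_error")
})

test_that("engine doses match a hand-computed product on the bundled fixture", {
  sv <- read_svalue_csv(system.file("extdata", "svalues_3organ_synthetic.csv",
                                    package = "psmadosim"))
  tiacs <- tibble::tibble(patient_id = "P1", organ = c("A", "B", "C"),
                          tiac_h = c(0.2, 0.1, 0.05))
  rep <- absorbed_dose(tiacs, sv)
  # oracle: explicit S-matrix product, independent of the join-based engine
  smat <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  for (i in seq_len(nrow(sv))) smat[sv$target[i], sv$source[i]] <- sv$gy_per_bq_s[i]
  oracle <- drop(smat %*% c(0.2, 0.1, 0.05)) * 3.6e9 * 1e3
  got <- setNames(rep$per_patient$dose_mGy_per_MBq, rep$per_patient$organ)
  expect_equal(got[c("A", "B", "C")], oracle[c("A", "B", "C")])
  # frozen spot value: dose to A = 3.6e12 * (0.2*2e-13 + 0.1*1.5e-15 + 0.05*2.5e-15)
  expect_equal(unname(got["A"]), 0.14499, tolerance = 1e-6)
})

test_that("dose scales linearly in the TIACs", {
  sv <- read_svalue_csv(system.file("extdata", "svalues_3organ_synthetic.csv",
                                    package = "psmadosim"))
  tiacs <- tibble::tibble(patient_id = "P1", organ = c("A", "B", "C"),
                          tiac_h = c(0.2, 0.1, 0.05))
  d1 <- absorbed_dose(tiacs, sv)$per_patient$dose_mGy_per_MBq
  d2 <- absorbed_dose(dplyr::mutate(tiacs, tiac_h = 2 * tiac_h),
                      sv)$per_patient$dose_mGy_per_MBq
  expect_equal(d2, 2 * d1)
})

test_that("tissue weights sum to one and effective dose preserves uniform fields", {
  for (scheme in c("ICRP103", "ICRP60")) {
    w <- tissue_weights(scheme)
    expect_equal(sum(w$w_T), 1, tolerance = 1e-12)
    # uniform organ dose d must give E = d under any complete weighting
    uni <- dplyr::mutate(psma11_dose_coefficients(),
                         median_mGy_per_MBq = 0.02)
    e <- effective_dose(uni, w)
    expect_equal(e$effective_dose_mSv_per_MBq, 0.02, tolerance = 1e-12)
  }
  bad <- tissue_weights("ICRP103")
  bad$w_T[1] <- bad$w_T[1] + 0.1
  expect_error(effective_dose(psma11_dose_coefficients(), bad),
               class = "psmadosim_config_error")
})

test_that("effective dose from the published medians matches the reported value", {
  e103 <- effective_dose(psma11_dose_coefficients())
  expect_equal(e103$scheme, "ICRP103")
  expect_equal(e103$effective_dose_mSv_per_MBq, 0.022, tolerance = 0.15)
  e60 <- effective_dose(psma11_dose_coefficients(), tissue_weights("ICRP60"))
  expect_equal(e60$effective_dose_mSv_per_MBq,
               e103$effective_dose_mSv_per_MBq, tolerance = 0.10)
  # E lies between the extreme organ coefficients entering it
  rng <- range(psma11_dose_coefficients()$median_mGy_per_MBq)
  expect_gt(e103$effective_dose_mSv_per_MBq, rng[1])
  expect_lt(e103$effective_dose_mSv_per_MBq, rng[2])
})

test_that("administration arithmetic multiplies through", {
  expect_equal(dose_for_administration(0.022, 2, 80), 3.52)
  expect_equal(signif(dose_for_administration(0.022, 2, 80), 2), 3.5)
  expect_equal(dose_for_administration(0.24, administered_MBq = 160), 38.4)
  expect_equal(signif(dose_for_administration(0.24, administered_MBq = 160), 1),
               40)
  expect_equal(dose_for_administration(0.24, administered_MBq = 0), 0)
  expect_error(dose_for_administration(0.24, -2, 80),
               class = "psmadosim_domain_error")
})
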