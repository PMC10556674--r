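test_that("elimination constant matches the two-point formula", {
  # half-life case: halving in 7 days
  expect_equal(elimination_constant(500, 250, 7), log(2) / 7)
  expect_equal(elimination_constant(600, 600, 7), 0)
  expect_equal(elimination_constant(600, 230.9, 7), 0.13642,
               tolerance = 1e-4)
  expect_error(elimination_constant(-5, 100, 7), "positive")
  expect_warning(k <- elimination_constant(100, 200, 7), "negative")
  expect_lt(k, 0)
})

test_that("dilution space is the dose-to-enrichment ratio", {
  expect_equal(dilution_space(1, 100000, 0, 50, 0), 2000)
  # linear in the dose
  expect_equal(dilution_space(2, 100000, 0, 50, 0), 4000)
  # 0.5 mol at enrichment ratio 4000 -> 2000 mol = 36.04 kg
  n <- dilution_space(0.5, 4000, 0, 1, 0)
  expect_equal(n, 2000)
  expect_equal(n * 18.02 / 1000, 36.04)
  expect_error(dilution_space(1, 100000, 0, 5, 10), "enrichment")
})

test_that("TBW averages the exchange-corrected spaces", {
  x <- 35
  expect_equal(tbw_from_spaces(1.041 * x, 1.007 * x), x)
  expect_equal(tbw_from_spaces(37.0, 36.2), 35.7456, tolerance = 1e-4)
  # monotone in both spaces
  base <- tbw_from_spaces(37, 36.2)
  expect_gt(tbw_from_spaces(37.5, 36.2), base)
  expect_gt(tbw_from_spaces(37, 36.7), base)
  expect_error(tbw_from_spaces(-1, 36), "positive")
})

test_that("body composition splits weight via the hydration factor", {
  bc <- body_composition(35.7456, 57.8)
  expect_equal(bc$ffm_kg, 48.833, tolerance = 1e-4)
  expect_equal(bc$fm_kg, 8.967, tolerance = 1e-4)
  expect_equal(bc$ffm_kg + bc$fm_kg, 57.8)
  # boundary: fully lean body
  bc0 <- body_composition(0.732 * 60, 60)
  expect_equal(bc0$fm_kg, 0)
  expect_warning(body_composition(50, 57.8), "exceeds body weight")
})

test_that("QC ratios flag excursions outside the configured ranges", {
  kin <- list(N_d = 37.0, N_O = 36.2, k_O = 0.12, k_d = 0.10)
  qc <- qc_ratios(kin)
  expect_equal(qc$dilution_space_ratio, 37 / 36.2)
  expect_equal(qc$elimination_rate_ratio, 1.2)
  expect_length(qc$flags, 0)

  low <- qc_ratios(list(N_d = 0.995 * 36, N_O = 36, k_O = 0.12, k_d = 0.1))
  expect_true("dsr_below_low" %in% low$flags)

  # widening a range never adds a flag
  cfg_wide <- dlw_config(dsr_low = 0.9, err_high = 2.0)
  kin_bad <- list(N_d = 0.95 * 36, N_O = 36, k_O = 0.19, k_d = 0.1)
  f_narrow <- qc_ratios(kin_bad)$flags
  f_wide <- qc_ratios(kin_bad, cfg_wide)$flags
  expect_true(all(f_wide %in% f_narrow))
})

test_that("Speakman and Weir equations reproduce hand-computed values", {
  r <- rco2_speakman(1998, 0.12, 0.10)
  expect_equal(r, 0.4554 * 1998 * (1.007 * 0.12 - 1.043 * 0.10) * 22.26)
  expect_equal(r, 335.0, tolerance = 1e-4)
  # zero crossing and linearity in N
  expect_equal(rco2_speakman(1000, 1.043 * 0.1 / 1.007, 0.1), 0)
  expect_equal(rco2_speakman(3996, 0.12, 0.10), 2 * r)

  expect_equal(tdee_weir(335.0, 0.85), 335.0 * (1.106 + 3.94 / 0.85))
  expect_equal(tdee_weir(335.0, 0.85), 1923.3, tolerance = 1e-4)
  expect_equal(tdee_weir(0, 0.85), 0)
  expect_equal(tdee_weir(100, 1.0), 504.6)
  # TDEE decreasing in RQ at fixed rCO2
  expect_lt(tdee_weir(335, 1.0), tdee_weir(335, 0.8))
  expect_error(tdee_weir(100, -1), "rq")
})

test_that("two-point run recovers the generator's truth without noise", {
  cfg <- simulation_config(n_participants = 10, seed = 42)
  co <- simulate_cohort(cfg)
  iso <- simulate_isotope_kinetics(co$truth, cfg)
  kt <- attr(iso, "kinetics_truth")
  for (i in c(1, 5, 10)) {
    res <- run_two_point(iso[i, ], co$participants$weight_start_kg[i])
    expect_equal(res$tdee_kcal, co$truth$true_tdee[i], tolerance = 1e-6)
    expect_equal(res$kinetics$k_O, kt$k_O[i], tolerance = 1e-9)
    expect_equal(res$kinetics$k_d, kt$k_d[i], tolerance = 1e-9)
    expect_equal(res$kinetics$N, kt$N_mol[i], tolerance = 1e-6)
    expect_equal(res$body_composition$tbw_kg, co$truth$true_tbw_kg[i],
                 tolerance = 1e-9)
    # unit coherence: kg = mol * molar mass
    expect_equal(res$kinetics$N_O_kg,
                 res$kinetics$N_O * 18.02 / 1000, tolerance = 1e-12)
  }

  # missing field named in the error
  broken <- as.list(iso[1, ])
  broken$E_final_d2 <- NA
  expect_error(run_two_point(broken, 57.8), "E_final_d2")
})

test_that("cohort run yields one positive TDEE per participant", {
  cfg <- simulation_config(seed = 11)
  co <- simulate_cohort(cfg)
  iso <- simulate_isotope_kinetics(co$truth, cfg)
  res <- run_dlw_cohort(iso, co$participants)
  expect_equal(nrow(res), 30L)
  expect_true(all(res$tdee_kcal > 0))
  expect_true(all(res$qc_flags == ""))
  expect_equal(res$tdee_kcal, co$truth$true_tdee, tolerance = 1e-6)
})
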