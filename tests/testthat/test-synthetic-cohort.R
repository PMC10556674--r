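test_that("cohort generation is deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 123)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$participants, b$participants)
  expect_identical(a$truth, b$truth)
  c2 <- simulate_cohort(simulation_config(seed = 124))
  expect_false(identical(a$participants$weight_start_kg,
                         c2$participants$weight_start_kg))
})

test_that("anthropometric draws respect the configured distributions", {
  co <- simulate_cohort(simulation_config(n_participants = 10000, seed = 2))
  p <- co$participants
  expect_equal(mean(p$weight_start_kg), 57.8, tolerance = 0.2 / 57.8)
  bmi <- p$weight_start_kg / (p$height_cm / 100)^2
  expect_true(all(bmi >= 18.5 & bmi <= 24.9))
  expect_true(all(p$age_y >= 18 & p$age_y <= 45))
  # body composition identity and positivity
  expect_true(all(co$truth$true_fm_kg > 0))
  expect_equal(co$truth$true_ffm_kg + co$truth$true_fm_kg,
               p$weight_start_kg, tolerance = 1e-12)
  expect_equal(co$truth$true_tbw_kg, 0.732 * co$truth$true_ffm_kg,
               tolerance = 1e-12)
})

test_that("simulated kinetics stay in the physiological QC band and invert", {
  cfg <- simulation_config(seed = 29)
  co <- simulate_cohort(cfg)
  iso <- simulate_isotope_kinetics(co$truth, cfg)
  kt <- attr(iso, "kinetics_truth")
  err <- kt$k_O / kt$k_d
  expect_true(all(err > 1.100 & err < 1.700))
  res <- run_dlw_cohort(iso, co$participants)
  expect_equal(res$tdee_kcal, co$truth$true_tdee, tolerance = 1e-6)
  expect_true(all(res$dilution_space_ratio > 1.000 &
                    res$dilution_space_ratio < 1.070))
})

test_that("enrichment noise leaves recovered TDEE unbiased within 1%", {
  n_rep <- 50
  rel_err <- numeric(0)
  for (s in seq_len(n_rep)) {
    cfg <- simulation_config(seed = 1000 + s, n_participants = 10,
                             enrichment_noise = 0.02)
    co <- simulate_cohort(cfg)
    iso <- simulate_isotope_kinetics(co$truth, cfg)
    res <- run_dlw_cohort(iso, co$participants)
    rel_err <- c(rel_err,
                 (res$tdee_kcal - co$truth$true_tdee) / co$truth$true_tdee)
  }
  expect_lt(abs(mean(rel_err)), 0.01)
})

test_that("zero-bias reporting reproduces the true intake exactly", {
  cfg <- simulation_config(seed = 53, n_participants = 5,
                           app_bias_mu = 0, app_bias_sd = 0,
                           day_noise_sd = 0)
  co <- simulate_cohort(cfg)
  occ <- simulate_reported_intake(co$truth, cfg, "app")
  daily <- aggregate_daily(occ)
  for (i in 1:5) {
    d <- daily[daily$participant_id == co$truth$participant_id[i], ]
    expect_equal(d$tdei_kcal[order(d$day)],
                 co$truth$true_daily_intake[[i]], tolerance = 1e-9)
  }
  expect_true(all(daily$occasions_n >= 3 & daily$occasions_n <= 9))
})

test_that("pooled within-subject CV recovers the configured value", {
  cvs <- vapply(1:30, function(s) {
    cfg <- simulation_config(seed = 2000 + s, app_bias_mu = 0,
                             app_bias_sd = 0)
    co <- simulate_cohort(cfg)
    occ <- simulate_reported_intake(co$truth, cfg, "app")
    series <- intake_series(aggregate_daily(occ))
    pooled_cv(series$cv_i)
  }, numeric(1))
  expect_lt(abs(mean(cvs) - 42.55), 5)
})

test_that("energy-balance mode couples weight change to the intake gap", {
  cfg <- simulation_config(seed = 59, energy_balance = TRUE)
  co <- simulate_cohort(cfg)
  tr <- co$truth
  # invertible through the energy-store coefficients
  expect_equal(delta_energy_stores(tr$d_fm_kg, tr$d_ffm_kg, cfg$days),
               tr$mean_intake - tr$true_tdee, tolerance = 1e-9)
  expect_equal(co$participants$weight_end_kg -
                 co$participants$weight_start_kg,
               tr$weight_change_kg, tolerance = 1e-12)
})

test_that("bundle writing and re-reading round-trips the interchange tables", {
  dir <- tempfile("bundle")
  b <- simulate_study(simulation_config(seed = 61, n_participants = 4))
  write_bundle(b, dir)
  p <- read_participants(file.path(dir, "participants.csv"))
  expect_identical(p$weight_start_kg, b$participants$weight_start_kg)
  iso <- read_isotopes(file.path(dir, "isotopes.csv"))
  expect_identical(iso$E_post_o18, b$isotopes$E_post_o18)
  occ <- read_occasions(file.path(dir, "occasions.csv"))
  expect_equal(nrow(occ), nrow(b$occasions))
  rec <- read_recall24(file.path(dir, "recall24.csv"))
  expect_identical(rec$tdei_kcal, b$recall24$tdei_kcal)
  unlink(dir, recursive = TRUE)
})
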