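#' Simulation configuration
#'
#' Defines the study conditions the synthetic cohort emulates: 30 adult
#' women of normal weight (BMI 18.5-24.9 kg/m2), seven days of app-based
#' intake recording plus a single-day 24-hour recall, and a 7-day DLW
#' measurement of energy expenditure. Defaults reproduce the reference
#' cohort's anthropometrics (age 28.5 +/- 6.7 y, height 1.63 +/- 0.07 m,
#' weight 57.8 +/- 6.1 kg), expenditure (2235.2 +/- 456.5 kcal/day),
#' day-to-day intake variability (within-subject CV 42.55%) and the
#' tool-specific reporting biases (app -329.6 +/- 599.1, recall
#' -543.0 +/- 642.6 kcal/day, participant-level mean +/- SD).
#'
#' @param n_participants Cohort size (default 30).
#' @param seed Integer seed; every draw is derived from it through named
#'   substreams.
#' @param age_mean,age_sd Age distribution, years; truncated to
#'   `age_range`.
#' @param age_range Admissible age range (default 18-45 y).
#' @param height_mean,height_sd Height distribution, m.
#' @param weight_mean,weight_sd Body-weight distribution, kg.
#' @param bmi_range BMI bounds enforced on every draw (default
#'   18.5-24.9 kg/m2).
#' @param bf_mean,bf_sd Body-fat fraction distribution (default
#'   0.27 +/- 0.04, truncated to 0.15-0.40).
#' @param tdee_mean,tdee_sd True TDEE distribution, kcal/day; truncated
#'   below at `min_pal` times BMR.
#' @param min_pal Lower PAL bound for the TDEE truncation (default 1.2).
#' @param within_cv Within-subject day-to-day CV of true intake, percent.
#' @param days Number of recording days (default 7).
#' @param app_bias_mu,app_bias_sd Participant-level reporting bias of the
#'   app, kcal/day.
#' @param recall_bias_mu,recall_bias_sd Participant-level reporting bias
#'   of the 24-hour recall, kcal/day.
#' @param day_noise_sd Day-level reporting noise, kcal (default 0).
#' @param energy_balance Couple intake to expenditure through the energy
#'   stores: the participant-level intake-expenditure imbalance drives the
#'   week's weight change through the 9.5/1.1 kcal/g coefficients
#'   (default `TRUE`).
#' @param eb_flux_sd SD of the participant-level energy imbalance,
#'   kcal/day (default 150).
#' @param fm_fraction Fraction of short-term mass change attributed to fat
#'   mass (default 0.75).
#' @param enrichment_noise Relative SD of multiplicative measurement noise
#'   on the isotope enrichments (default 0 = noise-free).
#' @param err_ratio_range Range the simulated elimination rate ratio
#'   k_O/k_d is drawn from (default 1.20-1.35, inside the 1.193-1.366
#'   physiological band).
#' @param occasions_app_mean,occasions_app_sd Eating occasions per day
#'   recorded with the app (default 7.5 +/- 1.9, clipped to 3-9).
#' @param occasions_recall_mean,occasions_recall_sd Eating occasions on
#'   the recall day (default 4.6 +/- 1.3, clipped to 1-8).
#' @param smoker_prob Probability of being a smoker (default 0.1).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_participants = 30L,
                              seed = 1L,
                              age_mean = 28.5, age_sd = 6.7,
                              age_range = c(18, 45),
                              height_mean = 1.63, height_sd = 0.07,
                              weight_mean = 57.8, weight_sd = 6.1,
                              bmi_range = c(18.5, 24.9),
                              bf_mean = 0.27, bf_sd = 0.04,
                              tdee_mean = 2235.2, tdee_sd = 456.5,
                              min_pal = 1.2,
                              within_cv = 42.55,
                              days = 7L,
                              app_bias_mu = -329.6, app_bias_sd = 599.1,
                              recall_bias_mu = -543.0,
                              recall_bias_sd = 642.6,
                              day_noise_sd = 0,
                              energy_balance = TRUE,
                              eb_flux_sd = 150,
                              fm_fraction = 0.75,
                              enrichment_noise = 0,
                              err_ratio_range = c(1.20, 1.35),
                              occasions_app_mean = 7.5,
                              occasions_app_sd = 1.9,
                              occasions_recall_mean = 4.6,
                              occasions_recall_sd = 1.3,
                              smoker_prob = 0.1) {
  if (n_participants < 2) {
    stop("simulation_config: n_participants must be >= 2", call. = FALSE)
  }
  sds <- c(age_sd, height_sd, weight_sd, bf_sd, tdee_sd, app_bias_sd,
           recall_bias_sd, day_noise_sd, eb_flux_sd, enrichment_noise)
  if (any(sds < 0)) {
    stop("simulation_config: SDs must be >= 0", call. = FALSE)
  }
  if (within_cv < 0) {
    stop("simulation_config: within_cv must be >= 0", call. = FALSE)
  }
  cfg <- as.list(environment())
  cfg$n_participants <- as.integer(n_participants)
  cfg$seed <- as.integer(seed)
  cfg$days <- as.integer(days)
  structure(cfg, class = "simulation_config")
}

# Deterministic substream seed below 2^31, derived from the global seed and
# a stream name.
sub_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) %% 65536 * 30269 + h * 30307 + 17) %%
               2147483563)
}

rnorm_trunc <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  if (sd == 0) {
    x <- rep(mean, n)
    if (any(x < lower | x > upper)) {
      stop("rnorm_trunc: degenerate draw outside truncation bounds",
           call. = FALSE)
    }
    return(x)
  }
  pl <- stats::pnorm(lower, mean, sd)
  pu <- stats::pnorm(upper, mean, sd)
  if (pu - pl <= 0) {
    stop("rnorm_trunc: infeasible truncation", call. = FALSE)
  }
  stats::qnorm(pl + (pu - pl) * stats::runif(n), mean, sd)
}

#' Simulate a study cohort
#'
#' Draws anthropometrics, body composition and true energy expenditure for
#' `n_participants`, together with the latent quantities the validation
#' estimators are benchmarked against: true total body water, true daily
#' intake over the recording week (lognormal day-to-day variation at the
#' configured within-subject CV), and - in energy-balance mode - the
#' week's weight change implied by the intake-expenditure imbalance
#' through the energy-store coefficients. Body weight is drawn at its
#' marginal distribution and height conditionally, so every draw respects
#' the BMI bounds.
#'
#' @param cfg A [simulation_config()].
#' @return A list with `participants` (interchange table, see
#'   [read_participants()]) and `truth` (tibble with `true_tdee`,
#'   `true_tbw_kg`, `true_ffm_kg`, `true_fm_kg`, `bmr_kcal`,
#'   `mean_intake`, `eb_flux`, `d_fm_kg`, `d_ffm_kg`, `weight_change_kg`
#'   and the list-column `true_daily_intake`).
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  set.seed(sub_seed(cfg$seed, "cohort"))
  n <- cfg$n_participants
  id <- sprintf("P%02d", seq_len(n))
  age <- rnorm_trunc(n, cfg$age_mean, cfg$age_sd, cfg$age_range[1],
                     cfg$age_range[2])
  weight <- rnorm_trunc(n, cfg$weight_mean, cfg$weight_sd, lower = 35)
  # height conditional on weight so that BMI stays inside the bounds
  h_lo <- sqrt(weight / cfg$bmi_range[2])
  h_hi <- sqrt(weight / cfg$bmi_range[1])
  height <- vapply(seq_len(n), function(i) {
    rnorm_trunc(1, cfg$height_mean, cfg$height_sd, h_lo[i], h_hi[i])
  }, numeric(1))
  bf <- rnorm_trunc(n, cfg$bf_mean, cfg$bf_sd, 0.15, 0.40)
  fm <- bf * weight
  ffm <- weight - fm
  tbw <- 0.732 * ffm
  bmr <- bmr_mifflin(weight, height * 100, age, "female")
  tdee <- vapply(seq_len(n), function(i) {
    rnorm_trunc(1, cfg$tdee_mean, cfg$tdee_sd, lower = cfg$min_pal * bmr[i])
  }, numeric(1))
  smoker <- stats::runif(n) < cfg$smoker_prob
  band <- sample(.activity_bands, n, replace = TRUE,
                 prob = c(0.17, 0.17, 0.53, 0.13))

  if (cfg$energy_balance) {
    eb_flux <- stats::rnorm(n, 0, cfg$eb_flux_sd)
    es <- energy_stores_config()
    # energy density of the mass change given the FM/FFM partition
    dens <- cfg$fm_fraction * es$kcal_per_g_fm +
      (1 - cfg$fm_fraction) * es$kcal_per_g_ffm
    dm_g <- eb_flux * cfg$days / dens
    d_fm <- cfg$fm_fraction * dm_g / 1000
    d_ffm <- (1 - cfg$fm_fraction) * dm_g / 1000
    weight_change <- dm_g / 1000
    mean_intake <- tdee + eb_flux
  } else {
    eb_flux <- rep(0, n)
    mean_intake <- tdee
    weight_change <- stats::rnorm(n, 0, 0.3)
    d_fm <- rep(NA_real_, n)
    d_ffm <- rep(NA_real_, n)
  }

  cv <- cfg$within_cv / 100
  sdlog <- sqrt(log(1 + cv^2))
  daily <- lapply(seq_len(n), function(i) {
    mean_intake[i] * stats::rlnorm(cfg$days, -sdlog^2 / 2, sdlog)
  })

  participants <- tibble::tibble(
    id = id, sex = "female", age_y = age, height_cm = height * 100,
    weight_start_kg = weight, weight_end_kg = weight + weight_change,
    smoker = smoker, activity_band = band
  )
  truth <- tibble::tibble(
    participant_id = id, true_tdee = tdee, true_tbw_kg = tbw,
    true_ffm_kg = ffm, true_fm_kg = fm, bmr_kcal = bmr,
    mean_intake = mean_intake, eb_flux = eb_flux,
    d_fm_kg = d_fm, d_ffm_kg = d_ffm, weight_change_kg = weight_change,
    within_cv = cfg$within_cv,
    true_daily_intake = daily
  )
  list(participants = participants, truth = truth)
}

#' Simulate two-point isotope kinetics for a cohort
#'
#' Inverts the DLW chain: for each participant the dilution spaces follow
#' from the true total body water (deuterium space 1.041 and oxygen space
#' 1.007 times TBW), doses follow the protocol rule (1.8 g of 10 atom%
#' H2-18O and 0.12 g of 99.9 atom% 2H2O per kg body water), and the
#' elimination constants are chosen so that the Speakman and Weir
#' equations at the configured respiratory quotient reproduce the true
#' TDEE exactly. Plateau enrichments are written as the mean of the two
#' same-day samples; optional multiplicative measurement noise perturbs
#' each individual sample.
#'
#' @param truth Truth table from [simulate_cohort()].
#' @param cfg A [simulation_config()].
#' @param dlw_cfg A [dlw_config()]; its `rq` closes the inversion.
#' @return An isotope interchange tibble (see [read_isotopes()]); the true
#'   elimination constants are attached as attribute `kinetics_truth`.
#' @export
simulate_isotope_kinetics <- function(truth, cfg = simulation_config(),
                                      dlw_cfg = dlw_config()) {
  set.seed(sub_seed(cfg$seed, "isotopes"))
  n <- nrow(truth)
  kg_per_mol <- dlw_cfg$water_molar_mass_g / 1000
  N_d_kg <- truth$true_tbw_kg * dlw_cfg$tbw_divisor_d2
  N_O_kg <- truth$true_tbw_kg * dlw_cfg$tbw_divisor_o18
  N_d_mol <- N_d_kg / kg_per_mol
  N_O_mol <- N_O_kg / kg_per_mol
  N_mol <- (N_d_mol + N_O_mol) / 2

  rco2 <- truth$true_tdee / (1.106 + 3.94 / dlw_cfg$rq)
  x <- rco2 / (dlw_cfg$speakman_coeff * N_mol * dlw_cfg$litres_per_mol_co2)
  rho <- stats::runif(n, cfg$err_ratio_range[1], cfg$err_ratio_range[2])
  k_d <- x / (dlw_cfg$o_weight * rho - dlw_cfg$d_weight)
  k_O <- rho * k_d

  dose <- dlw_dose(truth$true_tbw_kg)
  dose_o18_mol <- dose$dose_o18_g / dlw_cfg$water_molar_mass_g
  dose_d2_mol <- dose$dose_d2_g / dlw_cfg$water_molar_mass_g
  E_pre_o18 <- stats::rnorm(n, 0, 2)
  E_pre_d2 <- stats::rnorm(n, 0, 5)
  E_post_o18 <- E_pre_o18 + dose_o18_mol * dose$ape_o18 * 1e4 / N_O_mol
  E_post_d2 <- E_pre_d2 + dose_d2_mol * dose$ape_d2 * 1e4 / N_d_mol
  t_post <- 3.5
  t_final <- t_post + cfg$days * 24
  el_days <- (t_final - t_post) / 24
  E_final_o18 <- E_pre_o18 + (E_post_o18 - E_pre_o18) * exp(-k_O * el_days)
  E_final_d2 <- E_pre_d2 + (E_post_d2 - E_pre_d2) * exp(-k_d * el_days)

  # two same-day samples per time point, averaged to the plateau value
  noisy_pair <- function(e) {
    if (cfg$enrichment_noise == 0) return(e)
    s1 <- e * (1 + stats::rnorm(length(e), 0, cfg$enrichment_noise))
    s2 <- e * (1 + stats::rnorm(length(e), 0, cfg$enrichment_noise))
    plateau_enrichment(s1, s2)
  }
  out <- tibble::tibble(
    participant_id = truth$participant_id,
    dose_o18_g = dose$dose_o18_g, dose_d2_g = dose$dose_d2_g,
    ape_o18 = dose$ape_o18, ape_d2 = dose$ape_d2,
    E_pre_o18 = E_pre_o18,
    E_post_o18 = noisy_pair(E_post_o18),
    E_final_o18 = noisy_pair(E_final_o18),
    E_pre_d2 = E_pre_d2,
    E_post_d2 = noisy_pair(E_post_d2),
    E_final_d2 = noisy_pair(E_final_d2),
    t_post_h = t_post, t_final_h = t_final
  )
  attr(out, "kinetics_truth") <- tibble::tibble(
    participant_id = truth$participant_id, k_O = k_O, k_d = k_d,
    N_mol = N_mol
  )
  out
}

#' Simulate reported intake for one tool
#'
#' Reported intake is the true daily intake plus a participant-level
#' reporting bias drawn from the tool's (mu, sigma) plus optional
#' day-level noise, floored at zero. For the app the daily total is split
#' into eating occasions (each a `before` image closed by `after` or
#' `ate_everything`); the recall reports a single extra day.
#'
#' @param truth Truth table from [simulate_cohort()].
#' @param cfg A [simulation_config()].
#' @param tool `"app"` (occasion rows over the recording week) or
#'   `"recall"` (single-day totals).
#' @return For `"app"` an occasions interchange tibble (see
#'   [read_occasions()]); for `"recall"` a recall tibble (see
#'   [read_recall24()]). The participant-level biases drawn are attached
#'   as attribute `bias_truth`.
#' @export
simulate_reported_intake <- function(truth, cfg = simulation_config(),
                                     tool = c("app", "recall")) {
  tool <- match.arg(tool)
  set.seed(sub_seed(cfg$seed, paste0("intake_", tool)))
  n <- nrow(truth)
  if (tool == "app") {
    bias <- stats::rnorm(n, cfg$app_bias_mu, cfg$app_bias_sd)
    # participant-day grid
    pid <- rep(truth$participant_id, each = cfg$days)
    day <- rep(seq_len(cfg$days), times = n)
    true_day <- unlist(truth$true_daily_intake, use.names = FALSE)
    reported <- pmax(0, true_day + rep(bias, each = cfg$days) +
                       stats::rnorm(n * cfg$days, 0, cfg$day_noise_sd))
    n_occ <- round(rnorm_trunc(n * cfg$days, cfg$occasions_app_mean,
                               cfg$occasions_app_sd, 3, 9))
    out <- occasion_rows(pid, day, reported, n_occ)
  } else {
    bias <- stats::rnorm(n, cfg$recall_bias_mu, cfg$recall_bias_sd)
    cv <- cfg$within_cv / 100
    sdlog <- sqrt(log(1 + cv^2))
    true_day <- truth$mean_intake * stats::rlnorm(n, -sdlog^2 / 2, sdlog)
    reported <- pmax(0, true_day + bias + stats::rnorm(n, 0,
                                                       cfg$day_noise_sd))
    occ <- round(rnorm_trunc(n, cfg$occasions_recall_mean,
                             cfg$occasions_recall_sd, 1, 8))
    mac <- macronutrient_split(reported)
    out <- tibble::tibble(
      participant_id = truth$participant_id, tdei_kcal = reported,
      carb_g = mac$carb_g, sugar_g = mac$sugar_g, fat_g = mac$fat_g,
      satfat_g = mac$satfat_g, protein_g = mac$protein_g,
      fiber_g = mac$fiber_g, occasions_n = as.integer(occ)
    )
  }
  attr(out, "bias_truth") <- tibble::tibble(
    participant_id = truth$participant_id, bias = bias
  )
  out
}

# Split reported participant-days into occasion item rows (a `before`
# image per occasion plus a closing image). About 30% of occasions leave
# leftovers (an `after` image), the rest close with `ate_everything`.
# Vectorized over all participant-days.
occasion_rows <- function(pid, day, tdei, n_occ) {
  pd <- seq_along(pid)                     # participant-day index
  g <- rep(pd, times = n_occ)              # occasion -> participant-day
  j <- sequence(n_occ)                     # occasion position in the day
  k <- rep(n_occ, times = n_occ)
  w <- stats::rgamma(length(g), shape = 2)
  wsum <- tapply(w, g, sum)[as.character(g)]
  share <- tdei[g] * w / as.numeric(wsum)
  leftover <- stats::runif(length(g)) < 0.3
  frac <- stats::runif(length(g), 0.05, 0.30)
  before_energy <- ifelse(leftover, share / (1 - frac), share)
  after_energy <- ifelse(leftover, before_energy * frac, 0)
  hours <- 8 + (j - 1) * (13 / pmax(1, k - 1))
  mins <- round(60 * (hours - floor(hours)))
  ts_open <- sprintf("2024-03-%02dT%02d:%02d:00", day[g], floor(hours),
                     mins)
  ts_close <- sprintf("2024-03-%02dT%02d:%02d:00", day[g], floor(hours),
                      pmin(59, mins + 20))
  mk <- function(ts, label, energy, item) {
    mac <- macronutrient_split(energy)
    tibble::tibble(participant_id = pid[g], day = as.integer(day[g]),
                   timestamp = ts, label = label, item_name = item,
                   energy_kcal = energy, carb_g = mac$carb_g,
                   sugar_g = mac$sugar_g, fat_g = mac$fat_g,
                   satfat_g = mac$satfat_g, protein_g = mac$protein_g,
                   fiber_g = mac$fiber_g)
  }
  out <- dplyr::bind_rows(
    mk(ts_open, "before", before_energy,
       sprintf("meal_%d_%d", day[g], j)),
    mk(ts_close, ifelse(leftover, "after", "ate_everything"),
       after_energy, sprintf("meal_%d_%d_end", day[g], j))
  )
  dplyr::arrange(out, .data$participant_id, .data$day, .data$timestamp)
}

# Fixed energy partition: 50% carbohydrate, 35% fat, 15% protein by
# energy; sugars a third of carbohydrate, saturated a third of fat,
# fiber 1.1 g per 100 kcal.
macronutrient_split <- function(energy_kcal) {
  carb <- 0.50 * energy_kcal / 4
  fat <- 0.35 * energy_kcal / 9
  protein <- 0.15 * energy_kcal / 4
  list(carb_g = carb, sugar_g = carb / 3, fat_g = fat, satfat_g = fat / 3,
       protein_g = protein, fiber_g = 0.011 * energy_kcal)
}

#' Simulate a complete study bundle
#'
#' Runs [simulate_cohort()], [simulate_isotope_kinetics()] and
#' [simulate_reported_intake()] for both tools and assembles the inputs of
#' [run_benchmark()].
#'
#' @param cfg A [simulation_config()].
#' @param dlw_cfg A [dlw_config()].
#' @return A list of class `study_bundle`: `participants`, `truth`,
#'   `isotopes`, `occasions`, `recall24`, `body_comp_change` (from the
#'   energy-balance truth when available) and the configuration.
#' @export
simulate_study <- function(cfg = simulation_config(),
                           dlw_cfg = dlw_config()) {
  cohort <- simulate_cohort(cfg)
  isotopes <- simulate_isotope_kinetics(cohort$truth, cfg, dlw_cfg)
  occasions <- simulate_reported_intake(cohort$truth, cfg, "app")
  recall <- simulate_reported_intake(cohort$truth, cfg, "recall")
  bcc <- if (cfg$energy_balance) {
    tibble::tibble(participant_id = cohort$truth$participant_id,
                   d_fm_kg = cohort$truth$d_fm_kg,
                   d_ffm_kg = cohort$truth$d_ffm_kg,
                   days = cfg$days)
  } else {
    NULL
  }
  structure(list(participants = cohort$participants, truth = cohort$truth,
                 isotopes = isotopes, occasions = occasions,
                 recall24 = recall, body_comp_change = bcc,
                 sim_config = cfg, dlw_config = dlw_cfg),
            class = "study_bundle")
}

#' Write a simulated bundle to a directory
#'
#' Writes `participants.csv`, `isotopes.csv`, `occasions.csv`,
#' `recall24.csv` and `truth.json`.
#'
#' @param bundle A `study_bundle` from [simulate_study()].
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_table_csv(bundle$participants, file.path(dir, "participants.csv"))
  write_table_csv(bundle$isotopes, file.path(dir, "isotopes.csv"))
  occ <- bundle$occasions
  occ$occasion_id <- NULL
  occ$unmatched <- NULL
  write_table_csv(occ, file.path(dir, "occasions.csv"))
  write_table_csv(bundle$recall24, file.path(dir, "recall24.csv"))
  truth <- bundle$truth
  truth$true_daily_intake <- lapply(truth$true_daily_intake, identity)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA)
  invisible(dir)
}
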