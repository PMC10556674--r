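#' Isotope elimination constant from the two-point protocol
#'
#' Computes the per-day elimination rate of a tracer from its
#' background-corrected enrichment at the start and end of the metabolic
#' period: `k = log(delta_E_initial / delta_E_final) / elapsed_days`.
#'
#' @param delta_E_initial Background-corrected enrichment at the post-dose
#'   plateau, ppm excess (> 0).
#' @param delta_E_final Background-corrected enrichment at the final
#'   sample, ppm excess (> 0).
#' @param elapsed_days Time between the two samples, days (> 0).
#' @return Elimination constant, per day. A final enrichment above the
#'   initial one yields a negative rate with a warning (protocol
#'   violation), never an error.
#' @export
#' @examples
#' elimination_constant(500, 250, 7) # one half-life in 7 days
elimination_constant <- function(delta_E_initial, delta_E_final,
                                 elapsed_days) {
  if (any(delta_E_initial <= 0) || any(delta_E_final <= 0)) {
    stop("elimination_constant: enrichments must be positive ",
         "(sample at or below background)", call. = FALSE)
  }
  if (any(elapsed_days <= 0)) {
    stop("elimination_constant: elapsed_days must be positive",
         call. = FALSE)
  }
  k <- log(delta_E_initial / delta_E_final) / elapsed_days
  if (any(k < 0)) {
    warning("elimination_constant: final enrichment exceeds initial ",
            "enrichment; negative rate returned", call. = FALSE)
  }
  k
}

#' Isotope dilution space by the plateau method
#'
#' `N = dose_mol * (E_dose - E_tap) / (E_plateau - E_pre)`: the apparent
#' body-water pool that dilutes the tracer dose to the observed plateau
#' enrichment.
#'
#' @param dose_mol Tracer dose, mol of water.
#' @param E_dose Enrichment of the dose, ppm excess.
#' @param E_tap Enrichment of local (tap) water, ppm excess (usually 0 for
#'   background-corrected data).
#' @param E_plateau Post-dose plateau enrichment, ppm excess.
#' @param E_pre Pre-dose enrichment, ppm excess.
#' @return Dilution space in mol. Multiply by
#'   `water_molar_mass_g / 1000` for kg.
#' @export
dilution_space <- function(dose_mol, E_dose, E_tap, E_plateau, E_pre) {
  if (any(E_plateau <= E_pre)) {
    stop("dilution_space: plateau enrichment does not exceed pre-dose ",
         "enrichment (no measurable enrichment)", call. = FALSE)
  }
  if (any(E_dose <= E_tap)) {
    stop("dilution_space: dose enrichment must exceed tap water",
         call. = FALSE)
  }
  if (any(dose_mol <= 0)) {
    stop("dilution_space: dose must be positive", call. = FALSE)
  }
  dose_mol * (E_dose - E_tap) / (E_plateau - E_pre)
}

#' Plateau enrichment from the two same-day samples
#'
#' The two-point protocol collects two urine samples a few hours after
#' dosing (and again on the final day); the plateau value is their
#' arithmetic mean.
#'
#' @param e1,e2 Enrichments of the two same-day samples, ppm excess.
#' @return Mean enrichment, ppm excess.
#' @export
plateau_enrichment <- function(e1, e2) (e1 + e2) / 2

#' Total body water from the two dilution spaces
#'
#' Averages the exchange-corrected spaces:
#' `TBW = (N_d / 1.041 + N_O / 1.007) / 2`.
#'
#' @param N_d_kg Deuterium dilution space, kg.
#' @param N_O_kg Oxygen-18 dilution space, kg.
#' @param cfg A [dlw_config()].
#' @return Total body water, kg.
#' @export
tbw_from_spaces <- function(N_d_kg, N_O_kg, cfg = dlw_config()) {
  if (any(N_d_kg <= 0) || any(N_O_kg <= 0)) {
    stop("tbw_from_spaces: dilution spaces must be positive", call. = FALSE)
  }
  (N_d_kg / cfg$tbw_divisor_d2 + N_O_kg / cfg$tbw_divisor_o18) / 2
}

#' Body composition from total body water
#'
#' Fat-free mass is TBW divided by the hydration factor (0.732); fat mass
#' is body weight minus fat-free mass. A fat-free mass exceeding body
#' weight yields a negative fat mass with a warning, never silent clipping.
#'
#' @param tbw_kg Total body water, kg (> 0).
#' @param weight_kg Body weight, kg (> 0).
#' @param cfg A [dlw_config()].
#' @param source Provenance of the estimate (`"isotope_dilution"`,
#'   `"bioimpedance"` or `"simulated"`).
#' @return A list of class `body_composition` with `tbw_kg`, `ffm_kg`,
#'   `fm_kg` and `source`; `ffm_kg + fm_kg` equals `weight_kg` exactly.
#' @export
body_composition <- function(tbw_kg, weight_kg, cfg = dlw_config(),
                             source = c("isotope_dilution", "bioimpedance",
                                        "simulated")) {
  source <- match.arg(source)
  if (tbw_kg <= 0) stop("body_composition: tbw_kg must be positive",
                        call. = FALSE)
  if (weight_kg <= 0) stop("body_composition: weight_kg must be positive",
                           call. = FALSE)
  ffm <- tbw_kg / cfg$hydration_factor
  fm <- weight_kg - ffm
  if (fm < -1e-9 * weight_kg) {
    warning("body_composition: fat-free mass exceeds body weight ",
            "(negative fat mass)", call. = FALSE)
  }
  structure(list(tbw_kg = tbw_kg, ffm_kg = ffm, fm_kg = fm, source = source),
            class = "body_composition")
}

#' Quality-control ratios of a DLW measurement
#'
#' The dilution space ratio (DSR, `N_d / N_O`) and the elimination rate
#' ratio (ERR, `k_O / k_d`) must lie within configured physiological
#' ranges; each violated bound adds a named flag.
#'
#' @param kin A list with `N_d`, `N_O` (mol or kg, consistent) and `k_O`,
#'   `k_d` (per day), e.g. the kinetics element of [run_two_point()].
#' @param cfg A [dlw_config()].
#' @return A list of class `qc_result` with `dilution_space_ratio`,
#'   `elimination_rate_ratio` and a character vector `flags`, empty iff
#'   both ratios are within range.
#' @export
qc_ratios <- function(kin, cfg = dlw_config()) {
  dsr <- kin$N_d / kin$N_O
  err <- kin$k_O / kin$k_d
  flags <- character(0)
  if (dsr < cfg$dsr_low) flags <- c(flags, "dsr_below_low")
  if (dsr > cfg$dsr_high) flags <- c(flags, "dsr_above_high")
  if (err < cfg$err_low) flags <- c(flags, "err_below_low")
  if (err > cfg$err_high) flags <- c(flags, "err_above_high")
  structure(list(dilution_space_ratio = dsr, elimination_rate_ratio = err,
                 flags = flags),
            class = "qc_result")
}

#' CO2 production by the Speakman two-point equation
#'
#' `rCO2 = 0.4554 * N * (1.007 * k_O - 1.043 * k_d) * 22.26` litres/day,
#' where `N` is total body water in mol.
#'
#' @param N_mol Total body water, mol (> 0).
#' @param k_O,k_d Elimination constants, per day.
#' @param cfg A [dlw_config()].
#' @return CO2 production, litres per day. A negative value (inconsistent
#'   kinetics) is returned with a warning, never clipped.
#' @export
rco2_speakman <- function(N_mol, k_O, k_d, cfg = dlw_config()) {
  if (any(N_mol <= 0)) stop("rco2_speakman: N_mol must be positive",
                            call. = FALSE)
  r <- cfg$speakman_coeff * N_mol *
    (cfg$o_weight * k_O - cfg$d_weight * k_d) * cfg$litres_per_mol_co2
  if (any(r < 0)) {
    warning("rco2_speakman: negative CO2 production (kinetics ",
            "inconsistency)", call. = FALSE)
  }
  r
}

#' Energy expenditure by the Weir equation
#'
#' `TDEE = rCO2 * (1.106 + 3.94 / RQ)` kcal/day.
#'
#' @param rco2_l_per_day CO2 production, litres per day (>= 0).
#' @param rq Respiratory quotient, in (0.67, 1.3].
#' @return Total daily energy expenditure, kcal/day.
#' @export
#' @examples
#' tdee_weir(335, rq = 0.85)
tdee_weir <- function(rco2_l_per_day, rq = 0.85) {
  if (rq <= 0.67 || rq > 1.3) {
    stop("tdee_weir: rq must lie in (0.67, 1.3]", call. = FALSE)
  }
  if (any(rco2_l_per_day < 0)) {
    stop("tdee_weir: rco2 must be non-negative", call. = FALSE)
  }
  rco2_l_per_day * (1.106 + 3.94 / rq)
}

#' Run the two-point DLW protocol for one participant
#'
#' Chains the elementary steps: dose conversion to mol, dilution spaces by
#' the plateau method, total body water as the mean of the two
#' exchange-corrected spaces, body composition, quality-control ratios,
#' CO2 production (Speakman) and energy expenditure (Weir). Elapsed time is
#' computed from the sample times in hours, not assumed to be 7 days.
#'
#' @param sample One row of an isotope table as returned by
#'   [read_isotopes()] (a list or one-row data frame with the interchange
#'   columns; post-dose and final enrichments already averaged over the two
#'   same-day samples, see [plateau_enrichment()]).
#' @param weight_kg Body weight at the start of the period, kg.
#' @param cfg A [dlw_config()].
#' @return A list of class `dlw_result` with `kinetics` (elimination
#'   constants, dilution spaces in mol and kg, total body water, elapsed
#'   days), `body_composition`, `qc` and `tdee_kcal`.
#' @export
run_two_point <- function(sample, weight_kg, cfg = dlw_config()) {
  sample <- as.list(sample)
  needed <- setdiff(names(.schema_isotopes), "participant_id")
  for (nm in needed) {
    v <- sample[[nm]]
    if (is.null(v) || is.na(v)) {
      stop("run_two_point: missing isotope field `", nm, "`", call. = FALSE)
    }
  }
  elapsed_days <- (sample$t_final_h - sample$t_post_h) / 24
  if (elapsed_days <= 0) {
    stop("run_two_point: elapsed time must be positive", call. = FALSE)
  }

  k_O <- elimination_constant(sample$E_post_o18 - sample$E_pre_o18,
                              sample$E_final_o18 - sample$E_pre_o18,
                              elapsed_days)
  k_d <- elimination_constant(sample$E_post_d2 - sample$E_pre_d2,
                              sample$E_final_d2 - sample$E_pre_d2,
                              elapsed_days)

  # dose enrichment: atom% excess expressed as ppm excess over the standard
  N_O_mol <- dilution_space(sample$dose_o18_g / cfg$water_molar_mass_g,
                            sample$ape_o18 * 1e4, 0,
                            sample$E_post_o18, sample$E_pre_o18)
  N_d_mol <- dilution_space(sample$dose_d2_g / cfg$water_molar_mass_g,
                            sample$ape_d2 * 1e4, 0,
                            sample$E_post_d2, sample$E_pre_d2)
  kg_per_mol <- cfg$water_molar_mass_g / 1000
  N_O_kg <- N_O_mol * kg_per_mol
  N_d_kg <- N_d_mol * kg_per_mol

  tbw_kg <- tbw_from_spaces(N_d_kg, N_O_kg, cfg)
  N_mol <- (N_O_mol + N_d_mol) / 2
  comp <- body_composition(tbw_kg, weight_kg, cfg,
                           source = "isotope_dilution")
  kin <- list(k_O = k_O, k_d = k_d, N_O = N_O_mol, N_d = N_d_mol,
              N_O_kg = N_O_kg, N_d_kg = N_d_kg, N = N_mol,
              elapsed_days = elapsed_days)
  qc <- qc_ratios(kin, cfg)
  rco2 <- rco2_speakman(N_mol, k_O, k_d, cfg)
  tdee <- tdee_weir(rco2, cfg$rq)
  structure(list(kinetics = kin, body_composition = comp, qc = qc,
                 rco2_l_per_day = rco2, tdee_kcal = tdee, rq = cfg$rq),
            class = "dlw_result")
}

#' Run the DLW engine over a cohort
#'
#' @param isotopes Isotope table ([read_isotopes()]).
#' @param participants Participants table ([read_participants()]); supplies
#'   the starting body weight per participant.
#' @param cfg A [dlw_config()].
#' @return A tibble with one row per participant: elimination constants,
#'   dilution spaces (kg), total body water, fat-free and fat mass, QC
#'   ratios and flags, and TDEE (kcal/day).
#' @export
run_dlw_cohort <- function(isotopes, participants, cfg = dlw_config()) {
  idx <- match(isotopes$participant_id, participants$id)
  if (anyNA(idx)) {
    stop("run_dlw_cohort: isotope rows without matching participant: ",
         paste(isotopes$participant_id[is.na(idx)], collapse = ", "),
         call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(isotopes)), function(i) {
    res <- run_two_point(isotopes[i, ], participants$weight_start_kg[idx[i]],
                         cfg)
    tibble::tibble(
      participant_id = isotopes$participant_id[i],
      k_O = res$kinetics$k_O, k_d = res$kinetics$k_d,
      N_O_kg = res$kinetics$N_O_kg, N_d_kg = res$kinetics$N_d_kg,
      tbw_kg = res$body_composition$tbw_kg,
      ffm_kg = res$body_composition$ffm_kg,
      fm_kg = res$body_composition$fm_kg,
      dilution_space_ratio = res$qc$dilution_space_ratio,
      elimination_rate_ratio = res$qc$elimination_rate_ratio,
      qc_flags = paste(res$qc$flags, collapse = ";"),
      rco2_l_per_day = res$rco2_l_per_day,
      tdee_kcal = res$tdee_kcal
    )
  })
  dplyr::bind_rows(rows)
}

#' Tracer doses for a given body-water pool
#'
#' Dosing rule of the protocol: 1.8 g of 10 atom% H2-18O and 0.12 g of
#' 99.9 atom% 2H2O per kg of body water. Used by the cohort simulator.
#'
#' @param tbw_kg Total body water, kg.
#' @return A list with `dose_o18_g`, `dose_d2_g`, `ape_o18`, `ape_d2`.
#' @export
dlw_dose <- function(tbw_kg) {
  list(dose_o18_g = 1.8 * tbw_kg, dose_d2_g = 0.12 * tbw_kg,
       ape_o18 = 10, ape_d2 = 99.9)
}

#' @export
print.dlw_result <- function(x, ...) {
  cat("Two-point DLW result\n")
  cat(sprintf("  k_O %.5f /d, k_d %.5f /d (ratio %.3f)\n",
              x$kinetics$k_O, x$kinetics$k_d,
              x$qc$elimination_rate_ratio))
  cat(sprintf("  TBW %.2f kg, FFM %.2f kg, FM %.2f kg\n",
              x$body_composition$tbw_kg, x$body_composition$ffm_kg,
              x$body_composition$fm_kg))
  cat(sprintf("  rCO2 %.1f L/d, TDEE %.1f kcal/d (RQ %.2f)\n",
              x$rco2_l_per_day, x$tdee_kcal, x$rq))
  if (length(x$qc$flags)) {
    cat("  QC flags:", paste(x$qc$flags, collapse = ", "), "\n")
  }
  invisible(x)
}
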