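#' Basal metabolic rate, Mifflin-St Jeor
#'
#' `BMR = 10 w + 6.25 h - 5 a - 161` (female) or `... + 5` (male), with
#' weight in kg, height in cm and age in years.
#'
#' @param weight_kg,height_cm,age_y Positive anthropometrics.
#' @param sex `"female"` or `"male"`.
#' @return BMR in kcal/day.
#' @export
#' @examples
#' bmr_mifflin(57.8, 163, 28.5, "female") # 1293.25
bmr_mifflin <- function(weight_kg, height_cm, age_y, sex = "female") {
  check_anthro(weight_kg, height_cm, age_y, "bmr_mifflin")
  sex_term <- ifelse(sex == "female", -161, 5)
  10 * weight_kg + 6.25 * height_cm - 5 * age_y + sex_term
}

#' Basal metabolic rate, Harris-Benedict (revised)
#'
#' Provided alongside Mifflin-St Jeor for cross-checking cohort means;
#' female: `447.593 + 9.247 w + 3.098 h - 4.330 a`, male:
#' `88.362 + 13.397 w + 4.799 h - 5.677 a`.
#'
#' @inheritParams bmr_mifflin
#' @return BMR in kcal/day.
#' @export
bmr_harris_benedict <- function(weight_kg, height_cm, age_y,
                                sex = "female") {
  check_anthro(weight_kg, height_cm, age_y, "bmr_harris_benedict")
  ifelse(sex == "female",
         447.593 + 9.247 * weight_kg + 3.098 * height_cm - 4.330 * age_y,
         88.362 + 13.397 * weight_kg + 4.799 * height_cm - 5.677 * age_y)
}

check_anthro <- function(weight_kg, height_cm, age_y, what) {
  if (any(weight_kg <= 0) || any(height_cm <= 0) || any(age_y <= 0)) {
    stop(what, ": weight, height and age must be positive", call. = FALSE)
  }
}

#' Physical activity level
#'
#' PAL of one participant is the TDEE:BMR ratio; the cohort PAL is the
#' mean of the individual ratios.
#'
#' @param tdee_kcal Total daily energy expenditure, kcal/day.
#' @param bmr_kcal Basal metabolic rate, kcal/day (> 0).
#' @return Individual PAL values (same length as inputs).
#' @export
pal <- function(tdee_kcal, bmr_kcal) {
  if (any(bmr_kcal <= 0)) stop("pal: bmr must be positive", call. = FALSE)
  tdee_kcal / bmr_kcal
}

#' Goldberg S factor
#'
#' Pooled coefficient of variation of the TDEI:BMR ratio:
#' `S = sqrt(CVwTDEI^2 / d + CVwB^2 + CVtP^2)`, combining the
#' within-subject intake CV over `d` assessment days, the BMR repeatability
#' CV and the total PAL variation.
#'
#' @param cv_wtdei Pooled within-subject intake CV, percent.
#' @param d_days Number of days of dietary assessment (>= 1).
#' @param cv_wb BMR repeatability CV, percent.
#' @param cv_tp PAL variation CV, percent.
#' @return S, percent.
#' @export
#' @examples
#' s_factor(26, 6, 4.1, 16.5) # 20.04
s_factor <- function(cv_wtdei, d_days, cv_wb, cv_tp) {
  if (d_days < 1) stop("s_factor: d_days must be >= 1", call. = FALSE)
  if (any(c(cv_wtdei, cv_wb, cv_tp) < 0)) {
    stop("s_factor: CVs must be non-negative", call. = FALSE)
  }
  sqrt(cv_wtdei^2 / d_days + cv_wb^2 + cv_tp^2)
}

#' Goldberg 95% confidence limits
#'
#' Exponential band around PAL:
#' `limit = PAL * exp(sd * S / (100 * sqrt(n)))` for `sd = sd_min`
#' (lower) and `sd = sd_max` (upper). The band is geometrically
#' symmetric: `lower * upper = PAL^2` when `sd_min = -sd_max`.
#'
#' @param pal_value Cohort physical activity level.
#' @param s S factor, percent.
#' @param n Number of participants (>= 1).
#' @param sd_min,sd_max Confidence multipliers (defaults -2, +2).
#' @return A named list `lower`, `upper`.
#' @export
#' @examples
#' goldberg_limits(1.66, 26.98, 30)
goldberg_limits <- function(pal_value, s, n, sd_min = -2, sd_max = 2) {
  if (n < 1) stop("goldberg_limits: n must be >= 1", call. = FALSE)
  if (s < 0) stop("goldberg_limits: s must be >= 0", call. = FALSE)
  list(lower = pal_value * exp(sd_min * s / (100 * sqrt(n))),
       upper = pal_value * exp(sd_max * s / (100 * sqrt(n))))
}

#' Classify energy-intake reporting plausibility
#'
#' A participant whose TDEI:BMR ratio falls strictly below the lower
#' Goldberg limit is an under-reporter, strictly above the upper limit an
#' over-reporter, otherwise plausible (boundary values are plausible).
#'
#' @param tdei_kcal Reported mean daily energy intake, kcal/day.
#' @param bmr_kcal Basal metabolic rate, kcal/day (> 0).
#' @param limits A list with `lower` and `upper` ([goldberg_limits()]).
#' @return Factor with levels `under`, `plausible`, `over`.
#' @export
classify_misreporting <- function(tdei_kcal, bmr_kcal, limits) {
  if (any(bmr_kcal <= 0)) {
    stop("classify_misreporting: bmr must be positive", call. = FALSE)
  }
  ratio <- tdei_kcal / bmr_kcal
  cls <- ifelse(ratio < limits$lower, "under",
                ifelse(ratio > limits$upper, "over", "plausible"))
  factor(cls, levels = c("under", "plausible", "over"))
}

#' Full Goldberg misreporting analysis for one tool
#'
#' Computes the S factor from the configured (or supplied study-specific)
#' CVs, the confidence band around the cohort PAL, and the per-participant
#' classification with counts.
#'
#' @param tdei_kcal Per-participant reported mean TDEI, kcal/day.
#' @param bmr_kcal Per-participant BMR, kcal/day.
#' @param tdee_kcal Per-participant TDEE, kcal/day (used when
#'   `cfg$pal == "computed"`).
#' @param cfg A [goldberg_config()].
#' @param n Number of participants entering the band width (defaults to
#'   `length(tdei_kcal)`).
#' @return A list of class `goldberg_result`: `s_factor`, `pal`,
#'   `lower_limit`, `upper_limit`, `ratio`, `classification`, `counts`
#'   (`n_under`, `n_plausible`, `n_over`) and the configuration used.
#' @export
goldberg_analysis <- function(tdei_kcal, bmr_kcal, tdee_kcal = NULL,
                              cfg = goldberg_config(),
                              n = length(tdei_kcal)) {
  pal_value <- if (identical(cfg$pal, "computed")) {
    if (is.null(tdee_kcal)) {
      stop("goldberg_analysis: tdee_kcal required when pal = \"computed\"",
           call. = FALSE)
    }
    mean(pal(tdee_kcal, bmr_kcal))
  } else {
    cfg$pal
  }
  s <- s_factor(cfg$cv_wtdei, cfg$d_days, cfg$cv_wb, cfg$cv_tp)
  lim <- goldberg_limits(pal_value, s, n, cfg$sd_min, cfg$sd_max)
  cls <- classify_misreporting(tdei_kcal, bmr_kcal, lim)
  counts <- table(cls)
  structure(list(
    s_factor = s, pal = pal_value,
    lower_limit = lim$lower, upper_limit = lim$upper,
    ratio = tdei_kcal / bmr_kcal, classification = cls,
    counts = list(n_under = unname(counts[["under"]]),
                  n_plausible = unname(counts[["plausible"]]),
                  n_over = unname(counts[["over"]])),
    config = cfg
  ), class = "goldberg_result")
}

#' @export
print.goldberg_result <- function(x, ...) {
  cat("Goldberg misreporting classification\n")
  cat(sprintf("  S = %.2f%%, PAL = %.3f, limits (%.2f, %.2f), d = %d days\n",
              x$s_factor, x$pal, x$lower_limit, x$upper_limit,
              x$config$d_days))
  cat(sprintf("  under %d / plausible %d / over %d (n = %d)\n",
              x$counts$n_under, x$counts$n_plausible, x$counts$n_over,
              length(x$classification)))
  invisible(x)
}

#' Daily change in body energy stores (EB method)
#'
#' Converts measured changes in fat mass and fat-free mass into an energy
#' flux: `dES = (dFM_g * 9.5 + dFFM_g * 1.1) / days` kcal/day.
#'
#' @param d_fm_kg Change in fat mass, kg.
#' @param d_ffm_kg Change in fat-free mass, kg.
#' @param days Length of the observation period, days (> 0).
#' @param cfg An [energy_stores_config()].
#' @return Energy-store change, kcal/day (negative = store depletion).
#' @export
#' @examples
#' delta_energy_stores(-0.2, 0.1, 7) # -255.7 kcal/day
delta_energy_stores <- function(d_fm_kg, d_ffm_kg, days,
                                cfg = energy_stores_config()) {
  if (any(days <= 0)) {
    stop("delta_energy_stores: days must be positive", call. = FALSE)
  }
  (d_fm_kg * 1000 * cfg$kcal_per_g_fm +
     d_ffm_kg * 1000 * cfg$kcal_per_g_ffm) / days
}
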