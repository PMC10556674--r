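#' Doubly labelled water engine configuration
#'
#' Coefficients and quality-control bounds for the two-point DLW protocol.
#' The total body water (TBW) combination divides the deuterium dilution
#' space by 1.041 and the oxygen-18 space by 1.007 (correcting for in vivo
#' isotope exchange) and averages them; fat-free mass is TBW divided by the
#' hydration factor 0.732. CO2 production uses the Speakman two-point
#' equation and energy expenditure the Weir equation at the configured
#' respiratory quotient.
#'
#' @param tbw_divisor_d2 Exchange correction divisor for the deuterium
#'   dilution space (dimensionless, default 1.041).
#' @param tbw_divisor_o18 Exchange correction divisor for the oxygen-18
#'   dilution space (default 1.007).
#' @param hydration_factor Water fraction of fat-free mass (default 0.732).
#' @param speakman_coeff Leading coefficient of the Speakman rCO2 equation
#'   (default 0.4554).
#' @param o_weight,d_weight Isotope weights applied to the elimination
#'   constants inside the Speakman equation (defaults 1.007 and 1.043).
#' @param litres_per_mol_co2 Molar volume of CO2 in litres (default 22.26).
#' @param water_molar_mass_g Molar mass of water, g/mol (default 18.02).
#' @param dsr_low,dsr_high Quality-control bounds on the dilution space
#'   ratio N_d/N_O (defaults 1.000 and 1.070).
#' @param err_low,err_high Quality-control bounds on the elimination rate
#'   ratio k_O/k_d (defaults 1.100 and 1.700).
#' @param rq Respiratory quotient used by the Weir equation (default 0.85,
#'   a typical food quotient for a mixed diet).
#' @return A list of class `dlw_config`.
#' @export
#' @examples
#' dlw_config()
#' dlw_config(rq = 0.88)
dlw_config <- function(tbw_divisor_d2 = 1.041,
                       tbw_divisor_o18 = 1.007,
                       hydration_factor = 0.732,
                       speakman_coeff = 0.4554,
                       o_weight = 1.007,
                       d_weight = 1.043,
                       litres_per_mol_co2 = 22.26,
                       water_molar_mass_g = 18.02,
                       dsr_low = 1.000,
                       dsr_high = 1.070,
                       err_low = 1.100,
                       err_high = 1.700,
                       rq = 0.85) {
  cfg <- list(
    tbw_divisor_d2 = tbw_divisor_d2, tbw_divisor_o18 = tbw_divisor_o18,
    hydration_factor = hydration_factor, speakman_coeff = speakman_coeff,
    o_weight = o_weight, d_weight = d_weight,
    litres_per_mol_co2 = litres_per_mol_co2,
    water_molar_mass_g = water_molar_mass_g,
    dsr_low = dsr_low, dsr_high = dsr_high,
    err_low = err_low, err_high = err_high, rq = rq
  )
  for (nm in setdiff(names(cfg), c("rq"))) {
    if (!is.numeric(cfg[[nm]]) || length(cfg[[nm]]) != 1L || cfg[[nm]] <= 0) {
      stop("dlw_config: `", nm, "` must be a single positive number",
           call. = FALSE)
    }
  }
  if (rq <= 0.67 || rq > 1.3) {
    stop("dlw_config: `rq` must lie in (0.67, 1.3]", call. = FALSE)
  }
  if (dsr_low >= dsr_high) stop("dlw_config: dsr_low must be < dsr_high",
                                call. = FALSE)
  if (err_low >= err_high) stop("dlw_config: err_low must be < err_high",
                                call. = FALSE)
  structure(cfg, class = "dlw_config")
}

#' Goldberg cut-off configuration
#'
#' Parameters of the Goldberg/Black confidence band around the physical
#' activity level (PAL) used to classify reported energy intake as
#' under-reported, plausible or over-reported.
#'
#' @param d_days Number of days of dietary assessment entering the S factor
#'   (default 6).
#' @param cv_wb Within-subject coefficient of variation of repeated BMR
#'   measurements, percent (default 4.1, the free-living value for women).
#' @param cv_tp Total variation in PAL, percent (default 16.5, the
#'   literature value for normal-weight women aged 18-29).
#' @param cv_wtdei Pooled within-subject CV of daily energy intake, percent
#'   (default 26, the literature value; compute the study-specific value
#'   with [pooled_cv()]).
#' @param sd_min,sd_max Multipliers for the lower/upper 95% confidence
#'   limits (defaults -2 and +2).
#' @param pal Either a fixed PAL value (> 1) or `"computed"` to take the
#'   mean of individual TDEE:BMR ratios.
#' @return A list of class `goldberg_config`.
#' @export
goldberg_config <- function(d_days = 6L,
                            cv_wb = 4.1,
                            cv_tp = 16.5,
                            cv_wtdei = 26,
                            sd_min = -2,
                            sd_max = 2,
                            pal = "computed") {
  if (d_days < 1) stop("goldberg_config: d_days must be >= 1", call. = FALSE)
  for (cv in list(cv_wb = cv_wb, cv_tp = cv_tp, cv_wtdei = cv_wtdei)) {
    if (cv < 0) stop("goldberg_config: CVs must be >= 0", call. = FALSE)
  }
  if (!(sd_min < 0 && sd_max > 0)) {
    stop("goldberg_config: need sd_min < 0 < sd_max", call. = FALSE)
  }
  if (is.numeric(pal) && pal <= 1) {
    stop("goldberg_config: numeric pal must exceed 1", call. = FALSE)
  }
  structure(list(d_days = as.integer(d_days), cv_wb = cv_wb, cv_tp = cv_tp,
                 cv_wtdei = cv_wtdei, sd_min = sd_min, sd_max = sd_max,
                 pal = pal),
            class = "goldberg_config")
}

#' Energy-store density coefficients
#'
#' Energy densities used by the energy expenditure/balance (EB) method to
#' convert changes in fat mass and fat-free mass into an energy flux.
#'
#' @param kcal_per_g_fm Energy density of fat mass, kcal/g (default 9.5).
#' @param kcal_per_g_ffm Energy density of fat-free mass, kcal/g
#'   (default 1.1).
#' @return A list of class `energy_stores_config`.
#' @export
energy_stores_config <- function(kcal_per_g_fm = 9.5, kcal_per_g_ffm = 1.1) {
  if (kcal_per_g_fm <= 0 || kcal_per_g_ffm <= 0) {
    stop("energy_stores_config: coefficients must be positive", call. = FALSE)
  }
  structure(list(kcal_per_g_fm = kcal_per_g_fm,
                 kcal_per_g_ffm = kcal_per_g_ffm),
            class = "energy_stores_config")
}

#' Study-level analysis configuration
#'
#' Bundles the unit conversion, respiratory quotient, Goldberg and DLW
#' settings, the Bonferroni factor for the three planned comparisons, and
#' the significance level.
#'
#' @param kcal_to_kj Conversion factor from kcal to kJ (default 4.184).
#' @param rq Respiratory quotient (default 0.85); forwarded to `dlw`.
#' @param goldberg A [goldberg_config()].
#' @param dlw A [dlw_config()].
#' @param bonferroni_factor Multiplicity correction factor (default 3, one
#'   per planned tool comparison).
#' @param alpha Significance level (default 0.05).
#' @param seed Integer seed recorded in report provenance.
#' @return A list of class `study_config`.
#' @export
study_config <- function(kcal_to_kj = 4.184,
                         rq = 0.85,
                         goldberg = goldberg_config(),
                         dlw = dlw_config(rq = rq),
                         bonferroni_factor = 3L,
                         alpha = 0.05,
                         seed = 1L) {
  if (kcal_to_kj <= 0) stop("study_config: kcal_to_kj must be positive",
                            call. = FALSE)
  if (bonferroni_factor < 1) {
    stop("study_config: bonferroni_factor must be >= 1", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) stop("study_config: alpha must be in (0,1)",
                                     call. = FALSE)
  stopifnot(inherits(goldberg, "goldberg_config"), inherits(dlw, "dlw_config"))
  structure(list(kcal_to_kj = kcal_to_kj, rq = rq, goldberg = goldberg,
                 dlw = dlw, bonferroni_factor = as.integer(bonferroni_factor),
                 alpha = alpha, seed = as.integer(seed)),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Reads a `config.yaml` whose top-level keys mirror the arguments of
#' [study_config()], with nested `goldberg:` and `dlw:` blocks forwarded to
#' [goldberg_config()] and [dlw_config()]. Missing keys fall back to the
#' defaults.
#'
#' @param path Path to a YAML file.
#' @return A `study_config` object.
#' @export
read_study_config <- function(path) {
  raw <- yaml::read_yaml(path)
  gb <- do.call(goldberg_config, raw$goldberg %||% list())
  dlw_args <- raw$dlw %||% list()
  if (is.null(dlw_args$rq) && !is.null(raw$rq)) dlw_args$rq <- raw$rq
  dl <- do.call(dlw_config, dlw_args)
  args <- raw[setdiff(names(raw), c("goldberg", "dlw"))]
  args$goldberg <- gb
  args$dlw <- dl
  do.call(study_config, args)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
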