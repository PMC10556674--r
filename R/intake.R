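#' Aggregate eating occasions to daily intake
#'
#' Consumed energy (and each macronutrient) per occasion is the `before`
#' total minus the `after` total; an `ate_everything` closing image
#' contributes an after total of zero, and a standalone `ate_everything`
#' record counts in full. Negative consumed values (after exceeding
#' before) are floored at zero with a warning. Daily values sum consumed
#' occasions per participant-day; `occasions_n` counts distinct occasions,
#' not item rows. Unmatched `after` records are ignored with a message.
#'
#' @param occasions Item table from [read_occasions()].
#' @param days Day indices every participant should report (default
#'   `1:7`); days without any recorded occasion appear with zero intake
#'   when `include_empty_days = TRUE`.
#' @param include_empty_days Include zero rows for unreported
#'   participant-days (default `TRUE`; omission is itself a reporting
#'   behaviour the validity analysis measures).
#' @return A tibble with one row per participant-day: `participant_id`,
#'   `day`, `tdei_kcal`, macronutrients (g) and `occasions_n`.
#' @export
aggregate_daily <- function(occasions, days = 1:7,
                            include_empty_days = TRUE) {
  if (!"occasion_id" %in% names(occasions)) {
    occasions <- assign_occasions(occasions)
  }
  n_unmatched <- sum(occasions$unmatched)
  if (n_unmatched > 0) {
    message("aggregate_daily: ignoring ", n_unmatched,
            " unmatched 'after' record(s)")
  }
  occasions <- occasions[!occasions$unmatched, , drop = FALSE]
  nutr <- c(tdei_kcal = "energy_kcal", carb_g = "carb_g", sugar_g = "sugar_g",
            fat_g = "fat_g", satfat_g = "satfat_g", protein_g = "protein_g",
            fiber_g = "fiber_g")

  per_occ <- occasions |>
    dplyr::group_by(.data$participant_id, .data$day, .data$occasion_id) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(unname(nutr)), ~ {
      has_before <- any(.data$label == "before")
      opening <- if (has_before) "before" else "ate_everything"
      sum(.x[.data$label == opening]) - sum(.x[.data$label == "after"])
    }), .groups = "drop")
  n_neg <- sum(per_occ$energy_kcal < 0)
  if (n_neg > 0) {
    warning("aggregate_daily: ", n_neg, " occasion(s) with after total ",
            "exceeding before total; consumed intake floored at 0",
            call. = FALSE)
  }
  for (col in unname(nutr)) per_occ[[col]] <- pmax(per_occ[[col]], 0)

  daily <- per_occ |>
    dplyr::group_by(.data$participant_id, .data$day) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(unname(nutr)), sum),
                     occasions_n = dplyr::n(), .groups = "drop")
  names(daily)[match(unname(nutr), names(daily))] <- names(nutr)

  if (include_empty_days && length(days) > 0) {
    grid <- expand.grid(participant_id = unique(occasions$participant_id),
                        day = as.integer(days), stringsAsFactors = FALSE)
    daily <- dplyr::left_join(tibble::as_tibble(grid), daily,
                              by = c("participant_id", "day"))
    zero_cols <- c(names(nutr), "occasions_n")
    for (col in zero_cols) {
      daily[[col]][is.na(daily[[col]])] <- 0
    }
  }
  daily$occasions_n <- as.integer(daily$occasions_n)
  dplyr::arrange(daily, .data$participant_id, .data$day)
}

#' Within-subject coefficient of variation
#'
#' `CV_i = 100 * SD / mean` over the available days of one participant,
#' with the sample (n-1) standard deviation.
#'
#' @param series Numeric vector of daily values (>= 2 values).
#' @return CV in percent.
#' @export
#' @examples
#' within_subject_cv(c(1000, 2000)) # 47.14
within_subject_cv <- function(series) {
  series <- series[is.finite(series)]
  if (length(series) < 2) {
    stop("within_subject_cv: at least two days required", call. = FALSE)
  }
  m <- mean(series)
  if (m <= 0) {
    stop("within_subject_cv: mean must be positive", call. = FALSE)
  }
  100 * stats::sd(series) / m
}

#' Pooled within-subject CV across a cohort
#'
#' Root mean square of the individual CVs:
#' `CVw = sqrt(sum(CV_i^2) / n)`. Bounded by the smallest and largest
#' individual CV.
#'
#' @param cv_list Numeric vector of per-participant CVs, percent.
#' @return Pooled CV, percent.
#' @export
#' @examples
#' pooled_cv(c(30, 50)) # sqrt(1700) = 41.23
pooled_cv <- function(cv_list) {
  if (length(cv_list) == 0) {
    stop("pooled_cv: empty CV list", call. = FALSE)
  }
  if (any(!is.finite(cv_list))) {
    stop("pooled_cv: CVs must be finite", call. = FALSE)
  }
  sqrt(mean(cv_list^2))
}

#' Per-participant intake series summary
#'
#' @param daily Daily intake table from [aggregate_daily()].
#' @return A tibble per participant with the number of days, mean TDEI
#'   (kcal/day), within-subject CV (percent, `NA` with fewer than 2 days),
#'   macronutrient means and mean eating occasions per day.
#' @export
intake_series <- function(daily) {
  daily |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::summarise(
      n_days = dplyr::n(),
      mean_tdei = mean(.data$tdei_kcal),
      cv_i = if (dplyr::n() >= 2 && mean(.data$tdei_kcal) > 0)
        within_subject_cv(.data$tdei_kcal) else NA_real_,
      dplyr::across(dplyr::all_of(c("carb_g", "sugar_g", "fat_g", "satfat_g",
                                    "protein_g", "fiber_g")), mean),
      occasions_per_day = mean(.data$occasions_n),
      .groups = "drop"
    )
}

#' Paired tool summary table
#'
#' Joins the per-participant app summary (7-day means) with the single-day
#' 24-hour recall totals; participants missing from either source are
#' excluded with a message and count.
#'
#' @param series Per-participant summary from [intake_series()].
#' @param recall Recall table from [read_recall24()].
#' @return A tibble, one row per participant present in both sources, with
#'   `_app` and `_recall` suffixed columns and paired differences
#'   `diff_tdei` (app - recall) and `diff_occasions`.
#' @export
tool_summary <- function(series, recall) {
  common <- intersect(series$participant_id, recall$participant_id)
  dropped <- length(unique(c(series$participant_id,
                             recall$participant_id))) - length(common)
  if (length(common) == 0) {
    stop("tool_summary: no participant present in both sources",
         call. = FALSE)
  }
  if (dropped > 0) {
    message("tool_summary: excluded ", dropped,
            " participant(s) missing from one source")
  }
  a <- series[series$participant_id %in% common, ]
  b <- recall[recall$participant_id %in% common, ]
  out <- dplyr::inner_join(a, b, by = "participant_id",
                           suffix = c("_app", "_recall"))
  out$tdei_app <- out$mean_tdei
  out$tdei_recall <- out$tdei_kcal
  out$occasions_recall <- as.numeric(out$occasions_n)
  out$diff_tdei <- out$tdei_app - out$tdei_recall
  out$diff_occasions <- out$occasions_per_day - out$occasions_recall
  out
}
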