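#' Bland-Altman agreement internals from summary statistics
#'
#' Computes the full Bland-Altman table from the bias (mean difference),
#' the sample SD of the differences and n. Limits of agreement use the
#' fixed 1.96 multiplier; the confidence intervals of the bias and of each
#' limit use the t quantile with n - 1 degrees of freedom, with
#' `SE(bias) = SD / sqrt(n)` and `SE(LoA) = SD * sqrt(3 / n)` (the
#' classical approximation).
#'
#' @param bias Mean of the differences (test minus reference).
#' @param sd_diff Sample standard deviation of the differences.
#' @param n Number of pairs (>= 2).
#' @param alpha Significance level for the confidence intervals
#'   (default 0.05).
#' @return A list of class `bland_altman` with `n`, `bias`, `bias_ci`,
#'   `sd_diff`, `se_bias`, `loa` (`lower`, `upper`), `se_loa`,
#'   `loa_ci_lower` and `loa_ci_upper` (each `(low, high)`).
#' @export
#' @examples
#' bland_altman_summary(-329.6, 599.1, 30)
bland_altman_summary <- function(bias, sd_diff, n, alpha = 0.05) {
  if (n < 2) stop("bland_altman_summary: n must be >= 2", call. = FALSE)
  if (sd_diff < 0) {
    stop("bland_altman_summary: sd_diff must be >= 0", call. = FALSE)
  }
  tq <- stats::qt(1 - alpha / 2, df = n - 1)
  se_bias <- sd_diff / sqrt(n)
  se_loa <- sd_diff * sqrt(3 / n)
  loa_l <- bias - 1.96 * sd_diff
  loa_u <- bias + 1.96 * sd_diff
  structure(list(
    n = as.integer(n), bias = bias,
    bias_ci = c(low = bias - tq * se_bias, high = bias + tq * se_bias),
    sd_diff = sd_diff, se_bias = se_bias,
    loa = c(lower = loa_l, upper = loa_u), se_loa = se_loa,
    loa_ci_lower = c(low = loa_l - tq * se_loa, high = loa_l + tq * se_loa),
    loa_ci_upper = c(low = loa_u - tq * se_loa, high = loa_u + tq * se_loa),
    alpha = alpha
  ), class = "bland_altman")
}

#' Bland-Altman analysis of paired estimates
#'
#' Differences are taken as test minus reference (`value_a - value_b`),
#' so a tool that under-reports relative to the reference yields a
#' negative bias.
#'
#' @param pairs A data frame with columns `value_a` (test method) and
#'   `value_b` (reference method), one row per participant, or two numeric
#'   vectors via `value_a`/`value_b`.
#' @param alpha Significance level for the confidence intervals.
#' @return A `bland_altman` object (see [bland_altman_summary()]), plus
#'   the `differences` and `means` vectors for plotting.
#' @export
bland_altman <- function(pairs, alpha = 0.05) {
  d <- pairs$value_a - pairs$value_b
  if (length(d) < 2) stop("bland_altman: need n >= 2 pairs", call. = FALSE)
  if (any(!is.finite(d))) {
    stop("bland_altman: non-finite differences", call. = FALSE)
  }
  out <- bland_altman_summary(mean(d), stats::sd(d), length(d), alpha)
  out$differences <- d
  out$means <- (pairs$value_a + pairs$value_b) / 2
  out
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d)\n", x$n))
  cat(sprintf("  bias %.1f [%.1f, %.1f], SD %.1f, SE %.1f\n",
              x$bias, x$bias_ci[["low"]], x$bias_ci[["high"]], x$sd_diff,
              x$se_bias))
  cat(sprintf("  LoA [%.1f, %.1f], SE LoA %.1f\n",
              x$loa[["lower"]], x$loa[["upper"]], x$se_loa))
  invisible(x)
}

#' Paired difference test with normality gating
#'
#' Shapiro-Wilk on the paired differences (at level 0.05) selects the
#' test: paired t when normality is not rejected, Wilcoxon signed-rank
#' otherwise. The p-value is Bonferroni-adjusted by the configured factor
#' and capped at 1. Zero-variance differences give a degenerate result
#' with the bias and no p-value.
#'
#' @inheritParams bland_altman
#' @param bonferroni_factor Multiplicity factor (default 3).
#' @return A list with `test_used` (`"paired_t"`, `"wilcoxon"` or
#'   `"degenerate"`), `statistic`, `p_raw`, `p_adj`, `shapiro_p` and
#'   `bias`.
#' @export
paired_difference_test <- function(pairs, alpha = 0.05,
                                   bonferroni_factor = 3) {
  d <- pairs$value_a - pairs$value_b
  if (length(d) < 3) {
    stop("paired_difference_test: need n >= 3 pairs", call. = FALSE)
  }
  if (stats::sd(d) == 0) {
    return(list(test_used = "degenerate", statistic = NA_real_,
                p_raw = NA_real_, p_adj = NA_real_, shapiro_p = NA_real_,
                bias = mean(d)))
  }
  sw <- stats::shapiro.test(d)
  if (sw$p.value >= 0.05) {
    ht <- stats::t.test(d)
    used <- "paired_t"
  } else {
    ht <- stats::wilcox.test(d, exact = FALSE)
    used <- "wilcoxon"
  }
  list(test_used = used, statistic = unname(ht$statistic),
       p_raw = ht$p.value,
       p_adj = min(1, bonferroni_factor * ht$p.value),
       shapiro_p = sw$p.value, bias = mean(d))
}

#' Pearson correlation with Bonferroni adjustment
#'
#' Reports both the correlation coefficient r and the coefficient of
#' determination r-squared, explicitly labelled, with the two-sided
#' p-value raw and Bonferroni-adjusted.
#'
#' @param x,y Numeric vectors (n >= 3, non-zero variance).
#' @param bonferroni_factor Multiplicity factor (default 3).
#' @return A list with `r`, `r_squared`, `p_raw`, `p_adj`, `n`.
#' @export
pearson_cor <- function(x, y, bonferroni_factor = 3) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("pearson_cor: need n >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("pearson_cor: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  list(r = r, r_squared = r^2, p_raw = ct$p.value,
       p_adj = min(1, bonferroni_factor * ct$p.value), n = length(x))
}

#' Intraclass correlation by random-intercept model
#'
#' Fits `value ~ 1 + (1 | participant)` by restricted maximum likelihood
#' and reports `ICC = var_between / (var_between + var_within)`, an index
#' of day-to-day diet stability. The F statistic, p-value and confidence
#' interval come from the one-way ANOVA representation with the exact F
#' method (average group size for unbalanced data).
#'
#' @param daily A data frame with columns `participant_id` and a value
#'   column (default `tdei_kcal`); at least 2 participants with at least
#'   2 days each.
#' @param value Name of the value column.
#' @param alpha Significance level of the confidence interval.
#' @return A list of class `icc_result` with `icc`, `ci` (`low`, `high`),
#'   `f_stat`, `df` (`num`, `den`), `p_value`, `var_between`,
#'   `var_within`, `within_sd`, `ms_between`, `ms_within`.
#' @export
icc_random_intercept <- function(daily, value = "tdei_kcal", alpha = 0.05) {
  df <- data.frame(id = factor(daily$participant_id), y = daily[[value]])
  df <- df[stats::complete.cases(df), ]
  sizes <- table(df$id)
  sizes <- sizes[sizes > 0]
  if (length(sizes) < 2 || max(sizes) < 2) {
    stop("icc_random_intercept: need >= 2 participants and repeated days",
         call. = FALSE)
  }
  fit <- lme4::lmer(y ~ 1 + (1 | id), data = df, REML = TRUE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_between <- vc$vcov[vc$grp == "id"]
  var_within <- vc$vcov[vc$grp == "Residual"]
  icc <- var_between / (var_between + var_within)

  # one-way ANOVA representation for F, p and the exact CI
  n_groups <- length(sizes)
  n_total <- sum(sizes)
  grand <- mean(df$y)
  group_means <- tapply(df$y, df$id, mean)
  ss_between <- sum(sizes * (group_means[names(sizes)] - grand)^2)
  ss_within <- sum((df$y - group_means[df$id])^2)
  df_b <- n_groups - 1
  df_w <- n_total - n_groups
  ms_between <- ss_between / df_b
  ms_within <- ss_within / df_w
  f_stat <- ms_between / ms_within
  p_value <- stats::pf(f_stat, df_b, df_w, lower.tail = FALSE)
  # average group size (unbalanced correction)
  k0 <- (n_total - sum(sizes^2) / n_total) / (n_groups - 1)
  f_low <- f_stat / stats::qf(1 - alpha / 2, df_b, df_w)
  f_high <- f_stat * stats::qf(1 - alpha / 2, df_w, df_b)
  ci <- c(low = (f_low - 1) / (f_low + k0 - 1),
          high = (f_high - 1) / (f_high + k0 - 1))
  ci <- pmin(pmax(ci, 0), 1)
  structure(list(icc = icc, ci = ci, f_stat = f_stat,
                 df = c(num = df_b, den = df_w), p_value = p_value,
                 var_between = var_between, var_within = var_within,
                 within_sd = sqrt(var_within),
                 ms_between = ms_between, ms_within = ms_within),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC %.3f [%.3f, %.3f], F(%d, %d) = %.3f, p = %.2g\n",
              x$icc, x$ci[["low"]], x$ci[["high"]], x$df[["num"]],
              x$df[["den"]], x$f_stat, x$p_value))
  cat(sprintf("  var between %.1f, var within %.1f, within SD %.1f\n",
              x$var_between, x$var_within, x$within_sd))
  invisible(x)
}

#' Over- and under-estimation summary
#'
#' Per-participant percentage difference
#' `p_i = 100 * (a_i - b_i) / b_i` against the reference; the mean
#' percentage difference (MPD) is the mean of the individual percentages,
#' not the percentage of the cohort means. Participants are split by the
#' sign of the raw difference; exact zeros form their own count.
#'
#' @inheritParams bland_altman
#' @return A list of class `over_under_summary` with `n_over`, `n_under`,
#'   `n_zero`, `mpd_overall`, `sd_pd_overall`, `mpd_over`, `mpd_under`
#'   (with SDs), `mean_delta_over`, `mean_delta_under` (with SDs), and the
#'   per-participant `pct_diff` vector.
#' @export
over_under_summary <- function(pairs) {
  a <- pairs$value_a
  b <- pairs$value_b
  if (length(a) < 1) stop("over_under_summary: empty input", call. = FALSE)
  if (any(b <= 0)) {
    stop("over_under_summary: reference values must be positive",
         call. = FALSE)
  }
  d <- a - b
  pd <- 100 * d / b
  over <- d > 0
  under <- d < 0
  msd <- function(v) {
    if (length(v) == 0) return(c(mean = NA_real_, sd = NA_real_))
    c(mean = mean(v), sd = if (length(v) > 1) stats::sd(v) else NA_real_)
  }
  m_over <- msd(pd[over]); m_under <- msd(pd[under])
  d_over <- msd(d[over]); d_under <- msd(d[under])
  structure(list(
    n = length(d), n_over = sum(over), n_under = sum(under),
    n_zero = sum(d == 0),
    mpd_overall = mean(pd),
    sd_pd_overall = if (length(pd) > 1) stats::sd(pd) else NA_real_,
    mpd_over = m_over[["mean"]], sd_pd_over = m_over[["sd"]],
    mpd_under = m_under[["mean"]], sd_pd_under = m_under[["sd"]],
    mean_delta_over = d_over[["mean"]], sd_delta_over = d_over[["sd"]],
    mean_delta_under = d_under[["mean"]], sd_delta_under = d_under[["sd"]],
    pct_diff = pd
  ), class = "over_under_summary")
}

#' Assemble a paired-estimates table
#'
#' @param participant_id Identifiers.
#' @param value_a Test-method values, kcal/day.
#' @param value_b Reference-method values, kcal/day.
#' @param label_a,label_b Method labels.
#' @return A tibble of paired estimates, one row per participant.
#' @export
paired_estimates <- function(participant_id, value_a, value_b,
                             label_a = "test", label_b = "reference") {
  stopifnot(length(value_a) == length(value_b),
            length(participant_id) == length(value_a))
  if (any(!is.finite(value_a)) || any(!is.finite(value_b))) {
    stop("paired_estimates: values must be finite", call. = FALSE)
  }
  if (anyDuplicated(participant_id)) {
    stop("paired_estimates: one row per participant", call. = FALSE)
  }
  tibble::tibble(participant_id = as.character(participant_id),
                 value_a = value_a, value_b = value_b,
                 label_a = label_a, label_b = label_b)
}
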