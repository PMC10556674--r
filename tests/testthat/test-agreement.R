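test_that("Bland-Altman internals are consistent with the definitions", {
  # hand case: differences -1, 0, 1
  ba <- bland_altman(pairs_from_diffs(c(-1, 0, 1)))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(unname(ba$loa), c(-1.96, 1.96))
  expect_equal(ba$se_bias * sqrt(ba$n), ba$sd_diff)

  # identical pairs: degenerate zero band
  ba0 <- bland_altman(pairs_from_diffs(rep(0, 5)))
  expect_equal(ba0$bias, 0)
  expect_equal(unname(ba0$loa), c(0, 0))

  # internal consistency on random differences
  set.seed(23)
  for (i in 1:10) {
    d <- rnorm(sample(5:60, 1), sd = runif(1, 1, 500))
    ba <- bland_altman(pairs_from_diffs(d))
    expect_equal(ba$loa[["upper"]] - ba$loa[["lower"]],
                 2 * 1.96 * ba$sd_diff, tolerance = 1e-12)
    expect_equal(ba$se_loa, ba$sd_diff * sqrt(3 / ba$n), tolerance = 1e-12)
    expect_true(ba$loa[["lower"]] < ba$bias && ba$bias < ba$loa[["upper"]])
  }
  expect_error(bland_altman(pairs_from_diffs(numeric(0))), "n >= 2")
})

test_that("paired test gates on normality and applies the Bonferroni cap", {
  set.seed(31)
  # normal differences -> paired t
  d <- rnorm(30, -300, 500)
  res <- paired_difference_test(pairs_from_diffs(d))
  expect_equal(res$test_used, "paired_t")
  expect_equal(res$p_adj, min(1, 3 * res$p_raw))

  # heavy-tailed differences -> Wilcoxon
  d2 <- c(rnorm(27, 0, 10), 4000, 5200, 6100)
  res2 <- paired_difference_test(pairs_from_diffs(d2))
  expect_equal(res2$test_used, "wilcoxon")

  # a raw p of 0.022 loses significance under the x3 adjustment
  expect_equal(min(1, 3 * 0.022), 0.066)
  # cap at 1
  d3 <- rnorm(20, 0, 100)
  res3 <- paired_difference_test(pairs_from_diffs(d3 - mean(d3)))
  expect_lte(res3$p_adj, 1)

  # zero variance -> degenerate, no p-value
  res4 <- paired_difference_test(pairs_from_diffs(rep(5, 10)))
  expect_equal(res4$test_used, "degenerate")
  expect_true(is.na(res4$p_raw))
  expect_equal(res4$bias, 5)
})

test_that("pearson matches a brute-force covariance computation", {
  expect_equal(pearson_cor(1:10, 2 * (1:10) + 1)$r, 1)
  expect_equal(pearson_cor(1:10, -3 * (1:10))$r, -1)
  expect_equal(pearson_cor(c(1, 2, 3), c(2, 1, 3))$r, 0.5)
  set.seed(37)
  for (i in 1:10) {
    x <- rnorm(25); y <- 0.4 * x + rnorm(25)
    res <- pearson_cor(x, y)
    r_brute <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(res$r, r_brute, tolerance = 1e-12)
    expect_equal(res$r_squared, r_brute^2, tolerance = 1e-12)
    expect_equal(res$p_adj, min(1, 3 * res$p_raw))
  }
  expect_error(pearson_cor(rep(1, 5), 1:5), "zero variance")
})

test_that("ICC matches the one-way ANOVA estimator on balanced data", {
  # constant distinct series per participant: all variance between
  daily1 <- data.frame(
    participant_id = rep(c("a", "b", "c"), each = 4),
    tdei_kcal = rep(c(1500, 2000, 2600), each = 4)
  )
  # zero within-variance is numerically degenerate for REML; the estimate
  # is still exact
  expect_equal(suppressWarnings(icc_random_intercept(daily1)$icc), 1,
               tolerance = 1e-6)

  # shared mean, pure noise: ICC near zero
  set.seed(41)
  daily0 <- data.frame(
    participant_id = rep(sprintf("p%02d", 1:30), each = 7),
    tdei_kcal = 2000 + rnorm(210, 0, 800)
  )
  expect_lte(icc_random_intercept(daily0)$icc, 0.05)

  # REML estimate agrees with the ANOVA moment estimator when balanced
  set.seed(43)
  mu <- rnorm(20, 0, 2)
  df <- data.frame(participant_id = rep(sprintf("p%02d", 1:20), each = 6),
                   tdei_kcal = rep(mu, each = 6) + rnorm(120, 0, 3))
  res <- icc_random_intercept(df)
  k <- 6
  anova_between <- (res$ms_between - res$ms_within) / k
  icc_anova <- anova_between / (anova_between + res$ms_within)
  expect_equal(res$icc, icc_anova, tolerance = 1e-6)
  expect_true(res$ci[["low"]] <= res$icc && res$icc <= res$ci[["high"]])
  expect_error(
    icc_random_intercept(data.frame(participant_id = c("a", "b"),
                                    tdei_kcal = c(1, 2))),
    "repeated"
  )
})

test_that("MPD is the mean of individual percentages, split by sign", {
  # uniform 10% under-reporting
  b <- c(1800, 2400, 2000)
  s1 <- over_under_summary(paired_estimates(1:3, 0.9 * b, b))
  expect_equal(s1$n_under, 3L)
  expect_equal(s1$mpd_overall, -10)

  s2 <- over_under_summary(paired_estimates(1:2, c(1200, 800), c(1000, 1000)))
  expect_equal(s2$n_over, 1L)
  expect_equal(s2$n_under, 1L)
  expect_equal(s2$mpd_over, 20)
  expect_equal(s2$mpd_under, -20)
  expect_equal(s2$mpd_overall, 0)

  s3 <- over_under_summary(paired_estimates(1:4, rep(1500, 4), rep(1500, 4)))
  expect_equal(s3$n_zero, 4L)
  expect_equal(s3$mpd_overall, 0)

  # brute-force check: MPD != percentage of means in general
  set.seed(47)
  a <- runif(30, 1000, 3000); b <- runif(30, 1500, 2800)
  s4 <- over_under_summary(paired_estimates(1:30, a, b))
  brute <- mean(sapply(seq_along(a), function(i) 100 * (a[i] - b[i]) / b[i]))
  expect_equal(s4$mpd_overall, brute, tolerance = 1e-12)
  pct_of_means <- 100 * (mean(a) - mean(b)) / mean(b)
  expect_false(isTRUE(all.equal(s4$mpd_overall, pct_of_means)))
  expect_error(over_under_summary(paired_estimates(1, 100, 0)), "positive")
})
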