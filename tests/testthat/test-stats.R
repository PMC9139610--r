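test_that("summary ANOVA reproduces published ring and sector F values", {
  # central ring, controls vs cases
  a <- anova_from_summary(group_summary(25, 32.252, 5.487),
                          group_summary(20, 21.515, 5.402))
  expect_equal(round(a$f_stat, 2), 43.13)
  expect_equal(a$df_within, 43L)
  expect_lt(a$p_value, 0.001)
  # within-control rings 1 vs 2 (regions as independent groups, df (1, 48))
  b <- anova_from_summary(group_summary(25, 32.252, 5.487),
                          group_summary(25, 14.928, 3.734))
  expect_equal(round(b$f_stat, 2), 170.33)
  expect_equal(b$df_within, 48L)
  # equal means give F = 0 whatever the SDs
  z <- anova_from_summary(group_summary(10, 5, 1), group_summary(14, 5, 3))
  expect_equal(z$f_stat, 0)
  expect_equal(z$p_value, 1)
  expect_error(anova_from_summary(group_summary(2, 1, 0), group_summary(3, 1, 0)),
               "undefined")
  expect_error(group_summary(1, 0, 1), "n >= 2")
})

test_that("raw-data ANOVA agrees with the summary formula and with t^2", {
  set.seed(7)
  for (i in 1:50) {
    a <- rnorm(sample(3:30, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    b <- rnorm(sample(3:30, 1), mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    raw <- anova_raw(a, b)
    summ <- anova_from_summary(group_summary(length(a), mean(a), sd(a)),
                               group_summary(length(b), mean(b), sd(b)))
    expect_equal(raw$f_stat, summ$f_stat, tolerance = 1e-10)
    # F = t^2 against the classical pooled t test
    tt <- t.test(a, b, var.equal = TRUE)
    expect_equal(raw$f_stat, unname(tt$statistic)^2, tolerance = 1e-10)
    expect_equal(raw$p_value, tt$p.value, tolerance = 1e-10)
  }
  # groups affinely standardized to the published outermost-ring summaries
  z1 <- as.numeric(scale(rnorm(25))); z2 <- as.numeric(scale(rnorm(20)))
  g1 <- 4.372 + 1.120 * z1; g2 <- 3.19 + 0.865 * z2
  expect_equal(round(anova_raw(g1, g2)$f_stat, 2), 15.06)
  expect_equal(anova_raw(g1, g1)$f_stat, 0)
  expect_error(anova_raw(rep(1, 5), rep(1, 7)), "undefined")
  expect_error(anova_raw(1, rnorm(5)), "at least 2")
})

test_that("linear fits reproduce the published sector r-squared values", {
  ctl <- linear_fit_r2(c(7.208, 6.868, 6.888, 7.036))
  expect_lt(abs(ctl$r_squared - 0.17), 0.01)  # printed-precision agreement
  mson <- linear_fit_r2(c(5.448, 5.481, 5.586, 5.676))
  expect_equal(round(mson$r_squared, 2), 0.96)
  # exactly collinear points
  expect_equal(linear_fit_r2(c(1, 3, 5, 7))$r_squared, 1.0)
  # r^2 is invariant to affine rescaling of x (ring index vs eccentricity)
  y <- c(9, 7, 6.5, 3, 2)
  expect_equal(linear_fit_r2(y, x = 1:5)$r_squared,
               linear_fit_r2(y, x = c(2.5, 7.5, 12.5, 17.5, 22.5))$r_squared,
               tolerance = 1e-12)
  expect_warning(f0 <- linear_fit_r2(c(2, 2, 2, 2)), "constant")
  expect_equal(f0$r_squared, 0)
  expect_error(linear_fit_r2(c(1, 2)), "at least 3")
  expect_error(linear_fit_r2(1:4, x = c(1, 3, 2, 4)), "increasing")
})

test_that("exponential fits reproduce the published ring r-squared values", {
  ctl_means <- c(32.252, 14.928, 9.448, 5.840, 4.372)
  f <- exponential_fit_r2(ctl_means)
  expect_equal(round(f$r_squared, 2), 0.97)
  expect_equal(f$space, "log")
  # case-group means: log-linear OLS gives ~0.967 (the study prints 0.95;
  # its fitting convention is not recoverable from the printed values)
  g <- exponential_fit_r2(c(21.515, 9.63, 7.02, 4.31, 3.19))
  expect_equal(g$r_squared, 0.9667, tolerance = 5e-4)
  # exact exponential data: r^2 = 1 in both modes
  y <- 5 * exp(-0.4 * (1:6))
  expect_equal(exponential_fit_r2(y)$r_squared, 1.0)
  expect_equal(suppressWarnings(exponential_fit_r2(y, mode = "nonlinear"))$r_squared,
               1.0)
  # nonlinear mode reports original-space r^2
  nl <- exponential_fit_r2(ctl_means, mode = "nonlinear")
  expect_equal(nl$space, "original")
  expect_gt(nl$r_squared, 0.97)
  expect_error(exponential_fit_r2(c(3, -1, 2)), "positive")
})

test_that("KS normality behaves under the null and against uniform data", {
  null_p <- vapply(1:100, function(s) {
    set.seed(s)
    ks_normality(rnorm(100))$p_value
  }, numeric(1))
  expect_gte(sum(null_p > 0.05), 90)
  unif_p <- vapply(1:100, function(s) {
    set.seed(s)
    ks_normality(runif(1000))$p_value
  }, numeric(1))
  expect_gte(sum(unif_p < 0.01), 95)
  expect_error(ks_normality(rep(1, 10)), "Constant")
  expect_error(ks_normality(rnorm(4)), "at least 5")
})

test_that("the power computation reproduces the published sample size", {
  pilot_c <- group_summary(12, 31.1, 6.2)
  pilot_m <- group_summary(10, 21.8, 5.9)
  pw <- power_sample_size(pilot_c, pilot_m)
  expect_equal(pw$n_per_group, 14L)
  expect_gte(pw$achieved_power, 0.90)
  # the same pilot with the pooled planning SD needs one eye more
  pw_pooled <- power_sample_size(pilot_c, pilot_m, planning_sd = "pooled")
  expect_equal(pw_pooled$n_per_group, 15L)
  # cross-check against the stock noncentral-t solver: the continuous
  # solutions bracket the two integer answers
  ct_case <- power.t.test(delta = 31.1 - 21.8, sd = 5.9, sig.level = 0.01,
                          power = 0.90, type = "two.sample")
  expect_equal(ceiling(ct_case$n), 14)
  ct_pool <- power.t.test(delta = 31.1 - 21.8, sd = pw_pooled$planning_sd_value,
                          sig.level = 0.01, power = 0.90, type = "two.sample")
  expect_equal(ceiling(ct_pool$n), 15)
  # monotonicity: a larger effect never needs more eyes; a stricter power
  # target never needs fewer
  pw_big <- power_sample_size(group_summary(12, 40.4, 6.2), pilot_m)
  expect_lte(pw_big$n_per_group, pw$n_per_group)
  pw_strict <- power_sample_size(pilot_c, pilot_m, power = 0.9999)
  expect_gt(pw_strict$n_per_group, pw$n_per_group)
  expect_error(power_sample_size(pilot_c, group_summary(10, 31.1, 5.9)),
               "Zero pilot effect")
})

test_that("tidiers expose results as tibbles", {
  a <- anova_from_summary(group_summary(25, 32.252, 5.487),
                          group_summary(20, 21.515, 5.402))
  expect_equal(tidy(a)$f_stat, a$f_stat)
  expect_equal(glance(a)$df_within, 43L)
  f <- linear_fit_r2(c(3, 2.5, 2, 1))
  expect_equal(tidy(f)$term, c("intercept", "slope"))
  expect_equal(glance(f)$r_squared, f$r_squared)
  pw <- power_sample_size(group_summary(12, 31.1, 6.2),
                          group_summary(10, 21.8, 5.9))
  expect_equal(tidy(pw)$n_per_group, 14L)
})
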