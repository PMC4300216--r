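test_that("interval averaging of instrumental series is exact and conservative", {
  ser <- instrumental_series("feb_mean_temp", 1820:1823, c(1, 2, 3, 4))
  rec1 <- reconstruction_series(1822, 1822, -10)
  al1 <- align_to_intervals(ser, rec1)
  expect_equal(al1$instrumental, 3)  # 1-year interval is that year's value

  rec4 <- reconstruction_series(1820, 1823, -10)
  expect_equal(align_to_intervals(ser, rec4)$instrumental, 2.5)

  # 15 four-year samples over 1820-1879 against an 1820-1876 series:
  # the last full interval is 1872-1875, so 14 samples survive
  starts <- seq(1820, by = 4, length.out = 15)
  recs <- reconstruction_series(starts, starts + 3, rnorm(15))
  ser2 <- instrumental_series("feb_mean_temp", 1820:1876, rnorm(57))
  expect_message(al <- align_to_intervals(ser2, recs), "partially covered")
  expect_identical(nrow(al), 14L)
  expect_identical(max(al$end_year), 1875L)

  # conservation: with full equal-length coverage, the mean of aligned
  # values equals the mean of the covered annual values
  covered <- ser2$years >= 1820 & ser2$years <= 1875
  expect_equal(mean(al$instrumental), mean(ser2$values[covered]),
               tolerance = 1e-12)

  expect_error(align_to_intervals(ser, reconstruction_series(1900, 1903, 0)),
               "no reconstruction samples")
  expect_error(instrumental_series("x", c(1820, 1822), c(1, 2)), "contiguous")
})

test_that("the t-test on means uses Welch degrees of freedom", {
  a <- c(0, 1, 2)
  b <- c(10, 11, 12)
  rep <- welch_t_test(a, b)
  # brute-force formula oracle
  t_hand <- (mean(a) - mean(b)) / sqrt(var(a) / 3 + var(b) / 3)
  df_hand <- (var(a) / 3 + var(b) / 3)^2 /
    ((var(a) / 3)^2 / 2 + (var(b) / 3)^2 / 2)
  expect_equal(rep$statistic, t_hand, tolerance = 1e-12)
  expect_equal(rep$df, df_hand, tolerance = 1e-12)
  expect_equal(rep$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)

  expect_equal(welch_t_test(a, a)$statistic, 0)

  # equal variances at n = 15 vs 15 give df near 28; strongly unequal
  # variances pull df towards the noisier group's 14
  set.seed(7)
  x <- rnorm(15); y <- rnorm(15)
  y_eq <- (y - mean(y)) / sd(y) * sd(x) + mean(y)
  expect_equal(welch_t_test(x, y_eq)$df, 28, tolerance = 1e-6)
  expect_lt(welch_t_test(x * 0.05, y)$df, 16)

  # the pooled switch restores Student's df = n1 + n2 - 2
  expect_equal(welch_t_test(x, y, var_equal = TRUE)$df, 28)
  expect_error(welch_t_test(1, b), "n >= 2")
})

test_that("variance F-tests work from data and from summary statistics", {
  set.seed(8)
  a <- rnorm(15, sd = 2); b <- rnorm(15)
  rep <- variance_f_test(a, b)
  f_hand <- var(a) / var(b)
  expect_equal(rep$statistic, f_hand, tolerance = 1e-12)
  expect_equal(rep$df, c(14, 14))
  tail <- pf(f_hand, 14, 14)
  expect_equal(rep$p_value, 2 * min(tail, 1 - tail), tolerance = 1e-12)

  expect_equal(variance_f_test(a, a)$statistic, 1)
  expect_error(variance_f_test(a, rep(1, 15)), "zero variance")

  # published-table path: sds in, F out
  s <- variance_f_test_summary(0.38, 2.17, 14, 14)
  expect_equal(s$statistic, 0.38^2 / 2.17^2, tolerance = 1e-12)
  expect_equal(round(s$statistic, 3), 0.031)
  expect_lt(s$p_value, 1e-6)
})

test_that("paired t-test handles frozen cases and degenerate differences", {
  rep3 <- paired_t_test(c(1, 2, 3))
  expect_equal(rep3$statistic, 2 / (1 / sqrt(3)), tolerance = 1e-12)
  expect_equal(rep3$df, 2)

  expect_equal(paired_t_test(rep(0, 5))$statistic, 0)
  expect_equal(paired_t_test(rnorm(133))$df, 132)
  expect_error(paired_t_test(1), "n >= 2")
})

test_that("OLS trend recovers slope, total change, and slope test", {
  toy <- instrumental_series("x", 1:5, c(2, 4, 6, 8, 10))
  tr <- suppressWarnings(ols_trend(toy))  # "essentially perfect fit"
  expect_equal(tr$slope, 2, tolerance = 1e-12)
  expect_equal(tr$total_change, 8, tolerance = 1e-12)
  expect_lt(tr$p_value, 1e-20)  # exact line: p collapses towards zero

  set.seed(9)
  ser <- instrumental_series("x", 1820:2012, 0.01 * (0:192) + rnorm(193))
  tr2 <- ols_trend(ser)
  expect_identical(tr2$df, 191)
  fit <- lm(ser$values ~ ser$years)
  expect_equal(tr2$t, summary(fit)$coefficients[2, 3], tolerance = 1e-12)

  expect_error(ols_trend(instrumental_series("x", 1:2, c(1, 2))), "n >= 3")
})

test_that("moving averages smooth with truncated ends", {
  expect_equal(moving_average(rep(4, 10)), rep(4, 10))
  ma <- moving_average(1:5, 5)
  expect_equal(ma[3], 3)
  expect_equal(ma[1], mean(1:3))  # truncated left end
  expect_error(moving_average(1:5, 4), "odd")

  set.seed(10)
  for (i in 1:5) {
    x <- rnorm(60)
    expect_lte(var(moving_average(x, 5)), var(x))
  }
})

test_that("period means and captured variance summarize reconstructions", {
  rec <- reconstruction_series(c(1200, 1204, 1900), c(1203, 1207, 1903),
                               c(-12, -10, -8))
  expect_equal(period_mean(rec, 1199, 1210), -11)
  expect_equal(period_mean(rec, 1900, 1905), -8)  # single sample
  expect_error(period_mean(rec, 1500, 1600), "no samples")

  x <- rnorm(20)
  expect_equal(variance_captured(x, x), 100)
  expect_equal(variance_captured(rep(1, 20), x), 0)
  expect_error(variance_captured(x, rep(2, 20)), "zero instrumental")
})

test_that("regression extension splices short station records", {
  yrs <- 1820:1900
  set.seed(11)
  ref_vals <- rnorm(length(yrs), 0, 2)
  ref <- instrumental_series("x", yrs, ref_vals)

  # exact linear relation with a gap before 1886: gap years recovered exactly
  tgt <- instrumental_series("x", 1886:1900,
                             2 * ref_vals[yrs >= 1886] + 1)
  ext <- suppressWarnings(extend_series_by_regression(tgt, ref))  # perfect fit
  expect_identical(ext$years, yrs)
  expect_equal(ext$values, 2 * ref_vals + 1, tolerance = 1e-9)
  expect_equal(attr(ext, "r2_adj"), 1, tolerance = 1e-9)

  # identity: target == reference
  ext2 <- suppressWarnings(extend_series_by_regression(ref, ref))
  expect_equal(ext2$values, ref_vals, tolerance = 1e-12)

  # noisy relation: fill errors behave like the residual sd
  true_gap <- 2 * ref_vals[yrs < 1886] + 1
  noisy <- instrumental_series("x", 1886:1900,
                               2 * ref_vals[yrs >= 1886] + 1 +
                                 rnorm(15, 0, 0.4))
  ext3 <- extend_series_by_regression(noisy, ref)
  fill <- ext3$values[yrs < 1886]
  expect_lt(sqrt(mean((fill - true_gap)^2)), 1.0)
  expect_gt(attr(ext3, "r2_adj"), 0.9)

  expect_error(
    extend_series_by_regression(
      instrumental_series("x", 1896:1900, rnorm(5)), ref),
    "overlapping years")
})
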