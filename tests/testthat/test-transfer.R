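test_that("one-component WA-PLS matches classical WA with inverse deshrinking", {
  # percentages give equal site weights, so the two estimators coincide
  for (seed in 1:5) {
    cal <- random_cal(12, 6, seed)
    tf <- fit_wapls(cal, "feb_mean_temp", n_components = 1)
    wa <- fit_wa_inverse(cal, "feb_mean_temp")
    expect_equal(unname(tf$fitted), unname(wa$fitted), tolerance = 1e-8)
    # and on unseen samples
    new <- random_cal(5, 6, seed + 100)$pollen
    expect_equal(unname(predict(tf, new)), unname(wa$predict(new)),
                 tolerance = 1e-8)
  }
})

test_that("degenerate gradients and malformed inputs are refused", {
  # every site shares one assemblage: no gradient information
  vals <- matrix(rep(c(50, 30, 20), each = 6), 6, 3,
                 dimnames = list(paste0("s", 1:6), c("A", "B", "C")))
  cal <- calibration_set(pollen_matrix(vals, kind = "percent"),
                         climate_table(paste0("s", 1:6),
                                       feb_mean_temp = c(-14, -13, -12, -11,
                                                         -10, -9)))
  expect_error(fit_wapls(cal, "feb_mean_temp", 1), "degenerate component")

  cal2 <- random_cal(8, 5, 1)
  cal2$climate$feb_mean_temp <- rep(-10, 8)
  expect_error(fit_wapls(cal2, "feb_mean_temp"), "constant")
  expect_error(fit_wapls(random_cal(8, 5, 1), "nope"), "not in climate")
})

test_that("apparent residuals have weighted mean zero and components are orthonormal", {
  for (seed in c(2, 3)) {
    cal <- random_cal(20, 8, seed)
    tf <- fit_wapls(cal, "feb_mean_temp", n_components = 3)
    expect_lt(abs(sum(tf$site_weights * tf$residuals)), 1e-10)

    # reconstruct the standardized component scores from the model and
    # check weighted orthonormality
    scores <- matrix(0, 20, 3)
    y <- cal$pollen$values[, tf$taxa]
    rs <- rowSums(y)
    for (a in 1:3) {
      s <- as.vector(y %*% tf$taxon_scores[, a]) / rs
      tr <- tf$transforms[[a]]
      if (a > 1) s <- s - as.vector(scores[, 1:(a - 1), drop = FALSE] %*% tr$ortho)
      scores[, a] <- (s - tr$mean) / tr$sd
    }
    w <- tf$site_weights
    for (a in 1:3) {
      expect_equal(sum(w * scores[, a]^2), 1, tolerance = 1e-8)
      for (b in seq_len(a - 1))
        expect_lt(abs(sum(w * scores[, a] * scores[, b])), 1e-8)
    }
  }
})

test_that("prediction is self-consistent, scale-invariant, and duplicate-stable", {
  cal <- random_cal(15, 7, 4)
  tf <- fit_wapls(cal, "feb_mean_temp", 2)

  # predicting the training set reproduces the apparent predictions
  expect_equal(unname(predict(tf, cal$pollen)), unname(tf$fitted),
               tolerance = 1e-10)

  # a sample equal to training site 3 gets site 3's apparent prediction
  one <- cal$pollen$values[3, , drop = FALSE]
  expect_equal(unname(predict(tf, one)), unname(tf$fitted[3]),
               tolerance = 1e-10)

  # multiplying a sample's percentages by a positive constant changes nothing
  expect_equal(unname(predict(tf, one * 7.3)), unname(tf$fitted[3]),
               tolerance = 1e-10)

  # duplicating every training site leaves the fit unchanged
  dbl <- cal_subset(cal, rep(seq_len(15), 2))
  tf2 <- fit_wapls(dbl, "feb_mean_temp", 2)
  expect_equal(unname(predict(tf2, cal$pollen)), unname(predict(tf, cal$pollen)),
               tolerance = 1e-8)

  # taxa unknown to the model are dropped from scoring
  extra <- cbind(one, Novel = 25)
  expect_message(p <- predict(tf, extra), "absent from training")
  expect_equal(unname(p), unname(tf$fitted[3]), tolerance = 1e-10)
})

test_that("leave-one-out cross-validation runs small and estimates honestly", {
  # structural: n = 4 sites yields 4 residuals
  cv4 <- loo_cross_validate(random_cal(4, 5, 6), "feb_mean_temp", 1)
  expect_length(cv4$residual, 4)

  # RMSEP_loo >= RMSE_app is the typical ordering; allow one exception
  worse <- 0
  for (seed in 1:20) {
    cal <- random_cal(25, 6, seed + 300)
    cv <- loo_cross_validate(cal, "feb_mean_temp", 2)
    if (cv$rmsep_loo < cv$rmse_app) worse <- worse + 1
  }
  expect_lte(worse, 1)
})

test_that("bootstrap RMSEP decomposes, reproduces, and tracks the LOO estimate", {
  cal <- synth_world(101)$cal
  bt <- bootstrap_rmsep(cal, "feb_mean_temp", 2, n_boot = 300, seed = 5)
  expect_equal(bt$rmsep_boot^2, bt$s1^2 + bt$s2^2, tolerance = 1e-9)

  bt2 <- bootstrap_rmsep(cal, "feb_mean_temp", 2, n_boot = 300, seed = 5)
  expect_identical(bt$rmsep_boot, bt2$rmsep_boot)
  expect_false(identical(
    bt$rmsep_boot,
    bootstrap_rmsep(cal, "feb_mean_temp", 2, n_boot = 300, seed = 6)$rmsep_boot))

  # the two validators agree on a well-behaved synthetic set
  cv <- loo_cross_validate(cal, "feb_mean_temp", 2)
  expect_lt(abs(bt$rmsep_boot - cv$rmsep_loo) / cv$rmsep_loo, 0.15)

  # too few cycles to see every site out-of-bag twice
  expect_error(bootstrap_rmsep(cal, "feb_mean_temp", 2, n_boot = 1, seed = 1),
               "increase n_boot")
})

test_that("noise-free responses make the bootstrap error mostly bias (s2)", {
  n <- 150
  pool <- make_species_pool(15, seed = 31)
  set.seed(32)
  g <- runif(n)
  cf <- data.frame(
    feb_mean_temp = -18 + g * 12,
    may_mean_temp = 8 + g * 10)
  expected <- t(apply(cf, 1, function(x)
    expected_assemblage(pool, c(feb_mean_temp = unname(x[1]),
                                may_mean_temp = unname(x[2])))))
  pm <- pollen_matrix(expected * 100,
                      ids = sprintf("s%03d", 1:n), taxa = pool$taxa,
                      kind = "percent", tol = 1e-6)
  cal <- calibration_set(pm, climate_table(sprintf("s%03d", 1:n),
                                           feb_mean_temp = cf$feb_mean_temp))
  bt <- bootstrap_rmsep(cal, "feb_mean_temp", 2, n_boot = 200, seed = 33)
  # without count noise the resampling variability s1 is a small part of
  # the error; what remains is the systematic misfit captured by s2
  expect_lt(bt$s1, 0.25 * bt$s2)
  expect_equal(bt$rmsep_boot / bt$s2, 1, tolerance = 0.05)
})

test_that("models serialize to JSON and back without changing predictions", {
  cal <- random_cal(18, 9, 8)
  tf <- fit_wapls(cal, "feb_mean_temp", 2)
  path <- withr::local_tempfile(fileext = ".json")
  write_wapls(tf, path)
  back <- read_wapls(path)
  expect_equal(unname(predict(back, cal$pollen)), unname(tf$fitted),
               tolerance = 1e-12)
  expect_identical(back$taxa, tf$taxa)
})
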