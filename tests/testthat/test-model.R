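# simulate an unbalanced study design (fixed + home sites), returning the
# log-scale panel the model consumes
study_panel <- function(n_home, grid, truth, n_fixed = 7, seed = 1) {
  sites <- generate_sites(c(NPACT_FIXED = n_fixed, NPACT_HOME = n_home),
                          seed = seed)
  latent <- simulate_latent_panel(sites, grid, truth)
  recs <- sample_network(latent, sites, seed = seed)
  raw <- to_two_week_panel(recs, sites, grid)
  panel <- panel_matrix(log(raw$values), raw$site_ids, grid, scale = "LOG",
                        mask = raw$mask)
  list(panel = panel, sites = sites, latent = latent)
}

test_that("zero-noise data reproduce the generating coefficients exactly", {
  grid <- tiny_grid(12)
  truth <- field_truth(c(1, 0.5), c(0, 0), seasonal_trend(grid), amp0 = 0.8,
                       resid_sill = 0, seed = 73)
  sp <- study_panel(20, grid, truth, seed = 73)
  fit <- fit_simplified(sp$panel, sp$sites, truth$trend, "constant")
  expect_equal(unname(fit$gamma0_hat), c(1, 0.5), tolerance = 1e-9)
  expect_equal(fit$theta_hat, 0.8, tolerance = 1e-9)
  expect_equal(fit$mu0_hat, 0, tolerance = 1e-9)
  expect_equal(fit$sigma2_hat, 0, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)

  cov_truth <- field_truth(c(1, 0.5), c(0.3, -0.2), seasonal_trend(grid),
                           amp0 = 0.6, resid_sill = 0, seed = 73)
  sp2 <- study_panel(20, grid, cov_truth, seed = 73)
  fit2 <- fit_simplified(sp2$panel, sp2$sites, cov_truth$trend, "covariate")
  expect_equal(unname(fit2$gamma1_hat), c(0.3, -0.2), tolerance = 1e-8)
  expect_equal(fit2$amp0_hat, 0.6, tolerance = 1e-8)
})

test_that("tidy and glance expose coefficients and fit summaries", {
  grid <- tiny_grid(10)
  truth <- field_truth(c(0.5, 0.2), c(0, 0), seasonal_trend(grid),
                       amp0 = 0.5, resid_sill = 0.02, resid_range_km = 5,
                       seed = 79)
  sp <- study_panel(15, grid, truth, seed = 79)
  fit <- fit_simplified(sp$panel, sp$sites, truth$trend, "constant")
  td <- tidy(fit)
  expect_equal(td$term, c("mu0", "gamma0_cov_1", "gamma0_cov_2", "theta"))
  expect_true(all(td$std.error > 0))
  gl <- glance(fit)
  expect_equal(gl$nobs, fit$n_obs)
  expect_equal(gl$df.residual, fit$n_obs - 4L)
  # standard errors match lm on the same design
  long <- as_tibble(sp$panel)
  X <- as.matrix(sp$sites[match(long$site_id, sp$sites$site_id),
                          c("cov_1", "cov_2")])
  df <- data.frame(y = long$value, x1 = X[, 1], x2 = X[, 2],
                   f = truth$trend$values[long$period])
  lmfit <- stats::lm(y ~ x1 + x2 + f, data = df)
  expect_equal(unname(td$estimate), unname(stats::coef(lmfit)),
               tolerance = 1e-10)
  expect_equal(unname(td$std.error),
               unname(sqrt(diag(stats::vcov(lmfit)))), tolerance = 1e-10)
})

test_that("rank-deficient designs name the collinear columns", {
  grid <- tiny_grid(8)
  truth <- field_truth(c(0.5, 0.2), c(0, 0), seasonal_trend(grid),
                       resid_sill = 0, seed = 83)
  sp <- study_panel(10, grid, truth, seed = 83)
  sites_bad <- sp$sites
  sites_bad$cov_2 <- 2 * sites_bad$cov_1
  expect_error(fit_simplified(sp$panel, sites_bad, truth$trend, "constant"),
               "collinear")
})

test_that("coefficient sampling variance scales roughly as 1/n", {
  grid <- tiny_grid(10)
  tf <- seasonal_trend(grid)
  est <- function(n_home, seed) {
    truth <- field_truth(c(0.6, 0.3), c(0, 0), tf, amp0 = 0.5,
                         resid_sill = 0.04, resid_range_km = 0.01,
                         seed = seed)
    sp <- study_panel(n_home, grid, truth, n_fixed = 5, seed = seed)
    fit <- fit_simplified(sp$panel, sp$sites, tf, "constant")
    fit$gamma0_hat[["cov_1"]]
  }
  small <- vapply(1:100, function(i) est(20, 1000 + i), numeric(1))
  big <- vapply(1:100, function(i) est(45, 2000 + i), numeric(1))
  # ~doubling the observation count should roughly halve the variance
  ratio <- stats::var(big) / stats::var(small)
  expect_gt(ratio, 0.25)
  expect_lt(ratio, 0.8)
})

test_that("long-term predictions reduce to the site mean in the noiseless limit", {
  grid <- tiny_grid(12)
  truth <- field_truth(c(0.8, 0.4), c(0, 0), seasonal_trend(grid),
                       amp0 = 0.7, resid_sill = 0, seed = 89)
  sp <- study_panel(15, grid, truth, seed = 89)
  fit <- fit_simplified(sp$panel, sp$sites, truth$trend, "constant")
  fixed_id <- sp$sites$site_id[sp$sites$network == "NPACT_FIXED"][1]
  pred <- predict_long_term(fit, sp$sites[sp$sites$site_id == fixed_id, ])
  i <- match(fixed_id, sp$panel$site_ids)
  expect_equal(pred$prediction, mean(sp$panel$values[i, ]), tolerance = 1e-9)
  # degenerate single-period window
  pred5 <- predict_long_term(fit, sp$sites[sp$sites$site_id == fixed_id, ],
                             window = 5)
  x <- as.numeric(sp$sites[match(fixed_id, sp$sites$site_id),
                           c("cov_1", "cov_2")])
  expect_equal(pred5$prediction,
               fit$mu0_hat + sum(x * fit$gamma0_hat) +
                 fit$theta_hat * truth$trend$values[5],
               tolerance = 1e-9)
  bad <- sp$sites[1, ]
  names(bad)[names(bad) == "cov_2"] <- "cov_zzz"
  expect_error(predict_long_term(fit, bad), "covariates")
})

test_that("held-out prediction RMSE matches the analytic error budget", {
  grid <- tiny_grid(20)
  tf <- seasonal_trend(grid)
  sd_e <- 0.2
  res <- vapply(1:100, function(i) {
    truth <- field_truth(c(0.6, 0.3), c(0, 0), tf, amp0 = 0.5,
                         resid_sill = sd_e^2, resid_range_km = 0.01,
                         seed = 3000 + i)
    sites <- generate_sites(c(NPACT_FIXED = 7, NPACT_HOME = 60),
                            seed = 3000 + i)
    latent <- simulate_latent_panel(sites, grid, truth)
    train_ids <- sites$site_id[1:57]
    test_ids <- sites$site_id[58:67]
    panel <- panel_matrix(latent$values[match(train_ids, latent$site_ids), ],
                          train_ids, grid, scale = "LOG")
    fit <- fit_simplified(panel, sites[match(train_ids, sites$site_id), ],
                          tf, "constant")
    pred <- predict_long_term(fit, sites[match(test_ids, sites$site_id), ])
    true_lt <- truth$mu0 +
      as.matrix(sites[match(test_ids, sites$site_id),
                      c("cov_1", "cov_2")]) %*% truth$gamma0 +
      0.5 * mean(tf$values)
    c(mse = mean((pred$prediction - true_lt)^2),
      analytic = mean(pred$se^2))
  }, numeric(2))
  # observed squared prediction error should match the plug-in coefficient
  # covariance (the analytic estimation-error budget; truth has no site
  # effect so that is the whole error)
  expect_equal(sqrt(mean(res["mse", ])), sqrt(mean(res["analytic", ])),
               tolerance = 0.2)
})

test_that("leave-one-site-out is perfectly calibrated without noise", {
  grid <- tiny_grid(12)
  truth <- field_truth(c(0.8, 0.4), c(0, 0), seasonal_trend(grid),
                       amp0 = 0.7, resid_sill = 0, seed = 97)
  sp <- study_panel(20, grid, truth, seed = 97)
  cv <- loso_cv(sp$panel, sp$sites, truth$trend, "constant")
  expect_equal(cv$cv_r2, 1, tolerance = 1e-6)
  expect_equal(cv$n_failed, 0)
})

test_that("constant amplitude underfits covariate-varying amplitudes", {
  grid <- tiny_grid(15)
  truth <- field_truth(c(0.5, 0.3), c(0.6, -0.4), seasonal_trend(grid),
                       amp0 = 0.5, resid_sill = 0.01, resid_range_km = 0.01,
                       seed = 101)
  sp <- study_panel(40, grid, truth, seed = 101)
  fit_c <- fit_simplified(sp$panel, sp$sites, truth$trend, "constant")
  fit_v <- fit_simplified(sp$panel, sp$sites, truth$trend, "covariate")
  expect_gt(fit_c$sigma2_hat, fit_v$sigma2_hat)
})
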