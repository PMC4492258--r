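coloc_sites <- function() {
  s <- manual_sites(2, network = c("NPACT_FIXED", "CSN_CORE"))
  s$coloc_group <- "g1"
  s$x_km <- c(5, 5); s$y_km <- c(5, 5)
  s
}

test_that("pairing collects exactly the jointly observed periods", {
  grid <- tiny_grid(6)
  mask_x <- matrix(TRUE, 2, 6); mask_x[1, 5:6] <- FALSE
  mask_y <- matrix(TRUE, 2, 6); mask_y[2, 1] <- FALSE
  px <- manual_panel(seq_len(12), 2, grid, mask = mask_x)
  py <- manual_panel(seq_len(12) + 1, 2, grid, mask = mask_y)
  pairs <- pair_colocated(px, py, coloc_sites(), "NPACT_FIXED", "CSN_CORE")
  # site 1 (x) observed 1:4; site 2 (y) observed 2:6 -> common 2:4
  expect_equal(pairs$period, 2:4)
  expect_equal(pairs$group_id, rep("g1", 3))

  win <- pair_colocated(px, py, coloc_sites(), "NPACT_FIXED", "CSN_CORE",
                        period_window = grid$periods$center[c(3, 6)])
  expect_equal(win$period, 3:4)

  none <- pair_colocated(px, py, coloc_sites(), "NPACT_FIXED", "CSN_CORE",
                         period_window = grid$periods$center[c(5, 5)])
  expect_equal(nrow(none), 0)
})

test_that("pairing equals a brute-force set intersection on simulated masks", {
  grid <- build_period_grid(wed, 200)
  withr::with_seed(31, {
    mx <- matrix(stats::runif(2 * 200) < 0.7, 2, 200)
    my <- matrix(stats::runif(2 * 200) < 0.7, 2, 200)
  })
  vx <- matrix(stats::rnorm(400), 2, 200); vx[!mx] <- NA
  vy <- matrix(stats::rnorm(400), 2, 200); vy[!my] <- NA
  px <- panel_matrix(vx, c("s01", "s02"), grid, scale = "LOG", mask = mx)
  py <- panel_matrix(vy, c("s01", "s02"), grid, scale = "LOG", mask = my)
  window <- grid$periods$center[c(1, 100)]
  pairs <- pair_colocated(px, py, coloc_sites(), "NPACT_FIXED", "CSN_CORE",
                          period_window = window)
  brute <- intersect(which(mx[1, ]), which(my[2, ]))
  brute <- brute[brute <= 100]
  expect_equal(pairs$period, brute)
})

test_that("comparison statistics match closed forms", {
  grid <- tiny_grid(5)
  x <- c(1, 2, 3, 4, 5)
  px <- manual_panel(rep(x, each = 2), 2, grid)
  pairs <- pair_colocated(px, px, coloc_sites(), "NPACT_FIXED", "CSN_CORE")
  cmp <- compare_colocated(pairs)
  expect_equal(cmp$pearson_r, 1)
  expect_equal(cmp$slope, 1)
  expect_equal(cmp$intercept, 0)
  expect_equal(cmp$mean_diff, 0)
  expect_equal(cmp$n_pairs, 5L)
})

test_that("a pure multiplicative bias shows up as a log-scale intercept shift", {
  grid <- tiny_grid(8)
  vals <- matrix(seq(0.5, 2, length.out = 8), 2, 8, byrow = TRUE)
  vals[2, ] <- vals[2, ] + log(0.8)  # y = x + ln 0.8 on the log scale
  p <- panel_matrix(vals, c("s01", "s02"), grid, scale = "LOG")
  pairs <- pair_colocated(p, p, coloc_sites(), "NPACT_FIXED", "CSN_CORE")
  # x from site 1, y from site 2
  cmp <- compare_colocated(pairs)
  expect_equal(cmp$pearson_r, 1)
  expect_equal(cmp$slope, 1, tolerance = 1e-12)
  expect_equal(cmp$intercept, log(0.8), tolerance = 1e-12)
})

test_that("r, slope and intercept agree with textbook formulas on random inputs", {
  withr::with_seed(37, {
    for (rep in 1:10) {
      n <- sample(4:12, 1)
      x <- stats::rnorm(n)
      y <- 0.5 * x + stats::rnorm(n, 0, 0.3)
      pairs <- tibble::tibble(group_id = "g", site_x = "a", site_y = "b",
                              period = seq_len(n), x = x, y = y)
      cmp <- compare_colocated(pairs)
      expect_equal(cmp$pearson_r, stats::cor(x, y), tolerance = 1e-12)
      fit <- stats::lm(y ~ x)
      expect_equal(cmp$slope, unname(stats::coef(fit)[2]), tolerance = 1e-12)
      expect_equal(cmp$intercept, unname(stats::coef(fit)[1]),
                   tolerance = 1e-12)
      expect_equal(cmp$mean_diff, mean(y - x), tolerance = 1e-12)
    }
  })
})

test_that("noisy co-location recovers the analytic correlation of the noise model", {
  # y = x + mean-one lognormal noise on the raw scale; on the log scale
  # y_log = x_log + e with e ~ N(-s^2/2, s^2), s^2 = ln(1 + cv^2);
  # analytic cor = sd(x) / sqrt(sd(x)^2 + s2)
  grid <- build_period_grid(wed, 100)
  sites <- coloc_sites()
  truth <- field_truth(c(0, 0), c(0, 0), seasonal_trend(grid), mu0 = 1,
                       amp0 = 1, resid_sill = 0.2, resid_range_km = 5,
                       nugget = 0, seed = 41)
  latent <- simulate_latent_panel(sites, grid, truth)
  dist <- default_distortions()
  dist$CSN_CORE <- network_distortion(noise_cv = 0.5)
  # integrated sampling at both sites so values stay on the 2-week scale
  design <- default_network_design()
  design$CSN_CORE <- list(type = "integrated")
  recs <- sample_network(latent, sites, design = design, distortion = dist,
                         seed = 41)
  panel <- to_two_week_panel(recs, sites, grid)
  lp <- panel_matrix(log(panel$values), panel$site_ids, grid, scale = "LOG")
  pairs <- pair_colocated(lp, lp, sites, "NPACT_FIXED", "CSN_CORE")
  cmp <- compare_colocated(pairs)
  s2 <- log(1 + 0.5^2)
  analytic <- stats::sd(pairs$x) / sqrt(stats::sd(pairs$x)^2 + s2)
  expect_equal(cmp$pearson_r, analytic, tolerance = 0.15)
})

test_that("degenerate comparison inputs error", {
  pairs <- tibble::tibble(group_id = "g", site_x = "a", site_y = "b",
                          period = 1:2, x = c(1, 2), y = c(1, 2))
  expect_error(compare_colocated(pairs), ">= 3")
  flat <- tibble::tibble(group_id = "g", site_x = "a", site_y = "b",
                         period = 1:4, x = rep(1, 4), y = 1:4)
  expect_error(compare_colocated(flat), "zero variance")
})

test_that("smoothing a constant panel returns the constant", {
  grid <- tiny_grid(10)
  p <- manual_panel(rep(5, 30), 3, grid)
  pat <- smooth_temporal_pattern(p)
  expect_equal(pat$values, rep(5, 10), tolerance = 1e-12)
  expect_equal(pat$n_sites_used, 3L)
})

test_that("a small bandwidth interpolates a single site's series", {
  grid <- tiny_grid(12)
  y <- sin(seq_len(12))
  p <- manual_panel(y, 1, grid)
  pat <- smooth_temporal_pattern(p, bandwidth = 1.0001)
  expect_equal(pat$values, y, tolerance = 1e-6)
})

test_that("the smoother is linear in the data", {
  grid <- tiny_grid(15)
  withr::with_seed(43, {
    vals <- matrix(stats::rnorm(4 * 15), 4, 15)
    vals[sample(60, 10)] <- NA
  })
  p <- panel_matrix(vals, sprintf("s%02d", 1:4), grid, scale = "LOG")
  p2 <- panel_matrix(2.5 * vals + 1, sprintf("s%02d", 1:4), grid,
                     scale = "LOG")
  a <- smooth_temporal_pattern(p, bandwidth = 4)
  b <- smooth_temporal_pattern(p2, bandwidth = 4)
  expect_equal(b$values, 2.5 * a$values + 1, tolerance = 1e-10)
})

test_that("no extrapolation beyond the observed period range", {
  grid <- tiny_grid(10)
  mask <- matrix(FALSE, 1, 10); mask[1, 3:7] <- TRUE
  p <- manual_panel(seq_len(10), 1, grid, mask = mask)
  pat <- smooth_temporal_pattern(p, bandwidth = 3)
  expect_true(all(is.na(pat$values[c(1, 2, 8, 9, 10)])))
  expect_true(all(is.finite(pat$values[3:7])))
})

test_that("smoothed fixed-site pattern tracks the true trend under noise", {
  grid <- build_period_grid(wed, 100)
  r1 <- rank1_panel(7, grid, noise_sd = 0.3, seed = 47)
  pat <- smooth_temporal_pattern(r1$panel, bandwidth = 4)
  expect_gte(stats::cor(pat$values, r1$f), 0.95)
})

test_that("pattern comparison metrics behave on identical, negated and thinned inputs", {
  grid <- tiny_grid(10)
  p <- manual_panel(sin(seq_len(30)), 3, grid)
  a <- smooth_temporal_pattern(p, bandwidth = 3)
  self <- compare_patterns(a, a)
  expect_equal(self$pearson_r, 1)
  expect_equal(self$rmse, 0)
  neg <- a; neg$values <- -a$values
  expect_equal(compare_patterns(a, neg)$pearson_r, -1)

  # full vs every-6th-day thinned, zero noise -> identical patterns
  sites <- manual_sites(4, network = "CSN_CORE")
  truth <- field_truth(c(0.3, 0.1), c(0.2, 0), seasonal_trend(grid),
                       mu0 = 0.5, resid_sill = 0, seed = 53)
  recs <- sample_network(simulate_latent_panel(sites, grid, truth), sites,
                         seed = 53)
  thin <- subsample_every_sixth(recs)
  pol <- aggregation_policy(min_daily_per_period = 2)
  pf <- transform_panel(to_two_week_panel(recs, sites, grid, pol))
  pt <- transform_panel(to_two_week_panel(thin, sites, grid, pol))
  cmp <- compare_patterns(smooth_temporal_pattern(pf, bandwidth = 3),
                          smooth_temporal_pattern(pt, bandwidth = 3))
  expect_equal(cmp$pearson_r, 1, tolerance = 1e-3)
})
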