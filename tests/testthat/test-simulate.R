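test_that("region preset reproduces study-area site counts", {
  la <- region_preset("los_angeles")
  expect_equal(sum(la), 137L)
  sites <- generate_sites(la, seed = 1)
  expect_equal(nrow(sites), 137L)
  expect_equal(sum(sites$network == "NPACT_HOME"), 116L)
  expect_equal(sum(sites$network %in% c("CSN_CORE", "CSN_SUPP")), 6L)
  expect_equal(nrow(generate_sites(c(NPACT_FIXED = 0), seed = 1)), 0L)
})

test_that("home sites cluster near the center, visibility sites sit peripherally", {
  sites <- generate_sites(c(NPACT_HOME = 1000, IMPROVE = 100),
                          region_size_km = 100, seed = 4)
  d <- sqrt((sites$x_km - 50)^2 + (sites$y_km - 50)^2)
  expect_lt(mean(d[sites$network == "NPACT_HOME"]),
            mean(d[sites$network == "IMPROVE"]))
})

test_that("co-location groups share coordinates and covariates; absent networks error", {
  sites <- generate_sites(c(NPACT_FIXED = 3, CSN_CORE = 2),
                          coloc_spec = list(c("NPACT_FIXED", "CSN_CORE")),
                          seed = 2)
  grp <- sites[!is.na(sites$coloc_group), ]
  expect_equal(nrow(grp), 2)
  expect_equal(length(unique(grp$x_km)), 1)
  expect_equal(grp$cov_1[1], grp$cov_1[2])
  expect_equal(grp$cov_2[1], grp$cov_2[2])
  expect_error(
    generate_sites(c(NPACT_FIXED = 3),
                   coloc_spec = list(c("NPACT_FIXED", "IMPROVE")), seed = 2),
    "absent network")
})

test_that("zero-noise latent panel equals the deterministic mean surface", {
  grid <- tiny_grid(8)
  sites <- manual_sites(4)
  tf <- seasonal_trend(grid)
  truth <- field_truth(c(0.4, -0.2), c(0.1, 0.3), tf, mu0 = 1, amp0 = 0.5,
                       resid_sill = 0, nugget = 0, seed = 9)
  panel <- simulate_latent_panel(sites, grid, truth)
  X <- as.matrix(sites[c("cov_1", "cov_2")])
  expected <- outer(1 + drop(X %*% c(0.4, -0.2)), rep(1, 8)) +
    outer(0.5 + drop(X %*% c(0.1, 0.3)), tf$values)
  expect_equal(unname(panel$values), expected, tolerance = 1e-12)
  expect_true(all(panel$mask))
  expect_identical(panel$scale, "LOG")
})

test_that("simulation is deterministic under a fixed seed", {
  grid <- tiny_grid(6)
  sites <- generate_sites(c(NPACT_FIXED = 5, NPACT_HOME = 20), seed = 3)
  truth <- field_truth(c(0.2, 0.1), c(0.1, 0), seasonal_trend(grid),
                       resid_sill = 0.05, resid_range_km = 8, nugget = 0.01,
                       seed = 3)
  p1 <- simulate_latent_panel(sites, grid, truth)
  p2 <- simulate_latent_panel(sites, grid, truth)
  expect_identical(p1$values, p2$values)
  r1 <- sample_network(p1, sites, seed = 3)
  r2 <- sample_network(p2, sites, seed = 3)
  expect_identical(r1, r2)
  expect_identical(generate_sites(c(NPACT_HOME = 10), seed = 5),
                   generate_sites(c(NPACT_HOME = 10), seed = 5))
})

test_that("residual spatial correlation decays with distance like exp(-d/range)", {
  grid <- build_period_grid(wed, 100)
  # two clusters of sites: pairs < 2 km apart and pairs > 50 km apart
  n <- 40
  withr::with_seed(21, {
    x <- c(stats::runif(n / 2, 0, 2), stats::runif(n / 2, 60, 100))
    y <- c(stats::runif(n / 2, 0, 2), stats::runif(n / 2, 60, 100))
  })
  sites <- manual_sites(n)
  sites$x_km <- x; sites$y_km <- y
  truth <- field_truth(c(0, 0), c(0, 0), seasonal_trend(grid),
                       resid_sill = 1, resid_range_km = 10, nugget = 0,
                       seed = 21)
  panel <- simulate_latent_panel(sites, grid, truth)
  resid <- panel$values  # mean surface is zero here
  d <- as.matrix(stats::dist(cbind(x, y)))
  cors <- stats::cor(t(resid))
  near <- d > 0 & d < 2
  far <- d > 50
  mean_near <- mean(cors[near])
  mean_far <- mean(cors[far])
  expect_gt(mean_near, mean_far)
  # compare with the analytic correlation exp(-d/range) at the two scales
  expect_equal(mean_near, mean(exp(-d[near] / 10)), tolerance = 0.15)
  expect_lt(abs(mean_far), 0.15)
})

test_that("home-site visit counts follow the configured distribution", {
  counts <- draw_home_visits(20000, seed = 8)
  expect_true(all(counts %in% 1:3))
  expect_equal(mean(counts), 1.8, tolerance = 0.02)
  expect_identical(draw_home_visits(50, seed = 8), draw_home_visits(50, seed = 8))
})

test_that("zero-distortion two-week sampling reproduces exp(latent) exactly", {
  grid <- tiny_grid(8)
  sites <- manual_sites(3)
  truth <- field_truth(c(0.3, 0.1), c(0.2, 0), seasonal_trend(grid),
                       resid_sill = 0, seed = 5)
  latent <- simulate_latent_panel(sites, grid, truth)
  recs <- sample_network(latent, sites, seed = 5)
  expect_equal(nrow(recs), 3 * 8)  # one record per site-period
  k <- assign_period(grid, recs$start_date, 14L)
  expect_equal(recs$value,
               exp(latent$values[cbind(match(recs$site_id, sites$site_id), k)]),
               tolerance = 1e-12)
})

test_that("every-3rd-day schedules yield 4 or 5 records per period", {
  grid <- tiny_grid(10)
  sites <- manual_sites(6, network = "CSN_CORE")
  truth <- field_truth(c(0, 0), c(0, 0), seasonal_trend(grid), seed = 6)
  latent <- simulate_latent_panel(sites, grid, truth)
  recs <- sample_network(latent, sites, seed = 6)
  per_cell <- recs |>
    dplyr::mutate(period = assign_period(grid, start_date, 1L)) |>
    dplyr::count(site_id, period)
  expect_true(all(per_cell$n %in% c(4L, 5L)))
  # brute-force calendar oracle: a 14-day window catches ceiling(n/3) of its
  # days on a 1-in-3 calendar, which is 4 or 5 depending on phase
  expect_setequal(unique(per_cell$n), c(4L, 5L))
})

test_that("multiplicative and additive distortions act on the concentration scale", {
  grid <- tiny_grid(4)
  sites <- manual_sites(2, network = "CSN_CORE")
  truth <- field_truth(c(0.5, 0), c(0, 0), seasonal_trend(grid), mu0 = 1,
                       resid_sill = 0, seed = 7)
  latent <- simulate_latent_panel(sites, grid, truth)
  dist <- default_distortions()
  dist$CSN_CORE <- network_distortion(mult_bias = 0.8, add_bias = -0.05)
  recs <- sample_network(latent, sites, distortion = dist, seed = 7)
  k <- assign_period(grid, recs$start_date, 1L)
  lat <- latent$values[cbind(match(recs$site_id, sites$site_id), k)]
  expect_equal(recs$value, pmax(exp(lat) * 0.8 - 0.05, 0), tolerance = 1e-12)
})
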