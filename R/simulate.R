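# Child-seed rule: every stochastic stage draws from seed + a fixed offset,
# so one run seed determines the whole pipeline while stages stay independent.
STAGE_SEED_OFFSETS <- c(
  sites = 101L, latent = 211L, sample = 307L, visits = 401L
)

child_seed <- function(seed, stage) {
  stopifnot(stage %in% names(STAGE_SEED_OFFSETS))
  (as.integer(seed) + STAGE_SEED_OFFSETS[[stage]]) %% .Machine$integer.max
}

#' Ground truth for the simulated concentration field
#'
#' The simulator generates log concentrations as
#' `log C(s, t) = mu(s) + A(s) f(t) + eps(s, t) + eta(s)`, with a long-term
#' mean surface `mu(s) = mu0 + x(s)' gamma0` and trend amplitude
#' `A(s) = amp0 + x(s)' gamma1` driven by geographic covariates around
#' explicit baselines, one smooth seasonal trend `f`, a spatially dependent
#' / temporally independent residual `eps` (zero-mean Gaussian field,
#' exponential covariance), and an iid site-level effect `eta`.
#'
#' @param gamma0 Covariate coefficients of the long-term mean (log scale).
#' @param gamma1 Covariate coefficients of the trend amplitude.
#' @param trend A `trend_function` (e.g. [seasonal_trend()]); the shared
#'   temporal basis `f`.
#' @param mu0 Baseline log concentration (intercept of the mean surface).
#' @param amp0 Baseline trend amplitude.
#' @param resid_sill Variance (sill) of the spatiotemporal residual.
#' @param resid_range_km Range of its exponential covariance
#'   `sill * exp(-d / range)`.
#' @param nugget Variance of the iid site-level effect.
#' @param seed Integer seed recorded with the truth.
#' @return A `field_truth` object.
#' @export
field_truth <- function(gamma0, gamma1, trend, mu0 = 0, amp0 = 0,
                        resid_sill = 0.05, resid_range_km = 10, nugget = 0,
                        seed = 1L) {
  stopifnot(resid_sill >= 0, nugget >= 0, resid_range_km > 0)
  stopifnot(inherits(trend, "trend_function"))
  if (length(gamma0) != length(gamma1)) {
    rlang::abort("`gamma0` and `gamma1` must have the same length.")
  }
  structure(
    list(gamma0 = as.numeric(gamma0), gamma1 = as.numeric(gamma1),
         trend = trend, mu0 = as.numeric(mu0), amp0 = as.numeric(amp0),
         resid_sill = resid_sill,
         resid_range_km = resid_range_km, nugget = nugget,
         seed = as.integer(seed)),
    class = "field_truth"
  )
}

#' Network-specific measurement distortion
#'
#' Statistical stand-ins for the method differences between networks
#' (thermal-optical protocol, blank correction, sampler hardware): a
#' multiplicative bias, an additive offset applied after exponentiation (so a
#' protocol difference appears as a negative intercept on the log scale when
#' configured), mean-one lognormal sampler noise, and extra day-to-day
#' variability for 24-hr samples around the two-week latent mean.
#'
#' @param mult_bias Multiplicative factor (> 0); 1 = unbiased.
#' @param add_bias Additive offset in ug/m3.
#' @param noise_cv Coefficient of variation of independent sampler noise.
#' @param daily_cv Extra CV applied to 24-hr samples only.
#' @return A `network_distortion` object.
#' @export
network_distortion <- function(mult_bias = 1, add_bias = 0, noise_cv = 0,
                               daily_cv = 0) {
  stopifnot(mult_bias > 0, noise_cv >= 0, daily_cv >= 0)
  structure(list(mult_bias = mult_bias, add_bias = add_bias,
                 noise_cv = noise_cv, daily_cv = daily_cv),
            class = "network_distortion")
}

#' Region presets: site counts by network
#'
#' Counts of long-term monitoring sites available within 200 km of each study
#' region's center, by network, for the six metropolitan study areas.
#'
#' @param region One of `"los_angeles"`, `"chicago"`, `"minneapolis"`,
#'   `"baltimore"`, `"new_york"`, `"winston_salem"`.
#' @return Named integer vector of site counts per network.
#' @examples
#' sum(region_preset("los_angeles"))  # 137 sites including home sites
#' @export
region_preset <- function(region = c("los_angeles", "chicago", "minneapolis",
                                     "baltimore", "new_york",
                                     "winston_salem")) {
  region <- match.arg(region)
  presets <- list(
    los_angeles   = c(CSN_CORE = 3, CSN_SUPP = 3, IMPROVE = 8,
                      NPACT_FIXED = 7, NPACT_HOME = 116),
    chicago       = c(CSN_CORE = 4, CSN_SUPP = 11, IMPROVE = 1,
                      NPACT_FIXED = 7, NPACT_HOME = 99),
    minneapolis   = c(CSN_CORE = 2, CSN_SUPP = 4, IMPROVE = 1,
                      NPACT_FIXED = 3, NPACT_HOME = 104),
    baltimore     = c(CSN_CORE = 8, CSN_SUPP = 19, IMPROVE = 5,
                      NPACT_FIXED = 5, NPACT_HOME = 87),
    new_york      = c(CSN_CORE = 14, CSN_SUPP = 11, IMPROVE = 3,
                      NPACT_FIXED = 3, NPACT_HOME = 107),
    winston_salem = c(CSN_CORE = 2, CSN_SUPP = 10, IMPROVE = 3,
                      NPACT_FIXED = 4, NPACT_HOME = 92)
  )
  storage.mode(presets[[region]]) <- "integer"
  presets[[region]]
}

#' Generate synthetic monitoring sites
#'
#' Emulates the spatial layout of the three networks: campaign (fixed +
#' home-outdoor) and urban regulatory sites cluster near the region center
#' where the cohort lives, while rural visibility-network sites sit on the
#' periphery. Covariate `cov_1` is a fixed affine function of
#' distance-to-center (a land-use-regression-style geographic predictor);
#' further covariates are iid standard normal. Co-located sites share both
#' coordinates and covariates.
#'
#' @param counts Named integer vector of sites per network (see
#'   [region_preset()]).
#' @param region_size_km Side of the square study region.
#' @param n_covariates Number of `cov_*` columns (>= 1).
#' @param coloc_spec List of length-2 character vectors; each pair of
#'   networks gets one co-location group (sites drawn from each network share
#'   a location). E.g. `list(c("NPACT_FIXED", "CSN_CORE"))`.
#' @param seed Integer seed.
#' @return A site tibble (`site_id`, `network`, `x_km`, `y_km`,
#'   `coloc_group`, `cov_*`).
#' @export
generate_sites <- function(counts, region_size_km = 100, n_covariates = 2,
                           coloc_spec = NULL, seed = 1L) {
  counts <- counts[counts > 0]
  if (length(counts) > 0 && !all(names(counts) %in% NETWORKS)) {
    rlang::abort(paste0("Unknown networks in `counts`: ",
                        paste(setdiff(names(counts), NETWORKS), collapse = ", ")))
  }
  stopifnot(n_covariates >= 1)
  if (length(counts) == 0) {
    empty <- tibble::tibble(site_id = character(), network = character(),
                            x_km = double(), y_km = double(),
                            coloc_group = character())
    for (j in seq_len(n_covariates)) empty[[paste0("cov_", j)]] <- double()
    return(empty)
  }
  center <- region_size_km / 2
  withr::with_seed(child_seed(seed, "sites"), {
    rows <- purrr::imap(as.list(counts), function(n, network) {
      n <- as.integer(n)
      if (network == "IMPROVE") {
        # peripheral ring
        r <- stats::runif(n, 0.30, 0.48) * region_size_km
        a <- stats::runif(n, 0, 2 * pi)
        x <- center + r * cos(a)
        y <- center + r * sin(a)
      } else {
        x <- stats::rnorm(n, center, region_size_km / 8)
        y <- stats::rnorm(n, center, region_size_km / 8)
        x <- pmin(pmax(x, 0), region_size_km)
        y <- pmin(pmax(y, 0), region_size_km)
      }
      tibble::tibble(
        site_id = sprintf("%s_%03d", tolower(network), seq_len(n)),
        network = network, x_km = x, y_km = y
      )
    })
    sites <- dplyr::bind_rows(rows)
    sites$coloc_group <- NA_character_
    if (!is.null(coloc_spec)) {
      used <- character(0)
      for (i in seq_along(coloc_spec)) {
        pair <- coloc_spec[[i]]
        stopifnot(length(pair) == 2)
        absent <- setdiff(pair, sites$network)
        if (length(absent) > 0) {
          rlang::abort(paste0("Co-location requested for absent network: ",
                              paste(absent, collapse = ", ")))
        }
        gid <- sprintf("coloc_%02d", i)
        anchor_id <- NULL
        for (network in pair) {
          cand <- sites$site_id[sites$network == network &
                                  is.na(sites$coloc_group) &
                                  !sites$site_id %in% used]
          if (length(cand) == 0) {
            rlang::abort(sprintf("No free %s site left to co-locate.", network))
          }
          pick <- cand[1]
          used <- c(used, pick)
          sites$coloc_group[sites$site_id == pick] <- gid
          if (is.null(anchor_id)) {
            anchor_id <- pick
          } else {
            j <- match(pick, sites$site_id)
            k <- match(anchor_id, sites$site_id)
            sites$x_km[j] <- sites$x_km[k]
            sites$y_km[j] <- sites$y_km[k]
          }
        }
      }
    }
    d <- sqrt((sites$x_km - center)^2 + (sites$y_km - center)^2)
    covs <- matrix(stats::rnorm(nrow(sites) * n_covariates), nrow(sites),
                   n_covariates)
    if (nrow(sites) > 0) {
      covs[, 1] <- (d - region_size_km / 4) / (region_size_km / 8)
    }
    colnames(covs) <- paste0("cov_", seq_len(n_covariates))
    sites <- dplyr::bind_cols(sites, tibble::as_tibble(covs))
    # co-located sites are the same place: same geography, same covariates
    if (any(!is.na(sites$coloc_group))) {
      cov_cols <- paste0("cov_", seq_len(n_covariates))
      for (gid in unique(stats::na.omit(sites$coloc_group))) {
        idx <- which(sites$coloc_group == gid)
        sites[idx, cov_cols] <- sites[rep(idx[1], length(idx)), cov_cols]
      }
    }
    validate_sites(sites)
  })
}

#' Simulate the latent two-week concentration panel
#'
#' Draws `log C(s, t)` for every site and period from the [field_truth()]
#' model: deterministic mean surface plus per-period Gaussian-field residuals
#' (exponential covariance, independent across periods) plus an iid site
#' effect. Fully observed, `"LOG"` scale.
#'
#' @param sites Site tibble (covariates must match `length(truth$gamma0)`).
#' @param grid A `period_grid` matching `truth$trend`.
#' @param truth A `field_truth`.
#' @return A `panel_matrix` on the `"LOG"` scale.
#' @export
simulate_latent_panel <- function(sites, grid, truth) {
  stopifnot(inherits(truth, "field_truth"), inherits(grid, "period_grid"))
  sites <- validate_sites(sites)
  X <- covariate_matrix(sites)
  if (ncol(X) != length(truth$gamma0)) {
    rlang::abort(sprintf(
      "Sites carry %d covariates but gamma0 has length %d.",
      ncol(X), length(truth$gamma0)))
  }
  f <- trend_on_grid(truth$trend, grid)
  n_s <- nrow(X)
  n_t <- grid$n_periods
  mu <- truth$mu0 + as.numeric(X %*% truth$gamma0)
  amp <- truth$amp0 + as.numeric(X %*% truth$gamma1)
  latent <- outer(mu, rep(1, n_t)) + outer(amp, f)
  withr::with_seed(child_seed(truth$seed, "latent"), {
    if (truth$resid_sill > 0) {
      d <- as.matrix(stats::dist(cbind(sites$x_km, sites$y_km)))
      sigma <- truth$resid_sill * exp(-d / truth$resid_range_km)
      # tiny jitter keeps the Cholesky stable when sites share coordinates
      diag(sigma) <- diag(sigma) + 1e-9 * truth$resid_sill
      L <- t(chol(sigma))
      latent <- latent + L %*% matrix(stats::rnorm(n_s * n_t), n_s, n_t)
    }
    if (truth$nugget > 0) {
      latent <- latent + stats::rnorm(n_s, 0, sqrt(truth$nugget))
    }
  })
  panel_matrix(latent, sites$site_id, grid, scale = "LOG")
}

#' Default per-network sampling designs
#'
#' Fixed campaign sites take one two-week integrated sample per period;
#' rotating home-outdoor sites take 1-3 two-week samples at random periods
#' (default probabilities 0.35/0.50/0.15, mean 1.8 samples per site);
#' regulatory sites take 24-hr samples every 3rd day (core speciation and
#' visibility networks) or every 6th day (supplemental speciation sites).
#'
#' @return Named list of per-network design specs, each a list with `type`
#'   (`"integrated"`, `"snapshot"` or `"daily"`) and type-specific fields
#'   (`p_visits` for snapshots, `step_days` for daily schedules).
#' @export
default_network_design <- function() {
  list(
    NPACT_FIXED = list(type = "integrated"),
    NPACT_HOME = list(type = "snapshot", p_visits = c(0.35, 0.50, 0.15)),
    CSN_CORE = list(type = "daily", step_days = 3L),
    CSN_SUPP = list(type = "daily", step_days = 6L),
    IMPROVE = list(type = "daily", step_days = 3L)
  )
}

#' @rdname default_network_design
#' @export
default_distortions <- function() {
  nets <- NETWORKS
  stats::setNames(lapply(nets, function(n) network_distortion()), nets)
}

default_method <- function(network) {
  switch(network,
         NPACT_FIXED = , NPACT_HOME = , IMPROVE = "TOR_BLANKCORR",
         CSN_CORE = , CSN_SUPP = "TOT_NOBLANK",
         "GENERIC")
}

#' Draw per-site visit counts for rotating home-outdoor sites
#'
#' @param n_sites Number of home sites.
#' @param p_visits Probabilities of 1, 2, 3 visits (default
#'   `c(0.35, 0.50, 0.15)`, mean 1.8).
#' @param seed Integer seed.
#' @return Integer vector of visit counts, length `n_sites`.
#' @export
draw_home_visits <- function(n_sites, p_visits = c(0.35, 0.50, 0.15),
                             seed = 1L) {
  stopifnot(length(p_visits) >= 1, all(p_visits >= 0), sum(p_visits) > 0)
  withr::with_seed(child_seed(seed, "visits"), {
    sample.int(length(p_visits), n_sites, replace = TRUE,
               prob = p_visits / sum(p_visits))
  })
}

# mean-one lognormal multiplier with coefficient of variation cv
lognormal_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log1p(cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Sample observed measurement records from a latent panel
#'
#' Applies each network's sampling design and measurement distortion to the
#' latent field. A record's value is
#' `(exp(latent) * mult_bias + add_bias) * noise`, with mean-one lognormal
#' noise of CV `noise_cv` (plus an extra `daily_cv` factor for 24-hr
#' records, which are generated around the period's two-week latent mean),
#' floored at zero.
#'
#' @param latent `panel_matrix` on the `"LOG"` scale.
#' @param sites Site tibble covering all panel sites.
#' @param pollutant Pollutant code for the records (default `"EC"`).
#' @param design Per-network design list (see [default_network_design()]).
#' @param distortion Named list of [network_distortion()] per network.
#' @param seed Integer seed.
#' @return A validated measurement tibble.
#' @export
sample_network <- function(latent, sites, pollutant = "EC",
                           design = default_network_design(),
                           distortion = default_distortions(), seed = 1L) {
  stopifnot(inherits(latent, "panel_matrix"))
  if (latent$scale != "LOG") {
    rlang::abort("`latent` must be on the LOG scale.")
  }
  sites <- validate_sites(sites)
  absent <- setdiff(latent$site_ids, sites$site_id)
  if (length(absent) > 0) {
    rlang::abort(paste0("Design references unknown sites: ",
                        paste(utils::head(absent, 5), collapse = ", ")))
  }
  grid <- latent$grid
  periods <- grid$periods
  withr::with_seed(child_seed(seed, "sample"), {
    recs <- purrr::map(latent$site_ids, function(sid) {
      network <- sites$network[match(sid, sites$site_id)]
      spec <- design[[network]]
      if (is.null(spec)) return(NULL)
      dist <- distortion[[network]] %||% network_distortion()
      lat <- latent$values[match(sid, latent$site_ids), ]
      if (spec$type == "integrated" || spec$type == "snapshot") {
        if (spec$type == "integrated") {
          ks <- periods$period
        } else {
          nv <- sample.int(length(spec$p_visits), 1, prob = spec$p_visits)
          ks <- sort(sample(periods$period, min(nv, grid$n_periods)))
        }
        value <- (exp(lat[ks]) * dist$mult_bias + dist$add_bias) *
          lognormal_noise(length(ks), dist$noise_cv)
        tibble::tibble(
          site_id = sid, pollutant = pollutant,
          start_date = periods$start[ks], duration_days = 14L,
          value = pmax(value, 0), method = default_method(network)
        )
      } else {
        step <- as.integer(spec$step_days)
        phase <- spec$phase %||% (sample.int(step, 1) - 1L)
        dates <- seq(grid_start(grid) + phase, grid_end(grid) - 1L, by = step)
        ks <- assign_period(grid, dates, 1L)
        keep <- !is.na(ks)
        dates <- dates[keep]; ks <- ks[keep]
        value <- (exp(lat[ks]) * dist$mult_bias + dist$add_bias) *
          lognormal_noise(length(ks), dist$noise_cv) *
          lognormal_noise(length(ks), dist$daily_cv)
        tibble::tibble(
          site_id = sid, pollutant = pollutant,
          start_date = dates, duration_days = 1L,
          value = pmax(value, 0), method = default_method(network)
        )
      }
    })
    validate_measurements(dplyr::bind_rows(recs))
  })
}
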