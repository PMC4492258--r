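RUN_CONFIG_KEYS <- c(
  "region", "counts", "region_size_km", "n_covariates", "coloc_spec",
  "anchor", "n_periods", "mu0", "amp0", "gamma0", "gamma1",
  "trend_peak_doy", "resid_sill",
  "resid_range_km", "nugget", "pollutant", "distortions",
  "min_daily_per_period", "transform", "logc_factor", "prefer_integrated",
  "bandwidth", "amplitude_mode", "min_regulatory_sites", "min_colocated_r",
  "min_trend_r", "single_trend_min_r", "seed", "output_dir"
)

#' Build a validated pipeline run configuration
#'
#' One configuration drives the full demonstration workflow
#' (simulate -> harmonize -> compare -> trend -> fit -> cv -> feasibility).
#' Unknown keys are rejected so typos cannot silently revert a setting to
#' its default.
#'
#' @param ... Configuration keys. Site layout: `region` (preset name) or
#'   `counts` (named per-network vector), `region_size_km`, `n_covariates`,
#'   `coloc_spec`. Grid: `anchor` (a Wednesday), `n_periods`. Truth:
#'   `gamma0`, `gamma1`, `trend_peak_doy`, `resid_sill`, `resid_range_km`,
#'   `nugget`, `pollutant`. Distortions: `distortions` (named list of
#'   [network_distortion()] argument lists). Policy: `min_daily_per_period`,
#'   `transform`, `logc_factor`, `prefer_integrated`. Analysis: `bandwidth`,
#'   `amplitude_mode`, feasibility thresholds, `single_trend_min_r`.
#'   `seed` and `output_dir`.
#' @return A validated `run_config` list.
#' @export
run_config <- function(...) {
  cfg <- list(...)
  unknown <- setdiff(names(cfg), RUN_CONFIG_KEYS)
  if (length(unknown) > 0 || (length(cfg) > 0 && any(names(cfg) == ""))) {
    rlang::abort(paste0("Unknown config keys: ",
                        paste(unknown, collapse = ", ")),
                 class = "mh_config_error")
  }
  defaults <- list(
    region = NULL, counts = NULL, region_size_km = 60, n_covariates = 2,
    coloc_spec = list(c("NPACT_FIXED", "CSN_CORE")),
    anchor = "2007-03-07", n_periods = 26,
    mu0 = 0.7, amp0 = 0.8, gamma0 = c(-0.3, 0.2), gamma1 = c(-0.1, 0.05),
    trend_peak_doy = 15,
    resid_sill = 0.05, resid_range_km = 10, nugget = 0.01,
    pollutant = "EC", distortions = NULL,
    min_daily_per_period = 2L, transform = "LOG1P", logc_factor = 0.1,
    prefer_integrated = FALSE, bandwidth = 6, amplitude_mode = "covariate",
    min_regulatory_sites = 10L, min_colocated_r = 0.8, min_trend_r = 0.9,
    single_trend_min_r = 0.7, seed = 1L, output_dir = tempfile("mh_run_")
  )
  cfg <- utils::modifyList(defaults, cfg)
  if (is.null(cfg$counts)) {
    cfg$counts <- if (is.null(cfg$region)) {
      c(CSN_CORE = 2, CSN_SUPP = 2, IMPROVE = 3, NPACT_FIXED = 7,
        NPACT_HOME = 50)
    } else {
      region_preset(cfg$region)
    }
  }
  cfg$counts <- unlist(cfg$counts)
  anchor <- as.Date(cfg$anchor)
  if (as.POSIXlt(anchor)$wday != 3L) {
    rlang::abort("`anchor` must be a Wednesday.", class = "mh_config_error")
  }
  cfg$anchor <- anchor
  if (length(cfg$gamma0) != length(cfg$gamma1) ||
      length(cfg$gamma0) != cfg$n_covariates) {
    rlang::abort("gamma0/gamma1 must have length n_covariates.",
                 class = "mh_config_error")
  }
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file whose top-level keys are `run_config()` arguments.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$coloc_spec)) cfg$coloc_spec <- lapply(cfg$coloc_spec, unlist)
  do.call(run_config, cfg)
}

config_distortions <- function(cfg) {
  d <- default_distortions()
  for (nm in names(cfg$distortions)) {
    d[[nm]] <- do.call(network_distortion, as.list(cfg$distortions[[nm]]))
  }
  d
}

config_policy <- function(cfg) {
  aggregation_policy(min_daily_per_period = cfg$min_daily_per_period,
                     transform = cfg$transform, logc_factor = cfg$logc_factor,
                     prefer_integrated = cfg$prefer_integrated)
}

config_grid <- function(cfg) build_period_grid(cfg$anchor, cfg$n_periods)

config_truth <- function(cfg) {
  field_truth(cfg$gamma0, cfg$gamma1,
              seasonal_trend(config_grid(cfg), cfg$trend_peak_doy),
              mu0 = cfg$mu0, amp0 = cfg$amp0,
              resid_sill = cfg$resid_sill,
              resid_range_km = cfg$resid_range_km,
              nugget = cfg$nugget, seed = cfg$seed)
}

artifact <- function(stage, name, path) {
  hash <- unname(tools::md5sum(path))
  tibble::tibble(stage = stage, artifact = name,
                 path = basename(path), md5 = hash)
}

#' Pipeline stages
#'
#' Each stage reads its inputs from the run directory, writes its outputs
#' there, and returns a manifest tibble (`stage`, `artifact`, `path`,
#' `md5`) — so any stage can be re-run from on-disk intermediates and
#' [run_all()] is just the stages in order.
#'
#' @param cfg A [run_config()].
#' @param dir Run directory.
#' @return A manifest tibble for the stage's artifacts.
#' @name pipeline-stages
NULL

#' @rdname pipeline-stages
#' @export
stage_simulate <- function(cfg, dir) {
  grid <- config_grid(cfg)
  truth <- config_truth(cfg)
  sites <- generate_sites(cfg$counts, cfg$region_size_km, cfg$n_covariates,
                          cfg$coloc_spec, seed = cfg$seed)
  latent <- simulate_latent_panel(sites, grid, truth)
  records <- sample_network(latent, sites, pollutant = cfg$pollutant,
                            distortion = config_distortions(cfg),
                            seed = cfg$seed)
  write_sites(sites, file.path(dir, "sites.csv"))
  write_measurements(records, file.path(dir, "measurements.csv"))
  write_panel(latent, file.path(dir, "latent_panel.csv"))
  jsonlite::write_json(
    list(mu0 = truth$mu0, amp0 = truth$amp0,
         gamma0 = truth$gamma0, gamma1 = truth$gamma1,
         resid_sill = truth$resid_sill, resid_range_km = truth$resid_range_km,
         nugget = truth$nugget, seed = truth$seed,
         trend = truth$trend$values),
    file.path(dir, "truth.json"), digits = NA, auto_unbox = TRUE)
  dplyr::bind_rows(
    artifact("simulate", "sites", file.path(dir, "sites.csv")),
    artifact("simulate", "measurements", file.path(dir, "measurements.csv")),
    artifact("simulate", "latent_panel", file.path(dir, "latent_panel.csv")),
    artifact("simulate", "truth", file.path(dir, "truth.json"))
  )
}

#' @rdname pipeline-stages
#' @export
stage_harmonize <- function(cfg, dir) {
  sites <- read_sites(file.path(dir, "sites.csv"))
  records <- read_measurements(file.path(dir, "measurements.csv"))
  panel <- to_two_week_panel(records, sites, config_grid(cfg),
                             config_policy(cfg))
  logp <- transform_panel(panel, config_policy(cfg))
  write_panel(panel, file.path(dir, "panel_raw.csv"))
  write_panel(logp, file.path(dir, "panel_log.csv"))
  dplyr::bind_rows(
    artifact("harmonize", "panel_raw", file.path(dir, "panel_raw.csv")),
    artifact("harmonize", "panel_log", file.path(dir, "panel_log.csv"))
  )
}

#' @rdname pipeline-stages
#' @export
stage_compare <- function(cfg, dir) {
  sites <- read_sites(file.path(dir, "sites.csv"))
  logp <- read_panel(file.path(dir, "panel_log.csv"))
  comparisons <- NULL
  if (any(!is.na(sites$coloc_group))) {
    nets <- unique(unlist(cfg$coloc_spec))
    pairs <- pair_colocated(logp, logp, sites, nets[1], nets[2])
    if (nrow(pairs) > 0) comparisons <- compare_colocated(pairs)
  }
  if (is.null(comparisons)) {
    comparisons <- tibble::tibble(group_id = character(), site_x = character(),
                                  site_y = character(), n_pairs = integer(),
                                  pearson_r = double(), slope = double(),
                                  intercept = double(), mean_diff = double())
  }
  readr::write_csv(comparisons, file.path(dir, "colocation.csv"))
  fixed <- sites$site_id[sites$network == "NPACT_FIXED"]
  pattern <- smooth_temporal_pattern(logp, intersect(fixed, logp$site_ids),
                                     bandwidth = cfg$bandwidth)
  jsonlite::write_json(
    list(bandwidth = pattern$bandwidth, n_sites_used = pattern$n_sites_used,
         values = pattern$values),
    file.path(dir, "pattern_fixed.json"), digits = NA, auto_unbox = TRUE,
    na = "null")
  dplyr::bind_rows(
    artifact("compare", "colocation", file.path(dir, "colocation.csv")),
    artifact("compare", "pattern_fixed", file.path(dir, "pattern_fixed.json"))
  )
}

#' @rdname pipeline-stages
#' @export
stage_trend <- function(cfg, dir) {
  sites <- read_sites(file.path(dir, "sites.csv"))
  logp <- read_panel(file.path(dir, "panel_log.csv"))
  fixed <- intersect(sites$site_id[sites$network == "NPACT_FIXED"],
                     logp$site_ids)
  raw_trend <- extract_trend_svd(panel_subset(logp, fixed))
  trend <- smooth_trend(raw_trend, bandwidth = cfg$bandwidth)
  jsonlite::write_json(
    list(values = trend$values, bandwidth = cfg$bandwidth,
         anchor = format(logp$grid$anchor), n_periods = logp$grid$n_periods,
         converged = attr(raw_trend, "converged"),
         n_iter = attr(raw_trend, "n_iter"),
         sites_used = attr(raw_trend, "sites_used")),
    file.path(dir, "trend.json"), digits = NA, auto_unbox = TRUE)
  artifact("trend", "trend", file.path(dir, "trend.json"))
}

read_trend_artifact <- function(dir) {
  tr <- jsonlite::read_json(file.path(dir, "trend.json"), simplifyVector = TRUE)
  grid <- build_period_grid(as.Date(tr$anchor), tr$n_periods)
  trend_function(tr$values, grid, bandwidth = tr$bandwidth)
}

#' @rdname pipeline-stages
#' @export
stage_fit <- function(cfg, dir) {
  sites <- read_sites(file.path(dir, "sites.csv"))
  logp <- read_panel(file.path(dir, "panel_log.csv"))
  trend <- read_trend_artifact(dir)
  study <- intersect(
    sites$site_id[sites$network %in% c("NPACT_FIXED", "NPACT_HOME")],
    logp$site_ids)
  fit <- fit_simplified(panel_subset(logp, study), sites, trend,
                        amplitude_mode = cfg$amplitude_mode)
  jsonlite::write_json(
    list(amplitude_mode = fit$amplitude_mode,
         coefficients = as.list(fit$coefficients),
         sigma2_hat = fit$sigma2_hat, r_squared = fit$r_squared,
         n_obs = fit$n_obs, trend = fit$trend$values,
         anchor = format(logp$grid$anchor),
         n_periods = logp$grid$n_periods,
         config = list(seed = cfg$seed, transform = cfg$transform,
                       bandwidth = cfg$bandwidth)),
    file.path(dir, "fit.json"), digits = NA, auto_unbox = TRUE)
  artifact("fit", "fit", file.path(dir, "fit.json"))
}

#' @rdname pipeline-stages
#' @export
stage_cv <- function(cfg, dir) {
  sites <- read_sites(file.path(dir, "sites.csv"))
  logp <- read_panel(file.path(dir, "panel_log.csv"))
  trend <- read_trend_artifact(dir)
  study <- intersect(
    sites$site_id[sites$network %in% c("NPACT_FIXED", "NPACT_HOME")],
    logp$site_ids)
  cv <- loso_cv(panel_subset(logp, study), sites, trend,
                amplitude_mode = cfg$amplitude_mode)
  readr::write_csv(cv$results, file.path(dir, "cv_sites.csv"))
  jsonlite::write_json(list(cv_r2 = cv$cv_r2, n_failed = cv$n_failed),
                       file.path(dir, "cv.json"), digits = NA,
                       auto_unbox = TRUE)
  dplyr::bind_rows(
    artifact("cv", "cv_sites", file.path(dir, "cv_sites.csv")),
    artifact("cv", "cv", file.path(dir, "cv.json"))
  )
}

#' @rdname pipeline-stages
#' @export
stage_feasibility <- function(cfg, dir) {
  sites <- read_sites(file.path(dir, "sites.csv"))
  logp <- read_panel(file.path(dir, "panel_log.csv"))
  comparisons <- readr::read_csv(file.path(dir, "colocation.csv"),
                                 show_col_types = FALSE)
  single <- check_single_trend(logp, sites, bandwidth = cfg$bandwidth,
                               min_r = cfg$single_trend_min_r)
  inputs <- feasibility_inputs(
    n_regulatory_sites = sum(sites$network %in%
                               c("CSN_CORE", "CSN_SUPP", "IMPROVE")),
    colocated_r = comparisons$pearson_r,
    trend_agreement_r = numeric(0),  # demo runs simulate one pollutant
    n_study_fixed_sites = sum(sites$network == "NPACT_FIXED"),
    single_trend_ok = single$ok
  )
  report <- assess_feasibility(inputs, feasibility_thresholds(
    cfg$min_regulatory_sites, cfg$min_colocated_r, cfg$min_trend_r))
  jsonlite::write_json(
    list(approach = report$approach, narrative = report$narrative,
         criteria = report$criteria, thresholds = report$thresholds,
         single_trend_r = single$pearson_r),
    file.path(dir, "feasibility.json"), digits = NA, auto_unbox = TRUE,
    na = "null")
  artifact("feasibility", "feasibility", file.path(dir, "feasibility.json"))
}

#' Run the full demonstration pipeline
#'
#' Executes simulate, harmonize, compare, trend, fit, cv and feasibility in
#' order, writing every artifact (CSV/JSON) plus a manifest with an MD5 hash
#' of each file. Identical config + seed reproduce identical hashes.
#'
#' @param cfg A [run_config()].
#' @return The manifest: list with `config` echo, `dir`, and `artifacts`
#'   tibble. Also written as `manifest.json` in the run directory.
#' @export
run_all <- function(cfg = run_config()) {
  stopifnot(inherits(cfg, "run_config"))
  dir <- cfg$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list(simulate = stage_simulate, harmonize = stage_harmonize,
                 compare = stage_compare, trend = stage_trend,
                 fit = stage_fit, cv = stage_cv,
                 feasibility = stage_feasibility)
  artifacts <- purrr::imap(stages, function(f, name) {
    tryCatch(f(cfg, dir), error = function(e) {
      rlang::abort(sprintf("Stage '%s' failed: %s", name,
                           conditionMessage(e)), parent = e)
    })
  })
  artifacts <- dplyr::bind_rows(artifacts)
  echo <- cfg
  echo$anchor <- format(echo$anchor)
  echo$output_dir <- NULL
  manifest <- list(config = unclass(echo), artifacts = artifacts)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       digits = NA, auto_unbox = TRUE, null = "null",
                       na = "null")
  invisible(c(manifest, list(dir = dir)))
}
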