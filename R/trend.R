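#' Temporal trend functions
#'
#' A `trend_function` is a smooth, spatially homogeneous temporal basis on a
#' two-week period grid, normalized to unit L2 norm. In the exposure model
#' each site scales the shared trend by its own amplitude, so the norm and
#' sign are pure conventions: the sign is fixed so the trend correlates
#' non-negatively with the panel-wide mean trajectory it was derived from.
#'
#' @param values Numeric vector, one value per grid period (finite).
#' @param grid The `period_grid` the trend lives on.
#' @param bandwidth Smoothing bandwidth used to produce it (`NA` if raw).
#' @param normalize Rescale to unit L2 norm (default `TRUE`).
#' @return A `trend_function`.
#' @export
trend_function <- function(values, grid, bandwidth = NA_real_,
                           normalize = TRUE) {
  stopifnot(inherits(grid, "period_grid"))
  values <- as.numeric(values)
  if (length(values) != grid$n_periods) {
    rlang::abort("`values` must have one entry per grid period.")
  }
  if (!all(is.finite(values))) rlang::abort("Trend values must be finite.")
  if (normalize) {
    nrm <- sqrt(sum(values^2))
    if (nrm == 0) rlang::abort("Cannot normalize an all-zero trend.")
    values <- values / nrm
  }
  structure(list(values = values, grid = grid, bandwidth = bandwidth),
            class = "trend_function")
}

#' @export
print.trend_function <- function(x, ...) {
  cat(sprintf("<trend_function> %d periods, range [%.3f, %.3f]%s\n",
              length(x$values), min(x$values), max(x$values),
              if (is.na(x$bandwidth)) "" else
                sprintf(", bandwidth %.1f periods", x$bandwidth)))
  invisible(x)
}

trend_on_grid <- function(trend, grid) {
  stopifnot(inherits(trend, "trend_function"))
  if (!same_grid(trend$grid, grid)) {
    rlang::abort("Trend is defined on a different period grid.")
  }
  trend$values
}

#' Smooth annual-cycle trend (simulator default)
#'
#' A unit-norm cosine of the day of year evaluated at period centers — the
#' canonical shared seasonal signal of combustion-related PM2.5 components.
#'
#' @param grid A `period_grid`.
#' @param peak_doy Day of year at which the cycle peaks (default 15, a winter
#'   peak typical of elemental carbon).
#' @return A `trend_function`.
#' @export
seasonal_trend <- function(grid, peak_doy = 15) {
  doy <- as.POSIXlt(grid$periods$center)$yday + 1
  trend_function(cos(2 * pi * (doy - peak_doy) / 365.25), grid)
}

#' @export
autoplot.trend_function <- function(object, ...) {
  df <- tibble::tibble(center_date = object$grid$periods$center,
                       value = object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$center_date, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "period center", y = "trend (unit L2)") +
    ggplot2::theme_minimal()
}

#' Extract a temporal trend by SVD with iterative imputation
#'
#' Derives the shared temporal trend from the panel of sites with long time
#' series. Sites observed in fewer than `min_frac_observed` of periods are
#' dropped (they cannot inform a full-length trend). The panel is
#' row-centered (site means belong to the long-term-mean surface, not the
#' trend), missing cells are initialized with column means (falling back to
#' the row then grand mean of the centered matrix, i.e. zero), and the
#' algorithm alternates rank-1 SVD reconstruction with refilling only the
#' originally missing cells until the largest imputed-cell change drops below
#' `impute_tol` or `max_iter` is reached. The first right singular vector,
#' unit-normalized with the sign convention of [trend_function()], is the
#' trend.
#'
#' @param panel A log-scale `panel_matrix`.
#' @param rank Rank of the reconstruction used during imputation (the trend
#'   is always the first component; default 1).
#' @param impute_tol Convergence tolerance on imputed cells (default 1e-6).
#' @param max_iter Maximum imputation sweeps (default 100).
#' @param min_frac_observed Minimum fraction of observed periods for a site
#'   to count as "long series" (default 0.5).
#' @return A `trend_function` with attributes `converged`, `n_iter`,
#'   `sites_used`, and `explained` (share of row-centered variance carried by
#'   the first component).
#' @export
extract_trend_svd <- function(panel, rank = 1L, impute_tol = 1e-6,
                              max_iter = 100L, min_frac_observed = 0.5) {
  stopifnot(inherits(panel, "panel_matrix"))
  frac <- rowMeans(panel$mask)
  keep <- frac >= min_frac_observed
  if (sum(keep) < 2) {
    rlang::abort(sprintf(
      "Need >= 2 sites observed in >= %.0f%% of periods; have %d.",
      100 * min_frac_observed, sum(keep)))
  }
  Y <- panel$values[keep, , drop = FALSE]
  mask <- panel$mask[keep, , drop = FALSE]
  if (any(colSums(mask) == 0)) {
    rlang::abort("Some periods have no observations among long-series sites.")
  }
  row_means <- rowSums(ifelse(mask, Y, 0)) / rowSums(mask)
  Yc <- Y - row_means
  # initialize missing cells: column mean, then row mean (= 0 after
  # centering), then grand mean (also 0)
  col_means <- colSums(ifelse(mask, Yc, 0)) / colSums(mask)
  Yimp <- ifelse(mask, Yc, rep(col_means, each = nrow(Yc)))
  Yimp[!is.finite(Yimp)] <- 0
  any_missing <- !all(mask)
  converged <- TRUE
  n_iter <- 0L
  if (any_missing) {
    converged <- FALSE
    for (i in seq_len(max_iter)) {
      n_iter <- i
      sv <- svd(Yimp, nu = rank, nv = rank)
      recon <- sv$u %*% (sv$d[seq_len(rank)] * t(sv$v))
      delta <- max(abs(recon[!mask] - Yimp[!mask]))
      Yimp[!mask] <- recon[!mask]
      if (delta < impute_tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      rlang::warn(sprintf(
        "SVD imputation did not converge in %d iterations (last change %.2e).",
        max_iter, delta))
    }
  } else {
    n_iter <- 1L
  }
  sv <- svd(Yimp)
  v <- sv$v[, 1]
  obs_col_means <- colSums(ifelse(panel$mask, panel$values, 0)) /
    pmax(colSums(panel$mask), 1L)
  if (stats::sd(obs_col_means) > 0 &&
      stats::cor(v, obs_col_means) < 0) {
    v <- -v
  }
  tf <- trend_function(v, panel$grid)
  attr(tf, "converged") <- converged
  attr(tf, "n_iter") <- n_iter
  attr(tf, "sites_used") <- panel$site_ids[keep]
  attr(tf, "explained") <- sv$d[1]^2 / sum(sv$d^2)
  tf
}

#' Smooth a trend function
#'
#' Applies the package's local-linear tri-cube smoother to the trend values
#' over the period index, then re-normalizes to unit L2 norm (smooth first,
#' normalize second).
#'
#' @param trend A `trend_function`.
#' @param bandwidth Smoother bandwidth in periods (default 6).
#' @return A smoothed, re-normalized `trend_function`.
#' @export
smooth_trend <- function(trend, bandwidth = 6) {
  stopifnot(inherits(trend, "trend_function"))
  t_idx <- as.numeric(trend$grid$periods$period)
  sm <- local_linear_smooth(t_idx, trend$values, t_idx, bandwidth)
  trend_function(sm, trend$grid, bandwidth = bandwidth)
}

#' Trend surrogacy check between pollutants
#'
#' When a pollutant's own monitoring record is too short to support trend
#' estimation, the trend from a better-monitored pollutant can stand in for
#' it — justified only when the two trend functions agree. Compares the two
#' trends with [compare_patterns()] and issues a verdict against a
#' correlation threshold.
#'
#' @param trend_component Trend estimated from the component of interest.
#' @param trend_target Candidate surrogate trend (another pollutant).
#' @param min_r Correlation threshold for adequacy (default 0.9).
#' @return A list: `pearson_r`, `rmse` (after unit-normalizing both),
#'   `adequate`, `min_r`.
#' @export
trend_surrogacy_check <- function(trend_component, trend_target,
                                  min_r = 0.9) {
  cmp <- compare_patterns(as_smoothed_pattern(trend_component),
                          as_smoothed_pattern(trend_target))
  list(pearson_r = cmp$pearson_r, rmse = cmp$rmse,
       adequate = is.finite(cmp$pearson_r) && cmp$pearson_r >= min_r,
       min_r = min_r)
}
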