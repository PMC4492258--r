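tricube <- function(u) {
  w <- (1 - abs(u)^3)^3
  w[abs(u) >= 1] <- 0
  w
}

# Deterministic local-linear smoother with tri-cube weights over distance in
# period units. Linear in y. Evaluation points outside [min(x), max(x)] give
# NA (no extrapolation); windows degenerating to < 2 distinct x fall back to
# the weighted mean.
local_linear_smooth <- function(x, y, x_eval, bandwidth) {
  stopifnot(length(x) == length(y), bandwidth > 0)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 1) rlang::abort("No points to smooth.")
  lo <- min(x); hi <- max(x)
  vapply(x_eval, function(x0) {
    if (x0 < lo || x0 > hi) return(NA_real_)
    w <- tricube((x - x0) / bandwidth)
    if (sum(w > 0) == 0) {
      # empty window: take the nearest points
      d <- abs(x - x0)
      w <- as.numeric(d <= min(d) + 1e-9)
    }
    xs <- x[w > 0]; ys <- y[w > 0]; ws <- w[w > 0]
    if (length(unique(xs)) < 2) {
      return(sum(ws * ys) / sum(ws))
    }
    xb <- sum(ws * xs) / sum(ws)
    yb <- sum(ws * ys) / sum(ws)
    sxx <- sum(ws * (xs - xb)^2)
    sxy <- sum(ws * (xs - xb) * (ys - yb))
    yb + (sxy / sxx) * (x0 - xb)
  }, numeric(1))
}

#' Smoothed cross-site temporal patterns
#'
#' A `smoothed_pattern` is the mean temporal trajectory of a pollutant
#' estimated by pooling the time series of a set of sites and smoothing with
#' a local-linear tri-cube smoother over the period index. Periods outside
#' the observed range are `NA` (the smoother never extrapolates).
#'
#' @param panel A `panel_matrix` (normally log scale).
#' @param site_ids Sites to pool; default all panel sites.
#' @param bandwidth Smoother bandwidth in periods (default 6).
#' @return A `smoothed_pattern`: list with `grid`, `values`, `bandwidth`,
#'   `n_sites_used`.
#' @export
smooth_temporal_pattern <- function(panel, site_ids = NULL, bandwidth = 6) {
  stopifnot(inherits(panel, "panel_matrix"))
  if (!is.null(site_ids)) panel <- panel_subset(panel, site_ids)
  long <- as_tibble.panel_matrix(panel)
  if (nrow(long) < 3 || length(unique(long$period)) < 3) {
    rlang::abort("Need observations in at least 3 periods to smooth.")
  }
  values <- local_linear_smooth(long$period, long$value,
                                as.numeric(panel$grid$periods$period),
                                bandwidth)
  structure(
    list(grid = panel$grid, values = values, bandwidth = bandwidth,
         n_sites_used = length(unique(long$site_id))),
    class = "smoothed_pattern"
  )
}

#' @export
print.smoothed_pattern <- function(x, ...) {
  cat(sprintf(
    "<smoothed_pattern> %d periods (%d non-missing), bandwidth %.1f, %d sites\n",
    length(x$values), sum(is.finite(x$values)), x$bandwidth, x$n_sites_used))
  invisible(x)
}

as_smoothed_pattern <- function(x) {
  if (inherits(x, "smoothed_pattern")) return(x)
  if (inherits(x, "trend_function")) {
    return(structure(list(grid = x$grid, values = x$values,
                          bandwidth = x$bandwidth, n_sites_used = NA_integer_),
                     class = "smoothed_pattern"))
  }
  rlang::abort("Expected a smoothed_pattern or trend_function.")
}

#' @export
autoplot.smoothed_pattern <- function(object, ...) {
  df <- tibble::tibble(center_date = object$grid$periods$center,
                       value = object$values)
  ggplot2::ggplot(df, ggplot2::aes(.data$center_date, .data$value)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::labs(x = "period center", y = "smoothed level") +
    ggplot2::theme_minimal()
}

#' Pair observations at co-located monitors
#'
#' For every co-location group having exactly one site in each of the two
#' requested networks, collects the periods observed in both panels together
#' with both (transformed-scale) values — the raw material of paired
#' between-network scatter plots.
#'
#' @param panel_x,panel_y `panel_matrix` objects on the same grid and scale
#'   (x = reference network, y = comparison network).
#' @param sites Site tibble with `coloc_group`.
#' @param network_x,network_y Networks to compare.
#' @param period_window Optional length-2 `Date` vector; only periods whose
#'   center falls inside `[min, max]` are kept.
#' @return Tibble: `group_id`, `site_x`, `site_y`, `period`, `center_date`,
#'   `x`, `y`.
#' @export
pair_colocated <- function(panel_x, panel_y, sites, network_x, network_y,
                           period_window = NULL) {
  stopifnot(inherits(panel_x, "panel_matrix"), inherits(panel_y, "panel_matrix"))
  if (!same_grid(panel_x$grid, panel_y$grid)) {
    rlang::abort("Panels are on different period grids.")
  }
  if (!identical(panel_x$scale, panel_y$scale)) {
    rlang::abort("Panels are on different scales.")
  }
  sites <- validate_sites(sites)
  groups <- unique(stats::na.omit(sites$coloc_group))
  centers <- panel_x$grid$periods$center
  in_window <- rep(TRUE, length(centers))
  if (!is.null(period_window)) {
    period_window <- as.Date(period_window)
    in_window <- centers >= min(period_window) & centers <= max(period_window)
  }
  out <- purrr::map(groups, function(gid) {
    members <- sites[which(sites$coloc_group == gid), ]
    sx <- members$site_id[members$network == network_x]
    sy <- members$site_id[members$network == network_y]
    if (length(sx) == 0 || length(sy) == 0) return(NULL)
    if (length(sx) > 1 || length(sy) > 1) {
      rlang::abort(sprintf(
        "Co-location group %s has more than one site in a requested network.",
        gid))
    }
    ix <- match(sx, panel_x$site_ids)
    iy <- match(sy, panel_y$site_ids)
    if (is.na(ix) || is.na(iy)) return(NULL)
    both <- panel_x$mask[ix, ] & panel_y$mask[iy, ] & in_window
    if (!any(both)) return(NULL)
    k <- unname(which(both))
    tibble::tibble(
      group_id = gid, site_x = sx, site_y = sy, period = k,
      center_date = centers[k],
      x = unname(panel_x$values[ix, k]), y = unname(panel_y$values[iy, k])
    )
  })
  dplyr::bind_rows(out)
}

#' Co-located monitor comparison statistics
#'
#' Per co-location group: Pearson correlation, best-fit line of y on x
#' (ordinary least squares by default, matching paired scatter plots; a
#' Deming errors-in-variables option with equal error variances is
#' available), and the mean difference — all on the panels' (log) scale. A
#' multiplicative between-network bias appears as an intercept shift on the
#' log scale; method artifacts show up as non-unit slopes or negative
#' intercepts.
#'
#' @param pairs Output of [pair_colocated()].
#' @param line One of `"ols"` (default) or `"deming"`.
#' @return Tibble with one row per group: `group_id`, `network_x` columns
#'   (`site_x`, `site_y`), `n_pairs`, `pearson_r`, `slope`, `intercept`,
#'   `mean_diff`.
#' @export
compare_colocated <- function(pairs, line = c("ols", "deming")) {
  line <- match.arg(line)
  stopifnot(all(c("group_id", "x", "y") %in% names(pairs)))
  pairs |>
    dplyr::group_by(.data$group_id, .data$site_x, .data$site_y) |>
    dplyr::group_modify(function(df, key) {
      if (nrow(df) < 3) {
        rlang::abort(sprintf("Group %s has %d pairs; need >= 3.",
                             key$group_id, nrow(df)))
      }
      x <- df$x; y <- df$y
      if (stats::sd(x) == 0) {
        rlang::abort(sprintf("Group %s: zero variance in x; slope undefined.",
                             key$group_id))
      }
      r <- stats::cor(x, y)
      if (line == "ols") {
        slope <- stats::cov(x, y) / stats::var(x)
      } else {
        sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
        slope <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
      }
      intercept <- mean(y) - slope * mean(x)
      tibble::tibble(n_pairs = nrow(df), pearson_r = r, slope = slope,
                     intercept = intercept, mean_diff = mean(y - x))
    }) |>
    dplyr::ungroup()
}

#' Scatter plot of co-located pairs with best-fit lines
#'
#' @param pairs Output of [pair_colocated()].
#' @param line Best-fit line type passed to [compare_colocated()].
#' @return A ggplot object, one facet per co-location group, identity line
#'   dashed and the fitted line solid.
#' @export
plot_colocated <- function(pairs, line = "ols") {
  stats_df <- compare_colocated(pairs, line = line)
  ggplot2::ggplot(pairs, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_abline(
      data = stats_df,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept)) +
    ggplot2::facet_wrap(~group_id) +
    ggplot2::labs(x = "network x (log scale)", y = "network y (log scale)") +
    ggplot2::theme_minimal()
}

#' Compare two smoothed temporal patterns
#'
#' Pearson correlation on the common non-missing periods and root mean
#' squared difference after unit (L2) normalizing both patterns on that
#' common support — so the RMSE compares shapes, not levels.
#'
#' @param a,b `smoothed_pattern` (or `trend_function`) objects on the same
#'   grid.
#' @return List: `pearson_r`, `rmse`, `n_common`.
#' @export
compare_patterns <- function(a, b) {
  a <- as_smoothed_pattern(a)
  b <- as_smoothed_pattern(b)
  if (!same_grid(a$grid, b$grid)) {
    rlang::abort("Patterns are on different period grids.")
  }
  common <- is.finite(a$values) & is.finite(b$values)
  if (sum(common) < 3) {
    rlang::abort("Fewer than 3 common non-missing periods.")
  }
  va <- a$values[common]
  vb <- b$values[common]
  r <- if (stats::sd(va) == 0 || stats::sd(vb) == 0) NA_real_ else
    stats::cor(va, vb)
  ua <- va / sqrt(sum(va^2))
  ub <- vb / sqrt(sum(vb^2))
  list(pearson_r = r, rmse = sqrt(mean((ua - ub)^2)), n_common = sum(common))
}
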