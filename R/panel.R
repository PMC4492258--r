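#' Site-by-period concentration panels
#'
#' A `panel_matrix` holds a sites x periods matrix of concentrations on a
#' common two-week [build_period_grid()] grid, together with an explicit
#' observation mask and a scale tag: `"RAW"` (ug/m3), `"LOG"` (natural log of
#' concentration, the simulator's latent scale), `"LOG1P"` (ln(x + 1)) or
#' `"LOGC"` (ln(x + c) with c = a fraction of the pollutant mean).
#'
#' @param values Numeric matrix, sites in rows, periods in columns. Cells not
#'   observed must be `NA`.
#' @param site_ids Character vector of row identities.
#' @param grid A `period_grid` with `n_periods` equal to `ncol(values)`.
#' @param scale One of `"RAW"`, `"LOG"`, `"LOG1P"`, `"LOGC"`.
#' @param mask Optional logical matrix (`TRUE` = observed); defaults to
#'   `!is.na(values)`.
#' @param logc_constant The additive constant actually used, recorded for
#'   `"LOGC"` panels so the transform is invertible.
#' @return A `panel_matrix` object.
#' @export
panel_matrix <- function(values, site_ids, grid, scale = "RAW", mask = NULL,
                         logc_constant = NULL) {
  values <- as.matrix(values)
  stopifnot(inherits(grid, "period_grid"))
  scale <- match.arg(scale, c("RAW", "LOG", "LOG1P", "LOGC"))
  if (ncol(values) != grid$n_periods) {
    rlang::abort("`values` must have one column per grid period.")
  }
  site_ids <- as.character(site_ids)
  if (length(site_ids) != nrow(values)) {
    rlang::abort("`site_ids` length must match `nrow(values)`.")
  }
  if (anyDuplicated(site_ids)) rlang::abort("`site_ids` must be unique.")
  if (is.null(mask)) mask <- !is.na(values)
  mask <- as.matrix(mask)
  if (!identical(dim(mask), dim(values))) {
    rlang::abort("`mask` must have the same dimensions as `values`.")
  }
  values[!mask] <- NA_real_
  if (scale == "RAW" && any(values[mask] < 0, na.rm = TRUE)) {
    rlang::abort("RAW panels must be non-negative where observed.")
  }
  dimnames(values) <- list(site_ids, format(grid$periods$center))
  dimnames(mask) <- dimnames(values)
  structure(
    list(values = values, mask = mask, site_ids = site_ids, grid = grid,
         scale = scale, logc_constant = logc_constant),
    class = "panel_matrix"
  )
}

#' @export
print.panel_matrix <- function(x, ...) {
  cat(sprintf(
    "<panel_matrix> %d sites x %d periods (%s scale), %.1f%% observed\n",
    nrow(x$values), ncol(x$values), x$scale, 100 * mean(x$mask)
  ))
  invisible(x)
}

#' @export
dim.panel_matrix <- function(x) dim(x$values)

#' Long-format view of a panel
#'
#' @param x A `panel_matrix`.
#' @param ... Unused.
#' @param drop_missing Keep only observed cells (default `TRUE`).
#' @return A tibble with `site_id`, `period`, `center_date`, `value`,
#'   `observed`.
#' @export
as_tibble.panel_matrix <- function(x, ..., drop_missing = TRUE) {
  out <- tibble::tibble(
    site_id = rep(x$site_ids, times = ncol(x$values)),
    period = rep(x$grid$periods$period, each = nrow(x$values)),
    center_date = rep(x$grid$periods$center, each = nrow(x$values)),
    value = as.vector(x$values),
    observed = as.vector(x$mask)
  )
  if (drop_missing) out <- dplyr::filter(out, .data$observed)
  out
}

#' Restrict a panel to a subset of sites
#'
#' @param panel A `panel_matrix`.
#' @param site_ids Sites to keep (must exist in the panel).
#' @return A `panel_matrix` with the selected rows, in the requested order.
#' @export
panel_subset <- function(panel, site_ids) {
  stopifnot(inherits(panel, "panel_matrix"))
  site_ids <- as.character(site_ids)
  missing <- setdiff(site_ids, panel$site_ids)
  if (length(missing) > 0) {
    rlang::abort(paste0("Unknown sites: ", paste(missing, collapse = ", ")))
  }
  idx <- match(site_ids, panel$site_ids)
  panel_matrix(panel$values[idx, , drop = FALSE], site_ids, panel$grid,
               scale = panel$scale, mask = panel$mask[idx, , drop = FALSE],
               logc_constant = panel$logc_constant)
}

#' Heatmap of a panel matrix
#'
#' @param object A `panel_matrix`.
#' @param ... Unused.
#' @return A ggplot object (sites on the y axis, period centers on the x
#'   axis, fill = value; unobserved cells blank).
#' @export
autoplot.panel_matrix <- function(object, ...) {
  df <- as_tibble.panel_matrix(object, drop_missing = TRUE)
  ggplot2::ggplot(df, ggplot2::aes(.data$center_date, .data$site_id,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = object$scale) +
    ggplot2::labs(x = "period center", y = NULL) +
    ggplot2::theme_minimal()
}
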