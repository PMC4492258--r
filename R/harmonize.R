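#' Aggregation and transformation policy
#'
#' Controls how raw records become two-week panels: the completeness rule for
#' averaging 24-hr samples within a period, the log transform (ln(x + 1) by
#' default; alternatively ln(x + c) with c a fraction of the pollutant mean,
#' used in sensitivity analyses), the day-overlap tolerance for aligning
#' 14-day samples, and the conflict rule when a cell receives both an
#' integrated and daily records.
#'
#' @param min_daily_per_period Minimum number of 24-hr samples for a period
#'   average (default 2; an every-6th-day schedule yields 2-3 per period).
#' @param transform `"LOG1P"` (ln(x + 1)) or `"LOGC"` (ln(x + c)).
#' @param logc_factor For `"LOGC"`: c = `logc_factor` times the mean of the
#'   observed cells (default 0.1), computed per pollutant over the whole
#'   panel.
#' @param min_overlap_days Passed to [assign_period()] for 14-day samples.
#' @param prefer_integrated If a site/period holds both a 14-day record and
#'   daily records, take the integrated value instead of erroring.
#' @return An `aggregation_policy`.
#' @export
aggregation_policy <- function(min_daily_per_period = 2L,
                               transform = c("LOG1P", "LOGC"),
                               logc_factor = 0.1,
                               min_overlap_days = 10L,
                               prefer_integrated = FALSE) {
  transform <- match.arg(transform)
  min_daily_per_period <- as.integer(min_daily_per_period)
  stopifnot(min_daily_per_period >= 1L, logc_factor > 0)
  structure(
    list(min_daily_per_period = min_daily_per_period, transform = transform,
         logc_factor = logc_factor,
         min_overlap_days = as.integer(min_overlap_days),
         prefer_integrated = isTRUE(prefer_integrated)),
    class = "aggregation_policy"
  )
}

#' Aggregate measurement records to a two-week panel
#'
#' Aligns every record to the period grid and fills each site-by-period cell:
#' a 14-day integrated record is used directly; otherwise the arithmetic mean
#' of the assigned 24-hr records, provided at least
#' `policy$min_daily_per_period` of them fall in the period; otherwise the
#' cell is missing. The mask reflects exactly this rule.
#'
#' @param records Measurement tibble, a single pollutant.
#' @param sites Site tibble defining panel rows (all record sites must
#'   appear).
#' @param grid A `period_grid`.
#' @param policy An [aggregation_policy()].
#' @return A `panel_matrix` on the `"RAW"` scale.
#' @export
to_two_week_panel <- function(records, sites, grid,
                              policy = aggregation_policy()) {
  records <- validate_measurements(records)
  sites <- validate_sites(sites)
  stopifnot(inherits(grid, "period_grid"), inherits(policy, "aggregation_policy"))
  if (length(unique(records$pollutant)) > 1) {
    rlang::abort(paste0("Records mix pollutants: ",
                        paste(unique(records$pollutant), collapse = ", ")))
  }
  unknown <- setdiff(records$site_id, sites$site_id)
  if (length(unknown) > 0) {
    rlang::abort(paste0("Records reference sites absent from `sites`: ",
                        paste(utils::head(unknown, 5), collapse = ", ")))
  }
  records$period <- assign_period(grid, records$start_date,
                                  records$duration_days,
                                  min_overlap_days = policy$min_overlap_days)
  records <- dplyr::filter(records, !is.na(.data$period))

  cells <- records |>
    dplyr::group_by(.data$site_id, .data$period) |>
    dplyr::summarise(
      n_integrated = sum(.data$duration_days == 14L),
      n_daily = sum(.data$duration_days == 1L),
      integrated_value = if (any(.data$duration_days == 14L))
        .data$value[.data$duration_days == 14L][1] else NA_real_,
      daily_mean = if (any(.data$duration_days == 1L))
        mean(.data$value[.data$duration_days == 1L]) else NA_real_,
      .groups = "drop"
    )
  multi <- cells$n_integrated > 1L
  if (any(multi)) {
    rlang::abort(sprintf(
      "Multiple 14-day records in one cell (e.g. site %s period %d).",
      cells$site_id[multi][1], cells$period[multi][1]))
  }
  conflict <- cells$n_integrated > 0L & cells$n_daily > 0L
  if (any(conflict) && !policy$prefer_integrated) {
    rlang::abort(sprintf(
      paste0("Site %s period %d has both a 14-day and daily records; set ",
             "`prefer_integrated = TRUE` to take the integrated value."),
      cells$site_id[conflict][1], cells$period[conflict][1]),
      class = "mh_conflict_error")
  }
  cells$cell_value <- dplyr::if_else(
    cells$n_integrated > 0L,
    cells$integrated_value,
    dplyr::if_else(cells$n_daily >= policy$min_daily_per_period,
                   cells$daily_mean, NA_real_)
  )
  values <- matrix(NA_real_, nrow(sites), grid$n_periods)
  idx <- cbind(match(cells$site_id, sites$site_id), cells$period)
  values[idx] <- cells$cell_value
  panel_matrix(values, sites$site_id, grid, scale = "RAW")
}

#' Log-transform a raw panel
#'
#' Observed cells become `ln(value + c)`, with c = 1 under `"LOG1P"` or
#' c = `logc_factor` times the mean of the observed cells under `"LOGC"`
#' (computed over the whole panel, i.e. per pollutant). The mask is
#' unchanged and the constant is recorded so the transform is invertible.
#'
#' @param panel A `"RAW"` `panel_matrix`.
#' @param policy An [aggregation_policy()].
#' @return A transformed `panel_matrix`.
#' @export
transform_panel <- function(panel, policy = aggregation_policy()) {
  stopifnot(inherits(panel, "panel_matrix"))
  if (panel$scale != "RAW") {
    rlang::abort(sprintf("Panel is already on the %s scale.", panel$scale))
  }
  if (policy$transform == "LOG1P") {
    const <- 1
  } else {
    const <- policy$logc_factor * mean(panel$values[panel$mask])
  }
  panel_matrix(log(panel$values + const), panel$site_ids, panel$grid,
               scale = policy$transform, mask = panel$mask,
               logc_constant = const)
}

#' Invert a log transform back to the raw scale
#'
#' @param panel A `"LOG1P"` or `"LOGC"` panel.
#' @return The `"RAW"` panel (exact up to machine precision).
#' @export
untransform_panel <- function(panel) {
  stopifnot(inherits(panel, "panel_matrix"))
  const <- switch(panel$scale,
                  LOG1P = 1,
                  LOGC = panel$logc_constant,
                  rlang::abort("Panel is not on a shifted-log scale."))
  panel_matrix(exp(panel$values) - const, panel$site_ids, panel$grid,
               scale = "RAW", mask = panel$mask)
}

#' Thin an every-3rd-day record series to every 6th day
#'
#' Emulates a supplemental-site schedule from a core-site series: per site,
#' the records are sorted by date and alternate dates are retained (`phase`
#' selects which alternate), exactly halving the calendar density. Input
#' series whose date spacing is not a regular 3 days trigger a warning and
#' are thinned on the sorted date sequence anyway.
#'
#' @param records 24-hr measurement tibble from every-3rd-day sites.
#' @param phase 0 (dates 1, 3, 5, ... of the sorted sequence) or 1 (the
#'   complement).
#' @return The thinned record tibble.
#' @export
subsample_every_sixth <- function(records, phase = 0L) {
  records <- validate_measurements(records)
  stopifnot(phase %in% c(0L, 1L))
  if (any(records$duration_days != 1L)) {
    rlang::abort("Thinning applies to 24-hr records only.")
  }
  records |>
    dplyr::group_by(.data$site_id, .data$pollutant) |>
    dplyr::group_modify(function(df, key) {
      df <- dplyr::arrange(df, .data$start_date)
      gaps <- diff(as.numeric(df$start_date))
      if (length(gaps) > 0 && any(gaps != 3)) {
        rlang::warn(sprintf(
          "Site %s: irregular calendar (gaps %s); thinning sorted dates.",
          key$site_id, paste(unique(gaps), collapse = "/")))
      }
      df[seq_len(nrow(df)) %% 2L == (1L - as.integer(phase)), ]
    }) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(MEASUREMENT_COLS))
}
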