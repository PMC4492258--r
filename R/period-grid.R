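#' Build a two-week period grid centered on alternate Wednesdays
#'
#' Regulatory speciation networks report 24-hour samples while cohort-focused
#' campaigns collect two-week integrated samples; every analysis in this
#' package works on a shared temporal grid of contiguous 14-day periods whose
#' center day (day 7, 0-based 6, of the half-open interval) falls on a
#' Wednesday, with centers spaced 14 days apart.
#'
#' Intervals are half-open `[start, end)`, so the grid tiles the calendar with
#' no gaps or overlaps: period `k` runs from `anchor - 7 + 14*(k-1)` through
#' the day before `anchor + 7 + 14*(k-1)`.
#'
#' @param anchor_wednesday A `Date` falling on a Wednesday; the center of the
#'   first period.
#' @param n_periods Number of periods (>= 1).
#' @return A `period_grid` object: list with `anchor`, `n_periods` and a
#'   `periods` tibble (`period`, `start`, `end`, `center`).
#' @examples
#' build_period_grid(as.Date("2007-03-07"), 3)
#' @export
build_period_grid <- function(anchor_wednesday, n_periods) {
  anchor_wednesday <- as.Date(anchor_wednesday)
  if (length(anchor_wednesday) != 1 || is.na(anchor_wednesday)) {
    rlang::abort("`anchor_wednesday` must be a single valid date.")
  }
  if (as.POSIXlt(anchor_wednesday)$wday != 3L) {
    rlang::abort(sprintf(
      "`anchor_wednesday` (%s) is a %s, not a Wednesday.",
      format(anchor_wednesday), weekdays(anchor_wednesday)
    ))
  }
  n_periods <- as.integer(n_periods)
  if (is.na(n_periods) || n_periods < 1L) {
    rlang::abort("`n_periods` must be a positive integer.")
  }
  k <- seq_len(n_periods) - 1L
  center <- anchor_wednesday + 14L * k
  periods <- tibble::tibble(
    period = k + 1L,
    start = center - 7L,
    end = center + 7L,
    center = center
  )
  structure(
    list(anchor = anchor_wednesday, n_periods = n_periods, periods = periods),
    class = "period_grid"
  )
}

#' @export
print.period_grid <- function(x, ...) {
  cat(sprintf(
    "<period_grid> %d two-week periods, centers %s to %s (anchor %s)\n",
    x$n_periods, format(x$periods$center[1]),
    format(x$periods$center[x$n_periods]), format(x$anchor)
  ))
  invisible(x)
}

#' @export
format.period_grid <- function(x, ...) {
  sprintf("period_grid(%s, %d)", format(x$anchor), x$n_periods)
}

grid_start <- function(grid) grid$periods$start[1]
grid_end <- function(grid) grid$periods$end[grid$n_periods]

same_grid <- function(a, b) {
  identical(a$anchor, b$anchor) && identical(a$n_periods, b$n_periods)
}

#' First Wednesday on or after a date
#'
#' Used as the default period-grid anchor: the first Wednesday on/after the
#' earliest measurement in a record set.
#'
#' @param date A `Date` (vectorized).
#' @return The next Wednesday (possibly `date` itself).
#' @export
next_wednesday <- function(date) {
  date <- as.Date(date)
  date + (3L - as.POSIXlt(date)$wday) %% 7L
}

#' Assign samples to grid periods
#'
#' 24-hour samples map to the unique period containing their start date.
#' 14-day samples map to the period with maximal day-overlap, and are dropped
#' (`NA`) when the best overlap is below `min_overlap_days` — an integrated
#' sample straddling two periods nearly evenly represents neither.
#'
#' @param grid A [build_period_grid()] grid.
#' @param sample_start `Date` vector of sample start dates.
#' @param duration_days Integer vector (recycled) of 1 or 14.
#' @param min_overlap_days Minimum day-overlap for a 14-day sample to be
#'   assigned (default 10).
#' @return Integer vector of period indices (1-based), `NA` where unassigned.
#' @export
assign_period <- function(grid, sample_start, duration_days,
                          min_overlap_days = 10L) {
  stopifnot(inherits(grid, "period_grid"))
  sample_start <- as.Date(sample_start)
  n <- length(sample_start)
  duration_days <- as.integer(rep_len(duration_days, n))
  if (!all(duration_days %in% c(1L, 14L))) {
    rlang::abort("`duration_days` must be 1 or 14.")
  }
  g0 <- grid_start(grid)
  out <- rep(NA_integer_, n)

  daily <- duration_days == 1L
  if (any(daily)) {
    idx <- as.integer(floor(as.numeric(sample_start[daily] - g0) / 14)) + 1L
    idx[idx < 1L | idx > grid$n_periods] <- NA_integer_
    out[daily] <- idx
  }

  integ <- !daily
  if (any(integ)) {
    s <- sample_start[integ]
    # candidate periods: the one containing the sample start, and the next
    k0 <- as.integer(floor(as.numeric(s - g0) / 14)) + 1L
    ov <- function(k) {
      valid <- k >= 1L & k <= grid$n_periods
      o <- rep(-Inf, length(k))
      ks <- g0 + 14 * (k[valid] - 1L)
      o[valid] <- pmin(as.numeric(ks) + 14, as.numeric(s[valid]) + 14) -
        pmax(as.numeric(ks), as.numeric(s[valid]))
      o
    }
    o0 <- ov(k0)
    o1 <- ov(k0 + 1L)
    best <- ifelse(o1 > o0, k0 + 1L, k0)
    best_ov <- pmax(o0, o1)
    best[best_ov < min_overlap_days] <- NA_integer_
    best[best < 1L | best > grid$n_periods] <- NA_integer_
    out[integ] <- best
  }
  out
}
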