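POLLUTANTS <- c("EC", "OC", "SILICON", "SULFUR", "PM25", "NOX")
NETWORKS <- c("NPACT_FIXED", "NPACT_HOME", "CSN_CORE", "CSN_SUPP", "IMPROVE")
METHODS <- c("TOR_BLANKCORR", "TOR_NOBLANK", "TOT_NOBLANK", "GENERIC")

MEASUREMENT_COLS <- c("site_id", "pollutant", "start_date", "duration_days",
                      "value", "method")

#' Validate a table of measurement records
#'
#' Checks the invariants every downstream stage relies on: non-negative finite
#' concentrations, durations of 1 (24-hr) or 14 (two-week integrated) days,
#' parseable dates and uniqueness of (site, pollutant, start date, duration).
#'
#' @param records A data frame with the measurement columns (`site_id`,
#'   `pollutant`, `start_date`, `duration_days`, `value`, `method`).
#' @return The validated tibble (dates coerced to `Date`), invisibly usable in
#'   a pipe; aborts with offending row numbers otherwise.
#' @export
validate_measurements <- function(records) {
  records <- tibble::as_tibble(records)
  missing <- setdiff(setdiff(MEASUREMENT_COLS, "method"), names(records))
  if (length(missing) > 0) {
    rlang::abort(paste0("Missing required columns: ",
                        paste(missing, collapse = ", ")), class = "mh_schema_error")
  }
  if (!"method" %in% names(records)) records$method <- "GENERIC"
  records$site_id <- as.character(records$site_id)
  records$pollutant <- as.character(records$pollutant)
  records$method <- as.character(records$method)
  records$duration_days <- as.integer(records$duration_days)
  records$value <- as.numeric(records$value)
  start <- as.Date(records$start_date, format = "%Y-%m-%d")
  bad_row <- function(cond, what) {
    if (any(cond, na.rm = FALSE)) {
      rows <- which(cond | is.na(cond))
      rlang::abort(
        sprintf("%s at row%s %s", what, if (length(rows) > 1) "s" else "",
                paste(utils::head(rows, 10), collapse = ", ")),
        class = "mh_validation_error"
      )
    }
  }
  bad_row(is.na(start), "Unparseable start_date")
  records$start_date <- start
  bad_row(!is.finite(records$value) | records$value < 0,
          "Negative or non-finite value")
  bad_row(!records$duration_days %in% c(1L, 14L),
          "duration_days must be 1 or 14")
  bad_row(!records$pollutant %in% POLLUTANTS,
          paste0("Unknown pollutant (expected one of ",
                 paste(POLLUTANTS, collapse = ", "), ")"))
  bad_row(!records$method %in% METHODS, "Unknown method")
  key <- paste(records$site_id, records$pollutant, records$start_date,
               records$duration_days)
  bad_row(duplicated(key), "Duplicate (site, pollutant, date, duration) key")
  records[MEASUREMENT_COLS]
}

#' Read measurement records from a delimited text file
#'
#' @param path CSV file with a header row.
#' @param schema Optional named character vector mapping the canonical column
#'   names to the file's column names, e.g.
#'   `c(site_id = "monitor", value = "conc")`.
#' @return A validated tibble of measurement records.
#' @export
read_measurements <- function(path, schema = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE,
                        col_types = readr::cols(.default = readr::col_character()))
  if (!is.null(schema)) {
    absent <- setdiff(unname(schema), names(df))
    if (length(absent) > 0) {
      rlang::abort(paste0("Schema names columns absent from file: ",
                          paste(absent, collapse = ", ")),
                   class = "mh_schema_error")
    }
    for (canon in names(schema)) {
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  validate_measurements(df)
}

#' Write measurement records to CSV
#'
#' @param records Measurement tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  records <- validate_measurements(records)
  readr::write_csv(records, path)
  invisible(path)
}

#' Read a site-metadata table
#'
#' Expected columns: `site_id`, `network`, `x_km`, `y_km`, optional
#' `coloc_group`, and any number of geographic covariates named `cov_*`.
#' Sites sharing a `coloc_group` value are treated as co-located monitors.
#'
#' @param path CSV file.
#' @return A validated site tibble.
#' @export
read_sites <- function(path) {
  validate_sites(readr::read_csv(path, show_col_types = FALSE))
}

#' @rdname read_sites
#' @param sites A site data frame to validate.
#' @export
validate_sites <- function(sites) {
  sites <- tibble::as_tibble(sites)
  required <- c("site_id", "network", "x_km", "y_km")
  missing <- setdiff(required, names(sites))
  if (length(missing) > 0) {
    rlang::abort(paste0("Missing site columns: ",
                        paste(missing, collapse = ", ")), class = "mh_schema_error")
  }
  sites$site_id <- as.character(sites$site_id)
  if (anyDuplicated(sites$site_id)) {
    rlang::abort("site_id must be unique.", class = "mh_validation_error")
  }
  if (!all(sites$network %in% NETWORKS)) {
    rlang::abort(paste0("network must be one of ",
                        paste(NETWORKS, collapse = ", ")),
                 class = "mh_validation_error")
  }
  if (!all(is.finite(sites$x_km)) || !all(is.finite(sites$y_km))) {
    rlang::abort("Coordinates must be finite.", class = "mh_validation_error")
  }
  if (!"coloc_group" %in% names(sites)) sites$coloc_group <- NA_character_
  sites$coloc_group <- as.character(sites$coloc_group)
  sites
}

#' @rdname read_sites
#' @param path Output path.
#' @export
write_sites <- function(sites, path) {
  readr::write_csv(validate_sites(sites), path)
  invisible(path)
}

covariate_names <- function(sites) {
  grep("^cov_", names(sites), value = TRUE)
}

covariate_matrix <- function(sites, names = covariate_names(sites)) {
  if (length(names) == 0) rlang::abort("Sites carry no cov_* covariates.")
  absent <- setdiff(names, colnames(sites))
  if (length(absent) > 0) {
    rlang::abort(paste0("Covariates absent from sites: ",
                        paste(absent, collapse = ", ")))
  }
  m <- as.matrix(sites[names])
  rownames(m) <- sites$site_id
  m
}

#' Write / read a panel matrix as wide CSV plus a JSON sidecar
#'
#' The CSV holds one row per site and one column per period center date, empty
#' cells marking missing values; the sidecar records the scale tag and the
#' grid so the round trip is exact (mask included).
#'
#' @param panel A `panel_matrix`.
#' @param path CSV output path; the sidecar goes to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "panel_matrix"))
  wide <- tibble::as_tibble(panel$values, .name_repair = "minimal")
  wide <- dplyr::bind_cols(tibble::tibble(site_id = panel$site_ids), wide)
  readr::write_csv(wide, path, na = "")
  sidecar <- list(
    scale = panel$scale,
    anchor = format(panel$grid$anchor),
    n_periods = panel$grid$n_periods,
    logc_constant = panel$logc_constant
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"))
  grid <- build_period_grid(as.Date(sidecar$anchor), sidecar$n_periods)
  wide <- readr::read_csv(path, show_col_types = FALSE, na = "")
  values <- as.matrix(wide[-1])
  storage.mode(values) <- "double"
  panel_matrix(values, wide$site_id, grid, scale = sidecar$scale,
               logc_constant = sidecar$logc_constant)
}
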