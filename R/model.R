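#' Fit the simplified single-trend spatiotemporal model
#'
#' The study-data-only model for a log-scale panel:
#' `y(s, t) = x(s)' gamma0 + A(s) f(t) + e(s, t)`, with one shared temporal
#' trend `f`, site long-term means carried entirely by geographic covariates,
#' amplitude `A(s)` either a single constant `theta` (`"constant"` mode) or
#' covariate-driven `x(s)' gamma1` (`"covariate"` mode), and residuals
#' treated as independent and homoscedastic — no spatial dependence
#' structure. Estimated by ordinary least squares on the pooled observed
#' cells; rotating home-outdoor sites with 1-3 snapshots enter as ordinary
#' rows, with no per-site intercepts.
#'
#' @param panel Log-scale `panel_matrix` (all study sites, fixed and home).
#' @param sites Site tibble with `cov_*` covariates for every panel site.
#' @param trend A `trend_function` on the panel's grid.
#' @param amplitude_mode `"constant"` or `"covariate"`.
#' @param intercept Include baseline terms (default `TRUE`): an intercept
#'   `mu0` in the mean surface and, in `"covariate"` mode, a baseline
#'   amplitude `amp0` so `A(s) = amp0 + x(s)' gamma1`. With
#'   `intercept = FALSE` the mean and amplitude are the bare covariate
#'   combinations.
#' @return A `simplified_fit`: coefficient estimates, their covariance,
#'   residual variance (`sigma2_hat`, mean square with the
#'   degrees-of-freedom divisor), R-squared, per-site residual summaries.
#' @export
fit_simplified <- function(panel, sites, trend,
                           amplitude_mode = c("constant", "covariate"),
                           intercept = TRUE) {
  amplitude_mode <- match.arg(amplitude_mode)
  stopifnot(inherits(panel, "panel_matrix"))
  if (panel$scale == "RAW") {
    rlang::abort("Fit the model on a log-scale panel.")
  }
  sites <- validate_sites(sites)
  f <- trend_on_grid(trend, panel$grid)
  long <- as_tibble.panel_matrix(panel)
  absent <- setdiff(unique(long$site_id), sites$site_id)
  if (length(absent) > 0) {
    rlang::abort(paste0("Panel sites missing covariates: ",
                        paste(utils::head(absent, 5), collapse = ", ")))
  }
  cov_names <- covariate_names(sites)
  X_sites <- covariate_matrix(sites, cov_names)
  X <- X_sites[match(long$site_id, sites$site_id), , drop = FALSE]
  ft <- f[long$period]
  mean_block <- if (intercept) cbind(1, X) else X
  mean_names <- c(if (intercept) "mu0", paste0("gamma0_", cov_names))
  if (amplitude_mode == "constant") {
    Z <- cbind(mean_block, ft)
    colnames(Z) <- c(mean_names, "theta")
  } else {
    amp_block <- if (intercept) cbind(ft, X * ft) else X * ft
    amp_names <- c(if (intercept) "amp0", paste0("gamma1_", cov_names))
    Z <- cbind(mean_block, amp_block)
    colnames(Z) <- c(mean_names, amp_names)
  }
  y <- long$value
  if (nrow(Z) < ncol(Z)) {
    rlang::abort(sprintf("Only %d observations for %d parameters.",
                         nrow(Z), ncol(Z)))
  }
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    dropped <- colnames(Z)[qz$pivot[(qz$rank + 1):ncol(Z)]]
    rlang::abort(paste0("Design matrix is rank deficient; collinear columns: ",
                        paste(dropped, collapse = ", ")))
  }
  coefs <- qr.coef(qz, y)
  resid <- y - as.numeric(Z %*% coefs)
  df_res <- nrow(Z) - ncol(Z)
  sigma2 <- if (df_res > 0) sum(resid^2) / df_res else 0
  vcov <- sigma2 * chol2inv(qr.R(qz))[order(qz$pivot), order(qz$pivot),
                                      drop = FALSE]
  dimnames(vcov) <- list(colnames(Z), colnames(Z))
  tss <- sum((y - mean(y))^2)
  site_resid <- tibble::tibble(site_id = long$site_id, resid = resid) |>
    dplyr::group_by(.data$site_id) |>
    dplyr::summarise(n = dplyr::n(), mean_resid = mean(.data$resid),
                     rmse = sqrt(mean(.data$resid^2)), .groups = "drop")
  structure(
    list(
      mu0_hat = if (intercept) unname(coefs["mu0"]) else 0,
      gamma0_hat = stats::setNames(
        coefs[paste0("gamma0_", cov_names)], cov_names),
      amplitude_mode = amplitude_mode,
      intercept = intercept,
      theta_hat = if (amplitude_mode == "constant")
        unname(coefs["theta"]) else NULL,
      amp0_hat = if (amplitude_mode == "covariate" && intercept)
        unname(coefs["amp0"]) else 0,
      gamma1_hat = if (amplitude_mode == "covariate")
        stats::setNames(coefs[paste0("gamma1_", cov_names)], cov_names)
        else NULL,
      coefficients = coefs,
      vcov = vcov,
      trend = trend,
      sigma2_hat = sigma2,
      n_obs = nrow(Z),
      df_residual = df_res,
      r_squared = if (tss > 0) 1 - sum(resid^2) / tss else NA_real_,
      covariate_names = cov_names,
      site_residuals = site_resid,
      fitted = as.numeric(Z %*% coefs),
      data = long["site_id"] |> dplyr::mutate(period = long$period, y = y)
    ),
    class = "simplified_fit"
  )
}

#' @export
print.simplified_fit <- function(x, ...) {
  cat(sprintf(
    "<simplified_fit> %s amplitude, %d obs, sigma2 = %.4g, R^2 = %.3f\n",
    x$amplitude_mode, x$n_obs, x$sigma2_hat, x$r_squared))
  print(tidy.simplified_fit(x))
  invisible(x)
}

#' Tidy a simplified model fit
#'
#' @param x A `simplified_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`.
#' @export
tidy.simplified_fit <- function(x, ...) {
  tibble::tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    std.error = sqrt(diag(x$vcov))
  )
}

#' @rdname tidy.simplified_fit
#' @return For `glance()`: a one-row tibble with `r.squared`, `sigma2`,
#'   `nobs`, `df.residual`.
#' @export
glance.simplified_fit <- function(x, ...) {
  tibble::tibble(r.squared = x$r_squared, sigma2 = x$sigma2_hat,
                 nobs = x$n_obs, df.residual = x$df_residual)
}

#' @export
autoplot.simplified_fit <- function(object, ...) {
  df <- tibble::tibble(fitted = object$fitted, observed = object$data$y)
  ggplot2::ggplot(df, ggplot2::aes(.data$fitted, .data$observed)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "fitted (log scale)", y = "observed (log scale)") +
    ggplot2::theme_minimal()
}

site_amplitude <- function(fit, X) {
  if (fit$amplitude_mode == "constant") {
    rep(fit$theta_hat, nrow(X))
  } else {
    fit$amp0_hat + as.numeric(X %*% fit$gamma1_hat)
  }
}

#' Predict long-term averages at new sites
#'
#' The long-term average over an averaging window of periods is
#' `x(s)' gamma0 + A(s) * mean(f(t))` on the model's log scale; the plug-in
#' standard error comes from the coefficient covariance under the model's
#' residual-independence assumption (it covers estimation error of the mean
#' surface, not the new-site residual).
#'
#' @param fit A `simplified_fit`.
#' @param new_sites Site tibble carrying the same `cov_*` names.
#' @param window Integer vector of period indices to average over (default:
#'   all grid periods).
#' @return Tibble: `site_id`, `prediction`, `se`.
#' @export
predict_long_term <- function(fit, new_sites, window = NULL) {
  stopifnot(inherits(fit, "simplified_fit"))
  new_sites <- validate_sites(new_sites)
  missing <- setdiff(fit$covariate_names, names(new_sites))
  if (length(missing) > 0) {
    rlang::abort(paste0("New sites lack covariates: ",
                        paste(missing, collapse = ", ")))
  }
  f <- fit$trend$values
  if (is.null(window)) window <- seq_along(f)
  stopifnot(all(window >= 1), all(window <= length(f)))
  fbar <- mean(f[window])
  X <- covariate_matrix(new_sites, fit$covariate_names)
  pred <- fit$mu0_hat + as.numeric(X %*% fit$gamma0_hat) +
    site_amplitude(fit, X) * fbar
  # per-site contrast vector c (in coefficient order): prediction = c' coef
  se <- vapply(seq_len(nrow(X)), function(i) {
    cvec <- c(
      if (fit$intercept) 1,
      X[i, ],
      if (fit$amplitude_mode == "constant") fbar else
        c(if (fit$intercept) fbar, X[i, ] * fbar)
    )
    sqrt(as.numeric(t(cvec) %*% fit$vcov %*% cvec))
  }, numeric(1))
  tibble::tibble(site_id = new_sites$site_id, prediction = pred, se = se)
}

#' Leave-one-site-out cross-validation
#'
#' Refits the simplified model with each site held out and predicts the held
#' site's long-term mean over exactly the periods it was observed; `cv_r2`
#' compares those predictions with the observed site means. The trend is
#' taken as given (it comes from the long-series sites and is treated as a
#' fixed basis). Folds whose refit fails are flagged, excluded and counted.
#'
#' @inheritParams fit_simplified
#' @return List: `results` (tibble `site_id`, `n_obs`, `observed`,
#'   `predicted`, `ok`), `cv_r2`, `n_failed`.
#' @export
loso_cv <- function(panel, sites, trend,
                    amplitude_mode = c("constant", "covariate")) {
  amplitude_mode <- match.arg(amplitude_mode)
  stopifnot(inherits(panel, "panel_matrix"))
  obs_sites <- panel$site_ids[rowSums(panel$mask) > 0]
  if (length(obs_sites) < 5) {
    rlang::abort("Need at least 5 observed sites for leave-one-site-out CV.")
  }
  rows <- purrr::map(obs_sites, function(sid) {
    i <- match(sid, panel$site_ids)
    periods <- which(panel$mask[i, ])
    observed <- mean(panel$values[i, periods])
    fold <- tryCatch({
      train <- panel_subset(panel, setdiff(obs_sites, sid))
      fit <- fit_simplified(train, sites, trend, amplitude_mode)
      pred <- predict_long_term(fit, sites[sites$site_id == sid, ],
                                window = periods)
      tibble::tibble(site_id = sid, n_obs = length(periods),
                     observed = observed, predicted = pred$prediction,
                     ok = TRUE)
    }, error = function(e) {
      rlang::warn(sprintf("Fold for site %s failed: %s", sid,
                          conditionMessage(e)))
      tibble::tibble(site_id = sid, n_obs = length(periods),
                     observed = observed, predicted = NA_real_, ok = FALSE)
    })
    fold
  })
  results <- dplyr::bind_rows(rows)
  good <- dplyr::filter(results, .data$ok)
  cv_r2 <- 1 - sum((good$observed - good$predicted)^2) /
    sum((good$observed - mean(good$observed))^2)
  list(results = results, cv_r2 = cv_r2, n_failed = sum(!results$ok))
}
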