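# Small in-code fixtures shared across test files.

wed <- as.Date("2007-03-07")  # a Wednesday

tiny_grid <- function(n = 10) build_period_grid(wed, n)

# sites at fixed coordinates with p standard-ish covariates, deterministic
manual_sites <- function(n, network = "NPACT_FIXED", p = 2, coloc = NULL) {
  covs <- matrix(sin(seq_len(n * p) * 1.7), n, p)
  df <- tibble::tibble(
    site_id = sprintf("s%02d", seq_len(n)),
    network = rep_len(network, n),
    x_km = 10 * cos(seq_len(n)), y_km = 10 * sin(seq_len(n)),
    coloc_group = if (is.null(coloc)) NA_character_ else rep_len(coloc, n)
  )
  colnames(covs) <- paste0("cov_", seq_len(p))
  dplyr::bind_cols(df, tibble::as_tibble(covs))
}

# a panel with explicit values (vector recycled row-wise) and optional mask
manual_panel <- function(values, n_sites, grid, scale = "LOG", mask = NULL) {
  m <- matrix(values, n_sites, grid$n_periods)
  panel_matrix(m, sprintf("s%02d", seq_len(n_sites)), grid, scale = scale,
               mask = mask)
}

# rank-1 log-scale panel: mu_s + a_s * f_t (f centered so the row-centered
# panel is exactly rank 1)
rank1_panel <- function(n_sites, grid, amp = NULL, mu = NULL, f = NULL,
                        noise_sd = 0, seed = 1) {
  n_t <- grid$n_periods
  if (is.null(f)) {
    f <- cos(2 * pi * seq_len(n_t) / n_t)
    f <- f - mean(f)
  }
  if (is.null(amp)) amp <- seq(0.5, 1.5, length.out = n_sites)
  if (is.null(mu)) mu <- seq(-1, 1, length.out = n_sites)
  values <- outer(mu, rep(1, n_t)) + outer(amp, f)
  if (noise_sd > 0) {
    values <- values + withr::with_seed(seed, {
      matrix(stats::rnorm(n_sites * n_t, 0, noise_sd), n_sites, n_t)
    })
  }
  list(panel = panel_matrix(values, sprintf("s%02d", seq_len(n_sites)), grid,
                            scale = "LOG"),
       f = f, amp = amp, mu = mu)
}

expect_tibble_equal <- function(a, b, tolerance = 1e-12) {
  expect_equal(as.data.frame(a), as.data.frame(b), tolerance = tolerance)
}
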