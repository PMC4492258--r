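---
title: "Harmonizing multi-network PM2.5 component data and fitting the simplified single-trend exposure model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Harmonizing multi-network PM2.5 component data and fitting the simplified single-trend exposure model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(monitorharm)
library(dplyr)
```

## The problem

Cohort studies of long-term exposure to PM2.5 components (elemental carbon,
silicon, sulfur, ...) need predicted concentrations at participant homes.
Three kinds of monitoring data are typically available, and they disagree in
design:

* **Campaign fixed sites** (3–7 per city): two-week integrated samples,
  collected continuously for one to several years.
* **Rotating home-outdoor sites** (~50–116 per city): one to three two-week
  samples each — dense in space, nearly empty in time.
* **Regulatory speciation/visibility networks**: 24-hour samples every 3rd
  or 6th day, sparse in urban space, long in time, and collected under
  different filter-analysis and blank-correction protocols.

This package implements the workflow for deciding whether such sources can
be combined and, when they cannot, for fitting a simplified exposure model
from the campaign data alone: temporal harmonization to a common two-week
grid, co-located comparability statistics, SVD trend extraction, the
single-trend spatiotemporal model with leave-one-site-out cross-validation,
and an explicit feasibility rule set. A synthetic-data generator emulates
all three designs so every stage is testable without proprietary data.

## The two-week period grid

All analyses live on a grid of contiguous 14-day intervals whose center day
is a Wednesday, centers 14 days apart. A 14-day interval has no unique
central day, so the package defines *center = start + 7 days* and requires
that day to be a Wednesday; intervals are half-open `[start, end)` so the
grid tiles the calendar without gaps. The anchor Wednesday is configurable
(default: the first Wednesday on/after the earliest measurement); analyses
are invariant to the anchor up to relabeling of periods.

Alignment rules: a 24-hour sample belongs to the unique interval containing
its start date (boundary days resolve by the half-open convention); a
14-day sample belongs to the interval it overlaps most, and is dropped when
the best overlap is under 10 days (a sample straddling two periods nearly
evenly represents neither). The 10-day tolerance is a package convention,
exposed in `aggregation_policy()`.

## Harmonization

`to_two_week_panel()` fills each site × period cell with the 14-day
integrated value when one exists, else the arithmetic mean of the period's
24-hour samples provided there are at least `min_daily_per_period` of them
(default 2: an every-6th-day schedule contributes 2–3 samples per period, so
the default keeps supplemental-site cells while discarding
single-sample averages). A cell holding both an integrated and daily records
is an error by default (`prefer_integrated = TRUE` takes the integrated
value); within one network-site the designs never mix, so a conflict
usually signals a data-preparation mistake.

Concentrations are analyzed as `ln(x + 1)` (`LOG1P`). The additive constant
stabilizes near-zero two-week averages; a sensitivity alternative `LOGC`
uses `c = 0.1 ×` the panel-wide pollutant mean, computed per pollutant (not
per site). Both transforms record their constant and invert exactly.

## What the simulator generates — and what it does not

`simulate_latent_panel()` draws log concentrations from

$$\log C(s,t) = \mu_0 + x(s)'\gamma_0 + \bigl(a_0 + x(s)'\gamma_1\bigr)\,f(t)
  + \varepsilon(s,t) + \eta(s),$$

with geographic covariates `x(s)`, one smooth seasonal trend `f` (unit-norm
cosine of day-of-year, winter peak by default), per-period Gaussian-field
residuals with exponential covariance `sill · exp(−d/range)` (temporally
independent, spatially dependent; the covariance family is a package choice
— the model class only requires *some* spatial dependence), and an iid
site-level effect. The explicit baselines $\mu_0$ and $a_0$ are equivalent
to a constant covariate; without them a distance covariate is forced to act
as an intercept and the fitted spatial gradient can invert, so the fitted
model includes them by default too (`intercept = TRUE` in
`fit_simplified()`; set `FALSE` for the bare covariate form).

`sample_network()` then applies each network's design: one integrated
sample per period at fixed sites; 1–3 snapshots per home site with
probabilities `(0.35, 0.50, 0.15)` — chosen to give the campaign's mean of
1.8 samples per site — at random periods; 24-hour samples on a 1-in-3 or
1-in-6 calendar with a random phase at regulatory sites. Method differences
between networks are emulated *statistically*, not chemically: a
multiplicative bias, an additive offset applied on the concentration scale
(so a protocol artifact appears as a negative intercept on the log scale),
mean-one lognormal sampler noise, and extra day-to-day variability for
24-hour samples drawn around the period's two-week latent mean. No daily
latent process, meteorology, or source chemistry is modeled: the simulator
reproduces the *aggregation mismatch* between 2-week and daily sampling and
the *systematic method differences*, which is what the downstream
statistics consume. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated generating model, not fidelity to
any particular city's atmosphere.

Determinism: one run seed fans out to per-stage child seeds by a fixed
additive-offset rule (`seed + offset(stage)`), so a single integer
reproduces the whole pipeline while stages remain independently
re-runnable.

## Comparability statistics

`pair_colocated()` pairs jointly observed periods at co-located monitors
(optionally windowed, e.g. to the era after a protocol change);
`compare_colocated()` reports Pearson correlation, the best-fit line of y
on x, and the mean difference on the log scale. The best-fit line is
ordinary least squares — matching how paired scatter plots are usually
annotated — with a Deming (equal-error-variance) option for
errors-in-variables reading. Under a pure multiplicative bias `m` with
large concentrations the log-scale intercept converges to `ln m`.

`smooth_temporal_pattern()` pools (period, value) points across a site set
and applies a deterministic local-linear smoother with tri-cube weights
over period distance. The smoother family and the default bandwidth of 6
periods (≈ 12 weeks) are package conventions, recorded in every output;
smoothing is linear in the data and never extrapolates beyond the observed
period range. `compare_patterns()` reports correlation and shape RMSE
(after unit-normalizing both patterns) on the common support.

## Trend extraction and the simplified model

`extract_trend_svd()` derives the shared temporal trend from sites observed
in at least 50% of periods (the operational meaning of "long series"; the
threshold is configurable). The panel is row-centered first — site means
belong to the long-term-mean surface, not the trend — then missing cells
are initialized with column means and the algorithm alternates rank-1 SVD
reconstruction with refilling only the originally missing cells
(tolerance 1e-6 on the largest imputed-cell change, at most 100 sweeps;
non-convergence returns the current answer with a warning and a flag). The
trend is the first right singular vector, unit-normalized, signed to
correlate non-negatively with the panel's mean trajectory; flipping the
input panel's sign flips the trend, so the convention makes results
reproducible rather than canonical. Smoothing (`smooth_trend()`) happens
*before* re-normalization — smooth-then-normalize, so the returned basis is
always unit length.

`fit_simplified()` is deliberately ordinary least squares: one shared
trend, long-term means carried entirely by covariates, residuals treated as
independent and homoscedastic. That *is* the simplification that makes the
model fittable from campaign data alone — with 3–7 fixed sites there is no
information to estimate spatially correlated residual fields, and home-site
snapshots (1–3 rows each) enter the pooled regression without per-site
intercepts, which would be unidentifiable. The amplitude is either one
constant θ or covariate-driven `a0 + x'γ1`; both modes are provided because
the adequacy of a spatially constant amplitude is an empirical question —
`loso_cv()` and the residual-variance comparison between modes are the
tools for answering it. `predict_long_term()` averages the trend over a
period window and propagates coefficient uncertainty only (the plug-in SE
deliberately excludes the new-site residual).

`trend_surrogacy_check()` compares the component's trend with a candidate
surrogate trend from a better-monitored pollutant; the default adequacy
threshold r ≥ 0.9 is strict because a borrowed trend enters the model as a
fixed basis — errors in it propagate unattenuated into every prediction.

## The feasibility rule set

`assess_feasibility()` codifies the choice among three modeling approaches
as explicit rules over the comparability evidence, evaluated in the order
the approaches are naturally considered:

1. **Combine all networks** — needs ≥ 10 regulatory sites *and* median
   co-located correlation ≥ 0.8.
2. **Surrogate trend** — needs median surrogate-trend agreement ≥ 0.9.
3. **Study data only, simplified** — needs the single-trend check to pass
   and ≥ 3 fixed sites.
4. Otherwise: none.

The published decision this encodes was qualitative; the numeric thresholds
are package defaults chosen to reproduce that decision from its own
reported evidence, every threshold is configurable, and the report echoes
each comparison so the recommendation is auditable. Median (not mean)
aggregation makes the rules robust to a single aberrant co-location. The
rule order resolves the case where both the surrogate-trend and simplified
approaches are viable in favor of the surrogate-trend full model, which
retains spatial dependence structure.

## A worked run

```{r demo}
cfg <- run_config(
  seed = 11L, n_periods = 16,
  counts = c(NPACT_FIXED = 7, NPACT_HOME = 30, CSN_CORE = 2, CSN_SUPP = 2,
             IMPROVE = 3),
  output_dir = file.path(tempdir(), "mh-demo"))
manifest <- run_all(cfg)
manifest$artifacts
jsonlite::read_json(file.path(cfg$output_dir, "feasibility.json"))$approach
```

The demonstration sizes (16 periods, ~44 sites) are the package's default
compromise between realism and a run that completes in seconds; the same
configuration object scales to the full multi-year presets
(`region_preset()`, 26+ periods) unchanged.

## Numerical conventions and degenerate inputs

* Ties in 14-day alignment (7/7-day overlap) fall below the 10-day
  tolerance and are dropped rather than broken arbitrarily.
* The latent-field Cholesky adds a jitter of `1e-9 × sill` to the diagonal
  so co-located sites (distance zero) keep the covariance factorizable.
* Smoother windows that degenerate to fewer than two distinct abscissae
  fall back to the weighted mean; empty tri-cube windows take the nearest
  observed points.
* Zero-variance inputs error in `compare_colocated()` (undefined slope) and
  return `NA` correlation in `compare_patterns()`.
* `sigma2_hat` uses the residual degrees-of-freedom divisor `n − k`.

## Known limitations

* The fitted model is the simplified one: no spatially correlated residual
  field, no kriging of trend coefficients, no joint likelihood. The
  simulator *generates* from the richer structure precisely so the
  simplification's cost is measurable (e.g. constant-amplitude fits show
  inflated residual variance when the true amplitude varies).
* Calibration models between networks (regressing one protocol on another
  to merge them) are out of scope; the package quantifies incompatibility
  but does not correct it.
* Trend extraction assumes one dominant temporal component; panels with two
  comparable singular values will yield an unstable first component, which
  the `explained` attribute flags.
* The plug-in prediction SE understates total uncertainty at new sites by
  the residual variance; it is an estimation-error budget, not a prediction
  interval.
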