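# gappypollen

Imputation of missing values in daily airborne pollen time series by
**Gappy Singular Value Decomposition (GSVD)** and by **moving-mean
interpolation**, plus the full simulation-study machinery needed to
evaluate them: pollen-season definition, controlled gap generation, RMSE
scoring, robust log-RMSE regression, and a synthetic multi-year pollen
generator.

## Who this is for

Aerobiological monitoring records — daily pollen concentrations in pollen
grains per cubic metre of air (p/m³), mostly from manually read Hirst-type
samplers — routinely contain runs of consecutive missing days. This package
is for analysts of such records who need to fill gaps before computing
season statistics or feeding the series into epidemiological models, and
for methodologists who want to quantify how imputation error depends on the
missingness pattern (proportion and gap length) and on the pollen's
day-to-day variability.

## The methods

**Moving mean.** Each missing day `i` in a gap of length `L` is replaced by
the mean of observed values in the symmetric window `[i − L, i + L]`
(twice the gap length, truncated at the edges; widened until it contains an
observation).

**Gappy SVD.** Stack aligned yearly series as columns of a matrix
`X = U Σ Vᵀ`. The leading `N` singular modes carry the seasonal structure
shared across columns; the truncation `X* = U* Σ* V*ᵀ` is the best rank-`N`
approximation and acts as a noise filter. Starting from an initial fill of
the gaps (column mean or linear interpolation), the algorithm alternates
SVD, rank-`N` truncation, and replacement of the gap entries by `X*`, until
the mean squared change of the imputed entries between iterations drops
below a tolerance (default `1e-6`). Observed entries are never modified;
imputed concentrations are clipped at zero.

**Evaluation.** Reconstructions are scored by
`RMSE = sqrt(mean((predicted − observed)²))` over the imputation window,
summarised as per-scenario medians, and modelled per pollen × station
stratum by OLS on `log(RMSE)` with method / %NA / gap length as categorical
covariates and heteroskedasticity-consistent (HC1) standard errors;
exponentiated coefficients `Exp(β)` are ratios of geometric-mean RMSE
versus the references (moving mean, 5%, 3 days).

## Worked example

```r
library(gappypollen)

ds <- make_study_fixture(seed = 1)       # 2 stations x 2 taxa x 5 synthetic years
s  <- ds[["ST2/alnus_like"]]
s
#> <pollen_series> ST2 / alnus_like
#>   1826 days: 2018-01-01 to 2022-12-31 (0 missing)

w <- season_bounds(s, 2022)              # 95-percentage season
w
#> <season_window> 2022-01-03 to 2022-04-06 (94 days)
round(variation_index(s, w), 1)          # day-to-day variability, %
#> [1] 74.4

# degrade the complete 2022 window with 3 random 5-day gaps (10% target)
plan <- plan_gaps(season_len = 151, na_prop = 0.10, gap_len = 5)
plan
#> <gap_plan> 151-day window, 10% target (15.10 days): 3 gap(s) of 5 days = 15 days (9.9%)
mask  <- place_gaps(151, plan, seed = 42)
truth <- align_to_window(s, season_window("2022-01-01", "2022-05-31"))
gappy <- replace(truth, mask, NA)

# impute against the 2018-2021 columns with a rank-3 Gappy SVD
hist <- lapply(2018:2021, function(y)
  align_to_window(s, season_window(sprintf("%d-01-01", y), sprintf("%d-05-31", y)),
                  drop_leap_day = TRUE))
gm  <- assemble_matrix(hist, list(gappy), include_reference_year = FALSE)
fit <- gappy_svd(gm, n_modes = 3, init = "linear")
fit
#> Gappy-SVD imputation
#>   matrix: 151 x 5, 15 imputed entries (2.0%)
#>   modes: 3, init: linear
#>   converged after 8 iteration(s), final delta 2.17e-07 (tol 1e-06)

rmse(fit$completed[, 5], truth)          # 20.56 p/m3
mm <- impute_moving_mean(pollen_series(seq(as.Date("2022-01-01"), by = "day",
                                           length.out = 151), gappy))
rmse(mm$values, truth)                   # 18.91 p/m3
```

The two errors are of the same order: on a single noisy season neither
method dominates, which is the point the simulation study quantifies
systematically. `run_study()` executes the whole design — 12 scenarios
(5/10/25% missing × 3/5/7/10-day gaps) per station and taxon, 100
replicate masks each, three methods — and returns replicate-level records,
per-cell median RMSEs, season statistics with the Variation Index, and the
stratified robust regression. A thin shell wrapper is installed as
`exec/pollenstudy` (`pollenstudy synth`, `pollenstudy run-study`).

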