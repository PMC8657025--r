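# streamfill

Hybrid GAM/ARIMA reconstruction of missing observations in high-frequency
in-situ water-quality time series.

## The problem

Optical nitrate sensors deployed in rivers report a concentration every 15
minutes, alongside co-located probes for water temperature, specific
conductance, dissolved oxygen, turbidity and water-surface elevation.
Power failures, fouling and quality-control screening leave gaps — isolated
missing points and contiguous day- to month-long stretches — that bias
summary statistics and trend tests. `streamfill` fills those gaps with
predictions that carry honest 95% intervals, for the scientists and
monitoring programmes that must report on such records.

## The method

For a response series \(Y_t\) on a regular 15-minute grid, each missing
timestamp is reconstructed by one of two models:

- **GAM** — when the covariates the model needs are available at \(t\):
  a penalized-spline additive model

  \(Y_t = \beta_0 + \sum_{k=1}^{m} s_k(X_{kt}) + \varepsilon_t,\qquad \varepsilon_t \sim N(0,\sigma^2)\)

  with thin-plate regression spline smooths \(s_k\) over the five
  water-quality covariates (turbidity as \(\log(\mathrm{turbidity}+1)\))
  plus the lagged responses \(Y_{t-1}, Y_{t-2}\). The term set is chosen
  once by forward/backward stepwise search on the Gaussian AIC.

- **ARIMA** — otherwise: an ARIMA\((p,d,q)\) model (\(d\) by repeated KPSS
  testing, \((p,q) \le 5\) by stepwise AIC search) fit to the 500 working
  values preceding the gap, forecast across the gap in one multi-step call
  so the interval widens with the horizon.

Reconstructed values feed the lag covariates and later ARIMA histories;
observed values are never altered. The package also ships the evaluation
machinery (random point removal, day/week block removal, RMSE / PWPI /
R² metrics, where PWPI is the proportion of reconstructions within the
sensor's precision interval: ±2 µmol/L below 20 µmol/L, ±10% above) and a
synthetic river-chemistry generator with known ground truth.

## A worked example

```r
library(streamfill)

synth <- generate_synthetic(synth_control(n_days = 60), seed = 1)
rec <- reconstruct(synth$series$nitrate, synth$series[-1])
print(rec)
#> <reconstruction> nitrate [umol/L], 5760 timestamps
#>   OBSERVED 5547 | GAM 209 | ARIMA 4 | UNFILLED 0
#>   GAM terms: lag1, elevation, lag2, temperature, log_turbidity, conductance, dissolved_oxygen
#>   ARIMA runs: 4 (median length 1)

te <- truth_errors(rec, synth$truth)   # pairs vs the generator's truth
rmse(te$true, te$predicted)
#> [1] 0.8334888
pwpi(te$true, te$predicted)
#> [1] 0.9812207
```

The 60-day series loses 213 of 5760 values to injected missingness (2%
random points plus a day-long sensor outage). Nearly all are filled by the
GAM — the four ARIMA entries are points whose covariates fell inside a
station outage — and 98.1% of the reconstructions land within the nitrate
sensor's own precision interval; the RMSE of 0.83 µmol/L is dominated by
the day-long gap, where the diel cycle cannot be recovered from lags alone.

Degrade-and-score the pipeline, as in a benchmarking study:

```r
res <- run_scenarios(synth$series$nitrate, synth$series[-1],
                     scenarios = c("pct20", "day10"), n_reps = 5)
summarize_scenarios(res)[, c("scenario", "rmse_median", "pwpi_median")]
#>       scenario rmse_median pwpi_median
#> day10    day10   1.5327790   0.9370079
#> pct20    pct20   0.6537827   0.9963899
```

Point removals reconstruct better than day-long blocks — the pattern that
motivates the hybrid design.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/streamfill.R generate --days 60 --seed 1 --out data.csv
Rscript inst/cli/streamfill.R reconstruct --input data.csv --output recon.csv
Rscript inst/cli/streamfill.R simulate --input data.csv --scenarios pct20,day10 --reps 5 --out results.csv
Rscript inst/cli/streamfill.R report --results results.csv
```

## Package layout

- `R/` — grid/series containers and alignment, design assembly, the GAM
  and ARIMA engines, the reconstruction sweep, metrics, the removal
  scenarios, the synthetic generator, CSV/config I/O, CLI.
- `tests/testthat/` — unit, property and end-to-end suites.
- `vignettes/hybrid-reconstruction.Rmd` — the model, its assumptions,
  numerical choices and known limitations.
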