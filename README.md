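# wqsource

Water quality index modelling and pollution-source apportionment for
surface-water monitoring data.

Routine river monitoring produces station-by-month tables of a dozen or so
physico-chemical and microbial parameters. Three questions follow: *how
good is the water overall*, *which parameters drive that answer*, and
*which pollution sources are responsible*. `wqsource` answers all three in
one tested chain, aimed at water-quality analysts and environmental
modellers:

1. **WQI scoring.** The additive index
   `WQI = Σᵢ Cᵢ Pᵢ / Σᵢ Pᵢ`, where each concentration is normalized onto a
   0–100 sub-index `Cᵢ` through a configurable breakpoint curve and
   weighted by `Pᵢ`, graded into Excellent/Good/Moderate/Poor/Very poor
   bands; plus per-parameter screening statistics (CV, class-standard
   exceedance rates against GB3838-2002).
2. **Key-parameter selection.** A from-scratch regression forest (500
   CART trees, MSE impurity, bootstrap + random feature subsets) models
   WQI from the raw parameters; mean-decrease-impurity importances
   `fnᵢ` (normalized to sum to 1) rank the parameters, and nested
   `WQI_RFmin` surrogate models over top-*k* prefixes are compared on
   R², MSE, MAE and MAPE to find the smallest adequate parameter set.
3. **Source apportionment.** Uncertainty-weighted positive matrix
   factorization `X = GF + E` (nonnegative contributions `G` and profiles
   `F`, minimizing `Q = Σ (E/U)²` by exact alternating nonnegative least
   squares, multi-start) yields the species-contribution matrix `c_ji`,
   and the bridge statistic
   `p_j = (1 − MAPE) Σᵢ fnᵢ c_ji`
   attributes WQI variation to each source, with the surrogate model's
   MAPE as an explicit error term so the accounting totals exactly 100%.

A synthetic monitoring-data generator with planted source structure
(seasonality, upstream→downstream gradients, lognormal noise, detection
limits) provides ground truth for every stage; see the methods vignette
(`vignettes/wqsource-methods.Rmd`) for the modelling details and design
decisions.

## Worked example

```r
library(wqsource)

# 1. synthetic monitoring campaign: 4 stations x 107 months, 5 planted sources
model <- generate_source_model(5, seed = 7)
river <- simulate_monitoring(model, n_stations = 4, n_months = 107, seed = 8)

# 2. score the water quality index
specs <- default_parameter_specs()
wqi <- wqi_table(river, specs)
round(tapply(wqi$WQI, wqi$station, mean), 1)
#>   S1   S2   S3   S4
#> 81.1 79.5 76.7 73.5

# 3. WQI regression forest and importance ranking
split <- train_test_split(nrow(river$values), 0.9, seed = 1)
rf <- fit_forest(river$values[split$train, ], wqi$WQI[split$train],
                 n_trees = 500, seed = 2)
imp <- feature_importance(rf)
print(imp)
#> Normalized feature importances (sum = 1):
#>     Fe     Mn F_coli     DO     TN  F_ion  NO3_N    SO4     Cl  NH3_N     TP
#> 0.2991 0.2602 0.1000 0.0833 0.0581 0.0363 0.0337 0.0251 0.0213 0.0197 0.0192
#>  CODMn     WT     pH
#> 0.0164 0.0149 0.0128
mets <- regression_metrics(wqi$WQI[split$test],
                           predict(rf, river$values[split$test, ]))
print(mets)
#> R2 0.9173  MSE 2.484  MAE 1.196  MAPE 1.590%

# 4. PMF source apportionment
U <- build_uncertainty(river$values, spec_mdl(specs), censored = river$censored)
pmf <- fit_pmf(river$values, U, p = 5, n_starts = 20, seed = 3)
print(pmf)
#> PMF solution: 5 factors, Q = 4883.09 (Q/dof = 1.29), converged, 20 starts
cm <- contribution_matrix(pmf)

# 5. attribute WQI variation to the sources
apportion_wqi(imp, cm, mets$mape_pct / 100, labels = label_sources(cm))
#> Source contributions to WQI variation (%):
#>                            source contribution_pct
#>             heavy metal pollution            47.73
#>  non-point agricultural pollution            18.76
#>           unexplained variability            13.73
#>           unexplained variability             9.80
#>           microbial contamination             8.38
#>                       model error             1.59
#> total: 100.0000%
```

Reading the output: water quality declines from the upstream station S1
(mean WQI 81, "Good") to the downstream S4 (73), driven by the planted
heavy-metal and microbial gradients; the forest independently recovers
Fe, Mn, faecal coliform, DO and TN as the most informative parameters;
the five-factor PMF (Q/dof ≈ 1.3, i.e. residuals consistent with the
assumed 10% uncertainties) yields a source accounting in which heavy-metal
pollution dominates the WQI variation and the model-error row closes the
budget at exactly 100%.

The whole chain — plus CSV/JSON artifacts and a run manifest — is also
available as one call, `run_pipeline(pipeline_config(...))`, or from the
shell via the CLI wrapper (`inst/cli/wqsource.R`) with subcommands
`simulate`, `wqi`, `train`, `select`, `pmf`, `apportion` and `run-all`.

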