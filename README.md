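# storacast

Forecasting and grading pesticide-residue decay in stored wheat.

Residues of dimethoate, chlorpyrifos and chlorpyrifos-methyl degrade slowly
in sealed, dark grain silos, and how fast they degrade depends on the
storage temperature and relative humidity. `storacast` is an R package for
analysts of grain-storage monitoring data who want to (1) forecast residue
concentrations days ahead from daily monitoring series and (2) turn those
forecasts into an ordered storage-quality grade per pesticide.

The package implements, from first principles:

- **A synthetic monitoring-data generator.** First-order decay
  `C(t) = C0 · exp(-k(T, H) · t)` with rate constant
  `k = k0 · exp(a·(T - T_ref)) · (1 + b·(H - H_ref))`, multiplicative
  Gaussian assay noise, a 3 × 3 factorial of temperatures {10, 25, 35} °C and
  humidities {54, 65, 75} % RH over 90 days, and a chronological 7:2:1
  train/test/validation split.
- **A decomposition/auto-correlation forecaster** (Autoformer-style):
  series decomposition `X = X_seasonal + X_trend` by padded moving average,
  attention replaced by lag scoring via the Wiener–Khinchin relation
  `R(τ) = F⁻¹(F(Q) · conj(F(K)))`, top-`⌊log L⌋` lag selection, softmax
  time-delay aggregation of circularly rolled values, and a two-branch
  decoder that accumulates trend while refining the seasonal part. Trained
  by a built-in reverse-mode autodiff tape with Adam — no external deep
  learning framework.
- **RNN, LSTM and Transformer baselines** sharing the same embedding,
  width, horizon and training interface, plus a repeat-last naive reference.
- **Five error metrics** — MAE, MSE, RMSE, MAPE, SMAPE (decimal convention)
  — and comparison tables with exact pairwise differences.
- **Quality grading**: the two-component index `Q_i = [d_i, d̄_i]` (observed
  concentration, mean of the next-*n*-day forecasts), clustered per
  pesticide with K-means++ (D²-weighted seeding + Lloyd iterations), the
  cluster count selected by silhouette coefficient with the Davies–Bouldin
  index as corroboration, and clusters ordered into quality levels
  (Level 1 = lowest residue = best quality).

## Worked example

```r
library(storacast)

# simulate the study design: 3 pesticides x 9 conditions x 90 days
ds <- split_dataset(build_dataset(n_days = 90, seed = 1))
ds
#> <storage_dataset> 2430 records, 3 pesticides, 9 conditions
#>   (test=486, train=1701, validation=243)

# small forecaster on a two-condition noiseless fixture
p  <- list(dimethoate = kinetic_params(0.05, base_rate = 0.03,
                                       temp_sensitivity = 0.05,
                                       humidity_sensitivity = 0.01))
fx <- split_dataset(build_dataset(p, list(storage_condition(25, 65),
                                          storage_condition(35, 75)),
                                  n_days = 60, seed = 2))
cfg <- forecaster_config(model_width = 8, feedforward_width = 16,
                         decomp_kernel = 7, context_length = 16,
                         label_length = 8, horizon = 4, seed = 11)
af <- fit_forecaster(fx, cfg, kind = "autoformer", epochs = 120,
                     batch_size = 8, learning_rate = 0.01)
nv <- fit_forecaster(fx, cfg, kind = "naive")
evaluate_forecaster(af, fx, "test")$metrics
#> MAE 0.00051  MSE 0.00000  RMSE 0.00065  MAPE 0.10408  SMAPE 0.11175  (n = 72)
evaluate_forecaster(af, fx, "test")$metrics$mse
#> [1] 4.22413e-07
evaluate_forecaster(nv, fx, "test")$metrics$mse
#> [1] 7.004383e-07
```

The trained forecaster's test MSE (4.2e-07) undercuts the repeat-last
naive baseline (7.0e-07): the model has learned the downward decay rather
than merely persisting the last observation. Grading quality from the
rolled forecasts:

```r
qt <- quality_index_table(af, fx, n = 4)  # (d_i, mean next-4-day forecast)
qr <- quality_report(qt, k_range = 2:5, seed = 3)
head(qr$report)
#>    pesticide cluster    center_d center_dbar sample_size quality_level
#> 1 dimethoate       1 0.007896282 0.006779107          55             1
#> 2 dimethoate       2 0.021319456 0.019558527          35             2
```

Each pesticide is clustered separately in the `(d, d̄)` plane; clusters are
ordered by their observed-concentration center, so Level 1 rows are the
lowest-residue (best) storage states.

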