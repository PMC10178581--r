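Package: storacast
Title: Forecasting and Grading Pesticide Residue Decay in Stored Wheat
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates first-order pesticide residue degradation in stored
    wheat under temperature and humidity treatments, forecasts residue
    concentrations with a decomposition/auto-correlation (Autoformer-style)
    neural forecaster trained by a built-in reverse-mode autodiff tape,
    benchmarks it against RNN, LSTM and Transformer baselines with the five
    standard forecast error metrics (MAE, MSE, RMSE, MAPE, SMAPE), and grades
    storage quality by clustering a two-component quality index with
    K-means++ under silhouette and Davies-Bouldin model selection.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
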