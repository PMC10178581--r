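#' Forecast error metrics
#'
#' Computes the five standard point-forecast error measures:
#' \deqn{MAE = \frac{1}{n}\sum |\hat d_i - d_i|, \quad
#'       MSE = \frac{1}{n}\sum (\hat d_i - d_i)^2, \quad
#'       RMSE = \sqrt{MSE},}
#' \deqn{MAPE = \frac{1}{n}\sum \left|\frac{\hat d_i - d_i}{d_i}\right|,
#'       \quad
#'       SMAPE = \frac{1}{n}\sum \frac{|\hat d_i - d_i|}
#'                                   {(|\hat d_i| + |d_i|)/2}.}
#' MAPE and SMAPE are reported as decimals, not percentages (set
#' `percent = TRUE` to multiply both by 100). Points with a zero true value
#' are excluded from MAPE with a warning and the MAPE `n` adjusted;
#' `smape = "literal"` switches the SMAPE denominator to
#' `(|d_hat| - |d|)/2`, an audit mode for a printed-formula variant that is
#' numerically unusable near accurate predictions.
#'
#' @param predictions,truths Equal-length numeric vectors.
#' @param smape `"standard"` (default) or `"literal"`.
#' @param percent If `TRUE`, express MAPE and SMAPE in percent.
#' @return A `metric_report`: list with `mae`, `mse`, `rmse`, `mape`,
#'   `smape`, `n` and `n_mape` (points retained for MAPE).
#' @examples
#' compute_metrics(c(2, 4), c(1, 2))
#' @export
compute_metrics <- function(predictions, truths,
                            smape = c("standard", "literal"),
                            percent = FALSE) {
  smape <- match.arg(smape)
  if (length(predictions) != length(truths) || length(truths) == 0)
    stopf("predictions and truths must be equal-length, non-empty vectors")
  err <- predictions - truths
  n <- length(err)
  mae <- mean(abs(err))
  mse <- mean(err^2)
  rmse <- sqrt(mse)
  nz <- truths != 0
  if (!any(nz)) stopf("all true values are zero; MAPE is undefined")
  if (any(!nz))
    warnf("%d point(s) with zero true value excluded from MAPE", sum(!nz))
  mape <- mean(abs(err[nz] / truths[nz]))
  den <- if (smape == "standard") (abs(predictions) + abs(truths)) / 2
  else (abs(predictions) - abs(truths)) / 2
  smape_val <- mean(abs(err) / den)
  scale <- if (percent) 100 else 1
  structure(list(mae = mae, mse = mse, rmse = rmse,
                 mape = mape * scale, smape = smape_val * scale,
                 n = n, n_mape = sum(nz)),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("MAE %.5f  MSE %.5f  RMSE %.5f  MAPE %.5f  SMAPE %.5f  (n = %d)\n",
              x$mae, x$mse, x$rmse, x$mape, x$smape, x$n))
  invisible(x)
}

metric_names <- c("MAE", "MSE", "RMSE", "MAPE", "SMAPE")

#' Model comparison table
#'
#' Wraps a per-model table of the five error metrics and exposes exact
#' pairwise differences between stored values.
#'
#' @param table Data frame with columns `model`, `MAE`, `MSE`, `RMSE`,
#'   `MAPE`, `SMAPE`, one row per model.
#' @return An object of class `comparison_table`.
#' @examples
#' ct <- comparison_table(reference_forecaster_metrics())
#' metric_differences(ct, "Transformer", "Autoformer")
#' @export
comparison_table <- function(table) {
  need <- c("model", metric_names)
  missing <- setdiff(need, names(table))
  if (length(missing))
    stopf("comparison table lacks column(s): %s",
          paste(missing, collapse = ", "))
  if (anyDuplicated(table$model)) stopf("duplicate model names")
  structure(list(table = as.data.frame(table)[, need]),
            class = "comparison_table")
}

#' Pairwise metric differences
#'
#' @param ct A [comparison_table()].
#' @param model_a,model_b Model names; returns metrics of `model_a` minus
#'   those of `model_b`.
#' @return Named numeric vector over MAE, MSE, RMSE, MAPE, SMAPE.
#' @export
metric_differences <- function(ct, model_a, model_b) {
  stopifnot(inherits(ct, "comparison_table"))
  tb <- ct$table
  for (m in c(model_a, model_b))
    if (!m %in% tb$model)
      stopf("model '%s' not in table (have: %s)", m,
            paste(tb$model, collapse = ", "))
  a <- unlist(tb[tb$model == model_a, metric_names])
  b <- unlist(tb[tb$model == model_b, metric_names])
  a - b
}

#' @export
print.comparison_table <- function(x, ...) {
  tb <- x$table
  tb[metric_names] <- lapply(tb[metric_names], function(v) sprintf("%.5f", v))
  print(tb, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.comparison_table <- function(x, ...) x$table

#' Write / read a comparison table as CSV
#'
#' Values are printed with five decimals (the precision of the benchmark
#' tables this mirrors) and round-trip losslessly at that precision.
#'
#' @param ct A `comparison_table`.
#' @param path CSV path.
#' @return `write_comparison_csv` returns `path` invisibly;
#'   `read_comparison_csv` returns a `comparison_table`.
#' @export
write_comparison_csv <- function(ct, path) {
  stopifnot(inherits(ct, "comparison_table"))
  tb <- ct$table
  tb[metric_names] <- lapply(tb[metric_names], function(v) sprintf("%.5f", v))
  utils::write.csv(tb, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_comparison_csv
#' @export
read_comparison_csv <- function(path) {
  comparison_table(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Train and compare forecasters on one dataset
#'
#' Fits each requested model kind on the training split, evaluates all of
#' them on the same test split and tabulates the five error metrics. All
#' kinds share the configured width, embedding and horizon for fairness.
#'
#' @param dataset A split `storage_dataset`.
#' @param config A [forecaster_config()].
#' @param kinds Character vector of model kinds (see [fit_forecaster()]).
#' @param split Evaluation split.
#' @param ... Passed to [fit_forecaster()] (epochs, learning_rate, ...).
#' @return A list with `table` (a [comparison_table()]) and `models` (the
#'   fitted forecasters, named by kind).
#' @export
compare_models <- function(dataset, config = forecaster_config(),
                           kinds = c("rnn", "lstm", "transformer",
                                     "autoformer"),
                           split = "test", ...) {
  if (length(kinds) < 1) stopf("need at least one model kind")
  models <- list()
  rows <- list()
  for (kind in kinds) {
    models[[kind]] <- fit_forecaster(dataset, config, kind = kind, ...)
    ev <- evaluate_forecaster(models[[kind]], dataset, split = split)
    m <- ev$metrics
    rows[[kind]] <- data.frame(model = kind, MAE = m$mae, MSE = m$mse,
                               RMSE = m$rmse, MAPE = m$mape, SMAPE = m$smape)
  }
  list(table = comparison_table(do.call(rbind, rows)), models = models)
}

#' Reference benchmark tables
#'
#' Published reference values shipped with the package for comparison-table
#' arithmetic and documentation examples: per-model error metrics of the
#' four forecaster architectures on a wheat storage monitoring benchmark,
#' and the corresponding per-pesticide cluster report (centers in mg/kg,
#' sample sizes and quality levels).
#'
#' @return `reference_forecaster_metrics()`: data frame with columns
#'   `model`, `MAE`, `MSE`, `RMSE`, `MAPE`, `SMAPE`.
#'   `reference_cluster_table()`: data frame with columns `pesticide`,
#'   `cluster`, `center_d`, `center_dbar`, `sample_size`, `quality_level`.
#' @export
reference_forecaster_metrics <- function() {
  utils::read.csv(system.file("extdata", "reference_forecaster_metrics.csv",
                              package = "storacast"),
                  stringsAsFactors = FALSE)
}

#' @rdname reference_forecaster_metrics
#' @export
reference_cluster_table <- function() {
  utils::read.csv(system.file("extdata", "reference_cluster_table.csv",
                              package = "storacast"),
                  stringsAsFactors = FALSE)
}
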