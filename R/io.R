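storage_csv_columns <- c("day", "temperature_C", "humidity_pct", "pesticide",
                         "concentration_mg_per_kg", "split")

#' Write / read storage monitoring records as CSV
#'
#' The canonical on-disk layout is one row per record with header
#' `day,temperature_C,humidity_pct,pesticide,concentration_mg_per_kg,split`,
#' UTF-8, '.' decimal separator. The reader is strict: a missing column is
#' an error, and rows with a non-numeric concentration (including localized
#' decimal commas), a negative or non-integer day, or an empty pesticide
#' name are rejected with their line numbers reported in a warning.
#'
#' @param dataset A `storage_dataset`.
#' @param path CSV file path.
#' @return `write_storage_csv` returns `path` invisibly; `read_storage_csv`
#'   returns a `storage_dataset` (rejected line numbers in attribute
#'   `rejected_lines`).
#' @export
write_storage_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "storage_dataset"))
  rec <- dataset$records
  out <- data.frame(day = rec$day,
                    temperature_C = rec$temperature,
                    humidity_pct = rec$humidity,
                    pesticide = rec$pesticide,
                    concentration_mg_per_kg = rec$concentration,
                    split = ifelse(is.na(rec$split), "", rec$split))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_storage_csv
#' @export
read_storage_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  if (nrow(raw) == 0) stopf("empty storage CSV: %s", path)
  missing <- setdiff(storage_csv_columns, names(raw))
  if (length(missing))
    stopf("storage CSV lacks column(s): %s", paste(missing, collapse = ", "))
  num_re <- "^-?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$"
  day_ok <- grepl("^[0-9]+$", raw$day)
  conc_ok <- grepl(num_re, raw$concentration_mg_per_kg)
  temp_ok <- grepl(num_re, raw$temperature_C)
  hum_ok <- grepl(num_re, raw$humidity_pct)
  pest_ok <- nzchar(trimws(raw$pesticide))
  ok <- day_ok & conc_ok & temp_ok & hum_ok & pest_ok
  if (!any(ok)) stopf("no valid record in %s", path)
  rejected <- which(!ok) + 1L   # +1: header line
  if (length(rejected))
    warnf("rejected %d malformed row(s) at line(s): %s",
          length(rejected), paste(rejected, collapse = ", "))
  raw <- raw[ok, ]
  records <- data.frame(day = as.integer(raw$day),
                        temperature = as.numeric(raw$temperature_C),
                        humidity = as.numeric(raw$humidity_pct),
                        pesticide = raw$pesticide,
                        concentration = as.numeric(raw$concentration_mg_per_kg),
                        split = ifelse(nzchar(raw$split), raw$split,
                                       NA_character_),
                        stringsAsFactors = FALSE)
  if (any(records$concentration < 0)) stopf("negative concentration in %s", path)
  structure(list(records = records, n_records = nrow(records),
                 rejected_lines = rejected),
            class = "storage_dataset")
}

#' Pipeline configuration
#'
#' Collects every knob of the end-to-end run: the synthetic-data design
#' (kinetics, condition grid, length, split ratios, residue limits), the
#' forecaster configuration and training protocol, and the quality
#' assessment settings. A single global seed fans out to per-stage seeds via
#' a fixed stage-name hash, so each stage is individually reproducible.
#'
#' @param seed Global seed.
#' @param n_days Days per simulated series.
#' @param noise_sd Relative assay noise of the generator.
#' @param ratios Split fractions (train, test, validation).
#' @param forecaster A [forecaster_config()].
#' @param training List of [fit_forecaster()] arguments
#'   (`epochs`, `learning_rate`, `batch_size`, `patience`).
#' @param kinds Model kinds to compare.
#' @param assessment List with `n` (days averaged into the quality index),
#'   `k_range` and `n_restarts`.
#' @param limits Named residue limits (mg/kg).
#' @param pesticides Optional subset of the default pesticide names, for
#'   reduced runs.
#' @param conditions Optional list of [storage_condition()]s overriding the
#'   default 3 x 3 grid.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1L,
                            n_days = 90L,
                            noise_sd = 0.05,
                            ratios = c(0.7, 0.2, 0.1),
                            pesticides = NULL,
                            conditions = NULL,
                            forecaster = forecaster_config(),
                            training = list(epochs = 60, learning_rate = 0.01),
                            kinds = c("naive", "autoformer"),
                            assessment = list(n = 7L, k_range = 2:7,
                                              n_restarts = 10L),
                            limits = default_residue_limits()) {
  structure(list(seed = as.integer(seed), n_days = n_days,
                 noise_sd = noise_sd, ratios = ratios,
                 pesticides = pesticides, conditions = conditions,
                 forecaster = forecaster, training = training,
                 kinds = kinds, assessment = assessment, limits = limits),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override [pipeline_config()] defaults; `forecaster:` keys
#' override [forecaster_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  fc <- do.call(forecaster_config, y$forecaster %||% list())
  args <- y[setdiff(names(y), "forecaster")]
  args$forecaster <- fc
  if (!is.null(args$limits)) args$limits <- unlist(args$limits)
  if (!is.null(args$assessment$k_range))
    args$assessment$k_range <- do.call(seq,
      as.list(range(unlist(args$assessment$k_range))))
  do.call(pipeline_config, args)
}

#' Run the full storage-quality pipeline
#'
#' Executes simulate -> split -> train -> evaluate -> quality assessment in
#' order, writing every intermediate artifact (dataset CSV, loss traces,
#' metric comparison CSV, quality index CSV, cluster report CSV, criteria
#' CSV) plus a JSON manifest recording seeds, per-stage row counts and the
#' configuration. Re-running with the same configuration reproduces the
#' same manifest counts and metric values.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Print one line per stage.
#' @return Invisibly, a list with the dataset, fitted models, comparison
#'   table, quality tables and manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir,
                         verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message(sprintf(...))
  manifest <- list(seed = config$seed, stages = list())

  params <- default_pesticide_params(noise_sd = config$noise_sd)
  if (!is.null(config$pesticides)) params <- params[config$pesticides]
  conditions <- config$conditions %||% default_conditions()
  say("[simulate] %d days x %d pesticides x %d conditions", config$n_days,
      length(params), length(conditions))
  ds <- build_dataset(params, conditions, n_days = config$n_days,
                      seed = derive_seed(config$seed, "simulate"))
  ds <- split_dataset(ds, config$ratios)
  write_storage_csv(ds, file.path(out_dir, "storage_records.csv"))
  counts <- table(ds$records$split)
  manifest$stages$simulate <- list(records = ds$n_records,
                                   split = as.list(counts))
  flags <- flag_over_limit(ds, config$limits)
  manifest$stages$limits <- list(over_limit = attr(flags, "n_flagged"))

  say("[train] kinds: %s", paste(config$kinds, collapse = ", "))
  fc <- config$forecaster
  fc$seed <- derive_seed(config$seed, "train")
  cmp <- do.call(compare_models,
                 c(list(dataset = ds, config = fc, kinds = config$kinds),
                   config$training))
  write_comparison_csv(cmp$table, file.path(out_dir, "model_comparison.csv"))
  for (kind in names(cmp$models)) {
    tr <- cmp$models[[kind]]$loss_trace
    if (!is.null(tr))
      utils::write.csv(tr, file.path(out_dir, sprintf("loss_%s.csv", kind)),
                       row.names = FALSE)
  }
  manifest$stages$train <- list(kinds = config$kinds,
                                test_metrics = lapply(
                                  split(cmp$table$table[-1],
                                        cmp$table$table$model), as.list))

  best_kind <- utils::tail(config$kinds, 1)
  say("[assess] quality index with n = %d using %s forecasts",
      config$assessment$n, best_kind)
  qt <- quality_index_table(cmp$models[[best_kind]], ds,
                            n = config$assessment$n)
  utils::write.csv(format_num(qt, c("d", "dbar"), 8),
                   file.path(out_dir, "quality_index.csv"),
                   row.names = FALSE, quote = FALSE)
  qr <- quality_report(qt, k_range = config$assessment$k_range,
                       seed = derive_seed(config$seed, "assess"),
                       n_restarts = config$assessment$n_restarts)
  utils::write.csv(format_num(qr$report, c("center_d", "center_dbar"), 8),
                   file.path(out_dir, "cluster_report.csv"),
                   row.names = FALSE, quote = FALSE)
  crit <- do.call(rbind, lapply(names(qr$selection), function(p)
    cbind(pesticide = p, qr$selection[[p]]$evaluation)))
  utils::write.csv(format_num(crit, c("silhouette", "davies_bouldin", "wcss"), 5),
                   file.path(out_dir, "cluster_criteria.csv"),
                   row.names = FALSE, quote = FALSE)
  manifest$stages$assess <- list(q_rows = nrow(qt),
                                 dropped_days = attr(qt, "n_dropped"),
                                 chosen_k = lapply(qr$selection,
                                                   function(s) s$chosen_k))

  manifest$config_hash <- config_hash(config)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  say("[done] artifacts in %s", out_dir)
  invisible(list(dataset = ds, comparison = cmp$table, models = cmp$models,
                 quality_index = qt, quality = qr, manifest = manifest))
}

format_num <- function(df, cols, digits) {
  for (cc in cols) df[[cc]] <- sprintf(paste0("%.", digits, "f"), df[[cc]])
  df
}

# Order-stable hash of the configuration (djb2 over its deparsed form).
config_hash <- function(config) {
  s <- paste(deparse(config), collapse = "")
  h <- 5381
  for (cc in utf8ToInt(s)) h <- (h * 33 + cc) %% 2^31
  sprintf("%08x", as.integer(h))
}
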