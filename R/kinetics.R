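#' Storage condition
#'
#' A pair of environmental parameters describing one silo treatment:
#' air temperature in degrees Celsius and relative humidity in percent.
#'
#' @param temperature Storage temperature in degrees C, within \[-10, 60\].
#' @param humidity Relative humidity in percent, within (0, 100\].
#' @return An object of class `storage_condition`.
#' @examples
#' storage_condition(25, 65)
#' @export
storage_condition <- function(temperature, humidity) {
  if (!is_number(temperature) || temperature < -10 || temperature > 60)
    stopf("temperature must be a finite value in [-10, 60] degrees C, got %s",
          format(temperature))
  if (!is_number(humidity) || humidity <= 0 || humidity > 100)
    stopf("humidity must be a finite value in (0, 100] percent, got %s",
          format(humidity))
  structure(list(temperature = temperature, humidity = humidity),
            class = "storage_condition")
}

#' First-order degradation kinetics parameters
#'
#' Parameters of the residue decay law used by the synthetic data generator.
#' Decay is first order (exponential in time); the rate constant is modulated
#' exponentially by temperature and linearly by relative humidity around a
#' reference condition:
#' `rate = base_rate * exp(temp_sensitivity * (T - T_ref)) *
#'         (1 + humidity_sensitivity * (H - H_ref))`.
#' Measurement noise is multiplicative Gaussian with relative standard
#' deviation `noise_sd`, reflecting assay relative error.
#'
#' @param initial_concentration Day-0 residue concentration, mg/kg, > 0.
#' @param base_rate Decay rate constant (1/day) at the reference condition.
#' @param temp_sensitivity Exponential temperature modifier (1/degree C).
#' @param humidity_sensitivity Linear humidity modifier (1/percent RH).
#' @param reference_temperature Reference temperature (degrees C).
#' @param reference_humidity Reference relative humidity (percent).
#' @param noise_sd Relative noise standard deviation (dimensionless, < 0.5).
#' @return An object of class `kinetic_params`.
#' @examples
#' kinetic_params(0.35, base_rate = 0.006, temp_sensitivity = 0.02)
#' @export
kinetic_params <- function(initial_concentration,
                           base_rate,
                           temp_sensitivity = 0,
                           humidity_sensitivity = 0,
                           reference_temperature = 25,
                           reference_humidity = 65,
                           noise_sd = 0) {
  vals <- c(initial_concentration, base_rate, temp_sensitivity,
            humidity_sensitivity, reference_temperature, reference_humidity,
            noise_sd)
  if (!all(is.finite(vals)))
    stopf("all kinetic parameters must be finite")
  if (initial_concentration <= 0)
    stopf("initial_concentration must be > 0 mg/kg")
  if (base_rate < 0 || temp_sensitivity < 0 || humidity_sensitivity < 0)
    stopf("base_rate and sensitivities must be >= 0")
  if (noise_sd < 0 || noise_sd >= 0.5)
    stopf("noise_sd must be in [0, 0.5) so concentrations stay positive with high probability")
  structure(list(initial_concentration = initial_concentration,
                 base_rate = base_rate,
                 temp_sensitivity = temp_sensitivity,
                 humidity_sensitivity = humidity_sensitivity,
                 reference_temperature = reference_temperature,
                 reference_humidity = reference_humidity,
                 noise_sd = noise_sd),
            class = "kinetic_params")
}

#' Degradation rate constant under a storage condition
#'
#' Evaluates the first-order rate constant at a given temperature and
#' humidity. The rate increases exponentially with temperature and linearly
#' with humidity; a negative humidity modifier (possible far below the
#' reference humidity) is clamped to zero with a warning.
#'
#' @param params A [kinetic_params()] object.
#' @param condition A [storage_condition()] object.
#' @return Rate constant in 1/day, always >= 0.
#' @examples
#' p <- kinetic_params(0.35, base_rate = 0.02, temp_sensitivity = 0.05)
#' degradation_rate(p, storage_condition(35, 65))
#' @export
degradation_rate <- function(params, condition) {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(condition, "storage_condition"))
  temp_mod <- exp(params$temp_sensitivity *
                    (condition$temperature - params$reference_temperature))
  hum_mod <- 1 + params$humidity_sensitivity *
    (condition$humidity - params$reference_humidity)
  rate <- params$base_rate * temp_mod * hum_mod
  if (rate < 0) {
    warnf("humidity modifier drove the rate negative (%.4g/day); clamped to 0",
          rate)
    rate <- 0
  }
  rate
}

#' Simulate one residue decay trajectory
#'
#' Generates a daily concentration series under first-order decay with
#' multiplicative Gaussian observation noise, clipped below at zero:
#' `C(t) = C0 * exp(-rate * t) * (1 + eps_t)`, `eps_t ~ N(0, noise_sd^2)`.
#'
#' @param params A [kinetic_params()] object.
#' @param condition A [storage_condition()] object.
#' @param n_days Number of daily observations (>= 2); days run 0..n_days-1.
#' @param seed Integer seed making the noise reproducible; `NULL` uses the
#'   current RNG state.
#' @param pesticide Pesticide name attached to the series.
#' @return A `residue_series` object: a list with `pesticide`, `condition`,
#'   `days` (integer, from 0) and `concentrations` (mg/kg, >= 0).
#' @examples
#' p <- kinetic_params(0.35, base_rate = 0.01, noise_sd = 0.05)
#' s <- simulate_series(p, storage_condition(25, 65), n_days = 30, seed = 1)
#' head(s$concentrations)
#' @export
simulate_series <- function(params, condition, n_days, seed = NULL,
                            pesticide = "unnamed") {
  stopifnot(inherits(params, "kinetic_params"),
            inherits(condition, "storage_condition"))
  if (!is_count(n_days, min = 2L)) stopf("n_days must be an integer >= 2")
  rate <- degradation_rate(params, condition)
  days <- 0:(n_days - 1L)
  clean <- params$initial_concentration * exp(-rate * days)
  eps <- if (params$noise_sd > 0) {
    with_seed(seed, stats::rnorm(n_days, 0, params$noise_sd))
  } else rep(0, n_days)
  conc <- pmax(clean * (1 + eps), 0)
  structure(list(pesticide = pesticide,
                 condition = condition,
                 days = as.integer(days),
                 concentrations = conc),
            class = "residue_series")
}

#' @export
print.residue_series <- function(x, ...) {
  cat(sprintf("<residue_series> %s at %g degC / %g%% RH, %d days, %.4g -> %.4g mg/kg\n",
              x$pesticide, x$condition$temperature, x$condition$humidity,
              length(x$days), x$concentrations[1],
              x$concentrations[length(x$concentrations)]))
  invisible(x)
}

#' Default kinetic parameters for the three monitored pesticides
#'
#' Dimethoate and chlorpyrifos-methyl decay fast and are strongly
#' temperature-sensitive; chlorpyrifos decays slowly and responds weakly to
#' both temperature and humidity. Initial concentrations sit near the
#' magnitudes reported for monitored wheat (dimethoate ~0.05 mg/kg,
#' chlorpyrifos ~0.35 mg/kg, chlorpyrifos-methyl ~3.5 mg/kg).
#'
#' @param noise_sd Relative assay noise applied to all three pesticides.
#' @return Named list of [kinetic_params()], one per pesticide.
#' @export
default_pesticide_params <- function(noise_sd = 0.05) {
  list(
    dimethoate = kinetic_params(0.05, base_rate = 0.020,
                                temp_sensitivity = 0.06,
                                humidity_sensitivity = 0.010,
                                noise_sd = noise_sd),
    chlorpyrifos = kinetic_params(0.35, base_rate = 0.006,
                                  temp_sensitivity = 0.02,
                                  humidity_sensitivity = 0.004,
                                  noise_sd = noise_sd),
    `chlorpyrifos-methyl` = kinetic_params(3.5, base_rate = 0.018,
                                           temp_sensitivity = 0.05,
                                           humidity_sensitivity = 0.010,
                                           noise_sd = noise_sd)
  )
}

#' Default factorial condition grid
#'
#' The 3 x 3 crossing of storage temperatures \{10, 25, 35\} degrees C and
#' relative humidities \{54, 65, 75\} percent used throughout.
#'
#' @return List of nine [storage_condition()] objects.
#' @export
default_conditions <- function() {
  grid <- expand.grid(temperature = c(10, 25, 35),
                      humidity = c(54, 65, 75))
  lapply(seq_len(nrow(grid)),
         function(i) storage_condition(grid$temperature[i], grid$humidity[i]))
}

#' Build a storage monitoring dataset
#'
#' Simulates one residue trajectory per (pesticide x condition) pair and
#' stacks them into a flat record table.
#'
#' @param pesticide_params Named list of [kinetic_params()] keyed by
#'   pesticide name.
#' @param conditions List of [storage_condition()] objects; duplicates are
#'   rejected.
#' @param n_days Days per series.
#' @param seed Integer seed; each series draws its noise from a seed derived
#'   from this one and its (pesticide, condition) label, so the dataset is
#'   reproducible as a whole.
#' @return A `storage_dataset`: list with `records` (data.frame with columns
#'   `day`, `temperature`, `humidity`, `pesticide`, `concentration`, `split`)
#'   and `n_records`.
#' @examples
#' ds <- build_dataset(default_pesticide_params(), default_conditions(),
#'                     n_days = 90, seed = 1)
#' ds$n_records
#' @export
build_dataset <- function(pesticide_params = default_pesticide_params(),
                          conditions = default_conditions(),
                          n_days = 90, seed = 1) {
  if (length(pesticide_params) == 0 || length(conditions) == 0)
    stopf("pesticide_params and conditions must be non-empty")
  if (is.null(names(pesticide_params)) || any(names(pesticide_params) == ""))
    stopf("pesticide_params must be a named list")
  keys <- unlist(lapply(conditions, function(cn)
    sprintf("%g|%g", cn$temperature, cn$humidity)))
  if (anyDuplicated(keys))
    stopf("duplicate (temperature, humidity) conditions: %s",
          paste(unique(keys[duplicated(keys)]), collapse = ", "))
  rows <- list()
  for (pest in names(pesticide_params)) {
    for (j in seq_along(conditions)) {
      cn <- conditions[[j]]
      sseed <- derive_seed(seed, paste(pest, keys[j]))
      s <- simulate_series(pesticide_params[[pest]], cn, n_days,
                           seed = sseed, pesticide = pest)
      rows[[length(rows) + 1L]] <- data.frame(
        day = s$days,
        temperature = cn$temperature,
        humidity = cn$humidity,
        pesticide = pest,
        concentration = s$concentrations,
        split = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  rownames(records) <- NULL
  structure(list(records = records, n_records = nrow(records)),
            class = "storage_dataset")
}

#' @export
print.storage_dataset <- function(x, ...) {
  sp <- if (all(is.na(x$records$split))) "unsplit" else
    paste(names(table(x$records$split)), table(x$records$split),
          sep = "=", collapse = ", ")
  cat(sprintf("<storage_dataset> %d records, %d pesticides, %d conditions (%s)\n",
              x$n_records, length(unique(x$records$pesticide)),
              nrow(unique(x$records[, c("temperature", "humidity")])), sp))
  invisible(x)
}

#' Split counts under the floor/round/remainder rule
#'
#' For `n` records and fractions `(train, test, validation)` the counts are
#' `train = floor(r1 * n)`, `test = round(r2 * n)` and
#' `validation = n - train - test`, which reproduces the canonical
#' 7:2:1 partition of 2655 records into (1858, 531, 266).
#'
#' @param n Total record count.
#' @param ratios Positive fractions summing to 1, ordered
#'   (train, test, validation).
#' @return Named integer vector `c(train, test, validation)`.
#' @examples
#' split_counts(2655)
#' @export
split_counts <- function(n, ratios = c(0.7, 0.2, 0.1)) {
  if (!is_count(n)) stopf("n must be a positive integer")
  if (length(ratios) != 3 || any(ratios <= 0) ||
      abs(sum(ratios) - 1) > 1e-8)
    stopf("ratios must be three positive fractions summing to 1")
  # epsilon guards against binary-fraction artefacts (0.7 * 90 = 62.999...)
  tr <- floor(ratios[1] * n + 1e-9)
  te <- round(ratios[2] * n)
  va <- n - tr - te
  out <- c(train = as.integer(tr), test = as.integer(te),
           validation = as.integer(va))
  if (any(out < 1))
    stopf("n = %d is too small for three non-empty splits at ratios %s",
          n, paste(ratios, collapse = ":"))
  out
}

#' Assign chronological train/test/validation splits
#'
#' Tags every record of a dataset with a split label. The split is
#' chronological within each (pesticide, condition) series - earliest days to
#' the training set, then test, then validation - so no future observation
#' leaks into training. Counts per series follow [split_counts()].
#'
#' @param dataset A `storage_dataset`.
#' @param ratios Fractions (train, test, validation), positive, summing to 1.
#' @return The dataset with its `split` column filled.
#' @export
split_dataset <- function(dataset, ratios = c(0.7, 0.2, 0.1)) {
  stopifnot(inherits(dataset, "storage_dataset"))
  rec <- dataset$records
  key <- interaction(rec$pesticide, rec$temperature, rec$humidity, drop = TRUE)
  for (k in levels(key)) {
    idx <- which(key == k)
    idx <- idx[order(rec$day[idx])]
    cnt <- split_counts(length(idx), ratios)
    lab <- rep(c("train", "test", "validation"), times = cnt)
    rec$split[idx] <- lab
  }
  dataset$records <- rec
  dataset
}

#' Default maximum residue limits (mg/kg)
#'
#' Regulatory ceilings used for over-limit flagging. The 0.05 mg/kg limit is
#' mapped to dimethoate and 0.5 mg/kg to chlorpyrifos; see the methods
#' vignette for the provenance of that mapping.
#'
#' @return Named numeric vector of limits in mg/kg.
#' @export
default_residue_limits <- function() {
  c(dimethoate = 0.05, chlorpyrifos = 0.5, `chlorpyrifos-methyl` = 5)
}

#' Flag records over their maximum residue limit
#'
#' A record is flagged when its concentration strictly exceeds the limit for
#' its pesticide; a record exactly at the limit is not flagged.
#'
#' @param dataset A `storage_dataset`.
#' @param limits Named numeric vector of limits (mg/kg) keyed by pesticide.
#' @return Logical vector, one flag per record, with attribute `n_flagged`.
#' @export
flag_over_limit <- function(dataset, limits = default_residue_limits()) {
  stopifnot(inherits(dataset, "storage_dataset"))
  if (any(limits <= 0)) stopf("limits must be positive")
  pests <- unique(dataset$records$pesticide)
  missing <- setdiff(pests, names(limits))
  if (length(missing))
    stopf("no residue limit provided for pesticide(s): %s",
          paste(missing, collapse = ", "))
  flags <- dataset$records$concentration >
    unname(limits[dataset$records$pesticide])
  attr(flags, "n_flagged") <- sum(flags)
  flags
}

#' Extract one series from a dataset
#'
#' @param dataset A `storage_dataset`.
#' @param pesticide Pesticide name.
#' @param condition A [storage_condition()].
#' @return A `residue_series` (with per-record `split` labels attached).
#' @export
dataset_series <- function(dataset, pesticide, condition) {
  stopifnot(inherits(dataset, "storage_dataset"))
  rec <- dataset$records
  sel <- rec$pesticide == pesticide &
    rec$temperature == condition$temperature &
    rec$humidity == condition$humidity
  if (!any(sel)) stopf("no records for %s at %g degC / %g%% RH",
                       pesticide, condition$temperature, condition$humidity)
  rec <- rec[sel, ]
  rec <- rec[order(rec$day), ]
  structure(list(pesticide = pesticide, condition = condition,
                 days = as.integer(rec$day),
                 concentrations = rec$concentration,
                 split = rec$split),
            class = "residue_series")
}
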