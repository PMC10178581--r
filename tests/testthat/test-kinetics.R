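test_that("degradation rate reduces to base_rate at the reference condition", {
  p <- kinetic_params(1, base_rate = 0.02, temp_sensitivity = 0.05,
                      humidity_sensitivity = 0.01)
  expect_equal(degradation_rate(p, storage_condition(25, 65)), 0.02)
  flat <- kinetic_params(1, base_rate = 0.02)
  for (cond in default_conditions())
    expect_equal(degradation_rate(flat, cond), 0.02)
})

test_that("degradation rate matches the closed-form modifier arithmetic", {
  p <- kinetic_params(1, base_rate = 0.02, temp_sensitivity = 0.05,
                      humidity_sensitivity = 0.01,
                      reference_temperature = 25, reference_humidity = 65)
  # independent arithmetic: 0.02 * e^{0.05*10} * (1 + 0.01*10)
  expect_equal(degradation_rate(p, storage_condition(35, 75)),
               0.02 * exp(0.5) * 1.1, tolerance = 1e-12)
})

test_that("rate increases with temperature and with humidity", {
  p <- kinetic_params(1, base_rate = 0.02, temp_sensitivity = 0.05,
                      humidity_sensitivity = 0.01)
  rT <- sapply(c(10, 25, 35), function(T)
    degradation_rate(p, storage_condition(T, 65)))
  rH <- sapply(c(54, 65, 75), function(H)
    degradation_rate(p, storage_condition(25, H)))
  expect_true(all(diff(rT) > 0))
  expect_true(all(diff(rH) > 0))
})

test_that("noiseless simulation is exact exponential decay", {
  p <- kinetic_params(0.4, base_rate = 0.03)
  s <- simulate_series(p, storage_condition(25, 65), n_days = 50)
  expect_equal(s$concentrations[1], 0.4)
  expect_equal(s$concentrations, 0.4 * exp(-0.03 * (0:49)))
  const <- simulate_series(kinetic_params(0.4, 0), storage_condition(25, 65), 20)
  expect_equal(const$concentrations, rep(0.4, 20))
})

test_that("log-linear fit on noiseless decay recovers the rate", {
  p <- kinetic_params(2, base_rate = 0.04, temp_sensitivity = 0.05)
  cond <- storage_condition(35, 65)
  s <- simulate_series(p, cond, n_days = 60)
  fit <- lm(log(s$concentrations) ~ s$days)
  expect_equal(unname(coef(fit)[2]), -degradation_rate(p, cond),
               tolerance = 1e-10)
})

test_that("simulation is seed-deterministic, positive and clipped", {
  p <- kinetic_params(0.05, base_rate = 0.02, noise_sd = 0.4)
  cond <- storage_condition(25, 65)
  a <- simulate_series(p, cond, 90, seed = 7)
  b <- simulate_series(p, cond, 90, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$concentrations >= 0))
  c2 <- simulate_series(p, cond, 90, seed = 8)
  expect_false(identical(a$concentrations, c2$concentrations))
})

test_that("day-90 concentration decreases monotonically across the grid", {
  p <- default_pesticide_params(noise_sd = 0)
  for (pest in names(p)) {
    for (H in c(54, 65, 75)) {
      final <- sapply(c(10, 25, 35), function(T)
        tail(simulate_series(p[[pest]], storage_condition(T, H), 90)$concentrations, 1))
      expect_true(all(diff(final) < 0), info = sprintf("%s at H=%g", pest, H))
    }
    for (T in c(10, 25, 35)) {
      final <- sapply(c(54, 65, 75), function(H)
        tail(simulate_series(p[[pest]], storage_condition(T, H), 90)$concentrations, 1))
      expect_true(all(diff(final) < 0), info = sprintf("%s at T=%g", pest, T))
    }
  }
})

test_that("dataset assembly yields one record per pesticide-condition-day", {
  small <- build_dataset(list(a = kinetic_params(1, 0.01)),
                         list(storage_condition(25, 65)), n_days = 10, seed = 1)
  expect_equal(small$n_records, 10)
  full <- build_dataset(n_days = 90, seed = 1)
  expect_equal(full$n_records, 3 * 9 * 90)
  again <- build_dataset(n_days = 90, seed = 1)
  expect_identical(full, again)
  expect_error(build_dataset(list(a = kinetic_params(1, 0.01)),
                             list(storage_condition(25, 65),
                                  storage_condition(25, 65)), 10, 1),
               "duplicate")
})

test_that("split rule follows floor/round/remainder and conserves records", {
  expect_identical(split_counts(10), c(train = 7L, test = 2L, validation = 1L))
  expect_identical(split_counts(101), c(train = 70L, test = 20L, validation = 11L))
  expect_identical(split_counts(90), c(train = 63L, test = 18L, validation = 9L))
  for (n in c(10, 37, 90, 101, 997))
    expect_equal(sum(split_counts(n)), n)
  expect_error(split_counts(2), "too small")
})

test_that("splits are chronological per series with no future leakage", {
  ds <- split_dataset(build_dataset(n_days = 90, seed = 3))
  rec <- ds$records
  key <- interaction(rec$pesticide, rec$temperature, rec$humidity, drop = TRUE)
  for (k in levels(key)) {
    rows <- rec[key == k, ]
    expect_true(max(rows$day[rows$split == "train"]) <
                  min(rows$day[rows$split == "test"]))
    expect_true(max(rows$day[rows$split == "test"]) <
                  min(rows$day[rows$split == "validation"]))
  }
  expect_equal(sum(table(rec$split)), nrow(rec))
})

test_that("over-limit flags use strict inequality and name missing pesticides", {
  ds <- build_dataset(list(a = kinetic_params(0.4, 0.01)),
                      list(storage_condition(25, 65)), n_days = 5, seed = 1)
  expect_equal(attr(flag_over_limit(ds, c(a = 1)), "n_flagged"), 0)
  ds$records$concentration <- c(0.6, 0.5, 0.49, 0.7, 0.1)
  flags <- flag_over_limit(ds, c(a = 0.5))
  expect_equal(as.logical(flags), c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(attr(flags, "n_flagged"), 2)
  expect_error(flag_over_limit(ds, c(b = 0.5)), "a")
})
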