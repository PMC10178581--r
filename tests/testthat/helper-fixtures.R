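# Shared fixtures: all data is generated in code at test time.

tiny_config <- function(...) {
  args <- list(model_width = 8, feedforward_width = 16, decomp_kernel = 7,
               context_length = 16, label_length = 8, horizon = 4, seed = 11)
  args[names(list(...))] <- list(...)
  do.call(forecaster_config, args)
}

# Noiseless first-order decay under two conditions of the study grid.
decay_fixture <- function(noise_sd = 0, n_days = 60) {
  p <- list(dimethoate = kinetic_params(0.05, base_rate = 0.03,
                                        temp_sensitivity = 0.05,
                                        humidity_sensitivity = 0.01,
                                        noise_sd = noise_sd))
  split_dataset(build_dataset(p, list(storage_condition(25, 65),
                                      storage_condition(35, 75)),
                              n_days = n_days, seed = 2))
}

# Three well-separated Gaussian blobs in the (d, dbar) plane.
planted_blobs <- function(n_per = 30, seed = 42) {
  withr::with_seed(seed, {
    centers <- rbind(c(0.05, 0.04), c(0.30, 0.22), c(0.90, 0.70))
    pts <- do.call(rbind, lapply(1:3, function(j)
      cbind(rnorm(n_per, centers[j, 1], 0.01),
            rnorm(n_per, centers[j, 2], 0.01))))
    list(points = pts, labels = rep(1:3, each = n_per), centers = centers)
  })
}
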