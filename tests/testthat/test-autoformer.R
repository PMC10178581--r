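test_that("decoder initialization extends seasonal with zeros and trend with the context mean", {
  cfg <- tiny_config()
  ctx <- rnorm(cfg$context_length) + 3
  ini <- prepare_decoder_input(ctx, cfg)
  L_dec <- cfg$label_length + cfg$horizon
  expect_length(ini$seasonal_init, L_dec)
  expect_length(ini$trend_init, L_dec)
  expect_equal(tail(ini$seasonal_init, cfg$horizon), rep(0, cfg$horizon))
  expect_equal(tail(ini$trend_init, cfg$horizon),
               rep(mean(ctx), cfg$horizon))
  # label slice reconstructs the observed context tail
  lab <- head(ini$seasonal_init, cfg$label_length) +
    head(ini$trend_init, cfg$label_length)
  expect_equal(lab, tail(ctx, cfg$label_length))
})

test_that("a constant context yields zero seasonal and constant trend placeholders", {
  cfg <- tiny_config()
  ini <- prepare_decoder_input(rep(2.5, cfg$context_length), cfg)
  expect_equal(ini$seasonal_init, rep(c(0, 0), c(cfg$label_length, cfg$horizon)))
  expect_equal(ini$trend_init, rep(2.5, cfg$label_length + cfg$horizon))
})

forward_pred <- function(cfg, params = NULL, kind = "autoformer") {
  ds <- decay_fixture(n_days = max(40, cfg$context_length + cfg$horizon + 20))
  tabs <- storacast:::dataset_series_tables(ds)
  w <- storacast:::collect_windows(tabs, cfg, "train")[[1]]
  backend <- storacast:::forecaster_backends()[[kind]]
  if (is.null(params)) withr::with_seed(5, params <- backend$init(cfg))
  ops <- storacast:::forward_ops(cfg)
  tape <- storacast:::ag_tape()
  leaves <- storacast:::ag_leaves(tape, params)
  pred <- backend$forward(tape, leaves, w, cfg, ops)
  list(pred = pred$value, params = params, w = w, ops = ops)
}

test_that("forward output is horizon x 1 across a config grid", {
  for (cl in c(12, 20)) for (h in c(1, 5)) for (nl in 1:2) {
    cfg <- forecaster_config(model_width = 6, feedforward_width = 8,
                             decomp_kernel = 5, context_length = cl,
                             label_length = cl %/% 2, horizon = h,
                             n_encoder_layers = nl, n_decoder_layers = nl,
                             seed = 1)
    r <- forward_pred(cfg)
    expect_identical(dim(r$pred), c(as.integer(h), 1L))
    expect_true(all(is.finite(r$pred)))
  }
})

test_that("zeroed trend projections leave the trend placeholder untouched", {
  cfg <- tiny_config()
  r0 <- forward_pred(cfg)
  params <- r0$params
  for (nm in grep("_T[123]$", names(params), value = TRUE))
    params[[nm]][] <- 0
  params$head_W[] <- 0
  params$head_b[] <- 0
  r <- forward_pred(cfg, params = params)
  expect_equal(as.numeric(r$pred),
               tail(as.numeric(r0$w$trend_init), cfg$horizon),
               tolerance = 1e-12)
})

test_that("with zeroed sublayer outputs the encoder is a cascade of seasonal extractions", {
  cfg <- tiny_config(n_encoder_layers = 2)
  ds <- decay_fixture()
  tabs <- storacast:::dataset_series_tables(ds)
  w <- storacast:::collect_windows(tabs, cfg, "train")[[1]]
  backend <- storacast:::forecaster_backends()$autoformer
  withr::with_seed(5, params <- backend$init(cfg))
  for (nm in grep("^e[0-9]+_(ac\\.o|F2|b2|b1)$", names(params), value = TRUE))
    params[[nm]][] <- 0
  ops <- storacast:::forward_ops(cfg)
  # manual composition: embedding then repeated seasonal extraction
  emb <- w$ctx_feat %*% params$emb_W +
    matrix(params$emb_b, cfg$context_length, cfg$model_width, byrow = TRUE) +
    ops$pe_enc
  k <- storacast:::effective_kernel(cfg)
  manual <- emb
  for (l in 1:(2 * cfg$n_encoder_layers))
    manual <- series_decomp(manual, k)$seasonal
  tape <- storacast:::ag_tape()
  leaves <- storacast:::ag_leaves(tape, params)
  enc_in <- storacast:::ag_add(tape,
    storacast:::ag_add_bias(tape,
      storacast:::ag_matmul(tape, storacast:::ag_const(tape, w$ctx_feat),
                            leaves$emb_W), leaves$emb_b),
    storacast:::ag_const(tape, ops$pe_enc))
  x <- enc_in
  for (l in seq_len(cfg$n_encoder_layers)) {
    W <- storacast:::leaf_group(leaves, sprintf("e%d_ac", l))
    a <- storacast:::ag_autocorr_layer(tape, x, x, W, cfg$autocorr_factor)
    s1 <- storacast:::ag_decomp(tape, storacast:::ag_add(tape, a, x),
                                ops$A_enc)$seasonal
    ff <- storacast:::ag_ffn(tape, s1, leaves[[sprintf("e%d_F1", l)]],
                             leaves[[sprintf("e%d_b1", l)]],
                             leaves[[sprintf("e%d_F2", l)]],
                             leaves[[sprintf("e%d_b2", l)]])
    x <- storacast:::ag_decomp(tape, storacast:::ag_add(tape, ff, s1),
                               ops$A_enc)$seasonal
  }
  expect_equal(x$value, manual, tolerance = 1e-10)
})

test_that("one-layer auto-correlation sublayer equals manual composition of the public ops", {
  cfg <- tiny_config()
  ds <- decay_fixture()
  tabs <- storacast:::dataset_series_tables(ds)
  w <- storacast:::collect_windows(tabs, cfg, "train")[[1]]
  backend <- storacast:::forecaster_backends()$autoformer
  withr::with_seed(8, params <- backend$init(cfg))
  ops <- storacast:::forward_ops(cfg)
  emb <- w$ctx_feat %*% params$emb_W +
    matrix(params$emb_b, cfg$context_length, cfg$model_width, byrow = TRUE) +
    ops$pe_enc
  # manual: project, score all lags, keep top floor(log L), softmax, aggregate
  Q <- emb %*% params$e1_ac.q
  K <- emb %*% params$e1_ac.k
  V <- emb %*% params$e1_ac.v
  sc <- autocorr_scores(Q, K)
  lags <- select_lags(sc, cfg$autocorr_factor)
  agg <- time_delay_aggregate(V, lags, sc[lags + 1])
  manual <- unclass(agg) %*% params$e1_ac.o
  attr(manual, "weights") <- NULL
  tape <- storacast:::ag_tape()
  leaves <- storacast:::ag_leaves(tape, params)
  xn <- storacast:::ag_const(tape, emb)
  out <- storacast:::ag_autocorr_layer(tape, xn, xn,
                                       storacast:::leaf_group(leaves, "e1_ac"),
                                       cfg$autocorr_factor)
  expect_equal(out$value, manual, tolerance = 1e-10)
})

test_that("progressive decomposition keeps seasonal + trend = input at every decoder stage", {
  cfg <- tiny_config()
  ds <- decay_fixture()
  tabs <- storacast:::dataset_series_tables(ds)
  w <- storacast:::collect_windows(tabs, cfg, "train")[[1]]
  ops <- storacast:::forward_ops(cfg)
  withr::with_seed(2, {
    x <- matrix(rnorm((cfg$label_length + cfg$horizon) * cfg$model_width),
                cfg$label_length + cfg$horizon)
    tape <- storacast:::ag_tape()
    xn <- storacast:::ag_const(tape, x)
    d <- storacast:::ag_decomp(tape, xn, ops$A_dec)
    expect_equal(d$seasonal$value + d$trend$value, x, tolerance = 1e-12)
  })
})

test_that("fitting is seed-deterministic and forecasting is repeatable", {
  cfg <- tiny_config()
  ds <- decay_fixture()
  m1 <- fit_forecaster(ds, cfg, kind = "autoformer", epochs = 4,
                       batch_size = 8, learning_rate = 0.01)
  m2 <- fit_forecaster(ds, cfg, kind = "autoformer", epochs = 4,
                       batch_size = 8, learning_rate = 0.01)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$params, m2$params)
  ctx <- ds$records[ds$records$temperature == 25, ][1:cfg$context_length, ]
  names(ctx)[names(ctx) == "concentration"] <- "concentration"
  nd <- data.frame(day = ctx$day, temperature = ctx$temperature,
                   humidity = ctx$humidity, pesticide = ctx$pesticide,
                   concentration = ctx$concentration)
  p1 <- predict(m1, nd)
  p2 <- predict(m1, nd)
  expect_identical(p1, p2)
  expect_length(p1, cfg$horizon)
})

test_that("training on a constant series drives the loss to zero", {
  p <- list(a = kinetic_params(0.4, 0))
  ds <- split_dataset(build_dataset(p, list(storage_condition(25, 65)),
                                    n_days = 50, seed = 1))
  cfg <- tiny_config()
  m <- fit_forecaster(ds, cfg, kind = "autoformer", epochs = 30,
                      batch_size = 8, learning_rate = 0.02)
  expect_lt(tail(m$loss_trace$train_loss, 1), 1e-3)
})

test_that("unusable window geometry raises informative errors", {
  ds <- decay_fixture(n_days = 30)
  cfg <- tiny_config(context_length = 24, label_length = 12)
  expect_error(fit_forecaster(ds, cfg, kind = "autoformer", epochs = 1),
               "offending series")
  m <- fit_forecaster(decay_fixture(), tiny_config(), kind = "naive")
  bad <- data.frame(day = 1:3, temperature = 25, humidity = 65,
                    pesticide = "dimethoate", concentration = c(1, 2, 3))
  expect_error(predict(m, bad), "context_length")
  expect_error(predict(m, bad[, 1:3]), "lacks column")
})
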