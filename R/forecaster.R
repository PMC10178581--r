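# Fitting interface shared by the Autoformer and the baselines: window
# extraction, per-series standardization, Adam optimization, prediction and
# split-wise evaluation.

series_key <- function(pesticide, temperature, humidity) {
  sprintf("%s|%g|%g", pesticide, temperature, humidity)
}

# Fixed affine scalings for the exogenous channels; concentrations are
# z-scored per series using train-split statistics only.
scale_temperature <- function(x) (x - 20) / 15
scale_humidity <- function(x) (x - 65) / 10

# Per-series list: ordered days, concentrations, split labels, train stats.
dataset_series_tables <- function(dataset) {
  rec <- dataset$records
  if (all(is.na(rec$split)))
    stopf("dataset has no split assignment; call split_dataset() first")
  key <- series_key(rec$pesticide, rec$temperature, rec$humidity)
  out <- list()
  for (k in unique(key)) {
    rows <- rec[key == k, ]
    rows <- rows[order(rows$day), ]
    tr <- rows$concentration[rows$split == "train"]
    if (length(tr) < 2) stopf("series %s has fewer than 2 training records", k)
    sdv <- stats::sd(tr)
    if (!is.finite(sdv) || sdv < 1e-12) sdv <- 1
    out[[k]] <- list(key = k, pesticide = rows$pesticide[1],
                     temperature = rows$temperature[1],
                     humidity = rows$humidity[1],
                     days = rows$day, conc = rows$concentration,
                     split = rows$split, mu = mean(tr), sd = sdv)
  }
  out
}

series_features <- function(tab) {
  cbind((tab$conc - tab$mu) / tab$sd,
        scale_temperature(rep(tab$temperature, length(tab$conc))),
        scale_humidity(rep(tab$humidity, length(tab$conc))))
}

make_window <- function(tab, feats, s, config) {
  Lc <- config$context_length
  h <- config$horizon
  ctx_idx <- s:(s + Lc - 1L)
  tgt_idx <- (s + Lc):(s + Lc + h - 1L)
  ctx_feat <- feats[ctx_idx, , drop = FALSE]
  dec <- prepare_decoder_input(ctx_feat[, 1], config)
  L_dec <- config$label_length + h
  dec_feat <- cbind(dec$seasonal_init,
                    rep(ctx_feat[1, 2], L_dec),
                    rep(ctx_feat[1, 3], L_dec))
  list(key = tab$key,
       ctx_feat = ctx_feat,
       dec_feat = dec_feat,
       trend_init = matrix(dec$trend_init, ncol = 1),
       target_std = matrix(feats[tgt_idx, 1], ncol = 1),
       target_raw = tab$conc[tgt_idx],
       target_days = tab$days[tgt_idx],
       last_obs = tab$conc[s + Lc - 1L],
       mu = tab$mu, sd = tab$sd)
}

# Training windows: every window whose context and horizon lie entirely in
# the chronological train prefix of a series. Evaluation windows: the
# horizon lies entirely in the requested split; the context takes the
# preceding days (earlier splits allowed - no future leakage).
collect_windows <- function(tabs, config, split = "train") {
  Lc <- config$context_length
  h <- config$horizon
  wins <- list()
  for (tab in tabs) {
    n <- length(tab$conc)
    feats <- series_features(tab)
    if (split == "train") {
      n_train <- sum(tab$split == "train")
      starts <- seq_len(max(0L, n_train - Lc - h + 1L))
    } else {
      pos <- which(tab$split == split)
      starts <- integer(0)
      if (length(pos)) {
        cand <- (min(pos) - Lc):(max(pos) - Lc - h + 1L)
        cand <- cand[cand >= 1L & cand + Lc + h - 1L <= n]
        if (length(cand))
          starts <- cand[vapply(cand, function(s)
            all(tab$split[(s + Lc):(s + Lc + h - 1L)] == split), logical(1))]
      }
    }
    for (s in starts) wins[[length(wins) + 1L]] <- make_window(tab, feats, s, config)
  }
  wins
}

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}

window_loss_and_grads <- function(backend, params, w, config, ops, training) {
  tape <- ag_tape()
  leaves <- ag_leaves(tape, params)
  pred <- backend$forward(tape, leaves, w, config, ops, training = training)
  loss <- ag_mse(tape, pred, w$target_std)
  if (training) {
    ag_backward(tape, loss)
    list(loss = loss$value, grads = ag_grads(tape))
  } else {
    list(loss = loss$value, pred = as.numeric(pred$value))
  }
}

#' Fit a residue forecaster
#'
#' Trains a forecaster of the requested kind on the chronological training
#' split of a storage dataset, by windowed mean-squared-error minimisation
#' with Adam. Concentrations are z-scored per series with train-split
#' statistics only; predictions are returned on the mg/kg scale. `"naive"`
#' repeats the last observed value across the horizon and needs no training
#' (it is the reference forecaster every learned model should beat).
#'
#' @param dataset A split `storage_dataset` (see [split_dataset()]).
#' @param config A [forecaster_config()].
#' @param kind One of `"autoformer"`, `"rnn"`, `"lstm"`, `"transformer"`,
#'   `"naive"`.
#' @param epochs Training epochs.
#' @param batch_size Windows per gradient step; `Inf` for full batch.
#' @param learning_rate Adam step size.
#' @param patience Early-stopping patience on validation loss; `Inf`
#'   disables early stopping.
#' @param verbose Print a progress line every 25 epochs.
#' @return An object of class `residue_forecaster` with the trained
#'   parameters, the per-series standardization statistics and the per-epoch
#'   loss trace (`epoch`, `train_loss`, `val_loss`).
#' @seealso [predict.residue_forecaster()], [evaluate_forecaster()],
#'   [compare_models()]
#' @export
fit_forecaster <- function(dataset, config = forecaster_config(),
                           kind = c("autoformer", "rnn", "lstm",
                                    "transformer", "naive"),
                           epochs = 150, batch_size = Inf,
                           learning_rate = 0.01, patience = Inf,
                           verbose = FALSE) {
  kind <- match.arg(kind)
  stopifnot(inherits(dataset, "storage_dataset"),
            inherits(config, "forecaster_config"))
  tabs <- dataset_series_tables(dataset)
  norms <- lapply(tabs, function(tb) tb[c("pesticide", "temperature",
                                          "humidity", "mu", "sd")])
  model <- structure(list(kind = kind, config = config, params = NULL,
                          norms = norms, loss_trace = NULL,
                          ops = forward_ops(config)),
                     class = "residue_forecaster")
  if (kind == "naive") return(model)

  wins <- collect_windows(tabs, config, "train")
  if (length(wins) == 0) {
    short <- names(tabs)[vapply(tabs, function(tb)
      sum(tb$split == "train") < config$context_length + config$horizon,
      logical(1))]
    stopf("no training window of length context + horizon = %d fits; offending series: %s",
          config$context_length + config$horizon,
          paste(short, collapse = ", "))
  }
  val_wins <- collect_windows(tabs, config, "validation")
  backend <- forecaster_backends()[[kind]]

  with_seed(derive_seed(config$seed, kind), {
    params <- backend$init(config)
    opt <- adam_new(params)
    nb <- min(batch_size, length(wins))
    trace <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
    best <- list(loss = Inf, params = params, since = 0L)
    for (ep in seq_len(epochs)) {
      perm <- sample(length(wins))
      ep_loss <- 0
      for (start in seq(1, length(wins), by = nb)) {
        idx <- perm[start:min(start + nb - 1L, length(wins))]
        gsum <- NULL
        for (i in idx) {
          r <- window_loss_and_grads(backend, params, wins[[i]], config,
                                     model$ops, training = TRUE)
          ep_loss <- ep_loss + r$loss
          gsum <- if (is.null(gsum)) r$grads else
            mapply(function(a, b) a + b, gsum, r$grads[names(gsum)],
                   SIMPLIFY = FALSE)
        }
        gsum <- lapply(gsum, function(g) g / length(idx))
        upd <- adam_step(params, gsum, opt, learning_rate)
        params <- upd$params
        opt <- upd$state
      }
      train_loss <- ep_loss / length(wins)
      val_loss <- if (length(val_wins)) {
        mean(vapply(val_wins, function(w)
          window_loss_and_grads(backend, params, w, config, model$ops,
                                training = FALSE)$loss, numeric(1)))
      } else NA_real_
      trace <- rbind(trace, data.frame(epoch = ep, train_loss = train_loss,
                                       val_loss = val_loss))
      if (verbose && ep %% 25 == 0)
        message(sprintf("[%s] epoch %d train %.5g val %.5g",
                        kind, ep, train_loss, val_loss))
      if (is.finite(patience) && length(val_wins)) {
        if (val_loss < best$loss - 1e-10) {
          best <- list(loss = val_loss, params = params, since = 0L)
        } else {
          best$since <- best$since + 1L
          if (best$since >= patience) { params <- best$params; break }
        }
      }
    }
    model$params <- params
    model$loss_trace <- trace
  })
  model
}

# Raw-scale prediction for one prepared window.
forecast_window <- function(model, w) {
  if (model$kind == "naive")
    return(rep(w$last_obs, model$config$horizon))
  backend <- forecaster_backends()[[model$kind]]
  r <- window_loss_and_grads(backend, model$params, w, model$config,
                             model$ops, training = FALSE)
  r$pred * w$sd + w$mu
}

#' Forecast from an observed context window
#'
#' @param object A fitted `residue_forecaster`.
#' @param newdata Data frame with columns `day`, `temperature`, `humidity`,
#'   `pesticide`, `concentration` and exactly `context_length` rows (one
#'   series, consecutive days).
#' @param ... Unused.
#' @return Numeric vector of `horizon` predicted concentrations (mg/kg).
#' @export
predict.residue_forecaster <- function(object, newdata, ...) {
  config <- object$config
  need <- c("day", "temperature", "humidity", "pesticide", "concentration")
  missing <- setdiff(need, names(newdata))
  if (length(missing))
    stopf("newdata lacks column(s): %s", paste(missing, collapse = ", "))
  if (nrow(newdata) != config$context_length)
    stopf("newdata must have exactly context_length = %d rows, got %d",
          config$context_length, nrow(newdata))
  newdata <- newdata[order(newdata$day), ]
  key <- series_key(newdata$pesticide[1], newdata$temperature[1],
                    newdata$humidity[1])
  nrm <- object$norms[[key]]
  if (is.null(nrm)) {
    warnf("series %s was not seen in training; standardizing with the supplied context", key)
    sdv <- stats::sd(newdata$concentration)
    nrm <- list(mu = mean(newdata$concentration),
                sd = if (is.finite(sdv) && sdv > 1e-12) sdv else 1)
  }
  tab <- list(key = key, pesticide = newdata$pesticide[1],
              temperature = newdata$temperature[1],
              humidity = newdata$humidity[1],
              days = c(newdata$day, newdata$day[nrow(newdata)] +
                         seq_len(config$horizon)),
              conc = c(newdata$concentration, rep(0, config$horizon)),
              split = NULL, mu = nrm$mu, sd = nrm$sd)
  w <- make_window(tab, series_features(tab), 1L, config)
  forecast_window(object, w)
}

#' Evaluate a forecaster on one split
#'
#' Slides evaluation windows whose full horizon lies in the requested split
#' (the context may reach back into earlier days), pools all horizon-step
#' predictions and computes the five error metrics.
#'
#' @param model A fitted `residue_forecaster`.
#' @param dataset The split `storage_dataset`.
#' @param split `"train"`, `"test"` or `"validation"`.
#' @param ... Passed to [compute_metrics()].
#' @return List with `metrics` (a `metric_report`) and `predictions`
#'   (data frame of pooled predicted/true pairs).
#' @export
evaluate_forecaster <- function(model, dataset, split = "test", ...) {
  tabs <- dataset_series_tables(dataset)
  wins <- collect_windows(tabs, model$config, split)
  if (length(wins) == 0)
    stopf("no evaluation window with its horizon inside the '%s' split", split)
  preds <- lapply(wins, function(w) forecast_window(model, w))
  df <- do.call(rbind, lapply(seq_along(wins), function(i)
    data.frame(series = wins[[i]]$key, day = wins[[i]]$target_days,
               step = seq_len(model$config$horizon),
               predicted = preds[[i]], true = wins[[i]]$target_raw)))
  list(metrics = compute_metrics(df$predicted, df$true, ...),
       predictions = df)
}

#' @export
print.residue_forecaster <- function(x, ...) {
  cat(sprintf("<residue_forecaster> kind=%s width=%d enc=%d dec=%d context=%d horizon=%d\n",
              x$kind, x$config$model_width, x$config$n_encoder_layers,
              x$config$n_decoder_layers, x$config$context_length,
              x$config$horizon))
  if (!is.null(x$loss_trace) && nrow(x$loss_trace))
    cat(sprintf("  trained %d epochs; final train MSE %.6g\n",
                nrow(x$loss_trace),
                x$loss_trace$train_loss[nrow(x$loss_trace)]))
  invisible(x)
}

#' @export
summary.residue_forecaster <- function(object, ...) {
  print(object)
  if (!is.null(object$params))
    cat(sprintf("  %d parameter tensors, %d scalar parameters\n",
                length(object$params),
                sum(vapply(object$params, length, numeric(1)))))
  cat(sprintf("  %d series standardizations stored\n", length(object$norms)))
  invisible(object)
}

#' @export
coef.residue_forecaster <- function(object, ...) object$params

#' @export
plot.residue_forecaster <- function(x, ...) {
  if (is.null(x$loss_trace) || !nrow(x$loss_trace))
    stopf("no loss trace recorded (naive forecaster?)")
  tr <- x$loss_trace
  plot(tr$epoch, tr$train_loss, type = "l", xlab = "epoch",
       ylab = "MSE (standardized)", main = sprintf("%s training", x$kind), ...)
  if (any(is.finite(tr$val_loss)))
    graphics::lines(tr$epoch, tr$val_loss, lty = 2)
  invisible(x)
}

#' @export
residuals.residue_forecaster <- function(object, dataset, split = "train", ...) {
  ev <- evaluate_forecaster(object, dataset, split = split)
  ev$predictions$true - ev$predictions$predicted
}
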