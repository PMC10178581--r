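#' Forecaster configuration
#'
#' Architecture and windowing hyperparameters shared by the Autoformer-style
#' forecaster and its baselines. Defaults are deliberately small so that
#' model fitting runs comfortably on one CPU; `decomp_kernel` is the
#' moving-average window of every series-decomposition block.
#'
#' @param model_width Hidden channel count of the sequence representation.
#' @param n_heads Head count; lag scores are pooled across channels before
#'   lag selection, so heads share one lag set (see the methods vignette).
#' @param n_encoder_layers,n_decoder_layers Block counts.
#' @param feedforward_width Hidden width of the position-wise feed-forward.
#' @param decomp_kernel Odd moving-average window for decomposition blocks.
#' @param autocorr_factor Lag-sparsity factor: keep `floor(factor * log(L))`
#'   lags.
#' @param context_length Observed days fed to the encoder.
#' @param label_length Trailing slice of the context replayed to the decoder
#'   (must not exceed `context_length`).
#' @param horizon Days predicted ahead; also the `n` used by the quality
#'   index.
#' @param dropout Dropout probability during training.
#' @param seed Integer seed controlling initialization, batching and dropout.
#' @return An object of class `forecaster_config`.
#' @export
forecaster_config <- function(model_width = 16,
                              n_heads = 1,
                              n_encoder_layers = 1,
                              n_decoder_layers = 1,
                              feedforward_width = 32,
                              decomp_kernel = 25,
                              autocorr_factor = 1,
                              context_length = 24,
                              label_length = 12,
                              horizon = 7,
                              dropout = 0,
                              seed = 1L) {
  stopifnot(is_count(model_width), is_count(n_heads),
            is_count(n_encoder_layers), is_count(n_decoder_layers),
            is_count(feedforward_width), is_count(context_length),
            is_count(label_length), is_count(horizon))
  if (label_length > context_length)
    stopf("label_length (%d) must not exceed context_length (%d)",
          label_length, context_length)
  if (decomp_kernel %% 2 == 0) stopf("decomp_kernel must be odd")
  if (autocorr_factor <= 0) stopf("autocorr_factor must be positive")
  if (dropout < 0 || dropout >= 1) stopf("dropout must be in [0, 1)")
  structure(list(model_width = model_width, n_heads = n_heads,
                 n_encoder_layers = n_encoder_layers,
                 n_decoder_layers = n_decoder_layers,
                 feedforward_width = feedforward_width,
                 decomp_kernel = decomp_kernel,
                 autocorr_factor = autocorr_factor,
                 context_length = context_length,
                 label_length = label_length,
                 horizon = horizon, dropout = dropout,
                 seed = as.integer(seed)),
            class = "forecaster_config")
}

# Effective decomposition kernel: clipped to the largest odd window legal
# for the shortest sequence the model sees (the decoder side).
effective_kernel <- function(config) {
  L <- min(config$context_length, config$label_length + config$horizon)
  min(config$decomp_kernel, 2L * L - 1L)
}

#' Decoder initialization from an observed context
#'
#' Decomposes the trailing `label_length` steps of the context; the seasonal
#' part is extended by `horizon` zeros (placeholder for the future seasonal
#' signal) and the trend part by `horizon` copies of the context mean
#' (placeholder for the future trend).
#'
#' @param context Numeric vector of observed values, length >=
#'   `label_length`.
#' @param config A [forecaster_config()].
#' @return List with `seasonal_init` and `trend_init`, both of length
#'   `label_length + horizon`.
#' @export
prepare_decoder_input <- function(context, config) {
  stopifnot(inherits(config, "forecaster_config"))
  if (config$horizon < 1) stopf("horizon must be >= 1")
  if (length(context) < config$label_length)
    stopf("context (length %d) shorter than label_length (%d)",
          length(context), config$label_length)
  lab <- utils::tail(context, config$label_length)
  dc <- series_decomp(lab, effective_kernel(config))
  list(seasonal_init = c(dc$seasonal, rep(0, config$horizon)),
       trend_init = c(dc$trend, rep(mean(context), config$horizon)))
}

# ---- parameters ------------------------------------------------------------

init_autoformer_params <- function(config) {
  d <- config$model_width; f <- config$feedforward_width
  p <- list(emb_W = init_weight(3, d), emb_b = matrix(0, 1, d),
            dec_emb_W = init_weight(3, d), dec_emb_b = matrix(0, 1, d),
            head_W = init_weight(d, 1), head_b = matrix(0, 1, 1))
  ac <- function() list(q = init_weight(d, d), k = init_weight(d, d),
                        v = init_weight(d, d), o = init_weight(d, d))
  for (l in seq_len(config$n_encoder_layers)) {
    p[[sprintf("e%d_ac", l)]] <- ac()
    p[[sprintf("e%d_F1", l)]] <- init_weight(d, f)
    p[[sprintf("e%d_b1", l)]] <- matrix(0, 1, f)
    p[[sprintf("e%d_F2", l)]] <- init_weight(f, d)
    p[[sprintf("e%d_b2", l)]] <- matrix(0, 1, d)
  }
  for (l in seq_len(config$n_decoder_layers)) {
    p[[sprintf("d%d_ac", l)]] <- ac()
    p[[sprintf("d%d_cac", l)]] <- ac()
    p[[sprintf("d%d_F1", l)]] <- init_weight(d, f)
    p[[sprintf("d%d_b1", l)]] <- matrix(0, 1, f)
    p[[sprintf("d%d_F2", l)]] <- init_weight(f, d)
    p[[sprintf("d%d_b2", l)]] <- matrix(0, 1, d)
    p[[sprintf("d%d_T1", l)]] <- init_weight(d, 1)
    p[[sprintf("d%d_T2", l)]] <- init_weight(d, 1)
    p[[sprintf("d%d_T3", l)]] <- init_weight(d, 1)
  }
  flatten_params(p)
}

# Parameters are stored flat (name -> matrix); nested Q/K/V/O groups are
# flattened with a "." separator so the optimizer sees plain matrices.
flatten_params <- function(p) {
  out <- list()
  for (nm in names(p)) {
    if (is.list(p[[nm]])) {
      for (sub in names(p[[nm]])) out[[paste0(nm, ".", sub)]] <- p[[nm]][[sub]]
    } else out[[nm]] <- p[[nm]]
  }
  out
}

leaf_group <- function(leaves, prefix) {
  list(q = leaves[[paste0(prefix, ".q")]], k = leaves[[paste0(prefix, ".k")]],
       v = leaves[[paste0(prefix, ".v")]], o = leaves[[paste0(prefix, ".o")]])
}

# ---- forward pass ----------------------------------------------------------

# w: window list with ctx_feat (L_ctx x 3, channel 1 standardized
# concentration), dec_feat (L_dec x 3), trend_init (L_dec x 1).
# ops: cached constants (moving-average maps, positional encodings).
# Returns the prediction node (L_dec x 1 before cropping; cropped to the
# last `horizon` rows).
autoformer_forward <- function(tape, leaves, w, config, ops, training = FALSE) {
  drop <- function(x) if (training && config$dropout > 0)
    ag_dropout(tape, x, config$dropout) else x
  fac <- config$autocorr_factor

  enc_in <- ag_add(tape,
                   ag_add_bias(tape,
                               ag_matmul(tape, ag_const(tape, w$ctx_feat),
                                         leaves$emb_W),
                               leaves$emb_b),
                   ag_const(tape, ops$pe_enc))
  x <- enc_in
  for (l in seq_len(config$n_encoder_layers)) {
    W <- leaf_group(leaves, sprintf("e%d_ac", l))
    a <- drop(ag_autocorr_layer(tape, x, x, W, fac))
    s1 <- ag_decomp(tape, ag_add(tape, a, x), ops$A_enc)$seasonal
    ff <- drop(ag_ffn(tape, s1, leaves[[sprintf("e%d_F1", l)]],
                      leaves[[sprintf("e%d_b1", l)]],
                      leaves[[sprintf("e%d_F2", l)]],
                      leaves[[sprintf("e%d_b2", l)]]))
    x <- ag_decomp(tape, ag_add(tape, ff, s1), ops$A_enc)$seasonal
  }
  enc_out <- x

  s <- ag_add(tape,
              ag_add_bias(tape,
                          ag_matmul(tape, ag_const(tape, w$dec_feat),
                                    leaves$dec_emb_W),
                          leaves$dec_emb_b),
              ag_const(tape, ops$pe_dec))
  t_acc <- ag_const(tape, w$trend_init)
  for (l in seq_len(config$n_decoder_layers)) {
    Wse <- leaf_group(leaves, sprintf("d%d_ac", l))
    a <- drop(ag_autocorr_layer(tape, s, s, Wse, fac))
    d1 <- ag_decomp(tape, ag_add(tape, a, s), ops$A_dec)
    Wcr <- leaf_group(leaves, sprintf("d%d_cac", l))
    cr <- drop(ag_autocorr_layer(tape, d1$seasonal, enc_out, Wcr, fac))
    d2 <- ag_decomp(tape, ag_add(tape, cr, d1$seasonal), ops$A_dec)
    ff <- drop(ag_ffn(tape, d2$seasonal, leaves[[sprintf("d%d_F1", l)]],
                      leaves[[sprintf("d%d_b1", l)]],
                      leaves[[sprintf("d%d_F2", l)]],
                      leaves[[sprintf("d%d_b2", l)]]))
    d3 <- ag_decomp(tape, ag_add(tape, ff, d2$seasonal), ops$A_dec)
    t_acc <- ag_add(tape, t_acc,
                    ag_add(tape,
                           ag_add(tape,
                                  ag_matmul(tape, d1$trend,
                                            leaves[[sprintf("d%d_T1", l)]]),
                                  ag_matmul(tape, d2$trend,
                                            leaves[[sprintf("d%d_T2", l)]])),
                           ag_matmul(tape, d3$trend,
                                     leaves[[sprintf("d%d_T3", l)]])))
    s <- d3$seasonal
  }
  pred_full <- ag_add(tape,
                      ag_add_bias(tape, ag_matmul(tape, s, leaves$head_W),
                                  leaves$head_b),
                      t_acc)
  L_dec <- nrow(pred_full$value)
  ag_rows(tape, pred_full, (L_dec - config$horizon + 1L):L_dec)
}

# Cached constant operators for a config.
forward_ops <- function(config) {
  d <- config$model_width
  L_ctx <- config$context_length
  L_dec <- config$label_length + config$horizon
  k <- effective_kernel(config)
  list(A_enc = build_ma_matrix(L_ctx, min(k, 2L * L_ctx - 1L)),
       A_dec = build_ma_matrix(L_dec, min(k, 2L * L_dec - 1L)),
       pe_enc = positional_encoding(L_ctx, d),
       pe_dec = positional_encoding(L_dec, d))
}
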