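# Baseline forecasters sharing the Autoformer's embedding, width, horizon
# and training interface: a single-layer RNN and LSTM (recurrent encoder +
# linear head mapping the final hidden state to the horizon) and a standard
# single-head dot-product attention encoder-decoder Transformer.

init_rnn_params <- function(config) {
  d <- config$model_width
  list(Wx = init_weight(3, d), Wh = init_weight(d, d), b = matrix(0, 1, d),
       head_W = init_weight(d, config$horizon),
       head_b = matrix(0, 1, config$horizon))
}

rnn_forward <- function(tape, leaves, w, config, ops, training = FALSE) {
  d <- config$model_width
  h <- ag_const(tape, matrix(0, 1, d))
  for (t in seq_len(nrow(w$ctx_feat))) {
    xt <- ag_const(tape, w$ctx_feat[t, , drop = FALSE])
    pre <- ag_add_bias(tape, ag_add(tape, ag_matmul(tape, xt, leaves$Wx),
                                    ag_matmul(tape, h, leaves$Wh)),
                       leaves$b)
    h <- ag_tanh(tape, pre)
  }
  y <- ag_add_bias(tape, ag_matmul(tape, h, leaves$head_W), leaves$head_b)
  ag_transpose(tape, y)   # horizon x 1, matching the Autoformer output shape
}

init_lstm_params <- function(config) {
  d <- config$model_width
  # forget-gate bias starts at 1 so early training keeps long-range state
  b <- matrix(0, 1, 4 * d)
  b[1, (d + 1):(2 * d)] <- 1
  list(Wx = init_weight(3, 4 * d), Wh = init_weight(d, 4 * d),
       b = b,
       head_W = init_weight(d, config$horizon),
       head_b = matrix(0, 1, config$horizon))
}

lstm_forward <- function(tape, leaves, w, config, ops, training = FALSE) {
  d <- config$model_width
  h <- ag_const(tape, matrix(0, 1, d))
  cc <- ag_const(tape, matrix(0, 1, d))
  for (t in seq_len(nrow(w$ctx_feat))) {
    xt <- ag_const(tape, w$ctx_feat[t, , drop = FALSE])
    z <- ag_add_bias(tape, ag_add(tape, ag_matmul(tape, xt, leaves$Wx),
                                  ag_matmul(tape, h, leaves$Wh)),
                     leaves$b)
    i <- ag_sigmoid(tape, ag_cols(tape, z, 1:d))
    f <- ag_sigmoid(tape, ag_cols(tape, z, (d + 1):(2 * d)))
    o <- ag_sigmoid(tape, ag_cols(tape, z, (2 * d + 1):(3 * d)))
    g <- ag_tanh(tape, ag_cols(tape, z, (3 * d + 1):(4 * d)))
    cc <- ag_add(tape, ag_hadamard(tape, f, cc), ag_hadamard(tape, i, g))
    h <- ag_hadamard(tape, o, ag_tanh(tape, cc))
  }
  y <- ag_add_bias(tape, ag_matmul(tape, h, leaves$head_W), leaves$head_b)
  ag_transpose(tape, y)
}

init_transformer_params <- function(config) {
  d <- config$model_width; f <- config$feedforward_width
  att <- function() list(q = init_weight(d, d), k = init_weight(d, d),
                         v = init_weight(d, d), o = init_weight(d, d))
  flatten_params(list(
    emb_W = init_weight(3, d), emb_b = matrix(0, 1, d),
    dec_emb_W = init_weight(3, d), dec_emb_b = matrix(0, 1, d),
    enc_att = att(), enc_F1 = init_weight(d, f), enc_b1 = matrix(0, 1, f),
    enc_F2 = init_weight(f, d), enc_b2 = matrix(0, 1, d),
    dec_att = att(), dec_xatt = att(),
    dec_F1 = init_weight(d, f), dec_b1 = matrix(0, 1, f),
    dec_F2 = init_weight(f, d), dec_b2 = matrix(0, 1, d),
    head_W = init_weight(d, 1), head_b = matrix(0, 1, 1)))
}

transformer_forward <- function(tape, leaves, w, config, ops,
                                training = FALSE) {
  drop <- function(x) if (training && config$dropout > 0)
    ag_dropout(tape, x, config$dropout) else x
  e <- ag_add(tape,
              ag_add_bias(tape, ag_matmul(tape, ag_const(tape, w$ctx_feat),
                                          leaves$emb_W), leaves$emb_b),
              ag_const(tape, ops$pe_enc))
  a <- drop(ag_dot_attention(tape, e, e, leaf_group(leaves, "enc_att")))
  x <- ag_add(tape, a, e)
  ff <- drop(ag_ffn(tape, x, leaves$enc_F1, leaves$enc_b1,
                    leaves$enc_F2, leaves$enc_b2))
  enc_out <- ag_add(tape, ff, x)

  dd <- ag_add(tape,
               ag_add_bias(tape, ag_matmul(tape, ag_const(tape, w$dec_feat),
                                           leaves$dec_emb_W),
                           leaves$dec_emb_b),
               ag_const(tape, ops$pe_dec))
  a1 <- drop(ag_dot_attention(tape, dd, dd, leaf_group(leaves, "dec_att")))
  d1 <- ag_add(tape, a1, dd)
  a2 <- drop(ag_dot_attention(tape, d1, enc_out,
                              leaf_group(leaves, "dec_xatt")))
  d2 <- ag_add(tape, a2, d1)
  ff2 <- drop(ag_ffn(tape, d2, leaves$dec_F1, leaves$dec_b1,
                     leaves$dec_F2, leaves$dec_b2))
  d3 <- ag_add(tape, ff2, d2)
  pred_full <- ag_add_bias(tape, ag_matmul(tape, d3, leaves$head_W),
                           leaves$head_b)
  L_dec <- nrow(pred_full$value)
  ag_rows(tape, pred_full, (L_dec - config$horizon + 1L):L_dec)
}

forecaster_backends <- function() {
  list(
    autoformer = list(init = init_autoformer_params,
                      forward = autoformer_forward),
    rnn = list(init = init_rnn_params, forward = rnn_forward),
    lstm = list(init = init_lstm_params, forward = lstm_forward),
    transformer = list(init = init_transformer_params,
                       forward = transformer_forward)
  )
}
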