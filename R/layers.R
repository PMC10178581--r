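# Network building blocks shared by the Autoformer and the baselines.
# All blocks operate on tape nodes (see autograd.R); parameters are plain
# matrices wrapped into named leaves at the start of each forward pass.

# Dense L x L operator equivalent to moving_average(x, kernel); lets the
# decomposition ride through the tape as a single linear map.
build_ma_matrix <- function(L, kernel) {
  if (kernel %% 2 == 0) stopf("kernel must be odd")
  p <- (kernel - 1L) / 2L
  A <- matrix(0, L, L)
  for (i in seq_len(L)) {
    idx <- pmin(pmax(seq(i - p, i + p), 1L), L)
    for (j in idx) A[i, j] <- A[i, j] + 1 / kernel
  }
  A
}

# Sinusoidal positional encoding, L x d.
positional_encoding <- function(L, d) {
  pos <- matrix(0, L, d)
  t <- 0:(L - 1)
  for (i in seq_len(ceiling(d / 2))) {
    freq <- 1 / 10000^((2 * (i - 1)) / d)
    pos[, 2 * i - 1] <- sin(t * freq)
    if (2 * i <= d) pos[, 2 * i] <- cos(t * freq)
  }
  pos
}

init_weight <- function(nr, nc) {
  matrix(stats::rnorm(nr * nc, sd = sqrt(2 / (nr + nc))), nr, nc)
}

ag_leaves <- function(tape, params) {
  out <- vector("list", length(params))
  names(out) <- names(params)
  for (nm in names(params)) out[[nm]] <- ag_leaf(tape, params[[nm]], nm)
  out
}

# Trend/seasonal split on the tape; A is the precomputed moving-average map.
ag_decomp <- function(tape, x, A) {
  trend <- ag_linmap(tape, A, x)
  list(seasonal = ag_sub(tape, x, trend), trend = trend)
}

# Auto-correlation sublayer: project to Q/K/V, score all circular lags via
# FFT, keep the top floor(factor * log L) lags, softmax their scores and
# aggregate the rolled value copies. `kv` defaults to `x` (self mode); in
# cross mode it is resampled to the query length first.
ag_autocorr_layer <- function(tape, x, kv, W, factor) {
  L <- nrow(x$value)
  kvr <- ag_resample(tape, kv, L)
  Q <- ag_matmul(tape, x, W$q)
  K <- ag_matmul(tape, kvr, W$k)
  V <- ag_matmul(tape, kvr, W$v)
  scores <- ag_autocorr_scores(tape, Q, K)
  lags <- select_lags(as.numeric(scores$value), factor = factor, L = L)
  sel <- ag_cols(tape, scores, lags + 1L)
  w <- ag_softmax_rows(tape, sel)
  agg <- ag_delay_agg(tape, V, w, lags)
  ag_matmul(tape, agg, W$o)
}

ag_ffn <- function(tape, x, W1, b1, W2, b2) {
  h <- ag_relu(tape, ag_add_bias(tape, ag_matmul(tape, x, W1), b1))
  ag_add_bias(tape, ag_matmul(tape, h, W2), b2)
}

# Single-head scaled dot-product attention (Transformer baseline).
ag_dot_attention <- function(tape, x, kv, W) {
  Q <- ag_matmul(tape, x, W$q)
  K <- ag_matmul(tape, kv, W$k)
  V <- ag_matmul(tape, kv, W$v)
  S <- ag_scale(tape, ag_matmul(tape, Q, ag_transpose(tape, K)),
                1 / sqrt(ncol(Q$value)))
  A <- ag_softmax_rows(tape, S)
  ag_matmul(tape, ag_matmul(tape, A, V), W$o)
}
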