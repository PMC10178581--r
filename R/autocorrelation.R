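#' Auto-correlation scores over all circular lags
#'
#' Computes, for every lag `tau` in 0..L-1, the circular lagged inner
#' product between a query and a key sequence,
#' `R(tau) = sum_t q[t] * k[(t + tau) mod L]`, averaged over channels.
#' The computation runs in the frequency domain via the Wiener-Khinchin
#' relation: `R = Re(IFFT(Conj(FFT(q)) * FFT(k)))`. When query and key are
#' the same real sequence the score at lag 0 is the maximum.
#'
#' If the key comes from a source of a different length it must be resampled
#' to the query length first (see [resample_length()]).
#'
#' @param query Numeric vector or L x d matrix.
#' @param key Numeric vector or matrix with the same dimensions as `query`.
#' @return Numeric vector of length L; element `tau + 1` is the score at
#'   lag `tau`.
#' @examples
#' x <- sin(2 * pi * (0:31) / 8)
#' which.max(autocorr_scores(x, x)[-1])   # lag 8, the period
#' @export
autocorr_scores <- function(query, key) {
  q <- if (is.null(dim(query))) matrix(as.numeric(query), ncol = 1) else as.matrix(query)
  k <- if (is.null(dim(key))) matrix(as.numeric(key), ncol = 1) else as.matrix(key)
  if (!identical(dim(q), dim(k)))
    stopf("query and key must share dimensions (got %s vs %s); resample the key first",
          paste(dim(q), collapse = "x"), paste(dim(k), collapse = "x"))
  L <- nrow(q)
  d <- ncol(q)
  acc <- numeric(L)
  for (j in seq_len(d)) {
    fq <- stats::fft(q[, j])
    fk <- stats::fft(k[, j])
    acc <- acc + Re(stats::fft(Conj(fq) * fk, inverse = TRUE)) / L
  }
  acc / d
}

#' Resample a sequence to a target length
#'
#' Truncates at the end (keeps the first `L` rows) or zero-pads at the end,
#' as needed to reach length `L`. Used to align encoder outputs with decoder
#' queries in cross correlation.
#'
#' @param x Numeric vector or matrix.
#' @param L Target length.
#' @return `x` with exactly `L` rows (or elements).
#' @export
resample_length <- function(x, L) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), ncol = 1) else as.matrix(x)
  n <- nrow(m)
  out <- if (n >= L) m[seq_len(L), , drop = FALSE] else
    rbind(m, matrix(0, L - n, ncol(m)))
  if (vec) as.numeric(out) else out
}

#' Select the top-k lags by score
#'
#' Sparsifies the lag set to `k = floor(factor * log(L))` lags with the
#' highest scores; ties are broken in favour of the smaller lag; lag 0 is
#' eligible. `k` is capped at `L`.
#'
#' @param scores Numeric length-L vector of lag scores (lag 0 first).
#' @param factor Positive multiplier of `log(L)`.
#' @param L Sequence length (defaults to `length(scores)`).
#' @return Integer vector of selected lags (0-based), ordered by decreasing
#'   score then increasing lag.
#' @examples
#' select_lags(c(5, 1, 9, 9), factor = 2 / log(4))   # lags 2 and 3
#' @export
select_lags <- function(scores, factor = 1, L = length(scores)) {
  if (factor <= 0) stopf("factor must be positive")
  k <- min(floor(factor * log(L)), L)
  if (k < 1)
    stopf("factor %g gives k = %d lags for L = %d; need k >= 1", factor, k, L)
  lags <- 0:(L - 1)
  ord <- order(-scores, lags)
  sort_sel <- ord[seq_len(k)]
  as.integer(lags[sort_sel])
}

#' Circularly roll a sequence
#'
#' `roll_series(x, tau)[t] = x[(t + tau) mod L]`: position `t` takes the
#' value `tau` steps ahead, wrapping around.
#'
#' @param x Numeric vector or matrix (rolled along rows).
#' @param tau Integer lag.
#' @return Rolled sequence, same shape as `x`.
#' @export
roll_series <- function(x, tau) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), ncol = 1) else as.matrix(x)
  L <- nrow(m)
  idx <- ((seq_len(L) - 1 + tau) %% L) + 1
  out <- m[idx, , drop = FALSE]
  if (vec) as.numeric(out) else out
}

#' Time-delay aggregation of lag-rolled copies
#'
#' Converts the scores of the selected lags to probabilities with a softmax
#' and returns the weighted sum of circularly rolled copies of the value
#' sequence - the phase-aligned information fusion step of the
#' auto-correlation mechanism. Because every rolled copy preserves the
#' per-channel mean, the aggregate does too.
#'
#' @param values Numeric vector or L x d matrix.
#' @param lags Integer vector of selected lags (0-based), non-empty.
#' @param scores Scores of the selected lags (same length as `lags`).
#' @return Aggregated sequence, same shape as `values`; the softmax weights
#'   are attached as attribute `weights`.
#' @examples
#' time_delay_aggregate(c(1, 2, 3, 4), lags = c(1, 2), scores = c(log(2), 0))
#' @export
time_delay_aggregate <- function(values, lags, scores) {
  if (length(lags) == 0) stopf("lag set must be non-empty")
  if (length(lags) != length(scores))
    stopf("lags and scores must have equal length")
  L <- if (is.null(dim(values))) length(values) else nrow(values)
  if (any(lags < 0 | lags >= L)) stopf("lags must lie in 0..L-1")
  w <- exp(scores - max(scores))
  w <- w / sum(w)
  out <- 0
  for (j in seq_along(lags)) out <- out + w[j] * roll_series(values, lags[j])
  attr(out, "weights") <- w
  out
}
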