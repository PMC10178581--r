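#' Centered moving average with edge-replication padding
#'
#' Smooths each channel of a sequence with an odd-width sliding mean. The
#' series is padded by replicating its first and last rows `(kernel - 1)/2`
#' times at each end, so the output keeps the input length. This is the
#' trend extractor of the series-decomposition block.
#'
#' @param x Numeric vector (one channel) or L x d matrix (d channels).
#' @param kernel Odd window width, `1 <= kernel <= 2L - 1`.
#' @return Same shape as `x`: the windowed means.
#' @examples
#' moving_average(c(1, 2, 3, 4, 5), 3)
#' @export
moving_average <- function(x, kernel) {
  vec <- is.null(dim(x))
  m <- if (vec) matrix(as.numeric(x), ncol = 1) else as.matrix(x)
  L <- nrow(m)
  if (!is_count(kernel)) stopf("kernel must be a positive integer")
  if (kernel %% 2 == 0) stopf("kernel must be odd (a centered window), got %d", kernel)
  if (kernel > 2 * L - 1) stopf("kernel %d exceeds 2L - 1 = %d", kernel, 2 * L - 1)
  if (kernel == 1) return(x)
  p <- (kernel - 1L) / 2L
  padded <- rbind(m[rep(1L, p), , drop = FALSE], m,
                  m[rep(L, p), , drop = FALSE])
  # windowed mean via cumulative sums, one pass per channel
  cs <- apply(padded, 2, cumsum)
  cs <- rbind(0, cs)
  out <- (cs[(kernel + 1L):(L + kernel), , drop = FALSE] -
            cs[1:L, , drop = FALSE]) / kernel
  if (vec) as.numeric(out) else out
}

#' Series decomposition into trend and seasonal parts
#'
#' Splits a sequence additively: the trend-cyclical part is the padded
#' moving average; the seasonal part is the residual. Reconstruction
#' `seasonal + trend == x` is exact by construction. Channels are
#' decomposed independently.
#'
#' @inheritParams moving_average
#' @return List with components `seasonal` and `trend`, each shaped like `x`.
#' @examples
#' d <- series_decomp(sin(1:48 / 3) + 0.1 * (1:48), kernel = 9)
#' range(d$seasonal + d$trend - (sin(1:48 / 3) + 0.1 * (1:48)))
#' @export
series_decomp <- function(x, kernel) {
  trend <- moving_average(x, kernel)
  list(seasonal = x - trend, trend = trend)
}
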