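# Independent brute-force oracles, deliberately written as literal loops so
# they share no code path with the implementation they check.

bf_circular_correlation <- function(q, k) {
  L <- length(q)
  sapply(0:(L - 1), function(tau) {
    acc <- 0
    for (t in seq_len(L)) acc <- acc + q[t] * k[((t - 1 + tau) %% L) + 1]
    acc
  })
}

bf_metrics <- function(pred, true) {
  n <- length(pred)
  mae <- 0; mse <- 0; mape <- 0; smape <- 0
  for (i in seq_len(n)) {
    e <- pred[i] - true[i]
    mae <- mae + abs(e) / n
    mse <- mse + e^2 / n
    mape <- mape + abs(e / true[i]) / n
    smape <- smape + abs(e) / ((abs(pred[i]) + abs(true[i])) / 2) / n
  }
  list(mae = mae, mse = mse, rmse = sqrt(mse), mape = mape, smape = smape)
}

bf_silhouette <- function(points, assign) {
  n <- nrow(points)
  euclid <- function(a, b) sqrt(sum((a - b)^2))
  total <- 0
  for (i in seq_len(n)) {
    own <- which(assign == assign[i] & seq_len(n) != i)
    a <- if (length(own) == 0) 0 else
      mean(sapply(own, function(j) euclid(points[i, ], points[j, ])))
    b <- Inf
    for (g in setdiff(unique(assign), assign[i])) {
      mem <- which(assign == g)
      b <- min(b, mean(sapply(mem, function(j)
        euclid(points[i, ], points[j, ]))))
    }
    s <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
    total <- total + s / n
  }
  total
}

bf_davies_bouldin <- function(points, assign, centers) {
  k <- nrow(centers)
  euclid <- function(a, b) sqrt(sum((a - b)^2))
  s <- sapply(seq_len(k), function(j) {
    mem <- which(assign == j)
    if (length(mem) == 0) 0 else
      mean(sapply(mem, function(i) euclid(points[i, ], centers[j, ])))
  })
  total <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) if (j != i)
      worst <- max(worst, (s[i] + s[j]) / euclid(centers[i, ], centers[j, ]))
    total <- total + worst / k
  }
  total
}

# Central finite-difference gradient of a scalar-valued function of one
# parameter matrix entry.
fd_grad <- function(f, params, nm, i, h = 1e-6) {
  up <- params; up[[nm]][i] <- up[[nm]][i] + h
  dn <- params; dn[[nm]][i] <- dn[[nm]][i] - h
  (f(up) - f(dn)) / (2 * h)
}
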