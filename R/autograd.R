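# Minimal reverse-mode autodiff on matrices.
#
# A tape records nodes in creation order (which is a topological order of the
# forward graph); ag_backward walks it in reverse, each node's `backward`
# closure accumulating gradients into its parents. Values and gradients are
# plain numeric matrices. Only the handful of operations the forecasters need
# are implemented; every backward rule is checked against central finite
# differences in the test suite.

ag_tape <- function() {
  e <- new.env(parent = emptyenv())
  e$nodes <- vector("list", 256L)
  e$n <- 0L
  e
}

ag_node <- function(tape, value, backward = NULL) {
  nd <- new.env(parent = emptyenv())
  nd$value <- value
  nd$grad <- NULL
  nd$backward <- backward
  tape$n <- tape$n + 1L
  if (tape$n > length(tape$nodes))
    tape$nodes <- c(tape$nodes, vector("list", length(tape$nodes)))
  tape$nodes[[tape$n]] <- nd
  nd
}

ag_accum <- function(p, g) {
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

# Leaf holding a parameter or input; name is used to harvest gradients.
ag_leaf <- function(tape, value, name = NULL) {
  nd <- ag_node(tape, value)
  nd$name <- name
  nd
}

ag_const <- function(tape, value) ag_node(tape, value)

ag_backward <- function(tape, loss) {
  loss$grad <- 1
  for (i in seq.int(tape$n, 1L)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$grad) && !is.null(nd$backward)) nd$backward(nd$grad)
  }
  invisible(NULL)
}

ag_add <- function(tape, a, b) {
  ag_node(tape, a$value + b$value, function(g) { ag_accum(a, g); ag_accum(b, g) })
}

ag_sub <- function(tape, a, b) {
  ag_node(tape, a$value - b$value, function(g) { ag_accum(a, g); ag_accum(b, -g) })
}

# y = X + 1 %o% bias  (bias is a length-d vector broadcast over rows)
ag_add_bias <- function(tape, a, b) {
  ag_node(tape, sweep(a$value, 2, as.numeric(b$value), "+"),
          function(g) {
            ag_accum(a, g)
            ag_accum(b, matrix(colSums(g), nrow = 1))
          })
}

ag_matmul <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ag_node(tape, av %*% bv, function(g) {
    ag_accum(a, g %*% t(bv))
    ag_accum(b, t(av) %*% g)
  })
}

ag_hadamard <- function(tape, a, b) {
  av <- a$value; bv <- b$value
  ag_node(tape, av * bv, function(g) {
    ag_accum(a, g * bv)
    ag_accum(b, g * av)
  })
}

ag_scale <- function(tape, a, s) {
  ag_node(tape, a$value * s, function(g) ag_accum(a, g * s))
}

ag_relu <- function(tape, a) {
  mask <- a$value > 0
  ag_node(tape, a$value * mask, function(g) ag_accum(a, g * mask))
}

ag_tanh <- function(tape, a) {
  y <- tanh(a$value)
  ag_node(tape, y, function(g) ag_accum(a, g * (1 - y^2)))
}

ag_sigmoid <- function(tape, a) {
  y <- 1 / (1 + exp(-a$value))
  ag_node(tape, y, function(g) ag_accum(a, g * y * (1 - y)))
}

# y = M %*% a for a constant matrix M (used for the moving-average operator)
ag_linmap <- function(tape, M, a) {
  ag_node(tape, M %*% a$value, function(g) ag_accum(a, t(M) %*% g))
}

ag_rows <- function(tape, a, idx) {
  nr <- nrow(a$value)
  ag_node(tape, a$value[idx, , drop = FALSE], function(g) {
    full <- matrix(0, nr, ncol(a$value))
    full[idx, ] <- full[idx, ] + g
    ag_accum(a, full)
  })
}

ag_cols <- function(tape, a, idx) {
  nc <- ncol(a$value)
  ag_node(tape, a$value[, idx, drop = FALSE], function(g) {
    full <- matrix(0, nrow(a$value), nc)
    full[, idx] <- full[, idx] + g
    ag_accum(a, full)
  })
}

# Inverted dropout with an externally drawn mask (caller owns the RNG).
ag_dropout <- function(tape, a, p) {
  if (p <= 0) return(a)
  mask <- (matrix(stats::runif(length(a$value)), nrow(a$value)) >= p) / (1 - p)
  ag_node(tape, a$value * mask, function(g) ag_accum(a, g * mask))
}

ag_vcat <- function(tape, a, b) {
  na <- nrow(a$value)
  ag_node(tape, rbind(a$value, b$value), function(g) {
    ag_accum(a, g[seq_len(na), , drop = FALSE])
    ag_accum(b, g[-seq_len(na), , drop = FALSE])
  })
}

ag_transpose <- function(tape, a) {
  ag_node(tape, t(a$value), function(g) ag_accum(a, t(g)))
}

# Truncate rows (keep the first L) or zero-pad rows at the end.
ag_resample <- function(tape, a, L) {
  n <- nrow(a$value)
  if (n == L) return(a)
  if (n > L) return(ag_rows(tape, a, seq_len(L)))
  nc <- ncol(a$value)
  ag_node(tape, rbind(a$value, matrix(0, L - n, nc)), function(g)
    ag_accum(a, g[seq_len(n), , drop = FALSE]))
}

# Row-wise softmax (used by the Transformer baseline's attention)
ag_softmax_rows <- function(tape, a) {
  v <- a$value
  y <- exp(v - apply(v, 1, max))
  y <- y / rowSums(y)
  ag_node(tape, y, function(g) {
    dot <- rowSums(g * y)
    ag_accum(a, (g - dot) * y)
  })
}

# Circular roll along rows; linear, so the adjoint is the inverse roll.
ag_roll <- function(tape, a, tau) {
  ag_node(tape, roll_series(a$value, tau), function(g)
    ag_accum(a, roll_series(g, -tau)))
}

# Auto-correlation scores over all lags, averaged over channels.
# Bilinear in (q, k):  R(tau) = mean_c sum_t q[t,c] k[(t+tau) mod L, c] / d.
# Forward uses the FFT path; backward distributes only through the lags that
# received gradient (the selected ones).
ag_autocorr_scores <- function(tape, q, k) {
  qv <- q$value; kv <- k$value
  L <- nrow(qv); d <- ncol(qv)
  sc <- autocorr_scores(qv, kv)
  ag_node(tape, matrix(sc, nrow = 1), function(g) {
    g <- as.numeric(g)
    hot <- which(g != 0)
    gq <- matrix(0, L, d); gk <- matrix(0, L, d)
    for (i in hot) {
      tau <- i - 1L
      gq <- gq + g[i] * roll_series(kv, tau) / d
      gk <- gk + g[i] * roll_series(qv, -tau) / d
    }
    ag_accum(q, gq)
    ag_accum(k, gk)
  })
}

# Weighted sum of rolled copies: out = sum_j w[j] * Roll(v, lags[j]);
# w is a 1 x k node (softmaxed scores), lags a constant integer vector.
ag_delay_agg <- function(tape, v, w, lags) {
  vv <- v$value
  wv <- as.numeric(w$value)
  out <- 0
  for (j in seq_along(lags)) out <- out + wv[j] * roll_series(vv, lags[j])
  ag_node(tape, out, function(g) {
    gv <- 0
    gw <- numeric(length(lags))
    for (j in seq_along(lags)) {
      gv <- gv + wv[j] * roll_series(g, -lags[j])
      gw[j] <- sum(g * roll_series(vv, lags[j]))
    }
    ag_accum(v, gv)
    ag_accum(w, matrix(gw, nrow = 1))
  })
}

# Mean squared error against a constant target; returns a scalar node.
ag_mse <- function(tape, pred, target) {
  diff <- pred$value - target
  n <- length(diff)
  ag_node(tape, sum(diff^2) / n, function(g) ag_accum(pred, g * 2 * diff / n))
}

# Harvest named leaf gradients after backward.
ag_grads <- function(tape) {
  out <- list()
  for (i in seq_len(tape$n)) {
    nd <- tape$nodes[[i]]
    if (!is.null(nd$name)) {
      g <- nd$grad
      if (is.null(g)) g <- matrix(0, nrow(nd$value), ncol(nd$value))
      out[[nd$name]] <- if (is.null(out[[nd$name]])) g else out[[nd$name]] + g
    }
  }
  out
}
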