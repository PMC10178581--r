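# Every backward rule used by the forecasters is validated against central
# finite differences through complete forward passes.

grad_check_forward <- function(kind, n_coords = 3, tol = 5e-5) {
  cfg <- forecaster_config(model_width = 4, feedforward_width = 6,
                           decomp_kernel = 5, context_length = 10,
                           label_length = 5, horizon = 3, seed = 7)
  ds <- split_dataset(build_dataset(
    list(a = kinetic_params(1, 0.05, 0.05, 0.01, noise_sd = 0.02)),
    list(storage_condition(25, 65)), n_days = 40, seed = 2))
  tabs <- storacast:::dataset_series_tables(ds)
  w <- storacast:::collect_windows(tabs, cfg, "train")[[3]]
  ops <- storacast:::forward_ops(cfg)
  backend <- storacast:::forecaster_backends()[[kind]]
  withr::with_seed(1, params <- backend$init(cfg))
  r <- storacast:::window_loss_and_grads(backend, params, w, cfg, ops,
                                         training = TRUE)
  f <- function(pp) storacast:::window_loss_and_grads(backend, pp, w, cfg,
                                                      ops, training = FALSE)$loss
  withr::with_seed(99, {
    for (nm in names(params)) {
      for (trial in seq_len(n_coords)) {
        i <- sample(length(params[[nm]]), 1)
        fd <- fd_grad(f, params, nm, i)
        an <- r$grads[[nm]][i]
        expect_lt(abs(fd - an) / max(1e-4, abs(fd), abs(an)), tol)
      }
    }
  })
}

test_that("autoformer gradients match finite differences", {
  grad_check_forward("autoformer")
})

test_that("lstm gradients match finite differences", {
  grad_check_forward("lstm")
})

test_that("rnn gradients match finite differences", {
  grad_check_forward("rnn")
})

test_that("transformer gradients match finite differences", {
  grad_check_forward("transformer")
})

test_that("elementary tape ops differentiate a composite expression correctly", {
  withr::with_seed(3, {
    A <- matrix(rnorm(12), 4, 3)
    B <- matrix(rnorm(9), 3, 3)
    f <- function(p) {
      tape <- storacast:::ag_tape()
      a <- storacast:::ag_leaf(tape, p$A, "A")
      b <- storacast:::ag_leaf(tape, p$B, "B")
      m <- storacast:::ag_matmul(tape, a, b)
      r <- storacast:::ag_relu(tape, m)
      s <- storacast:::ag_softmax_rows(tape, r)
      t1 <- storacast:::ag_tanh(tape, storacast:::ag_transpose(tape, s))
      h <- storacast:::ag_hadamard(tape, t1, t1)
      loss <- storacast:::ag_mse(tape, h, matrix(0.3, 3, 4))
      list(tape = tape, loss = loss)
    }
    p <- list(A = A, B = B)
    g <- f(p)
    storacast:::ag_backward(g$tape, g$loss)
    grads <- storacast:::ag_grads(g$tape)
    for (nm in c("A", "B")) {
      for (i in sample(length(p[[nm]]), 4)) {
        fd <- fd_grad(function(pp) f(pp)$loss$value, p, nm, i)
        expect_equal(grads[[nm]][i], fd, tolerance = 1e-5)
      }
    }
  })
})

test_that("roll, resample and linmap adjoints are exact transposes", {
  withr::with_seed(4, {
    x <- matrix(rnorm(18), 6, 3)
    g <- matrix(rnorm(18), 6, 3)
    tape <- storacast:::ag_tape()
    xn <- storacast:::ag_leaf(tape, x, "x")
    rolled <- storacast:::ag_roll(tape, xn, 2L)
    rolled$grad <- g
    rolled$backward(g)
    # <Roll x, g> == <x, Roll^T g>
    expect_equal(sum(rolled$value * g), sum(x * xn$grad), tolerance = 1e-12)

    M <- storacast:::build_ma_matrix(6, 3)
    tape2 <- storacast:::ag_tape()
    xn2 <- storacast:::ag_leaf(tape2, x, "x")
    mm <- storacast:::ag_linmap(tape2, M, xn2)
    mm$backward(g)
    expect_equal(sum(mm$value * g), sum(x * xn2$grad), tolerance = 1e-12)
  })
})
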