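make_series <- function(conc, pesticide = "dimethoate") {
  structure(list(pesticide = pesticide,
                 condition = storage_condition(25, 65),
                 days = as.integer(seq_along(conc) - 1),
                 concentrations = conc),
            class = "residue_series")
}

test_that("quality index pairs observations with mean next-n forecasts", {
  s <- make_series(rep(2, 4))
  fo <- matrix(2, 4, 3)
  q <- build_quality_index(s, fo, n = 3)
  expect_equal(q$d, rep(2, 4))
  expect_equal(q$dbar, rep(2, 4))

  s5 <- make_series(c(5, 4, 3, 2, 1))
  fo5 <- rbind(c(4.0, 3.0), c(3.2, 2.2), c(2.1, 1.1), c(1.0, 0.6), c(NA, NA))
  q5 <- build_quality_index(s5, fo5, n = 2)
  expect_equal(nrow(q5), 4)
  expect_equal(attr(q5, "n_dropped"), 1)
  expect_equal(q5$dbar, c(3.5, 2.7, 1.6, 0.8))   # hand-averaged pairs
  q1 <- build_quality_index(s5, fo5[, 1, drop = FALSE], n = 1)
  expect_equal(q1$dbar, fo5[1:4, 1])
  expect_error(build_quality_index(s5, fo5, n = 3), "exceeds")
})

test_that("D-squared seeding never re-picks a chosen point and is seed-stable", {
  pts <- rbind(c(0, 0), c(1, 0), c(0, 1), c(5, 5))
  for (seed in 1:50) {
    idx <- attr(kmeanspp_seed(pts, 3, seed = seed), "index")
    expect_equal(anyDuplicated(idx), 0)
  }
  expect_identical(kmeanspp_seed(pts, 3, seed = 9),
                   kmeanspp_seed(pts, 3, seed = 9))
  expect_error(kmeanspp_seed(rbind(c(0, 0), c(0, 0)), 2), "distinct")
})

test_that("conditional second-center frequency follows the D-squared law", {
  # collinear points 0, 1, 100: given c1 = 0, P(next = 100) = 100^2 / (1 + 100^2)
  pts <- matrix(c(0, 1, 100), ncol = 1)
  hits <- 0; tot <- 0
  for (seed in 1:3000) {
    idx <- attr(kmeanspp_seed(pts, 2, seed = seed), "index")
    if (idx[1] == 1) { tot <- tot + 1; hits <- hits + (idx[2] == 3) }
  }
  p <- 100^2 / (1 + 100^2)
  expect_gt(tot, 500)
  expect_lt(abs(hits - tot * p), 3 * sqrt(tot * p * (1 - p)) + 1)
})

test_that("Lloyd iterations converge with non-increasing WCSS", {
  pts <- rbind(c(0, 0), c(0.2, 0), c(10, 10), c(10.2, 10))
  fit <- kmeans_fit(pts, rbind(c(0, 0), c(10, 10)))
  expect_equal(fit$centers[order(fit$centers[, 1]), ],
               rbind(c(0.1, 0), c(10.1, 10)), tolerance = 1e-12)
  expect_equal(sort(fit$sizes), c(2L, 2L))
  expect_true(all(diff(fit$wcss_trace) <= 1e-12))

  exact <- kmeans_fit(pts, pts)   # k = n: zero variance in one iteration
  expect_equal(exact$wcss, 0)
})

test_that("silhouette and Davies-Bouldin match brute-force pairwise computation", {
  withr::with_seed(41, {
    for (rep in 1:5) {
      pts <- matrix(rnorm(2 * sample(10:50, 1)), ncol = 2)
      k <- sample(2:4, 1)
      fit <- kmeanspp(pts, k, seed = rep, n_restarts = 3)
      expect_equal(silhouette_score(pts, fit$assignments),
                   bf_silhouette(pts, fit$assignments), tolerance = 1e-9)
      expect_equal(davies_bouldin(pts, fit$assignments, fit$centers),
                   bf_davies_bouldin(pts, fit$assignments, fit$centers),
                   tolerance = 1e-9)
    }
  })
})

test_that("silhouette agrees with the independent reference implementation", {
  withr::with_seed(42, {
    pts <- matrix(rnorm(60), ncol = 2)
    fit <- kmeanspp(pts, 3, seed = 1)
    ref <- mean(cluster::silhouette(fit$assignments, dist(pts))[, 3])
    expect_equal(silhouette_score(pts, fit$assignments), ref,
                 tolerance = 1e-9)
  })
})

test_that("hand-worked four-point configurations give the expected criteria", {
  # long thin rectangle split along the long axis
  pts <- rbind(c(0, 0), c(10, 0), c(0, 1), c(10, 1))
  assign <- c(1, 2, 1, 2)
  # a(i) = 1 for every point; b(i) = mean(10, sqrt(101)) for every point
  b <- mean(c(10, sqrt(101)))
  expect_equal(silhouette_score(pts, assign), (b - 1) / b, tolerance = 1e-12)
  centers <- rbind(c(0, 0.5), c(10, 0.5))
  # symmetric clusters: s_i = 0.5 each, center distance 10 -> DBI = 2*0.5/10
  expect_equal(davies_bouldin(pts, assign, centers), 0.1, tolerance = 1e-12)

  singles <- rbind(c(0, 0), c(3, 4))
  expect_equal(davies_bouldin(singles, c(1, 2), singles), 0)
  expect_error(davies_bouldin(pts, assign, rbind(c(0, 0), c(0, 0))),
               "coincident")
  expect_error(silhouette_score(pts, rep(1, 4)), "two clusters")

  tight <- rbind(matrix(rnorm(20, 0, 0.01), ncol = 2),
                 matrix(rnorm(20, 50, 0.01), ncol = 2))
  expect_gt(silhouette_score(tight, rep(1:2, each = 10)), 0.9)
})

test_that("select_k recovers planted structure and reports both criteria", {
  blobs <- planted_blobs()
  sel <- select_k(blobs$points, k_range = 2:7, seed = 5, n_restarts = 5)
  expect_equal(sel$chosen_k, 3)
  expect_equal(sel$dbi_k, 3)
  expect_true(sel$agree)
  sel1 <- select_k(blobs$points, k_range = 4, seed = 5, n_restarts = 3)
  expect_equal(sel1$chosen_k, 4)
  again <- select_k(blobs$points, k_range = 2:7, seed = 5, n_restarts = 5)
  expect_identical(sel$evaluation, again$evaluation)
})

test_that("quality levels order clusters by ascending observed-concentration center", {
  expect_equal(assign_quality_levels(rbind(c(0.1, 0), c(0.3, 0), c(0.2, 0))),
               c(1L, 3L, 2L))
  expect_equal(assign_quality_levels(matrix(c(0.5, 0.5), 1, 2)), 1L)
  # tie on the first coordinate broken by the second
  expect_equal(assign_quality_levels(rbind(c(0.2, 0.9), c(0.2, 0.1))),
               c(2L, 1L))
})

test_that("per-pesticide grading conserves sample counts and orders levels by center", {
  blobs <- planted_blobs()
  qt <- data.frame(pesticide = rep(c("a", "b"), each = nrow(blobs$points)),
                   d = rep(blobs$points[, 1], 2),
                   dbar = rep(blobs$points[, 2], 2))
  qr <- quality_report(qt, k_range = 2:5, seed = 3, n_restarts = 5)
  for (pest in c("a", "b")) {
    sub <- qr$report[qr$report$pesticide == pest, ]
    expect_equal(sum(sub$sample_size), nrow(blobs$points))
    expect_equal(sort(sub$quality_level), seq_len(nrow(sub)))
    ord <- order(sub$center_d)
    expect_equal(sub$quality_level[ord], seq_len(nrow(sub)))
  }
  expect_equal(cluster_shares(c(810, 1080, 765)), c(31, 41, 29))
})
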