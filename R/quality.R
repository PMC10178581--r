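#' Two-component storage quality index
#'
#' For each day `i` with a complete forecast window, pairs the observed
#' concentration `d_i` with `dbar_i`, the mean of the model's predictions
#' for the next `n` days. The resulting 2-D points are the feature space in
#' which storage quality is clustered and graded.
#'
#' @param observed A `residue_series`.
#' @param forecasts Numeric matrix of per-day horizon predictions: row `i`
#'   holds the forecasts issued at day position `i` for the following days;
#'   at least `n` columns. Rows with any `NA` in their first `n` columns are
#'   dropped (and counted).
#' @param n Days averaged into `dbar_i` (>= 1, <= `ncol(forecasts)`).
#' @return Data frame with columns `pesticide`, `day`, `d` (observed,
#'   mg/kg) and `dbar` (mean next-`n`-day prediction, mg/kg); the number of
#'   dropped days is attached as attribute `n_dropped`.
#' @export
build_quality_index <- function(observed, forecasts, n) {
  stopifnot(inherits(observed, "residue_series"))
  forecasts <- as.matrix(forecasts)
  if (!is_count(n)) stopf("n must be a positive integer")
  if (n > ncol(forecasts))
    stopf("n = %d exceeds the forecast horizon (%d columns)", n,
          ncol(forecasts))
  if (nrow(forecasts) != length(observed$days))
    stopf("forecasts must have one row per observed day")
  fo <- forecasts[, seq_len(n), drop = FALSE]
  keep <- !apply(fo, 1, anyNA)
  out <- data.frame(pesticide = observed$pesticide,
                    day = observed$days[keep],
                    d = observed$concentrations[keep],
                    dbar = rowMeans(fo[keep, , drop = FALSE]))
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Roll a fitted forecaster over a dataset to build quality-index tables
#'
#' For every series and every day with a full context behind it, issues a
#' forecast and averages its first `n` steps; days without a full context
#' (the first `context_length - 1` of each series) are dropped and counted.
#'
#' @param model A fitted `residue_forecaster`.
#' @param dataset The split `storage_dataset` the model was trained on.
#' @param n Days averaged into `dbar`; defaults to the model horizon.
#' @return Data frame with columns `pesticide`, `temperature`, `humidity`,
#'   `day`, `d`, `dbar` pooled over all series; dropped-day count in
#'   attribute `n_dropped`.
#' @export
quality_index_table <- function(model, dataset, n = model$config$horizon) {
  config <- model$config
  if (n > config$horizon)
    stopf("n = %d exceeds the model horizon %d", n, config$horizon)
  tabs <- dataset_series_tables(dataset)
  Lc <- config$context_length
  rows <- list()
  dropped <- 0L
  for (tab in tabs) {
    feats <- series_features(tab)
    nd <- length(tab$conc)
    dropped <- dropped + min(Lc - 1L, nd)
    if (nd < Lc) next
    for (i in Lc:nd) {
      w <- make_window_open(tab, feats, i - Lc + 1L, config)
      pred <- forecast_window(model, w)
      rows[[length(rows) + 1L]] <- data.frame(
        pesticide = tab$pesticide, temperature = tab$temperature,
        humidity = tab$humidity, day = tab$days[i],
        d = tab$conc[i], dbar = mean(pred[seq_len(n)]))
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "n_dropped") <- dropped
  out
}

# Window whose horizon may extend past the observed series (no targets).
make_window_open <- function(tab, feats, s, config) {
  Lc <- config$context_length
  ctx_idx <- s:(s + Lc - 1L)
  ctx_feat <- feats[ctx_idx, , drop = FALSE]
  dec <- prepare_decoder_input(ctx_feat[, 1], config)
  L_dec <- config$label_length + config$horizon
  list(key = tab$key, ctx_feat = ctx_feat,
       dec_feat = cbind(dec$seasonal_init,
                        rep(ctx_feat[1, 2], L_dec),
                        rep(ctx_feat[1, 3], L_dec)),
       trend_init = matrix(dec$trend_init, ncol = 1),
       last_obs = tab$conc[s + Lc - 1L], mu = tab$mu, sd = tab$sd)
}

# ---- K-means++ -------------------------------------------------------------

#' K-means++ seeding
#'
#' Chooses `k` initial centers by D-squared sampling: the first center is
#' uniform over the points; each subsequent center is drawn with probability
#' proportional to the squared Euclidean distance to its nearest already
#' chosen center (so points already chosen have probability zero).
#'
#' @param points Numeric matrix, one row per point.
#' @param k Number of centers, at most the number of distinct points.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return `k x ncol(points)` matrix of initial centers, with the chosen
#'   row indices as attribute `index`.
#' @export
kmeanspp_seed <- function(points, k, seed = NULL) {
  points <- as.matrix(points)
  n_distinct <- nrow(unique(points))
  if (!is_count(k) || k > n_distinct)
    stopf("k must be a positive integer <= %d distinct points", n_distinct)
  with_seed(seed, {
    idx <- sample.int(nrow(points), 1L)
    d2 <- rowSums(sweep(points, 2, points[idx, ], "-")^2)
    while (length(idx) < k) {
      nxt <- sample.int(nrow(points), 1L, prob = d2 / sum(d2))
      idx <- c(idx, nxt)
      d2 <- pmin(d2, rowSums(sweep(points, 2, points[nxt, ], "-")^2))
    }
    structure(points[idx, , drop = FALSE], index = idx)
  })
}

nearest_center <- function(points, centers) {
  d2 <- sapply(seq_len(nrow(centers)), function(j)
    rowSums(sweep(points, 2, centers[j, ], "-")^2))
  d2 <- matrix(d2, nrow = nrow(points))
  list(assign = max.col(-d2, ties.method = "first"),
       d2 = d2[cbind(seq_len(nrow(points)), max.col(-d2, ties.method = "first"))])
}

#' Lloyd iterations from given centers
#'
#' Standard K-means refinement: assign each point to its nearest center,
#' recompute centers as cluster means, repeat until the largest center
#' shift falls below `tolerance` or `max_iter` is reached. The within-cluster
#' sum of squares is non-increasing across iterations. A cluster emptied by
#' reassignment is re-seeded with the point farthest from its own center
#' (with a warning).
#'
#' @param points Numeric matrix of observations (rows).
#' @param centers Initial centers, e.g. from [kmeanspp_seed()]; must be
#'   distinct.
#' @param tolerance Convergence threshold on the maximum center shift.
#' @param max_iter Iteration cap.
#' @return An object of class `cluster_model`: list with `k`, `centers`,
#'   `assignments`, `sizes`, `wcss`, `iterations`, `wcss_trace`.
#' @export
kmeans_fit <- function(points, centers, tolerance = 1e-8, max_iter = 100L) {
  points <- as.matrix(points)
  centers <- as.matrix(centers)
  if (anyDuplicated(centers)) stopf("initial centers must be distinct")
  k <- nrow(centers)
  trace <- numeric(0)
  for (it in seq_len(max_iter)) {
    nc <- nearest_center(points, centers)
    trace <- c(trace, sum(nc$d2))
    newc <- centers
    for (j in seq_len(k)) {
      members <- nc$assign == j
      if (!any(members)) {
        far <- which.max(rowSums(sweep(points, 2, centers[j, ], "-")^2))
        warnf("cluster %d emptied; re-seeded at point %d", j, far)
        newc[j, ] <- points[far, ]
      } else {
        newc[j, ] <- colMeans(points[members, , drop = FALSE])
      }
    }
    shift <- max(sqrt(rowSums((newc - centers)^2)))
    centers <- newc
    if (shift < tolerance) break
  }
  nc <- nearest_center(points, centers)
  structure(list(k = k, centers = centers, assignments = nc$assign,
                 sizes = tabulate(nc$assign, k), wcss = sum(nc$d2),
                 iterations = it, wcss_trace = trace,
                 points = points),
            class = "cluster_model")
}

#' Fit K-means++ with restarts
#'
#' Runs [kmeanspp_seed()] + [kmeans_fit()] `n_restarts` times with derived
#' seeds and keeps the fit with the lowest within-cluster sum of squares.
#'
#' @inheritParams kmeanspp_seed
#' @param n_restarts Number of seeded restarts.
#' @param ... Passed to [kmeans_fit()].
#' @return The best `cluster_model`.
#' @export
kmeanspp <- function(points, k, seed = 1L, n_restarts = 10L, ...) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    ini <- kmeanspp_seed(points, k, seed = derive_seed(seed, sprintf("k%d_r%d", k, r)))
    ini <- unique(ini)
    if (nrow(ini) < k) next
    fit <- kmeans_fit(points, ini, ...)
    if (is.null(best) || fit$wcss < best$wcss) best <- fit
  }
  if (is.null(best)) stopf("no restart produced %d distinct initial centers", k)
  best
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> k=%d, sizes=(%s), WCSS=%.6g, %d iterations\n",
              x$k, paste(x$sizes, collapse = ", "), x$wcss, x$iterations))
  invisible(x)
}

#' @export
predict.cluster_model <- function(object, newdata, ...) {
  nearest_center(as.matrix(newdata), object$centers)$assign
}

#' @export
plot.cluster_model <- function(x, ...) {
  pts <- x$points
  if (ncol(pts) < 2) stopf("plotting needs >= 2 dimensions")
  plot(pts[, 1], pts[, 2], col = x$assignments, pch = 16,
       xlab = "observed d (mg/kg)", ylab = "mean next-n-day forecast (mg/kg)",
       ...)
  graphics::points(x$centers[, 1], x$centers[, 2], pch = 8, cex = 2)
  invisible(x)
}

# ---- cluster quality criteria ---------------------------------------------

#' Silhouette coefficient
#'
#' Mean over points of `(b(i) - a(i)) / max(a(i), b(i))`, where `a(i)` is
#' the mean distance to the other members of the point's cluster (0 for a
#' singleton) and `b(i)` the smallest mean distance to the points of any
#' other cluster. Lies in \[-1, 1\]; larger is better.
#'
#' @param points Numeric matrix of observations.
#' @param assignments Integer cluster labels, at least two distinct.
#' @return The silhouette coefficient (scalar).
#' @export
silhouette_score <- function(points, assignments) {
  points <- as.matrix(points)
  cl <- sort(unique(assignments))
  if (length(cl) < 2) stopf("silhouette needs at least two clusters")
  D <- as.matrix(stats::dist(points))
  s <- vapply(seq_len(nrow(points)), function(i) {
    own <- assignments == assignments[i]
    a <- if (sum(own) == 1) 0 else mean(D[i, own & seq_len(nrow(points)) != i])
    b <- min(vapply(setdiff(cl, assignments[i]), function(g)
      mean(D[i, assignments == g]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Davies-Bouldin index
#'
#' With `s_i` the mean distance of cluster `i`'s points to its center and
#' `d_ij` the distance between centers `i` and `j`:
#' `DBI = mean_i max_{j != i} (s_i + s_j) / d_ij`. Non-negative; smaller is
#' better. Coincident centers are an error.
#'
#' @param points Numeric matrix of observations.
#' @param assignments Integer cluster labels (1..k).
#' @param centers `k x d` matrix of cluster centers.
#' @return The Davies-Bouldin index (scalar).
#' @export
davies_bouldin <- function(points, assignments, centers) {
  points <- as.matrix(points)
  centers <- as.matrix(centers)
  k <- nrow(centers)
  if (k < 2) stopf("Davies-Bouldin needs at least two clusters")
  s <- vapply(seq_len(k), function(j) {
    m <- assignments == j
    if (!any(m)) 0 else
      mean(sqrt(rowSums(sweep(points[m, , drop = FALSE], 2, centers[j, ], "-")^2)))
  }, numeric(1))
  dc <- as.matrix(stats::dist(centers))
  ratios <- vapply(seq_len(k), function(i) {
    others <- setdiff(seq_len(k), i)
    dij <- dc[i, others]
    if (any(dij == 0))
      stopf("coincident centers %d and %d", i, others[which(dij == 0)[1]])
    max((s[i] + s[others]) / dij)
  }, numeric(1))
  mean(ratios)
}

#' Choose the cluster count by silhouette and Davies-Bouldin
#'
#' Fits K-means++ (best of `n_restarts` seeded restarts by WCSS) for each
#' candidate `k`, tabulates both criteria and selects `k` by silhouette
#' maximum (ties to the smaller `k`); the Davies-Bouldin minimizer is
#' reported alongside, and a disagreement between the two criteria is noted
#' in the result rather than silently resolved.
#'
#' @param points Numeric matrix of observations.
#' @param k_range Candidate cluster counts.
#' @param seed Integer seed for the restart schedule.
#' @param n_restarts Restarts per `k`.
#' @return An object of class `cluster_selection`: list with `evaluation`
#'   (data frame `k`, `silhouette`, `davies_bouldin`, `wcss`), `chosen_k`,
#'   `dbi_k`, `agree`, and `models` (fitted `cluster_model` per `k`).
#' @export
select_k <- function(points, k_range = 2:7, seed = 1L, n_restarts = 10L) {
  points <- as.matrix(points)
  n_distinct <- nrow(unique(points))
  if (any(k_range > n_distinct))
    stopf("k_range exceeds the %d distinct points", n_distinct)
  models <- list()
  rows <- list()
  for (k in k_range) {
    fit <- kmeanspp(points, k, seed = seed, n_restarts = n_restarts)
    models[[as.character(k)]] <- fit
    rows[[as.character(k)]] <- data.frame(
      k = k,
      silhouette = if (k >= 2) silhouette_score(points, fit$assignments) else NA,
      davies_bouldin = if (k >= 2)
        davies_bouldin(points, fit$assignments, fit$centers) else NA,
      wcss = fit$wcss)
  }
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  chosen <- ev$k[which.max(ev$silhouette)]
  dbi_k <- ev$k[which.min(ev$davies_bouldin)]
  structure(list(evaluation = ev, chosen_k = chosen, dbi_k = dbi_k,
                 agree = chosen == dbi_k, models = models),
            class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  print(x$evaluation, row.names = FALSE)
  cat(sprintf("chosen k = %d by silhouette; Davies-Bouldin minimum at k = %d%s\n",
              x$chosen_k, x$dbi_k,
              if (x$agree) " (criteria agree)" else " (criteria disagree)"))
  invisible(x)
}

#' Order clusters into quality levels
#'
#' Sorts clusters by ascending first center coordinate (the observed
#' concentration), ties broken by the second coordinate; Level 1 - the
#' lowest residue concentration - is the best storage quality.
#'
#' @param model A fitted `cluster_model` (or a bare matrix of centers).
#' @return Integer vector: `levels[j]` is the quality level of cluster `j`.
#' @examples
#' assign_quality_levels(rbind(c(0.1, 0), c(0.3, 0), c(0.2, 0)))
#' @export
assign_quality_levels <- function(model) {
  centers <- if (inherits(model, "cluster_model")) model$centers
  else as.matrix(model)
  ord <- order(centers[, 1],
               if (ncol(centers) > 1) centers[, 2] else seq_len(nrow(centers)))
  levels <- integer(nrow(centers))
  levels[ord] <- seq_len(nrow(centers))
  levels
}

#' Percentage share of each cluster
#'
#' @param sizes Integer cluster sample sizes.
#' @return Rounded percentage per cluster (integers summing to ~100).
#' @export
cluster_shares <- function(sizes) {
  if (any(sizes < 0)) stopf("sizes must be non-negative")
  round(100 * sizes / sum(sizes))
}

#' Per-pesticide quality grading report
#'
#' Clusters each pesticide's quality-index table separately (the per-
#' pesticide tables may share days but are graded independently), selects
#' `k` per pesticide via [select_k()], and emits a flat report of centers,
#' sample sizes and ordered quality levels.
#'
#' @param qtable Pooled quality-index table (from [quality_index_table()] or
#'   rows of [build_quality_index()] stacked), with columns `pesticide`,
#'   `d`, `dbar`.
#' @param k_range Candidate cluster counts per pesticide.
#' @param seed Seed for the clustering restarts.
#' @param n_restarts Restarts per candidate `k`.
#' @param k Optional fixed cluster count overriding selection.
#' @return List with `report` (data frame `pesticide`, `cluster`,
#'   `center_d`, `center_dbar`, `sample_size`, `quality_level`),
#'   `selection` (per-pesticide `cluster_selection`, `NULL` when `k` fixed)
#'   and `models`.
#' @export
quality_report <- function(qtable, k_range = 2:7, seed = 1L,
                           n_restarts = 10L, k = NULL) {
  stopifnot(all(c("pesticide", "d", "dbar") %in% names(qtable)))
  report <- list()
  selection <- list()
  models <- list()
  for (pest in unique(qtable$pesticide)) {
    pts <- as.matrix(qtable[qtable$pesticide == pest, c("d", "dbar")])
    if (is.null(k)) {
      sel <- select_k(pts, k_range = k_range, seed = seed,
                      n_restarts = n_restarts)
      selection[[pest]] <- sel
      fit <- sel$models[[as.character(sel$chosen_k)]]
    } else {
      fit <- kmeanspp(pts, k, seed = seed, n_restarts = n_restarts)
    }
    lev <- assign_quality_levels(fit)
    models[[pest]] <- fit
    report[[pest]] <- data.frame(pesticide = pest, cluster = seq_len(fit$k),
                                 center_d = fit$centers[, 1],
                                 center_dbar = fit$centers[, 2],
                                 sample_size = fit$sizes,
                                 quality_level = lev)
  }
  out <- do.call(rbind, report)
  rownames(out) <- NULL
  list(report = out, selection = if (length(selection)) selection else NULL,
       models = models)
}
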