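# K-means++ clustering of normalized single-cell features, elbow-rule model
# selection, mapping of clusters to differentiation states from their
# temporal drift, and per-timepoint proportion tables.

#' K-means++ seeding
#'
#' D-squared weighting: the first centroid is drawn uniformly from the data;
#' each subsequent centroid is drawn with probability proportional to the
#' squared distance to the nearest centroid already chosen, so points far
#' from the current centroids are preferred and duplicate picks are
#' impossible while distinct points remain.
#'
#' @param points numeric matrix (rows = cells, cols = features).
#' @param k number of centroids; must not exceed the number of distinct
#'   points.
#' @param seed integer seed.
#' @return k x d matrix of initial centroids (rows of `points`).
#' @export
kmeanspp_seed <- function(points, k, seed) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (k > nrow(unique(points))) {
    stop("k exceeds the number of distinct points")
  }
  set.seed(as.integer(seed))
  idx <- integer(k)
  idx[1L] <- sample.int(n, 1L)
  if (k > 1L) {
    d2 <- rowSums((points - rep(points[idx[1L], ], each = n))^2)
    for (j in 2:k) {
      if (sum(d2) <= 0) stop("k exceeds the number of distinct points")
      idx[j] <- sample.int(n, 1L, prob = d2)
      d2 <- pmin(d2, rowSums((points - rep(points[idx[j], ], each = n))^2))
    }
  }
  points[idx, , drop = FALSE]
}

# Squared Euclidean distances from every point to every centroid.
#' @keywords internal
dist2_to_centroids <- function(points, centroids) {
  pp <- rowSums(points^2)
  cc <- rowSums(centroids^2)
  outer(pp, cc, "+") - 2 * points %*% t(centroids)
}

# One Lloyd descent from given starting centroids.
#' @keywords internal
lloyd <- function(points, centroids, tol, max_iter) {
  k <- nrow(centroids)
  n <- nrow(points)
  for (it in seq_len(max_iter)) {
    d2 <- dist2_to_centroids(points, centroids)
    assign <- max.col(-d2, ties.method = "first")
    new_c <- centroids
    for (j in seq_len(k)) {
      members <- assign == j
      if (!any(members)) {
        # empty cluster: re-seed at the point farthest from its centroid
        far <- which.max(d2[cbind(seq_len(n), assign)])
        new_c[j, ] <- points[far, ]
        assign[far] <- j
      } else {
        new_c[j, ] <- colMeans(points[members, , drop = FALSE])
      }
    }
    shift <- max(sqrt(rowSums((new_c - centroids)^2)))
    centroids <- new_c
    if (shift < tol) break
  }
  d2 <- dist2_to_centroids(points, centroids)
  assign <- max.col(-d2, ties.method = "first")
  wcss <- sum(d2[cbind(seq_len(n), assign)])
  list(centroids = centroids, assignments = assign, wcss = wcss, iter = it)
}

#' Fit K-means with K-means++ seeding
#'
#' Runs `n_restarts` independent K-means++ seedings followed by Lloyd
#' iterations (squared Euclidean distance; ties broken towards the lowest
#' cluster index; an emptied cluster is re-seeded at the farthest point) and
#' returns the solution with the lowest within-cluster sum of squares.
#' Deterministic given `seed`. Optional `warm_start` centroids are evaluated
#' as an extra candidate.
#'
#' @param points numeric matrix or data frame of features.
#' @param k number of clusters.
#' @param seed integer seed.
#' @param n_restarts number of seeded restarts (default 10).
#' @param tol convergence threshold on the maximum centroid shift.
#' @param max_iter Lloyd iteration cap.
#' @param warm_start optional centroid matrix used as an extra start.
#' @return object of class `kmeans_model`: `k`, `centroids`, `assignments`,
#'   `wcss`, `seed`, `iter`.
#' @export
fit_kmeans <- function(points, k, seed, n_restarts = 10L, tol = 1e-6,
                       max_iter = 300L, warm_start = NULL) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  best <- NULL
  n <- nrow(points)
  if (n <= 12L && choose(n, k) <= 64L) {
    # tiny input: D^2 sampling adds nothing -- seed from every k-subset
    for (sub in utils::combn(n, k, simplify = FALSE)) {
      sol <- lloyd(points, points[sub, , drop = FALSE], tol, max_iter)
      if (is.null(best) || sol$wcss < best$wcss) best <- sol
    }
  }
  for (r in seq_len(n_restarts)) {
    init <- kmeanspp_seed(points, k, seed = (as.integer(seed) + r) %% .Machine$integer.max)
    sol <- lloyd(points, init, tol, max_iter)
    if (is.null(best) || sol$wcss < best$wcss) best <- sol
  }
  if (!is.null(warm_start) && nrow(warm_start) == k) {
    sol <- lloyd(points, as.matrix(warm_start), tol, max_iter)
    if (sol$wcss < best$wcss) best <- sol
  }
  structure(list(k = as.integer(k), centroids = best$centroids,
                 assignments = best$assignments, wcss = best$wcss,
                 seed = as.integer(seed), iter = best$iter),
            class = "kmeans_model")
}

#' @export
print.kmeans_model <- function(x, ...) {
  cat(sprintf("<kmeans_model> k = %d, n = %d, wcss = %.6g (seed %d)\n",
              x$k, length(x$assignments), x$wcss, x$seed))
  invisible(x)
}

#' Elbow-rule selection of the cluster number
#'
#' Computes the within-cluster sum of squares over `k_range` (best of
#' restarts per k, warm-started from the previous k's solution plus its
#' farthest point so the curve is non-increasing) and selects the knee of
#' the WCSS curve: the interior k with the maximum vertical distance below
#' the chord joining the curve's endpoints. This chord criterion locates
#' the point where the marginal gain of another cluster collapses and,
#' unlike the raw second difference (whose first entry is dominated by the
#' always-large 1-to-2 drop when clusters are arranged along one axis),
#' is stable for elongated cluster layouts. When the knee is weak -- its
#' distance below the chord is less than 40 percent of the total WCSS drop
#' over `k_range` -- the curve is effectively smooth (no strong elbow) and
#' `flat` is set.
#'
#' @param points numeric matrix of normalized features.
#' @param k_range inclusive integer range of candidate k (>= 3 values).
#' @param seed integer seed.
#' @param ... passed to [fit_kmeans()].
#' @return object of class `elbow_result`: `k_range`, `wcss_curve`,
#'   `k_selected`, `flat`, `chord_distance`, `models` (the fitted model
#'   per k).
#' @export
elbow_select <- function(points, k_range = 1:8, seed, ...) {
  points <- as.matrix(points)
  k_range <- sort(unique(as.integer(k_range)))
  if (length(k_range) < 3L) {
    stop("k_range must contain at least 3 values (second difference undefined)")
  }
  if (max(k_range) > nrow(points) - 1L) {
    stop("k_range must stay below the number of points")
  }
  wcss <- numeric(length(k_range))
  models <- vector("list", length(k_range))
  prev <- NULL
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    warm <- NULL
    if (!is.null(prev)) {
      d2 <- dist2_to_centroids(points, prev$centroids)
      far <- which.max(apply(d2, 1L, min))
      warm <- rbind(prev$centroids, points[far, ])
    }
    m <- fit_kmeans(points, k, seed = seed, warm_start = warm, ...)
    wcss[i] <- m$wcss
    models[[i]] <- m
    prev <- m
  }
  nk <- length(k_range)
  chord <- wcss[1L] + (wcss[nk] - wcss[1L]) *
    (k_range - k_range[1L]) / (k_range[nk] - k_range[1L])
  dist <- chord - wcss           # vertical distance below the chord
  interior <- 2:(nk - 1L)
  sel <- interior[which.max(dist[interior])]
  # knee prominence: how far the knee stands proud of the chord, relative
  # to the total WCSS drop; smooth single-mode curves stay below ~0.3
  prominence <- max(dist[interior]) / (wcss[1L] - wcss[nk])
  flat <- !is.finite(prominence) || prominence < 0.4
  structure(list(k_range = k_range, wcss_curve = wcss,
                 k_selected = k_range[sel], flat = flat,
                 chord_distance = dist, models = models),
            class = "elbow_result")
}

#' @export
print.elbow_result <- function(x, ...) {
  cat(sprintf("<elbow_result> k selected = %d over k in [%d, %d]%s\n",
              x$k_selected, min(x$k_range), max(x$k_range),
              if (x$flat) " (flat curve: weak elbow)" else ""))
  cat("wcss:", format(signif(x$wcss_curve, 5)), "\n")
  invisible(x)
}

#' Cluster a normalized feature table
#'
#' Convenience wrapper that refuses unnormalized input (the schema flag set
#' by [normalize_features()] or [apply_normalization()]), optionally selects
#' k by the elbow rule, and fits the final K-means++ model on the feature
#' columns.
#'
#' @param x normalized feature table.
#' @param k integer, or `"auto"` for elbow-rule selection.
#' @param seed integer seed.
#' @param k_range candidate range for `k = "auto"`.
#' @param feature_cols feature columns; defaults to the normalization's.
#' @param ... passed to [fit_kmeans()].
#' @return list with `model` (`kmeans_model`) and `elbow`
#'   (`elbow_result` or NULL when k was fixed).
#' @export
cluster_cells <- function(x, k = "auto", seed, k_range = 1:8,
                          feature_cols = NULL, ...) {
  if (!isTRUE(attr(x, "normalized"))) {
    stop("feature table is not normalized; run normalize_features() first")
  }
  if (is.null(feature_cols)) feature_cols <- attr(x, "feature_cols")
  pts <- as.matrix(x[feature_cols])
  elbow <- NULL
  if (identical(k, "auto")) {
    elbow <- elbow_select(pts, k_range = k_range, seed = seed, ...)
    k <- elbow$k_selected
  }
  model <- fit_kmeans(pts, k = k, seed = seed, ...)
  list(model = model, elbow = elbow)
}

#' Map clusters to differentiation states from their temporal drift
#'
#' With k = 3 and at least two distinct days, the cluster whose occupancy
#' fraction decreases most from the earliest to the latest day is labelled
#' `undiff`, the one that increases most `diff`, and the remaining cluster
#' `differentiating` -- the same temporal pattern used to interpret the
#' clusters in induction experiments. A mixture with no clear drift (tie)
#' raises an ambiguity error.
#'
#' @param model a `kmeans_model` with `k = 3`.
#' @param days day label per cell (same order as the model's assignments).
#' @return named character vector: state per cluster index (1..3).
#' @export
assign_states <- function(model, days) {
  if (model$k != 3L) {
    stop("state assignment requires k = 3, got k = ", model$k)
  }
  days <- as.numeric(days)
  if (length(days) != length(model$assignments)) {
    stop("days must label every clustered cell")
  }
  ud <- sort(unique(days))
  if (length(ud) < 2L) stop("need at least 2 distinct days")
  frac_at <- function(d) {
    a <- model$assignments[days == d]
    tabulate(a, nbins = 3L) / length(a)
  }
  drift <- frac_at(ud[length(ud)]) - frac_at(ud[1L])
  lo <- which(drift == min(drift))
  hi <- which(drift == max(drift))
  if (length(lo) > 1L || length(hi) > 1L || min(drift) >= 0 || max(drift) <= 0) {
    stop("ambiguous temporal drift: cannot map clusters to states")
  }
  states <- rep("differentiating", 3L)
  states[lo] <- "undiff"
  states[hi] <- "diff"
  stats::setNames(states, paste0("cluster", 1:3))
}

#' Per-timepoint cluster proportions across replicate fields
#'
#' For every day and cluster, the mean and SD (across replicate fields) of
#' the per-field fraction of cells in that cluster. Fields with zero cells
#' on a day are excluded with a warning. A single field gives SD 0.
#'
#' @param assignments integer cluster index per cell.
#' @param day,field day and replicate-field label per cell.
#' @param k number of clusters (defaults to the maximum assignment).
#' @return data frame of class `proportion_table` with columns `day`,
#'   `cluster`, `mean_fraction`, `sd_fraction`, `n_fields`.
#' @export
proportion_table <- function(assignments, day, field, k = max(assignments)) {
  stopifnot(length(assignments) == length(day),
            length(assignments) == length(field))
  out <- list()
  for (d in sort(unique(day))) {
    in_day <- day == d
    fl <- unique(field[in_day])
    fr <- matrix(NA_real_, length(fl), k)
    for (i in seq_along(fl)) {
      a <- assignments[in_day & field == fl[i]]
      if (length(a) == 0L) {
        warning("field ", fl[i], " has no cells on day ", d, "; excluded")
        next
      }
      fr[i, ] <- tabulate(a, nbins = k) / length(a)
    }
    fr <- fr[stats::complete.cases(fr), , drop = FALSE]
    for (j in seq_len(k)) {
      sdj <- if (nrow(fr) > 1L) stats::sd(fr[, j]) else 0
      out[[length(out) + 1L]] <- data.frame(
        day = d, cluster = j,
        mean_fraction = mean(fr[, j]), sd_fraction = sdj,
        n_fields = nrow(fr))
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("proportion_table", class(res))
  res
}

#' Combined fraction of a cluster subset per timepoint
#'
#' Mean and SD across fields of the per-field summed fraction of the given
#' clusters -- e.g. differentiating + differentiated, the quantity compared
#' against the fraction of ALP-stained cells.
#'
#' @inheritParams proportion_table
#' @param clusters integer cluster indices to sum.
#' @return data frame with `day`, `mean_fraction`, `sd_fraction`, `n_fields`.
#' @export
combined_proportion <- function(assignments, day, field, clusters) {
  out <- list()
  for (d in sort(unique(day))) {
    in_day <- day == d
    fl <- unique(field[in_day])
    fr <- rep(NA_real_, length(fl))
    for (i in seq_along(fl)) {
      a <- assignments[in_day & field == fl[i]]
      if (length(a) == 0L) next
      fr[i] <- mean(a %in% clusters)
    }
    fr <- fr[!is.na(fr)]
    out[[length(out) + 1L]] <- data.frame(
      day = d, mean_fraction = mean(fr),
      sd_fraction = if (length(fr) > 1L) stats::sd(fr) else 0,
      n_fields = length(fr))
  }
  do.call(rbind, out)
}
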