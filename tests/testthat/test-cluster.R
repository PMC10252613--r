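# K-means++ clustering, elbow selection, state mapping, proportions.

# Exhaustive-partition optimum for small n: enumerate every assignment of n
# points to k non-empty groups and minimize the within-cluster SS directly.
brute_force_wcss <- function(points, k) {
  n <- nrow(points)
  best <- Inf
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  for (i in seq_len(nrow(grid))) {
    a <- as.integer(grid[i, ])
    if (length(unique(a)) < k) next
    w <- 0
    for (j in seq_len(k)) {
      m <- points[a == j, , drop = FALSE]
      w <- w + sum(sweep(m, 2, colMeans(m))^2)
    }
    best <- min(best, w)
  }
  best
}

test_that("seeding with k = n returns a permutation of the points", {
  pts <- matrix(c(0, 3, 7, 12, 20, 1), ncol = 2)
  seeds <- kmeanspp_seed(pts, 3, seed = 1)
  expect_equal(dim(seeds), c(3L, 2L))
  expect_equal(nrow(unique(rbind(pts, seeds))), 3L)
})

test_that("with two points the second seed is always the other point", {
  pts <- matrix(c(0, 10), ncol = 1)
  for (s in 1:25) {
    seeds <- sort(kmeanspp_seed(pts, 2, seed = s)[, 1])
    expect_equal(seeds, c(0, 10))
  }
})

test_that("D-squared seeding hits all three well-separated blobs nearly always", {
  pts <- make_blob_points(n_per = 20, centres = c(0, 2, 4), sd = 0.05, seed = 2)
  hit <- 0L
  for (s in 1:1000) {
    seeds <- kmeanspp_seed(pts, 3, seed = s)
    blob <- round(seeds[, 1] / 2)
    if (length(unique(blob)) == 3L) hit <- hit + 1L
  }
  expect_gte(hit / 1000, 0.95)
})

test_that("k exceeding the number of distinct points is rejected", {
  pts <- matrix(c(0, 0, 1, 1), ncol = 1)
  expect_error(kmeanspp_seed(pts, 3, seed = 1), "distinct")
})

test_that("the two-pair line instance has the known optimum", {
  pts <- matrix(c(0, 1, 9, 10), ncol = 1)
  m <- fit_kmeans(pts, 2, seed = 3)
  expect_equal(sort(m$centroids[, 1]), c(0.5, 9.5))
  expect_equal(m$wcss, 1.0, tolerance = 1e-9)
})

test_that("k = 1 reduces to the mean and total sum of squares", {
  set.seed(4)
  pts <- matrix(rnorm(40), ncol = 2)
  m <- fit_kmeans(pts, 1, seed = 4)
  expect_equal(as.numeric(m$centroids), colMeans(pts), tolerance = 1e-9)
  expect_equal(m$wcss, sum(sweep(pts, 2, colMeans(pts))^2), tolerance = 1e-9)
})

test_that("fitted WCSS equals the exhaustive-partition optimum for tiny n", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(4:8, 1)
    pts <- matrix(runif(n * 2), ncol = 2)
    m <- fit_kmeans(pts, 2, seed = i)
    expect_equal(m$wcss, brute_force_wcss(pts, 2), tolerance = 1e-9)
  }
})

test_that("model invariants hold: nearest-centroid assignment and exact WCSS", {
  pts <- make_blob_points(n_per = 30, seed = 6)
  m <- fit_kmeans(pts, 3, seed = 6)
  d2 <- matrix(0, nrow(pts), 3)
  for (j in 1:3) d2[, j] <- rowSums(sweep(pts, 2, m$centroids[j, ])^2)
  expect_equal(m$assignments, max.col(-d2, ties.method = "first"))
  expect_equal(m$wcss, sum(d2[cbind(seq_len(nrow(pts)), m$assignments)]),
               tolerance = 1e-9)
  expect_identical(fit_kmeans(pts, 3, seed = 6), m)  # determinism
})

test_that("shuffling rows only relabels the partition", {
  pts <- make_blob_points(n_per = 25, seed = 7)
  m1 <- fit_kmeans(pts, 3, seed = 7)
  perm <- sample(nrow(pts))
  m2 <- fit_kmeans(pts[perm, ], 3, seed = 8)
  expect_equal(m2$wcss, m1$wcss, tolerance = 1e-9)
  # same partition up to cluster relabelling
  tab <- table(m1$assignments[perm], m2$assignments)
  expect_equal(sum(tab > 0), 3L)
})

test_that("the elbow rule selects k = 3 for three separated blobs", {
  pts <- make_blob_points(n_per = 50, centres = c(0, 2, 4), sd = 0.05, seed = 9)
  e <- elbow_select(pts, 1:8, seed = 9)
  expect_equal(e$k_selected, 3L)
  expect_false(e$flat)
  expect_true(all(diff(e$wcss_curve) <= 1e-9))
})

test_that("a single Gaussian cloud is flagged as having no strong elbow", {
  set.seed(10)
  pts <- matrix(rnorm(900), ncol = 3)
  e <- elbow_select(pts, 1:8, seed = 10)
  expect_true(e$flat)
})

test_that("elbow selection needs at least three candidate k", {
  pts <- make_blob_points(n_per = 10, seed = 11)
  expect_error(elbow_select(pts, 2:3, seed = 11), "at least 3")
})

test_that("clusters map to states by temporal drift, recovering the truth", {
  ft <- synth_feature_table(120, modality = "FLIM_A2", seed = 12)
  nf <- normalize_features(ft)
  cl <- cluster_cells(nf$table, k = 3, seed = 12)
  mp <- assign_states(cl$model, nf$table$day)
  pred <- unname(mp[cl$model$assignments])
  expect_gte(mean(pred == ft$state), 0.9)
})

test_that("state mapping is invariant to cluster relabelling", {
  ft <- synth_feature_table(100, modality = "FLIM_A2", seed = 13)
  nf <- normalize_features(ft)
  cl <- cluster_cells(nf$table, k = 3, seed = 13)
  mp <- assign_states(cl$model, nf$table$day)
  perm <- c(3L, 1L, 2L)
  m2 <- cl$model
  m2$assignments <- perm[cl$model$assignments]
  m2$centroids <- cl$model$centroids[order(perm), ]
  mp2 <- assign_states(m2, nf$table$day)
  expect_equal(unname(mp2[perm]), unname(mp))
})

test_that("a drift-free symmetric mixture is an ambiguity error", {
  model <- structure(list(k = 3L,
                          assignments = rep(1:3, times = 20),
                          centroids = diag(3), wcss = 0, seed = 1L),
                     class = "kmeans_model")
  days <- rep(c(1, 28), each = 30)
  expect_error(assign_states(model, days), "ambiguous")
  expect_error(assign_states(model, rep(1, 60)), "distinct days")
})

test_that("state mapping requires k = 3", {
  model <- structure(list(k = 2L, assignments = rep(1:2, 20)),
                     class = "kmeans_model")
  expect_error(assign_states(model, rep(c(1, 28), 20)), "k = 3")
})

test_that("proportion table means and SDs follow the per-field fractions", {
  # one field, all cells in cluster 1
  p1 <- proportion_table(rep(1L, 10), day = rep(1, 10), field = rep(1, 10), k = 2)
  expect_equal(p1$mean_fraction[p1$cluster == 1], 1.0)
  expect_equal(p1$sd_fraction[p1$cluster == 1], 0)
  # two fields with fractions 0.4 and 0.6 in cluster 1
  a <- c(rep(1L, 4), rep(2L, 6), rep(1L, 6), rep(2L, 4))
  p2 <- proportion_table(a, day = rep(1, 20), field = rep(1:2, each = 10), k = 2)
  expect_equal(p2$mean_fraction[p2$cluster == 1], 0.5)
  expect_equal(p2$sd_fraction[p2$cluster == 1], sd(c(0.4, 0.6)), tolerance = 1e-9)
  # fractions sum to one per day
  sums <- tapply(p2$mean_fraction, p2$day, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
})

test_that("combined cluster fractions sum the per-field shares", {
  a <- c(rep(1L, 4), rep(2L, 3), rep(3L, 3))
  cp <- combined_proportion(a, day = rep(1, 10), field = rep(1, 10), clusters = 2:3)
  expect_equal(cp$mean_fraction, 0.6)
})

test_that("clustering refuses an unnormalized feature table", {
  ft <- synth_feature_table(50, modality = "FLIM_A2", seed = 14)
  expect_error(cluster_cells(ft, k = 3, seed = 14), "not normalized")
})
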