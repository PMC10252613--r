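# Synthetic field and decay generator.

mix_all_undiff <- timepoint_mixture(1, c(undiff = 1, differentiating = 0, diff = 0))

test_that("single-cell field has exactly one ground-truth record of the right state", {
  f <- generate_field(128, 128, 1, mix_all_undiff, modality = "FLIM_A2", seed = 0)
  expect_equal(nrow(f$ground_truth$cells), 1L)
  expect_equal(f$ground_truth$cells$state, "undiff")
})

test_that("same seed reproduces images and ground truth bit-identically", {
  a <- generate_field(256, 256, 12, default_timepoint_mixtures()[[2]],
                      modality = "SRS", seed = 123)
  b <- generate_field(256, 256, 12, default_timepoint_mixtures()[[2]],
                      modality = "SRS", seed = 123)
  expect_identical(a, b)
  cc <- generate_field(256, 256, 12, default_timepoint_mixtures()[[2]],
                       modality = "SRS", seed = 124)
  expect_false(identical(a$pixels, cc$pixels))
})

test_that("per-cell a2 peaks follow the state distribution (Monte Carlo)", {
  f <- generate_field(640, 640, 50, mix_all_undiff, modality = "FLIM_A2",
                      seed = 7, spacing_factor = 1.1)
  peaks <- f$ground_truth$cells$a2_peak
  se <- 0.020 / sqrt(length(peaks))
  expect_lt(abs(mean(peaks) - 0.19), 3 * se)
})

test_that("realized state counts match the mixture to within rounding", {
  mx <- timepoint_mixture(7, c(undiff = 0.5, differentiating = 0.3, diff = 0.2))
  f <- generate_field(640, 640, 41, mx, seed = 9, spacing_factor = 1.0)
  tab <- table(f$ground_truth$cells$state)
  expect_true(all(abs(tab[c("undiff", "differentiating", "diff")] -
                        41 * c(0.5, 0.3, 0.2)) < 1))
  expect_equal(sum(tab), 41L)
})

test_that("geometry invariants hold: polygons in bounds, nuclei inside cells and disjoint", {
  f <- generate_field(512, 512, 30, default_timepoint_mixtures()[[3]],
                      seed = 21, spacing_factor = 1.0)
  polys <- f$ground_truth$polygons
  for (p in polys) {
    expect_true(all(p$cell[, 1] >= 0 & p$cell[, 1] <= 511))
    expect_true(all(p$cell[, 2] >= 0 & p$cell[, 2] <= 511))
    # every nucleus vertex inside its cell polygon
    expect_true(all(stemstate:::points_in_polygon(p$nucleus[, 1], p$nucleus[, 2], p$cell)))
  }
  # nuclei pairwise disjoint: no vertex of one inside another
  for (i in seq_along(polys)) {
    for (j in seq_along(polys)) {
      if (i == j) next
      expect_false(any(stemstate:::points_in_polygon(
        polys[[i]]$nucleus[, 1], polys[[i]]$nucleus[, 2], polys[[j]]$nucleus)))
    }
  }
})

test_that("raising droplet load raises expected per-cell SRS intensity", {
  lo <- default_state_configs()
  hi <- default_state_configs()
  hi$undiff$droplet_count_mean <- 12
  f_lo <- generate_field(512, 512, 20, mix_all_undiff, state_configs = lo,
                         modality = "SRS", seed = 5, spacing_factor = 1.0)
  f_hi <- generate_field(512, 512, 20, mix_all_undiff, state_configs = hi,
                         modality = "SRS", seed = 5, spacing_factor = 1.0)
  expect_gt(mean(f_hi$ground_truth$cells$mean_srs),
            mean(f_lo$ground_truth$cells$mean_srs))
})

test_that("placement failure raises an explicit error", {
  expect_error(
    generate_field(128, 128, 60, mix_all_undiff, seed = 1,
                   spacing_factor = 1.5, max_tries = 50),
    "placement failed")
})

test_that("decay counts are a multinomial draw conserving the photon number", {
  d <- generate_decay(0.8, 0.4, 0.2, 2.5, n_photons = 54321, seed = 2)
  expect_equal(sum(d$counts), 54321L)
  expect_true(all(d$counts >= 0))
  expect_equal(length(d$counts), d$n_bins)
})

test_that("pure short-lifetime decay has the truncated-exponential mean", {
  tau <- 0.4; tmax <- 12.5; nb <- 256L
  d <- generate_decay(1, tau, 0, tau, n_photons = 2e5, n_bins = nb,
                      t_max_ns = tmax, seed = 3)
  centers <- (d$bin_edges_ns[-1] + d$bin_edges_ns[-(nb + 1)]) / 2
  emp_mean <- sum(centers * d$counts) / sum(d$counts)
  # closed-form mean of the truncated exponential
  m <- tau - tmax * exp(-tmax / tau) / (1 - exp(-tmax / tau))
  w <- tmax / nb
  se <- tau / sqrt(sum(d$counts))
  expect_lt(abs(emp_mean - m), w / 2 + 4 * se)
})

test_that("equal lifetimes are indistinguishable from a mono-exponential", {
  d <- generate_decay(0.5, 1.0, 0.5, 1.0, n_photons = 1e5, seed = 4)
  nb <- d$n_bins
  e <- d$bin_edges_ns
  p <- (exp(-e[-(nb + 1)] / 1.0) - exp(-e[-1] / 1.0)) / (1 - exp(-e[nb + 1] / 1.0))
  keep <- p * 1e5 >= 5  # chi-square validity
  gof <- suppressWarnings(
    stats::chisq.test(c(d$counts[keep], sum(d$counts[!keep])),
                      p = c(p[keep], sum(p[!keep]))))
  expect_gt(gof$p.value, 0.01)
})

test_that("decay generator validates its inputs", {
  expect_error(generate_decay(0.7, 0.4, 0.2, 2.5, 1e4), "equal 1")
  expect_error(generate_decay(0.8, -0.4, 0.2, 2.5, 1e4), "positive")
  expect_error(generate_decay(0.8, 2.5, 0.2, 0.4, 1e4), "exceed")
  expect_error(generate_decay(0.8, 0.4, 0.2, 2.5, 10), "1000")
})

test_that("feature tables follow the requested mixtures", {
  ft <- synth_feature_table(60, modality = "FLIM_A2", seed = 31)
  expect_equal(nrow(ft), 60 * 5)
  expect_setequal(unique(ft$day), c(1, 7, 14, 21, 28))
  d28 <- ft[ft$day == 28, ]
  expect_equal(sum(d28$state == "diff"), 42L)  # 0.70 * 60
  expect_true(all(ft$a2_peak >= 0 & ft$a2_peak <= 1))
  expect_identical(ft, synth_feature_table(60, modality = "FLIM_A2", seed = 31))
})
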