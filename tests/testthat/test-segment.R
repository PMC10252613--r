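# Sliding-window segmentation.

test_that("window matrix covers a degenerate size distribution with one entry", {
  sizes <- matrix(rep(c(100, 60), each = 10), ncol = 2)
  wsm <- estimate_window_matrix(sizes)
  expect_equal(nrow(wsm), 1L)
  expect_gte(wsm[1, 1], 100)
  expect_gte(wsm[1, 2], 60)
})

test_that("bimodal sizes give at least two window entries, sorted by area", {
  sizes <- rbind(matrix(rep(c(40, 40), each = 20), ncol = 2),
                 matrix(rep(c(120, 100), each = 20), ncol = 2))
  wsm <- estimate_window_matrix(sizes)
  expect_gte(nrow(wsm), 2L)
  areas <- as.numeric(wsm[, 1]) * as.numeric(wsm[, 2])
  expect_true(all(diff(areas) >= 0))
  expect_true(all(wsm >= 32))
})

test_that("window matrix requires at least 5 measurements", {
  expect_error(estimate_window_matrix(matrix(c(50, 50, 60, 60), 2, 2)), "at least 5")
})

test_that("sliding a 50x50 window over a 100x100 field yields 11 x 11 positions", {
  wsm <- structure(cbind(height = 50L, width = 50L), class = "window_matrix")
  w <- slide_windows(c(100L, 100L), wsm)
  expect_equal(nrow(w), 121L)
  expect_setequal(unique(w$top), seq(0, 50, by = 5))
})

test_that("a window equal to the field gives exactly one placement", {
  wsm <- structure(cbind(height = 64L, width = 64L), class = "window_matrix")
  w <- slide_windows(c(64L, 64L), wsm)
  expect_equal(nrow(w), 1L)
  expect_equal(c(w$top, w$left), c(0L, 0L))
})

test_that("the union of windows covers every pixel (border clamping)", {
  wsm <- structure(cbind(height = 30L, width = 30L), class = "window_matrix")
  w <- slide_windows(c(97L, 83L), wsm)
  covered <- matrix(FALSE, 97, 83)
  for (i in seq_len(nrow(w))) {
    covered[(w$top[i] + 1):(w$top[i] + 30), (w$left[i] + 1):(w$left[i] + 30)] <- TRUE
  }
  expect_true(all(covered))
})

test_that("oversized windows are skipped with a warning", {
  wsm <- structure(cbind(height = c(40L, 200L), width = c(40L, 200L)),
                   class = "window_matrix")
  expect_warning(w <- slide_windows(c(100L, 100L), wsm), "skipped")
  expect_true(all(w$height == 40L))
})

test_that("a centred synthetic cell with a round nucleus is accepted", {
  crop <- make_cell_crop(offset = c(0, 0), seed = 3)
  d <- screen_crop(crop)
  expect_true(d$accepted)
  expect_true(is.na(d$rejection_reason))
  expect_gte(d$nucleus$circularity, 0.7)
})

test_that("a blank crop is rejected as no_contour", {
  set.seed(4)
  crop <- matrix(pmax(0, rnorm(81 * 81, 0, 0.004)), 81, 81)
  d <- screen_crop(crop)
  expect_false(d$accepted)
  expect_equal(d$rejection_reason, "no_contour")
})

test_that("a nucleus far from the crop centre is rejected as off_center", {
  # r_max = 0.15 * diag(81x81) ~ 17 px; nucleus centre offset ~20 px,
  # still fully inside the cell so the hole stays interior
  crop <- make_cell_crop(n = 81L, cell_r = 32L, offset = c(14, 14), seed = 5)
  d <- screen_crop(crop)
  expect_false(d$accepted)
  expect_equal(d$rejection_reason, "off_center")
})

test_that("screening is translation-equivariant in field coordinates", {
  set.seed(6)
  canvas <- matrix(pmax(0, rnorm(160 * 160, 0, 0.004)), 160, 160)
  ctr <- 80.5
  di <- outer(seq_len(160) - ctr, rep(1, 160))
  dj <- outer(rep(1, 160), seq_len(160) - ctr)
  cell <- di^2 + dj^2 <= 25^2
  canvas[cell] <- pmax(0, rnorm(sum(cell), 0.25, 0.03))
  nuc <- di^2 + dj^2 <= 7^2
  canvas[nuc] <- abs(rnorm(sum(nuc), 0, 0.003))
  d1 <- screen_crop(canvas[40:120, 40:120], offset = c(39, 39))
  d2 <- screen_crop(canvas[44:124, 36:116], offset = c(43, 35))
  expect_true(d1$accepted && d2$accepted)
  expect_equal(d1$nucleus_centroid_field, d2$nucleus_centroid_field,
               tolerance = 1e-8)
})

test_that("lowering the circularity threshold never reduces raw acceptances", {
  f <- generate_field(448, 448, 20, default_timepoint_mixtures()[[2]],
                      seed = 31, spacing_factor = 1.1)
  counts <- sapply(c(0.9, 0.7, 0.5), function(cm) {
    segment_field(f, params = segment_params(c_min = cm))$n_accepted_raw
  })
  expect_true(all(diff(counts) >= 0))
})

test_that("duplicate detections collapse to one; disjoint ones survive", {
  mk_det <- function(pixels, bbox, off) {
    list(accepted = TRUE, centroid_offset_px = off,
         nucleus_pixels_field = pixels, nucleus_bbox = bbox)
  }
  d1 <- mk_det(1001:1100, c(0, 99, 5, 5), off = 1.0)
  d2 <- mk_det(1001:1100, c(0, 99, 5, 5), off = 2.0)
  kept <- deduplicate(list(d2, d1))
  expect_length(kept, 1L)
  expect_equal(kept[[1]]$centroid_offset_px, 1.0)  # best-centred one wins
  d3 <- mk_det(50001:50100, c(0, 99, 250, 250), off = 3.0)
  expect_length(deduplicate(list(d1, d3)), 2L)
  # partial overlap above the IoU threshold is still a duplicate
  d4 <- mk_det(1051:1150, c(0, 99, 5, 6), off = 4.0)
  expect_length(deduplicate(list(d1, d4), iou_max = 0.3), 1L)
})

test_that("well-separated cells are recovered with high recall and precision", {
  for (s in 1:2) {
    f <- generate_field(640, 640, 50, default_timepoint_mixtures()[[s]],
                        seed = 60 + s, spacing_factor = 1.15)
    seg <- segment_field(f)
    ev <- evaluate_detections(seg$detections, f)
    expect_gte(ev$recall, 0.9)
    expect_gte(ev$precision, 0.9)
  }
})

test_that("disabling the prescreen changes throughput, not detections", {
  f <- generate_field(384, 384, 10, default_timepoint_mixtures()[[1]],
                      seed = 77, spacing_factor = 1.15)
  a <- segment_field(f, params = segment_params(prescreen = TRUE))
  b <- segment_field(f, params = segment_params(prescreen = FALSE))
  ctr <- function(seg) {
    m <- t(vapply(seg$detections, `[[`, numeric(2), "nucleus_centroid_field"))
    m[order(m[, 1], m[, 2]), , drop = FALSE]
  }
  expect_equal(ctr(a), ctr(b), tolerance = 1e-8)
})
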