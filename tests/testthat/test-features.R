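# Mask construction and feature extraction.

test_that("the mask recovers the rendered cell footprint", {
  # the mask recipe dilates by construction (~2 px margin), so shape
  # fidelity is scored against the footprint expanded by that margin,
  # with a looser bound against the raw polygon
  mx <- timepoint_mixture(14, c(undiff = 0.34, differentiating = 0.33, diff = 0.33))
  f <- generate_field(320, 320, 3, mx, modality = "FLIM_A2", seed = 41,
                      spacing_factor = 1.2)
  gt <- f$ground_truth
  for (i in seq_len(3)) {
    poly <- gt$polygons[[i]]$cell
    r0 <- floor(min(poly[, 1])) - 6; r1 <- ceiling(max(poly[, 1])) + 6
    c0 <- floor(min(poly[, 2])) - 6; c1 <- ceiling(max(poly[, 2])) + 6
    crop <- f$pixels[(r0 + 1):(r1 + 1), (c0 + 1):(c1 + 1)]
    mask <- build_mask(crop)
    # rasterize the true polygon in crop coordinates
    nr <- nrow(crop); nc <- ncol(crop)
    pr <- rep(seq_len(nr) - 1 + r0, nc)
    pc <- rep(seq_len(nc) - 1 + c0, each = nr)
    truth <- matrix(stemstate:::points_in_polygon(pr, pc, poly), nr, nc)
    truth_dil <- stemstate:::dilate_binary(truth * 1, 5L) > 0
    iou_dil <- sum(mask & truth_dil) / sum(mask | truth_dil)
    expect_gte(iou_dil, 0.8)
    iou_raw <- sum(mask & truth) / sum(mask | truth)
    expect_gte(iou_raw, 0.7)
  }
})

test_that("the mask keeps only the largest of two blobs", {
  m <- matrix(0, 80, 80)
  m[10:50, 10:50] <- 0.5   # 41x41 blob
  m[60:70, 60:70] <- 0.5   # 11x11 blob
  mask <- build_mask(m)
  expect_true(all(which(mask) %in% which(row(m) <= 55 & col(m) <= 55)))
  expect_equal(max(stemstate:::label_components(mask * 1L)), 1L)
})

test_that("a uniform crop raises a mask failure", {
  expect_error(build_mask(matrix(3, 40, 40)), "mask failure")
})

test_that("a delta a2 distribution gives its bin centre and minimal FWHM", {
  crop <- matrix(0.30, 40, 40)
  mask <- matrix(TRUE, 40, 40)
  h <- a2_histogram_features(crop, mask, bin_width = 0.01)
  expect_lt(abs(h$a2_peak - 0.30), 0.005 + 1e-12)
  expect_lte(h$a2_fwhm, 0.01 + 1e-12)
})

test_that("a Gaussian a2 distribution has FWHM near 2.355 sigma", {
  set.seed(8)
  v <- rnorm(1e4, 0.2, 0.03)
  crop <- matrix(v, 100, 100)
  h <- a2_histogram_features(crop, matrix(TRUE, 100, 100), bin_width = 0.01)
  expect_lt(abs(h$a2_fwhm - 2.3548 * 0.03) / (2.3548 * 0.03), 0.15)
  expect_lt(abs(h$a2_peak - 0.2), 0.015)
})

test_that("the taller mode of a bimodal distribution wins", {
  set.seed(9)
  v <- c(rnorm(6000, 0.35, 0.01), rnorm(4000, 0.15, 0.01))
  crop <- matrix(v, 100, 100)
  h <- a2_histogram_features(crop, matrix(TRUE, 100, 100), bin_width = 0.01)
  expect_lt(abs(h$a2_peak - 0.35), 0.005 + 1e-12)
})

test_that("too few masked pixels is a feature failure", {
  crop <- matrix(0.3, 10, 10)
  mask <- matrix(FALSE, 10, 10); mask[1:5, 1:5] <- TRUE
  expect_error(a2_histogram_features(crop, mask), "feature failure")
})

test_that("morphology features match analytic shapes", {
  disk <- morphology_features(make_disk(50))
  expect_gte(disk$circularity, 0.95)
  expect_lte(disk$circularity, 1.02)
  expect_equal(disk$area, sum(make_disk(50)))
  sq <- morphology_features(make_square(50))
  expect_lt(abs(sq$circularity - pi / 4), 0.05)
  ln <- morphology_features(make_line(40))
  expect_lt(ln$circularity, sq$circularity)
  expect_lt(ln$circularity, disk$circularity)
})

test_that("mean gray value is the masked average", {
  crop <- matrix(7, 20, 20)
  expect_equal(mean_gray(crop, matrix(TRUE, 20, 20)), 7)
  crop2 <- matrix(c(0, 10), 20, 20)
  expect_equal(mean_gray(crop2, matrix(TRUE, 20, 20)), 5)
  expect_error(mean_gray(crop, matrix(FALSE, 20, 20)), "empty")
})

test_that("measured a2 peaks track the generator's ground truth", {
  mx <- default_timepoint_mixtures()[[3]]
  f <- generate_field(640, 640, 30, mx, modality = "FLIM_A2", seed = 43,
                      spacing_factor = 1.15)
  seg <- segment_field(f)
  gt <- f$ground_truth$cells
  errs <- c()
  for (d in seg$detections) {
    w <- d$window
    crop <- f$pixels[(w["top"] + 1):(w["top"] + w["height"]),
                     (w["left"] + 1):(w["left"] + w["width"])]
    fv <- tryCatch(extract_features(crop, build_mask(crop), "FLIM_A2"),
                   error = function(e) NULL)
    if (is.null(fv)) next
    j <- which.min((gt$centroid_row - d$nucleus_centroid_field[1])^2 +
                     (gt$centroid_col - d$nucleus_centroid_field[2])^2)
    errs <- c(errs, abs(fv$a2_peak - gt$a2_peak[j]))
  }
  expect_gte(length(errs), 25)
  expect_lte(median(errs), 0.02)
})

test_that("segment-module contour and feature-module morphology agree", {
  crop <- make_cell_crop(seed = 10)
  det <- screen_crop(crop)
  expect_true(det$accepted)
  mask <- stemstate:::label_components(
    stemstate:::close_binary(
      stemstate:::binarize(crop, stemstate:::hist_peak_threshold(crop)), 5L), 8L) > 0
  mf <- morphology_features(mask)
  expect_lt(abs(mf$area - det$cell$area) / det$cell$area, 0.02)
  expect_lt(abs(mf$perimeter - det$cell$perimeter) / det$cell$perimeter, 0.02)
})

test_that("min-max normalization scales, warns on constants, and round-trips", {
  x <- data.frame(cell_id = 1:3, a = c(2, 4, 6), b = c(1, 1, 1))
  expect_warning(nf <- normalize_features(x), "constant")
  expect_equal(nf$table$a, c(0, 0.5, 1))
  expect_equal(nf$table$b, c(0, 0, 0))
  expect_true(isTRUE(attr(nf$table, "normalized")))
  back <- denormalize_features(nf$table, nf$params)
  expect_equal(back$a, x$a, tolerance = 1e-9)
  expect_equal(back$b, x$b, tolerance = 1e-9)
  y <- data.frame(a = c(3, 5), b = c(1, 2))
  proj <- apply_normalization(y, nf$params)
  expect_equal(proj$a, c(0.25, 0.75))
})

test_that("normalization rejects degenerate input", {
  expect_error(normalize_features(data.frame(a = 1)), "2 rows")
  expect_error(normalize_features(data.frame(a = c(1, NA))), "missing")
})
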