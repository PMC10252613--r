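# Sliding-window single-cell segmentation for dense adherent monolayers with
# unclear boundaries: crops are screened individually (binarize, close, find
# contours, sort by area, convex hull of the nucleus candidate, circularity
# and centre tests) and overlapping detections resolved by non-maximum
# suppression on nucleus overlap.

#' Segmentation screening parameters
#'
#' @param c_min minimum circularity of the nucleus convex hull (default 0.7).
#' @param r_max_frac maximum distance of the nucleus centroid from the crop
#'   centre, as a fraction of the crop diagonal (default 0.15).
#' @param min_cell_area minimum area (px) of the largest contour for it to
#'   count as a cell.
#' @param min_nucleus_area minimum area (px) of the nucleus candidate.
#' @param closing_size diameter of the elliptical closing element (px).
#' @param hist_bins histogram bins used by the adaptive threshold.
#' @param iou_max nucleus-overlap IoU above which two detections are
#'   considered duplicates.
#' @param prescreen skip windows whose foreground count (from a field-level
#'   binarization) is below `min_cell_area`; a pure speed optimization that
#'   only discards windows that cannot contain a cell.
#' @return list of class `segment_params`.
#' @export
segment_params <- function(c_min = 0.7, r_max_frac = 0.15,
                           min_cell_area = 200L, min_nucleus_area = 30L,
                           closing_size = 5L, hist_bins = 256L,
                           iou_max = 0.3, prescreen = TRUE) {
  stopifnot(c_min > 0, c_min <= 1, r_max_frac > 0, r_max_frac < 1)
  structure(list(c_min = c_min, r_max_frac = r_max_frac,
                 min_cell_area = as.integer(min_cell_area),
                 min_nucleus_area = as.integer(min_nucleus_area),
                 closing_size = as.integer(closing_size),
                 hist_bins = as.integer(hist_bins),
                 iou_max = iou_max, prescreen = isTRUE(prescreen)),
            class = "segment_params")
}

#' Estimate the window-size matrix from measured cell sizes
#'
#' Mimics the manual evaluation of ~50 cell bounding boxes: windows are
#' placed at the 25/50/75/95th percentiles of the observed bounding-box
#' areas (each dimension taken at the same percentile and inflated by
#' `inflate`), deduplicated, and returned sorted ascending by area.
#'
#' @param cell_sizes matrix or data frame with two columns
#'   (height px, width px), one row per measured cell; at least 5 rows.
#' @param probs percentiles of the size distribution to cover.
#' @param inflate multiplicative margin applied to each dimension.
#' @param min_dim minimum window dimension (px).
#' @return integer matrix of class `window_matrix` with columns
#'   `height`, `width`, sorted ascending by area.
#' @export
estimate_window_matrix <- function(cell_sizes, probs = c(0.25, 0.5, 0.75, 0.95),
                                   inflate = 1.2, min_dim = 32L) {
  cell_sizes <- as.matrix(cell_sizes)
  if (nrow(cell_sizes) < 5L) {
    stop("need at least 5 measured cell sizes, got ", nrow(cell_sizes))
  }
  h <- as.numeric(stats::quantile(cell_sizes[, 1L], probs, names = FALSE))
  w <- as.numeric(stats::quantile(cell_sizes[, 2L], probs, names = FALSE))
  hh <- pmax(as.integer(min_dim), as.integer(ceiling(h * inflate)))
  ww <- pmax(as.integer(min_dim), as.integer(ceiling(w * inflate)))
  m <- unique(cbind(height = hh, width = ww))
  m <- m[order(m[, 1L] * as.numeric(m[, 2L])), , drop = FALSE]
  structure(m, class = c("window_matrix", class(m)))
}

#' Enumerate sliding-window positions
#'
#' For each window size (H, W) the step is 10 percent of the window
#' dimension (rounded up) and the final row/column of windows is clamped to
#' the field border, so the union of windows covers every pixel.
#'
#' @param field an `image_field`, or `c(height, width)` of the field.
#' @param wsm a [estimate_window_matrix()] `window_matrix`.
#' @param step_frac step size as a fraction of the window dimension.
#' @return data frame with 0-based `top`, `left` and `height`, `width`;
#'   window sizes larger than the field are skipped with a warning.
#' @export
slide_windows <- function(field, wsm, step_frac = 0.1) {
  dims <- if (inherits(field, "image_field")) c(field$height, field$width) else field
  H <- dims[1L]; W <- dims[2L]
  out <- vector("list", nrow(wsm))
  for (i in seq_len(nrow(wsm))) {
    h <- unname(wsm[i, 1L]); w <- unname(wsm[i, 2L])
    if (h > H || w > W) {
      warning(sprintf("window %dx%d larger than field %dx%d; skipped", h, w, H, W))
      next
    }
    sh <- max(1L, as.integer(ceiling(step_frac * h)))
    sw <- max(1L, as.integer(ceiling(step_frac * w)))
    tops <- unique(c(seq.int(0L, H - h, by = sh), H - h))
    lefts <- unique(c(seq.int(0L, W - w, by = sw), W - w))
    out[[i]] <- data.frame(top = rep(tops, times = length(lefts)),
                           left = rep(lefts, each = length(tops)),
                           height = h, width = w)
  }
  do.call(rbind, out)
}

# Build a Contour record (polygon, area = pixel count, smoothed-trace
# perimeter, pixel centroid) for one labelled component.
#' @keywords internal
contour_record <- function(mask, area, centroid) {
  tr <- trace_contour(mask)
  structure(list(points = tr$points, area = area, perimeter = tr$perimeter,
                 circularity = circularity(area, tr$perimeter),
                 centroid = centroid), class = "cell_contour")
}

#' Screen one crop for a centred single cell
#'
#' Pipeline: adaptive histogram-peak binarization, morphological closing,
#' contour detection (foreground components and interior holes, so the
#' darker nucleus inside a bright cell is found), sort by area descending.
#' The largest contour is taken as the cell, the second largest as the
#' nucleus candidate; the crop is accepted iff the nucleus candidate's
#' centroid lies within `r_max_frac` of the crop diagonal from the crop
#' centre and its convex hull's circularity reaches `c_min`. The cheap
#' centroid test runs first (its failure dominates in sliding windows), so
#' a crop failing both reports `off_center`; contours are only traced for
#' crops that get that far. Rejection is a value (`rejection_reason`), not
#' an error.
#'
#' @param crop 2-D numeric matrix.
#' @param params a [segment_params()] list.
#' @param offset 0-based (top, left) of the crop within its field, used to
#'   report field coordinates.
#' @return object of class `cell_detection` with elements `window`,
#'   `cell` and `nucleus` contours (populated as far as screening got),
#'   `accepted`, `rejection_reason` (one of no_contour, off_center,
#'   low_circularity, duplicate or NA), `centroid_offset_px`, and
#'   field-coordinate nucleus centroid/pixels.
#' @export
screen_crop <- function(crop, params = segment_params(), offset = c(0L, 0L)) {
  nr <- nrow(crop); nc <- ncol(crop)
  det <- structure(list(
    window = c(top = offset[1L], left = offset[2L], height = nr, width = nc),
    cell = NULL, nucleus = NULL, accepted = FALSE,
    rejection_reason = "no_contour",
    centroid_offset_px = NA_real_,
    nucleus_centroid_field = c(NA_real_, NA_real_),
    nucleus_pixels_field = integer()
  ), class = "cell_detection")

  thr <- hist_peak_threshold(crop, n_bins = params$hist_bins)
  if (!is.finite(thr)) return(det)
  bin <- binarize(crop, thr)
  if (sum(bin) < params$min_cell_area) return(det)
  closed <- close_binary(bin, params$closing_size)

  fg <- label_components(closed, 8L)
  holes <- label_components(1 - closed, 4L)
  fg_area <- tabulate(fg[fg > 0])
  h_area <- tabulate(holes[holes > 0])
  if (length(h_area)) {
    # a hole touching the crop border is outside background, not a nucleus
    on_border <- unique(c(holes[1L, ], holes[nr, ], holes[, 1L], holes[, nc]))
    h_area[on_border[on_border > 0]] <- 0L
  }
  cand <- rbind(
    if (length(fg_area)) cbind(type = 1L, id = seq_along(fg_area), area = fg_area),
    if (length(h_area)) cbind(type = 2L, id = seq_along(h_area), area = h_area)
  )
  cand <- cand[cand[, "area"] >= params$min_nucleus_area, , drop = FALSE]
  if (is.null(cand) || nrow(cand) < 2L) return(det)
  cand <- cand[order(-cand[, "area"]), , drop = FALSE]
  if (cand[1L, "area"] < params$min_cell_area) return(det)

  get_mask <- function(k) {
    if (cand[k, "type"] == 1L) fg == cand[k, "id"] else holes == cand[k, "id"]
  }
  nuc_k <- 2L
  if (nrow(cand) > 2L && cand[3L, "area"] == cand[2L, "area"]) {
    # area tie for the nucleus slot: prefer the more circular contour
    circ_of <- function(k) {
      hl <- convex_hull_polygon(trace_contour(get_mask(k))$points)
      circularity(abs(shoelace_area(hl)), polygon_perimeter(hl))
    }
    if (circ_of(3L) > circ_of(2L)) nuc_k <- 3L
  }
  nuc_mask <- get_mask(nuc_k)
  nuc_idx <- which(nuc_mask)
  nuc_centroid <- c(mean((nuc_idx - 1L) %% nr), mean((nuc_idx - 1L) %/% nr))
  centre <- c((nr - 1) / 2, (nc - 1) / 2)
  det$centroid_offset_px <- sqrt(sum((nuc_centroid - centre)^2))
  det$nucleus_centroid_field <- nuc_centroid + offset
  if (det$centroid_offset_px > params$r_max_frac * sqrt(nr^2 + nc^2)) {
    det$rejection_reason <- "off_center"
    return(det)
  }

  nuc_tr <- trace_contour(nuc_mask)
  hull <- convex_hull_polygon(nuc_tr$points)
  hull_area <- abs(shoelace_area(hull))
  hull_per <- polygon_perimeter(hull)
  hull_circ <- circularity(hull_area, hull_per)
  det$nucleus <- structure(list(points = hull, area = hull_area,
                                perimeter = hull_per, circularity = hull_circ,
                                centroid = nuc_centroid), class = "cell_contour")
  if (hull_circ < params$c_min) {
    det$rejection_reason <- "low_circularity"
    return(det)
  }

  cell_idx <- which(get_mask(1L))
  cell_centroid <- c(mean((cell_idx - 1L) %% nr), mean((cell_idx - 1L) %/% nr))
  det$cell <- contour_record(get_mask(1L), unname(cand[1L, "area"]), cell_centroid)
  det$accepted <- TRUE
  det$rejection_reason <- NA_character_
  det$nucleus_pixels_field <- nuc_idx  # crop-local; lifted by segment_field()
  det
}

# Lift crop-local nucleus pixel indices to field linear indices; also
# returns the 0-based field bounding box used to gate overlap tests.
#' @keywords internal
lift_pixels <- function(idx, crop_nrow, offset, field_nrow) {
  r <- ((idx - 1L) %% crop_nrow) + offset[1L]        # 0-based field row
  cc <- ((idx - 1L) %/% crop_nrow) + offset[2L]      # 0-based field col
  list(pixels = cc * field_nrow + r + 1L,
       bbox = c(min(r), max(r), min(cc), max(cc)))
}

#' Remove duplicate detections by non-maximum suppression
#'
#' Overlapping windows detect the same cell many times. Detections are
#' visited in order of increasing nucleus centroid offset (best first); a
#' detection is kept unless its nucleus mask overlaps an already kept
#' nucleus with IoU above `iou_max`, in which case it is marked `duplicate`.
#'
#' @param detections list of accepted `cell_detection`s from one field.
#' @param iou_max overlap threshold (default 0.3).
#' @return list of surviving detections; suppressed ones are dropped.
#' @export
deduplicate <- function(detections, iou_max = 0.3) {
  acc <- Filter(function(d) isTRUE(d$accepted), detections)
  if (length(acc) <= 1L) return(acc)
  ord <- order(vapply(acc, `[[`, numeric(1), "centroid_offset_px"))
  kept <- list()
  kept_px <- list()
  kept_bb <- list()
  for (i in ord) {
    px <- acc[[i]]$nucleus_pixels_field
    bb <- acc[[i]]$nucleus_bbox
    dup <- FALSE
    for (k in seq_along(kept_px)) {
      kb <- kept_bb[[k]]
      if (!is.null(bb) && !is.null(kb) &&
          (bb[1L] > kb[2L] || kb[1L] > bb[2L] ||
           bb[3L] > kb[4L] || kb[3L] > bb[4L])) {
        next  # disjoint bounding boxes cannot overlap
      }
      kp <- kept_px[[k]]
      inter <- length(intersect(px, kp))
      if (inter > 0 && inter / (length(px) + length(kp) - inter) > iou_max) {
        dup <- TRUE
        break
      }
    }
    if (!dup) {
      kept[[length(kept) + 1L]] <- acc[[i]]
      kept_px[[length(kept_px) + 1L]] <- px
      kept_bb[[length(kept_bb) + 1L]] <- bb
    }
  }
  kept
}

#' Segment a whole field
#'
#' Runs [slide_windows()] over the field, screens every crop with
#' [screen_crop()], and resolves duplicates with [deduplicate()].
#'
#' @param field an `image_field`.
#' @param wsm a `window_matrix`; if NULL and the field carries ground truth,
#'   it is estimated from up to 50 ground-truth bounding boxes.
#' @param params a [segment_params()] list.
#' @return list with `detections` (deduplicated accepted detections, nucleus
#'   pixel indices in field coordinates), `n_windows`, `n_accepted_raw`, and
#'   `log` (data frame of per-window outcomes).
#' @export
segment_field <- function(field, wsm = NULL, params = segment_params()) {
  stopifnot(inherits(field, "image_field"))
  if (is.null(wsm)) {
    gt <- field$ground_truth$cells
    if (is.null(gt)) stop("no window matrix given and field has no ground truth")
    n <- min(50L, nrow(gt))
    wsm <- estimate_window_matrix(cbind(gt$bbox_height, gt$bbox_width)[seq_len(n), , drop = FALSE])
  }
  wins <- slide_windows(field, wsm)
  img <- field$pixels
  fnr <- nrow(img)
  screen_mask <- rep(TRUE, nrow(wins))
  reasons <- character(nrow(wins))
  if (params$prescreen) {
    # A window can only be accepted when a nucleus -- an interior hole of
    # the closed binary image -- sits near its centre. Locate all hole
    # centroids once at field level and screen only nearby windows; the
    # others are classified cheaply from the integral image. This changes
    # nothing for fields with dark nuclei and can be disabled via
    # segment_params(prescreen = FALSE).
    fthr <- hist_peak_threshold(img, n_bins = params$hist_bins)
    if (is.finite(fthr)) {
      fbin <- binarize(img, fthr)
      ii <- integral_image(fbin)
      fclosed <- close_binary(fbin, params$closing_size)
      fholes <- label_components(1 - fclosed, 4L)
      ht <- component_table(fholes)
      ht <- ht[!ht$touches_border & ht$area >= params$min_nucleus_area, , drop = FALSE]
      ctr_r <- wins$top + (wins$height - 1) / 2
      ctr_c <- wins$left + (wins$width - 1) / 2
      rmax <- params$r_max_frac * sqrt(wins$height^2 + wins$width^2) + 4
      near_hole <- rep(FALSE, nrow(wins))
      for (j in seq_len(nrow(ht))) {
        near_hole <- near_hole |
          ((ctr_r - ht$centroid_row[j])^2 + (ctr_c - ht$centroid_col[j])^2 <= rmax^2)
      }
      iip <- rbind(0, cbind(0, ii))  # zero-padded for vectorized queries
      r0 <- wins$top + 1L; r1 <- wins$top + wins$height + 1L
      c0 <- wins$left + 1L; c1 <- wins$left + wins$width + 1L
      fg_cnt <- iip[cbind(r1, c1)] - iip[cbind(r0, c1)] -
        iip[cbind(r1, c0)] + iip[cbind(r0, c0)]
      screen_mask <- near_hole & fg_cnt >= params$min_cell_area
      reasons[!screen_mask] <- ifelse(fg_cnt[!screen_mask] < params$min_cell_area,
                                      "no_contour", "off_center")
    }
  }
  dets <- vector("list", nrow(wins))
  for (i in which(screen_mask)) {
    t0 <- wins$top[i]; l0 <- wins$left[i]
    h <- wins$height[i]; w <- wins$width[i]
    crop <- img[(t0 + 1L):(t0 + h), (l0 + 1L):(l0 + w), drop = FALSE]
    d <- screen_crop(crop, params, offset = c(t0, l0))
    if (d$accepted) {
      lifted <- lift_pixels(d$nucleus_pixels_field, h, c(t0, l0), fnr)
      d$nucleus_pixels_field <- lifted$pixels
      d$nucleus_bbox <- lifted$bbox
      dets[[i]] <- d
      reasons[i] <- "accepted"
    } else {
      reasons[i] <- d$rejection_reason
    }
  }
  accepted <- Filter(Negate(is.null), dets)
  survivors <- deduplicate(accepted, params$iou_max)
  list(
    detections = survivors,
    n_windows = nrow(wins),
    n_accepted_raw = length(accepted),
    log = data.frame(wins, outcome = reasons, stringsAsFactors = FALSE)
  )
}

#' Score detections against synthetic ground truth
#'
#' A detection matches a true cell when its nucleus centroid falls inside
#' that cell's true nucleus polygon; each true cell can absorb one detection
#' (greedy, best centroid offset first).
#'
#' @param detections deduplicated detections from [segment_field()].
#' @param field the `image_field` they came from (must carry ground truth).
#' @return list with `recall`, `precision`, `n_true`, `n_detected`,
#'   `n_matched`.
#' @export
evaluate_detections <- function(detections, field) {
  gt <- field$ground_truth
  if (is.null(gt)) stop("field carries no ground truth")
  n_true <- nrow(gt$cells)
  matched <- rep(FALSE, n_true)
  tp <- 0L
  ord <- order(vapply(detections, `[[`, numeric(1), "centroid_offset_px"))
  for (i in ord) {
    ctr <- detections[[i]]$nucleus_centroid_field
    for (j in seq_len(n_true)) {
      if (!matched[j] &&
          points_in_polygon(ctr[1L], ctr[2L], gt$polygons[[j]]$nucleus)) {
        matched[j] <- TRUE
        tp <- tp + 1L
        break
      }
    }
  }
  nd <- length(detections)
  list(recall = if (n_true) tp / n_true else NA_real_,
       precision = if (nd) tp / nd else NA_real_,
       n_true = n_true, n_detected = nd, n_matched = tp)
}
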