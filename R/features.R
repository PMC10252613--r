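# Single-cell mask construction and feature extraction. FLIM cells are
# described by (area, a2 histogram peak, a2 FWHM); SRS cells by (area,
# perimeter, circularity, mean gray value).

#' Build the single-cell mask for a crop
#'
#' The crop is binarized at the grayscale-histogram peak (pixels above the
#' background peak become foreground), dilated with a `dilate_size` square
#' kernel to recover cell pixels lost at binarization, smoothed with a
#' `mean_size` mean filter and re-binarized at 0.5, and finally reduced to
#' its largest connected component. Interior holes (the dark nucleus) are
#' filled: the result is a cell *region* mask. Note the recipe's dilation
#' leaves a margin of roughly `dilate_size/2` pixels of background around
#' the true cell footprint by construction.
#'
#' @param crop 2-D numeric matrix.
#' @param hist_bins histogram bins for the adaptive threshold.
#' @param dilate_size dilation kernel size (px, default 5).
#' @param mean_size mean-filter kernel size (px, default 3).
#' @return logical matrix of class `cell_mask` (exactly one connected
#'   foreground component).
#' @export
build_mask <- function(crop, hist_bins = 256L, dilate_size = 5L, mean_size = 3L) {
  thr <- hist_peak_threshold(crop, n_bins = hist_bins)
  bin <- binarize(crop, thr)
  if (sum(bin) == 0) {
    stop("mask failure: empty foreground after thresholding")
  }
  bin <- dilate_binary(bin, dilate_size)
  bin <- binarize(mean_filter_binary(bin, mean_size), 0.5)
  lab <- label_components(bin)
  if (max(lab) == 0) {
    stop("mask failure: no connected component after filtering")
  }
  areas <- tabulate(lab[lab > 0L])
  mask <- lab == which.max(areas)
  # fill interior holes: background components not touching the border
  bg <- label_components(1 - mask, 4L)
  nr <- nrow(mask); nc <- ncol(mask)
  border_ids <- unique(c(bg[1L, ], bg[nr, ], bg[, 1L], bg[, nc]))
  fill <- bg > 0 & !(bg %in% border_ids)
  mask[fill] <- TRUE
  structure(mask, class = c("cell_mask", class(mask)))
}

#' a2 histogram peak and full width at half maximum
#'
#' Histogram of the masked a2 values with fixed bin width over \[0, 1\]. The
#' peak is the centre of the modal bin; the FWHM is the distance between the
#' two half-maximum crossings of the histogram envelope, located by linear
#' interpolation between bin centres (measured around the global modal bin
#' only). If a crossing is not reached before the histogram edge, that edge
#' is used.
#'
#' Because [build_mask()] dilates the binarized cell (on purpose, to avoid
#' losing interior pixels), the mask carries a margin of near-zero
#' background pixels and the dark nucleus; pixels at or below `a2_floor`
#' are therefore excluded so they cannot form a spurious background mode.
#' Protein-bound fractions of real cells sit far above the default floor.
#'
#' @param crop a2 crop (values in \[0, 1\]; values outside are clipped).
#' @param mask logical mask with at least 50 foreground pixels (after the
#'   floor is applied).
#' @param bin_width histogram bin width (default 0.01, i.e. one percentage
#'   point of a2).
#' @param a2_floor a2 value at or below which masked pixels are treated as
#'   background/nucleus and ignored (default 0.02; 0 disables).
#' @return list with `a2_peak` and `a2_fwhm` (both fractions).
#' @export
a2_histogram_features <- function(crop, mask, bin_width = 0.01, a2_floor = 0.02) {
  v <- crop[mask]
  v <- v[v > a2_floor]
  if (length(v) < 50L) {
    stop("feature failure: fewer than 50 masked pixels (", length(v), ")")
  }
  v <- pmin(1, pmax(0, v))
  brk <- seq(0, 1, by = bin_width)
  if (brk[length(brk)] < 1) brk <- c(brk, 1)
  nb <- length(brk) - 1L
  cnt <- tabulate(findInterval(v, brk, rightmost.closed = TRUE, all.inside = TRUE),
                  nbins = nb)
  ctr <- (brk[-length(brk)] + brk[-1L]) / 2
  m <- which.max(cnt)
  half <- cnt[m] / 2
  cross <- function(i_from, i_to) {
    # walk from the modal bin towards i_to, interpolate the half crossing
    idx <- if (i_from <= i_to) i_from:i_to else i_from:i_to
    prev <- i_from
    for (i in idx[-1L]) {
      if (cnt[i] < half) {
        f <- (cnt[prev] - half) / (cnt[prev] - cnt[i])
        return(ctr[prev] + f * (ctr[i] - ctr[prev]))
      }
      prev <- i
    }
    ctr[i_to]  # edge reached without crossing
  }
  left <- if (m > 1L) cross(m, 1L) else ctr[1L] - bin_width / 2
  right <- if (m < nb) cross(m, nb) else ctr[nb] + bin_width / 2
  list(a2_peak = ctr[m], a2_fwhm = right - left)
}

#' Morphological features of a cell mask
#'
#' Area is the foreground pixel count; the perimeter is the length of the
#' traced outer boundary polygon (marching-squares contour with smoothed
#' vertices, so diagonal steps contribute their Euclidean length);
#' circularity is `4*pi*area / perimeter^2`.
#'
#' @param mask logical or 0/1 matrix with a single foreground component.
#' @return list with `area`, `perimeter`, `circularity`.
#' @export
morphology_features <- function(mask) {
  area <- sum(mask)
  if (area == 0) stop("empty mask")
  tr <- trace_contour(mask)
  list(area = area, perimeter = tr$perimeter,
       circularity = circularity(area, tr$perimeter))
}

#' Mean gray value of the masked cell region
#'
#' Total gray value of the cellular region divided by its pixel count.
#'
#' @param crop intensity crop.
#' @param mask logical mask.
#' @return mean intensity.
#' @export
mean_gray <- function(crop, mask) {
  n <- sum(mask)
  if (n == 0) stop("empty mask")
  sum(crop[mask]) / n
}

#' Extract the modality's feature vector for one cell
#'
#' @param crop the single-cell crop.
#' @param mask its [build_mask()] result.
#' @param modality `"FLIM_A2"` or `"SRS"`.
#' @param bin_width a2 histogram bin width (FLIM only).
#' @return one-row data frame with the modality's features.
#' @export
extract_features <- function(crop, mask, modality = c("FLIM_A2", "SRS"),
                             bin_width = 0.01) {
  modality <- match.arg(modality)
  morph <- morphology_features(mask)
  if (modality == "FLIM_A2") {
    h <- a2_histogram_features(crop, mask, bin_width)
    data.frame(area = morph$area, a2_peak = h$a2_peak, a2_fwhm = h$a2_fwhm)
  } else {
    data.frame(area = morph$area, perimeter = morph$perimeter,
               circularity = morph$circularity,
               mean_gray = mean_gray(crop, mask))
  }
}

#' Min-max normalize feature columns
#'
#' Scales each feature column to \[0, 1\] and records the per-feature min and
#' range so new cells can be projected into the same space. Constant columns
#' are mapped to 0 with a warning. The returned table carries the attribute
#' `normalized = TRUE`, which the clustering stage requires.
#'
#' @param x data frame; at least 2 rows, no missing values in the feature
#'   columns.
#' @param feature_cols columns to scale; defaults to all numeric columns
#'   except identifiers (`cell_id`, `day`, `field`, `cluster`).
#' @return list with `table` (scaled copy of `x`) and `params` (data frame
#'   feature/min/range).
#' @export
normalize_features <- function(x, feature_cols = NULL) {
  if (nrow(x) < 2L) stop("need at least 2 rows to normalize")
  if (is.null(feature_cols)) {
    ids <- c("cell_id", "day", "field", "cluster", "state")
    feature_cols <- setdiff(names(x)[vapply(x, is.numeric, logical(1))], ids)
  }
  if (length(feature_cols) == 0L) stop("no feature columns to normalize")
  if (anyNA(x[feature_cols])) stop("missing values in feature columns")
  mins <- vapply(x[feature_cols], min, numeric(1))
  rngs <- vapply(x[feature_cols], function(v) diff(range(v)), numeric(1))
  if (any(rngs == 0)) {
    warning("constant feature column(s) mapped to 0: ",
            paste(feature_cols[rngs == 0], collapse = ", "))
  }
  for (i in seq_along(feature_cols)) {
    cc <- feature_cols[i]
    x[[cc]] <- if (rngs[i] == 0) rep(0, nrow(x)) else (x[[cc]] - mins[i]) / rngs[i]
  }
  attr(x, "normalized") <- TRUE
  attr(x, "feature_cols") <- feature_cols
  list(table = x,
       params = data.frame(feature = feature_cols, min = unname(mins),
                           range = unname(rngs), stringsAsFactors = FALSE))
}

#' Invert a min-max normalization
#' @param x normalized table (or matrix/data frame of scaled columns).
#' @param params the `params` element returned by [normalize_features()].
#' @return table on the original scale.
#' @export
denormalize_features <- function(x, params) {
  for (i in seq_len(nrow(params))) {
    cc <- params$feature[i]
    if (!cc %in% names(x)) next
    x[[cc]] <- if (params$range[i] == 0) rep(params$min[i], nrow(x))
               else x[[cc]] * params$range[i] + params$min[i]
  }
  attr(x, "normalized") <- NULL
  x
}

#' Project new cells into an existing normalized feature space
#' @inheritParams denormalize_features
#' @export
apply_normalization <- function(x, params) {
  for (i in seq_len(nrow(params))) {
    cc <- params$feature[i]
    if (!cc %in% names(x)) stop("missing feature column: ", cc)
    x[[cc]] <- if (params$range[i] == 0) rep(0, nrow(x))
               else (x[[cc]] - params$min[i]) / params$range[i]
  }
  attr(x, "normalized") <- TRUE
  attr(x, "feature_cols") <- params$feature
  x
}
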