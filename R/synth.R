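# Synthetic microscopy generator: renders FLIM a2 maps and SRS lipid images
# of adherent spindle-shaped cell monolayers with per-cell ground truth, and
# simulates time-binned NAD(P)H photon-arrival histograms.

#' Per-state generator configuration
#'
#' Describes how cells of one differentiation state look in the two imaging
#' modalities: the centre and spread of the per-cell protein-bound NAD(P)H
#' fraction (a2), the within-cell pixel spread of a2 (which sets the
#' histogram FWHM), lipid-droplet load for the SRS channel, and cell
#' geometry (area, elongation).
#'
#' @param state_name one of `"undiff"`, `"differentiating"`, `"diff"`.
#' @param a2_peak_mean mean of the per-cell a2 histogram peak, fraction in (0,1).
#' @param a2_peak_sd cell-to-cell SD of the a2 peak.
#' @param a2_width_mean within-cell SD of pixel a2 values (the rendered a2
#'   histogram has FWHM close to 2.355 times this value).
#' @param droplet_count_mean mean number of lipid droplets per cell (Poisson).
#' @param droplet_intensity_mean added SRS photon rate inside a droplet
#'   (arbitrary counts).
#' @param cell_area_mean,cell_area_sd cell area distribution, px^2.
#' @param eccentricity_range interval in \[0, 1) from which the ellipse
#'   eccentricity is drawn; higher = more spindle-like.
#' @return object of class `state_config`.
#' @seealso [default_state_configs()]
#' @export
state_config <- function(state_name,
                         a2_peak_mean, a2_peak_sd, a2_width_mean,
                         droplet_count_mean, droplet_intensity_mean,
                         cell_area_mean, cell_area_sd,
                         eccentricity_range) {
  state_name <- match.arg(state_name, c("undiff", "differentiating", "diff"))
  stopifnot(
    a2_peak_mean > 0, a2_peak_mean < 1,
    a2_peak_sd >= 0, a2_width_mean >= 0,
    droplet_count_mean >= 0, droplet_intensity_mean >= 0,
    cell_area_mean > 0, cell_area_sd >= 0,
    length(eccentricity_range) == 2L,
    eccentricity_range[1] >= 0, eccentricity_range[2] < 1,
    eccentricity_range[1] <= eccentricity_range[2]
  )
  structure(list(
    state_name = state_name,
    a2_peak_mean = a2_peak_mean, a2_peak_sd = a2_peak_sd,
    a2_width_mean = a2_width_mean,
    droplet_count_mean = droplet_count_mean,
    droplet_intensity_mean = droplet_intensity_mean,
    cell_area_mean = cell_area_mean, cell_area_sd = cell_area_sd,
    eccentricity_range = as.numeric(eccentricity_range)
  ), class = "state_config")
}

#' Default state configurations
#'
#' Defaults encode the differentiation trend reported for MSCs: the a2 peak
#' sits near 19 percent in undifferentiated cells and rises above 30 percent
#' in differentiated ones, the a2 histogram broadens, lipid-droplet load
#' increases steadily during adipogenesis, and cells become larger and
#' rounder as they mature.
#'
#' @return named list of three [state_config()] objects
#'   (`undiff`, `differentiating`, `diff`).
#' @export
default_state_configs <- function() {
  list(
    undiff = state_config("undiff",
      a2_peak_mean = 0.19, a2_peak_sd = 0.020, a2_width_mean = 0.035,
      droplet_count_mean = 1, droplet_intensity_mean = 900,
      cell_area_mean = 1500, cell_area_sd = 250,
      eccentricity_range = c(0.80, 0.95)),
    differentiating = state_config("differentiating",
      a2_peak_mean = 0.25, a2_peak_sd = 0.020, a2_width_mean = 0.050,
      droplet_count_mean = 6, droplet_intensity_mean = 1100,
      cell_area_mean = 2100, cell_area_sd = 300,
      eccentricity_range = c(0.60, 0.85)),
    diff = state_config("diff",
      a2_peak_mean = 0.32, a2_peak_sd = 0.025, a2_width_mean = 0.065,
      droplet_count_mean = 14, droplet_intensity_mean = 1300,
      cell_area_mean = 2700, cell_area_sd = 400,
      eccentricity_range = c(0.30, 0.65))
  )
}

#' State mixture at one induction timepoint
#'
#' @param day integer day label (e.g. 1, 7, 14, 21, 28).
#' @param fractions named numeric vector with entries `undiff`,
#'   `differentiating`, `diff`; must sum to 1 within 1e-9.
#' @return object of class `timepoint_mixture`.
#' @export
timepoint_mixture <- function(day, fractions) {
  stopifnot(length(day) == 1L, is.numeric(fractions))
  need <- c("undiff", "differentiating", "diff")
  if (!all(need %in% names(fractions))) {
    stop("fractions must be named with: ", paste(need, collapse = ", "))
  }
  fractions <- fractions[need]
  if (any(fractions < 0) || any(fractions > 1) || abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must lie in [0,1] and sum to 1")
  }
  structure(list(day = as.integer(day), fractions = fractions),
            class = "timepoint_mixture")
}

#' Default induction time course
#'
#' Five timepoints (Days 1, 7, 14, 21, 28) whose state mixtures drift from
#' mostly undifferentiated to mostly differentiated, the pattern seen across
#' a 28-day adipogenic or osteogenic induction.
#'
#' @return list of five [timepoint_mixture()] objects.
#' @export
default_timepoint_mixtures <- function() {
  mk <- function(day, u, g, d) {
    timepoint_mixture(day, c(undiff = u, differentiating = g, diff = d))
  }
  list(
    mk(1L, 0.80, 0.10, 0.10),
    mk(7L, 0.30, 0.50, 0.20),
    mk(14L, 0.15, 0.55, 0.30),
    mk(21L, 0.10, 0.50, 0.40),
    mk(28L, 0.05, 0.25, 0.70)
  )
}

# Deterministic allocation of n cells to states: floor shares, remainder to
# the largest fractional parts, so realized counts match the mixture to
# within rounding.
#' @keywords internal
allocate_states <- function(n, mixture) {
  fr <- mixture$fractions
  base <- floor(fr * n)
  rem <- n - sum(base)
  if (rem > 0L) {
    extra <- order(fr * n - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1L
  }
  rep(names(fr), times = base)
}

# Radius of a perturbed ellipse in polar direction theta (cell local frame).
#' @keywords internal
cell_radius <- function(theta, a, b, amp, freq, phase) {
  re <- a * b / sqrt((b * cos(theta))^2 + (a * sin(theta))^2)
  re * (1 + amp * sin(freq * theta + phase))
}

# Closed polygon of a perturbed ellipse in field coordinates (0-based row/col).
#' @keywords internal
cell_polygon <- function(row0, col0, a, b, phi, amp, freq, phase, n_vertices = 256L) {
  th <- seq(0, 2 * pi, length.out = n_vertices + 1L)[-(n_vertices + 1L)]
  r <- cell_radius(th, a, b, amp, freq, phase)
  u <- r * cos(th); v <- r * sin(th)
  cbind(row = row0 + u * cos(phi) - v * sin(phi),
        col = col0 + u * sin(phi) + v * cos(phi))
}

# Pixel membership of a perturbed ellipse, restricted to a bounding box.
# Returns linear indices into the field matrix (1-based).
#' @keywords internal
cell_pixels <- function(nr, nc, row0, col0, a, b, phi, amp, freq, phase, scale = 1) {
  rmax <- a * (1 + abs(amp)) * scale + 1
  r_lo <- max(1L, floor(row0 - rmax) + 1L)
  r_hi <- min(nr, ceiling(row0 + rmax) + 1L)
  c_lo <- max(1L, floor(col0 - rmax) + 1L)
  c_hi <- min(nc, ceiling(col0 + rmax) + 1L)
  rr <- (r_lo:r_hi) - 1L
  cc <- (c_lo:c_hi) - 1L
  dr <- outer(rr - row0, rep(1, length(cc)))
  dc <- outer(rep(1, length(rr)), cc - col0)
  u <- dr * cos(phi) + dc * sin(phi)
  v <- -dr * sin(phi) + dc * cos(phi)
  th <- atan2(v, u)
  inside <- (u^2 + v^2) <= (cell_radius(th, a, b, amp, freq, phase) * scale)^2
  idx <- which(inside)
  lr <- ((idx - 1L) %% length(rr)) + 1L
  lc <- ((idx - 1L) %/% length(rr)) + 1L
  (c_lo + lc - 2L) * nr + (r_lo + lr - 1L)
}

#' Generate one synthetic microscopy field with ground truth
#'
#' Renders `n_cells` perturbed-ellipse cells (random orientation, state-driven
#' area and eccentricity, darker near-circular nucleus) on a noisy background.
#' For the FLIM modality pixel values are a2 fractions in \[0, 1\] drawn from a
#' per-cell Gaussian whose centre and spread come from the state config; for
#' SRS a photon-rate map (background, cytoplasm, dark nucleus, bright lipid
#' droplets) is sampled with Poisson shot noise. Cells may touch (boundaries
#' are deliberately unclear at the default spacing) but nuclei never overlap.
#'
#' @param width,height field size in pixels.
#' @param n_cells number of cells to place (>= 1).
#' @param mixture a [timepoint_mixture()]; realized state counts match its
#'   fractions to within rounding.
#' @param state_configs named list of [state_config()]s covering every state
#'   present in the mixture.
#' @param modality `"FLIM_A2"` or `"SRS"`.
#' @param seed integer seed; identical seed and parameters give bit-identical
#'   output.
#' @param spacing_factor minimum centre distance between two cells as a
#'   multiple of the sum of their effective radii; values below 1 let cells
#'   touch, values above ~1.1 keep them separated.
#' @param max_tries placement attempts per cell before giving up.
#' @param noise list of rendering rates: `read_noise_sd` (FLIM background and
#'   a2 read noise), `bg_rate`, `cyto_rate`, `nucleus_rate` (SRS Poisson
#'   rates), `nucleus_sd` (FLIM nucleus darkness spread).
#' @return object of class `image_field`: list with `pixels` (matrix,
#'   `height` x `width`), `modality`, `width`, `height`, `day`, `seed` and
#'   `ground_truth` (list with per-cell data frame `cells` and `polygons`,
#'   a list of cell/nucleus polygons in 0-based row/col coordinates).
#' @export
generate_field <- function(width = 512L, height = 512L, n_cells,
                           mixture,
                           state_configs = default_state_configs(),
                           modality = c("FLIM_A2", "SRS"),
                           seed,
                           spacing_factor = 0.9,
                           max_tries = 2000L,
                           noise = list()) {
  modality <- match.arg(modality)
  stopifnot(n_cells >= 1L, width >= 64L, height >= 64L)
  if (missing(seed)) stop("seed must be set")
  nz <- utils::modifyList(list(read_noise_sd = 0.004, nucleus_sd = 0.003,
                               bg_rate = 10, cyto_rate = 150, nucleus_rate = 2),
                          noise)
  set.seed(as.integer(seed))

  states <- allocate_states(n_cells, mixture)
  states <- states[sample.int(n_cells)]

  # --- sample per-cell geometry and photometry -------------------------------
  cells <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    cfg <- state_configs[[states[i]]]
    if (is.null(cfg)) stop("no state_config for state ", states[i])
    area <- max(200, stats::rnorm(1L, cfg$cell_area_mean, cfg$cell_area_sd))
    ecc <- stats::runif(1L, cfg$eccentricity_range[1], cfg$eccentricity_range[2])
    a <- sqrt(area / (pi * sqrt(1 - ecc^2)))
    b <- area / (pi * a)
    cells[[i]] <- list(
      state = states[i],
      area = area, ecc = ecc, a = a, b = b,
      phi = stats::runif(1L, 0, pi),
      amp = stats::runif(1L, 0.05, 0.12),
      freq = sample(3:6, 1L),
      phase = stats::runif(1L, 0, 2 * pi),
      r_eff = sqrt(area / pi),
      a2_peak = min(0.98, max(0.02, stats::rnorm(1L, cfg$a2_peak_mean, cfg$a2_peak_sd))),
      a2_width = cfg$a2_width_mean * stats::runif(1L, 0.9, 1.1),
      droplet_n = stats::rpois(1L, cfg$droplet_count_mean),
      droplet_int = cfg$droplet_intensity_mean
    )
  }

  # --- placement: rejection sampling on cell centres -------------------------
  centres <- matrix(NA_real_, n_cells, 2L)
  for (i in seq_len(n_cells)) {
    ci <- cells[[i]]
    margin <- ci$a * (1 + ci$amp) + 2
    if (2 * margin >= min(width, height)) {
      stop("cell placement failed: cell larger than field")
    }
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      r0 <- stats::runif(1L, margin, height - 1 - margin)
      c0 <- stats::runif(1L, margin, width - 1 - margin)
      ok <- TRUE
      if (i > 1L) {
        for (j in seq_len(i - 1L)) {
          dj <- sqrt((r0 - centres[j, 1L])^2 + (c0 - centres[j, 2L])^2)
          # hard floor keeps nuclei (0.30 r_eff, offset up to 0.10 r_eff)
          # from ever overlapping even when cytoplasm is allowed to touch
          min_d <- max(spacing_factor * (ci$r_eff + cells[[j]]$r_eff),
                       0.40 * (ci$r_eff + cells[[j]]$r_eff) + 3)
          if (dj < min_d) { ok <- FALSE; break }
        }
      }
      if (ok) { centres[i, ] <- c(r0, c0); placed <- TRUE; break }
    }
    if (!placed) {
      stop("cell placement failed: could not place cell ", i, " after ",
           max_tries, " tries (reduce n_cells or spacing_factor)")
    }
  }

  # --- nucleus geometry: near-circular, small offset from the cell centre ----
  for (i in seq_len(n_cells)) {
    ci <- cells[[i]]
    rn <- 0.30 * ci$r_eff
    off_r <- stats::runif(1L, 0, 0.10 * ci$r_eff)
    off_th <- stats::runif(1L, 0, 2 * pi)
    cells[[i]]$nuc <- list(
      row0 = centres[i, 1L] + off_r * cos(off_th),
      col0 = centres[i, 2L] + off_r * sin(off_th),
      a = rn, b = 0.85 * rn,
      phi = stats::runif(1L, 0, pi)
    )
  }

  # --- render ---------------------------------------------------------------
  nr <- as.integer(height); nc <- as.integer(width)
  cell_px <- vector("list", n_cells)
  nuc_px <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    ci <- cells[[i]]
    cell_px[[i]] <- cell_pixels(nr, nc, centres[i, 1L], centres[i, 2L],
                                ci$a, ci$b, ci$phi, ci$amp, ci$freq, ci$phase)
    nuc_px[[i]] <- cell_pixels(nr, nc, ci$nuc$row0, ci$nuc$col0,
                               ci$nuc$a, ci$nuc$b, ci$nuc$phi, 0, 1, 0)
  }

  if (modality == "FLIM_A2") {
    img <- matrix(pmin(1, pmax(0, stats::rnorm(nr * nc, 0, nz$read_noise_sd))), nr, nc)
    for (i in seq_len(n_cells)) {
      ci <- cells[[i]]
      px <- cell_px[[i]]
      img[px] <- pmin(1, pmax(0, stats::rnorm(length(px), ci$a2_peak, ci$a2_width)))
    }
    for (i in seq_len(n_cells)) {
      px <- nuc_px[[i]]
      img[px] <- abs(stats::rnorm(length(px), 0, nz$nucleus_sd))
    }
  } else {
    lam <- matrix(nz$bg_rate, nr, nc)
    for (i in seq_len(n_cells)) {
      ci <- cells[[i]]
      lam[cell_px[[i]]] <- nz$cyto_rate
      if (ci$droplet_n > 0L) {
        for (d in seq_len(ci$droplet_n)) {
          # droplet centre uniform in the inner 85% of the cell body
          th <- stats::runif(1L, 0, 2 * pi)
          rho <- sqrt(stats::runif(1L)) * 0.85
          rmax <- cell_radius(th, ci$a, ci$b, ci$amp, ci$freq, ci$phase)
          u <- rho * rmax * cos(th); v <- rho * rmax * sin(th)
          dr0 <- centres[i, 1L] + u * cos(ci$phi) - v * sin(ci$phi)
          dc0 <- centres[i, 2L] + u * sin(ci$phi) + v * cos(ci$phi)
          rad <- stats::runif(1L, 2, 3.5)
          dpx <- cell_pixels(nr, nc, dr0, dc0, rad, rad, 0, 0, 1, 0)
          lam[dpx] <- lam[dpx] + ci$droplet_int
        }
      }
    }
    for (i in seq_len(n_cells)) {
      lam[nuc_px[[i]]] <- nz$nucleus_rate
    }
    img <- matrix(pmin(65535, stats::rpois(nr * nc, lam)), nr, nc)
  }

  # --- ground truth ---------------------------------------------------------
  polygons <- vector("list", n_cells)
  mean_srs <- rep(NA_real_, n_cells)
  area_px <- integer(n_cells)
  bbox_h <- integer(n_cells); bbox_w <- integer(n_cells)
  for (i in seq_len(n_cells)) {
    ci <- cells[[i]]
    poly <- cell_polygon(centres[i, 1L], centres[i, 2L],
                         ci$a, ci$b, ci$phi, ci$amp, ci$freq, ci$phase)
    npoly <- cell_polygon(ci$nuc$row0, ci$nuc$col0,
                          ci$nuc$a, ci$nuc$b, ci$nuc$phi, 0, 1, 0, 64L)
    polygons[[i]] <- list(cell = poly, nucleus = npoly)
    area_px[i] <- length(cell_px[[i]])
    bbox_h[i] <- ceiling(diff(range(poly[, 1L]))) + 1L
    bbox_w[i] <- ceiling(diff(range(poly[, 2L]))) + 1L
    if (modality == "SRS") {
      mean_srs[i] <- mean(img[cell_px[[i]]])
    }
  }
  gt_cells <- data.frame(
    cell_id = seq_len(n_cells),
    state = states,
    centroid_row = centres[, 1L],
    centroid_col = centres[, 2L],
    a2_peak = if (modality == "FLIM_A2") vapply(cells, `[[`, numeric(1), "a2_peak") else NA_real_,
    mean_srs = mean_srs,
    area_px = area_px,
    bbox_height = bbox_h,
    bbox_width = bbox_w,
    stringsAsFactors = FALSE
  )

  structure(list(
    pixels = img,
    modality = modality,
    width = nc, height = nr,
    day = mixture$day,
    seed = as.integer(seed),
    ground_truth = list(cells = gt_cells, polygons = polygons)
  ), class = "image_field")
}

#' @export
print.image_field <- function(x, ...) {
  cat(sprintf("<image_field> %s, %d x %d px, day %s, %d cells (seed %d)\n",
              x$modality, x$height, x$width,
              ifelse(is.null(x$day), "NA", x$day),
              nrow(x$ground_truth$cells), x$seed))
  invisible(x)
}

#' Simulate a time-binned NAD(P)H fluorescence decay
#'
#' Photon arrival times follow the bi-exponential density
#' `a1*exp(-t/tau1) + a2*exp(-t/tau2)` truncated to the acquisition window
#' `[0, t_max_ns]`; counts are a single multinomial draw over the uniform
#' time bins, so the total photon number is conserved exactly.
#'
#' @param a1,a2 fractional amplitudes of the free / protein-bound components;
#'   must sum to 1 within 1e-9.
#' @param tau1_ns,tau2_ns component lifetimes in ns, `tau1_ns <= tau2_ns`,
#'   both positive.
#' @param n_photons total photon count (>= 1000 for a usable histogram).
#' @param n_bins number of uniform time bins (>= 16).
#' @param t_max_ns acquisition window length in ns (default 12.5, an 80 MHz
#'   repetition period).
#' @param seed optional integer seed.
#' @return object of class `decay_curve`: list with `bin_edges_ns`,
#'   `counts`, `n_bins`, `t_max_ns`.
#' @export
generate_decay <- function(a1, tau1_ns, a2, tau2_ns, n_photons,
                           n_bins = 256L, t_max_ns = 12.5, seed = NULL) {
  if (abs(a1 + a2 - 1) > 1e-9) stop("a1 + a2 must equal 1")
  if (a1 < 0 || a2 < 0) stop("amplitudes must be non-negative")
  if (tau1_ns <= 0 || tau2_ns <= 0) stop("lifetimes must be positive")
  if (tau1_ns > tau2_ns) stop("tau1_ns must not exceed tau2_ns")
  if (n_photons < 1000) stop("n_photons must be at least 1000")
  if (n_bins < 16L) stop("n_bins must be at least 16")
  if (!is.null(seed)) set.seed(as.integer(seed))
  edges <- seq(0, t_max_ns, length.out = n_bins + 1L)
  p <- a1 * decay_bin_probs(edges, tau1_ns) + a2 * decay_bin_probs(edges, tau2_ns)
  counts <- as.integer(stats::rmultinom(1L, n_photons, p))
  structure(list(bin_edges_ns = edges, counts = counts,
                 n_bins = as.integer(n_bins), t_max_ns = t_max_ns),
            class = "decay_curve")
}

# Probability mass per bin of an exponential lifetime truncated to the
# acquisition window (normalized over [0, t_max]).
#' @keywords internal
decay_bin_probs <- function(edges, tau) {
  tmax <- edges[length(edges)]
  (exp(-edges[-length(edges)] / tau) - exp(-edges[-1L] / tau)) /
    (1 - exp(-tmax / tau))
}

#' @export
print.decay_curve <- function(x, ...) {
  cat(sprintf("<decay_curve> %d bins over %.3g ns, %d photons\n",
              x$n_bins, x$t_max_ns, sum(x$counts)))
  invisible(x)
}

#' Draw per-cell feature tables directly from the state distributions
#'
#' Samples the same per-cell quantities the image renderer uses (a2 peak and
#' width, area, eccentricity-driven shape, droplet load) without rasterizing
#' images, and adds small measurement noise emulating histogram read-out and
#' contour tracing. Useful for benchmarking the clustering stage at scale.
#'
#' @param n_per_day cells per timepoint.
#' @param mixtures list of [timepoint_mixture()]s.
#' @param state_configs named list of [state_config()]s.
#' @param modality `"FLIM_A2"` (area, a2_peak, a2_fwhm) or `"SRS"`
#'   (area, perimeter, circularity, mean_gray).
#' @param seed integer seed.
#' @param n_fields number of replicate fields each timepoint's cells are
#'   split across (field labels drive the proportion-table SDs).
#' @return data frame with columns cell_id, day, field, state and the
#'   modality's features.
#' @export
synth_feature_table <- function(n_per_day = 150L,
                                mixtures = default_timepoint_mixtures(),
                                state_configs = default_state_configs(),
                                modality = c("FLIM_A2", "SRS"),
                                seed,
                                n_fields = 3L) {
  modality <- match.arg(modality)
  if (missing(seed)) stop("seed must be set")
  set.seed(as.integer(seed))
  out <- list()
  cell_id <- 0L
  for (mx in mixtures) {
    states <- allocate_states(n_per_day, mx)
    states <- states[sample.int(n_per_day)]
    fields <- rep_len(seq_len(n_fields), n_per_day)
    for (i in seq_len(n_per_day)) {
      cfg <- state_configs[[states[i]]]
      cell_id <- cell_id + 1L
      area <- max(200, stats::rnorm(1L, cfg$cell_area_mean, cfg$cell_area_sd))
      row <- list(cell_id = cell_id, day = mx$day, field = fields[i],
                  state = states[i])
      if (modality == "FLIM_A2") {
        a2_peak <- min(0.98, max(0.02, stats::rnorm(1L, cfg$a2_peak_mean, cfg$a2_peak_sd)))
        width <- cfg$a2_width_mean * stats::runif(1L, 0.9, 1.1)
        row$area <- area * (1 + stats::rnorm(1L, 0, 0.03))
        row$a2_peak <- min(1, max(0, a2_peak + stats::rnorm(1L, 0, 0.005)))
        row$a2_fwhm <- max(0.01, 2.3548 * width + stats::rnorm(1L, 0, 0.005))
      } else {
        ecc <- stats::runif(1L, cfg$eccentricity_range[1], cfg$eccentricity_range[2])
        a <- sqrt(area / (pi * sqrt(1 - ecc^2)))
        b <- area / (pi * a)
        # Ramanujan ellipse perimeter, plus tracing noise
        h3 <- 3 * (a + b)
        per <- pi * (h3 - sqrt((h3 - 2 * a) * (h3 - 2 * b))) * (1 + stats::rnorm(1L, 0, 0.02))
        n_drop <- stats::rpois(1L, cfg$droplet_count_mean)
        drop_area <- pi * stats::runif(max(1L, n_drop), 2, 3.5)^2
        gain <- if (n_drop > 0L) sum(drop_area[seq_len(n_drop)]) * cfg$droplet_intensity_mean / area else 0
        row$area <- area * (1 + stats::rnorm(1L, 0, 0.03))
        row$perimeter <- per
        row$circularity <- min(1, 4 * pi * area / per^2)
        row$mean_gray <- max(0, 150 + gain + stats::rnorm(1L, 0, 8))
      }
      out[[cell_id]] <- row
    }
  }
  do.call(rbind.data.frame, c(out, list(stringsAsFactors = FALSE)))
}
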