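# End-to-end orchestration: synthesize fields per timepoint, segment,
# extract features, cluster, map states, tabulate proportions and annotate
# between-day differences -- one deterministic run per configuration.

#' Build a pipeline run configuration
#'
#' All downstream randomness is derived from the single `seed`; re-running
#' an identical configuration reproduces every output bit-identically.
#' The default sizes (3 replicate fields of 50 cells per timepoint, with
#' cells allowed to touch) keep the accepted single-cell count per
#' timepoint inside the 150-200 band the clustering stage expects.
#'
#' @param seed master seed (mandatory).
#' @param out_dir output directory.
#' @param modalities character vector, subset of `c("FLIM_A2", "SRS")`.
#' @param mixtures list of [timepoint_mixture()]s (one per timepoint).
#' @param state_configs named list of [state_config()]s.
#' @param n_cells_per_field,fields_per_day field content per timepoint.
#' @param width,height field size (px).
#' @param spacing_factor cell placement spacing (see [generate_field()]).
#' @param segment a [segment_params()] list.
#' @param bin_width a2 histogram bin width.
#' @param k `"auto"` (elbow rule) or a fixed integer.
#' @param k_range candidate k range for the elbow rule.
#' @param n_restarts K-means++ restarts.
#' @return list of class `run_config`.
#' @export
run_config <- function(seed, out_dir,
                       modalities = "FLIM_A2",
                       mixtures = default_timepoint_mixtures(),
                       state_configs = default_state_configs(),
                       n_cells_per_field = 50L, fields_per_day = 3L,
                       width = 512L, height = 512L,
                       spacing_factor = 0.8,
                       segment = segment_params(),
                       bin_width = 0.01,
                       k = "auto", k_range = 1:8, n_restarts = 10L) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(all(modalities %in% c("FLIM_A2", "SRS")), length(mixtures) >= 2L)
  structure(list(
    seed = as.integer(seed), out_dir = out_dir, modalities = modalities,
    mixtures = mixtures, state_configs = state_configs,
    n_cells_per_field = as.integer(n_cells_per_field),
    fields_per_day = as.integer(fields_per_day),
    width = as.integer(width), height = as.integer(height),
    spacing_factor = spacing_factor, segment = segment,
    bin_width = bin_width, k = k, k_range = k_range,
    n_restarts = as.integer(n_restarts)
  ), class = "run_config")
}

#' Load a run configuration from YAML
#'
#' Recognized top-level keys mirror the [run_config()] arguments; `mixtures`
#' is a list of `{day, undiff, differentiating, diff}` entries and
#' `state_configs` a map state -> [state_config()] fields.
#'
#' @param path YAML file.
#' @return a `run_config`.
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c("seed", "out_dir", "modalities",
                                  "n_cells_per_field", "fields_per_day",
                                  "width", "height", "spacing_factor",
                                  "bin_width", "k", "k_range", "n_restarts"))]
  if (!is.null(y$mixtures)) {
    args$mixtures <- lapply(y$mixtures, function(m) {
      timepoint_mixture(m$day, c(undiff = m$undiff,
                                 differentiating = m$differentiating,
                                 diff = m$diff))
    })
  }
  if (!is.null(y$state_configs)) {
    args$state_configs <- lapply(names(y$state_configs), function(nm) {
      do.call(state_config, c(list(state_name = nm), y$state_configs[[nm]]))
    })
    names(args$state_configs) <- names(y$state_configs)
  }
  if (!is.null(y$segment)) args$segment <- do.call(segment_params, y$segment)
  do.call(run_config, args)
}

# Deterministic per-stage seed derivation from the master seed.
#' @keywords internal
derive_seed <- function(master, modality_index, day_index = 0L, field_index = 0L) {
  (as.integer(master) * 2654435L + modality_index * 97911L +
     day_index * 7919L + field_index * 131L) %% 2147483647L
}

#' Run the full analysis pipeline
#'
#' For each configured modality: generate `fields_per_day` synthetic fields
#' per timepoint, estimate the per-day window matrix from up to 50
#' ground-truth cell sizes, segment every field, extract the modality's
#' features from every accepted cell, min-max normalize, select k by the
#' elbow rule (unless fixed), fit K-means++, map clusters to differentiation
#' states by temporal drift, build the proportion table (plus the
#' differentiating + differentiated sum), and Z-test the primary feature
#' between consecutive timepoints. Any stage failure aborts with the stage
#' and field context. All tables, the model and a run manifest are written
#' under `config$out_dir`.
#'
#' @param config a [run_config()].
#' @return invisibly, the run report (also stored as `manifest.json`):
#'   per-modality counts at each stage, selected k, wcss curve, state
#'   mapping, proportion rows, stats annotations and md5 checksums of every
#'   written file.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  report <- list(seed = config$seed, modalities = list())
  for (mi in seq_along(config$modalities)) {
    modality <- config$modalities[mi]
    arm <- run_arm(config, modality, mi)
    report$modalities[[modality]] <- arm
  }
  files <- list.files(out, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  sums <- tools::md5sum(files)
  report$checksums <- as.list(stats::setNames(unname(sums),
                                              sub(paste0("^", out, "/?"), "", files)))
  manifest <- file.path(out, "manifest.json")
  writeLines(canonical_json(report), manifest)
  invisible(c(report, manifest = manifest))
}

# One modality arm of the pipeline.
#' @keywords internal
run_arm <- function(config, modality, mi) {
  out <- file.path(config$out_dir, tolower(modality))
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", what, "' failed (", modality, "): ",
           conditionMessage(e), call. = FALSE)
    })
  }

  # --- synthesis ------------------------------------------------------------
  fields <- list()
  for (di in seq_along(config$mixtures)) {
    mx <- config$mixtures[[di]]
    for (fi in seq_len(config$fields_per_day)) {
      fld <- stage(sprintf("synth day %d field %d", mx$day, fi),
        generate_field(width = config$width, height = config$height,
                       n_cells = config$n_cells_per_field, mixture = mx,
                       state_configs = config$state_configs,
                       modality = modality,
                       seed = derive_seed(config$seed, mi, di, fi),
                       spacing_factor = config$spacing_factor))
      write_image_field(fld, out, sprintf("day%02d_field%02d", mx$day, fi))
      fields[[length(fields) + 1L]] <- fld
    }
  }

  # --- segmentation + features ----------------------------------------------
  feats <- list()
  n_detected <- 0L
  counts_by_day <- list()
  excluded <- list()
  for (di in seq_along(config$mixtures)) {
    mx <- config$mixtures[[di]]
    day_fields <- fields[(di - 1L) * config$fields_per_day + seq_len(config$fields_per_day)]
    sizes <- do.call(rbind, lapply(day_fields, function(f) {
      cbind(f$ground_truth$cells$bbox_height, f$ground_truth$cells$bbox_width)
    }))
    wsm <- stage(sprintf("window matrix day %d", mx$day),
                 estimate_window_matrix(sizes[seq_len(min(50L, nrow(sizes))), , drop = FALSE]))
    n_day <- 0L
    for (fi in seq_along(day_fields)) {
      fld <- day_fields[[fi]]
      seg <- stage(sprintf("segment day %d field %d", mx$day, fi),
                   segment_field(fld, wsm, config$segment))
      n_detected <- n_detected + length(seg$detections)
      for (d in seg$detections) {
        w <- d$window
        crop <- fld$pixels[(w["top"] + 1L):(w["top"] + w["height"]),
                           (w["left"] + 1L):(w["left"] + w["width"]), drop = FALSE]
        row <- tryCatch({
          mask <- build_mask(crop, hist_bins = config$segment$hist_bins)
          fv <- extract_features(crop, mask, modality, config$bin_width)
          cbind(data.frame(day = mx$day, field = fi), fv)
        }, error = function(e) {
          excluded[[length(excluded) + 1L]] <<- list(
            day = mx$day, field = fi, window = unname(w),
            reason = conditionMessage(e))
          NULL
        })
        if (!is.null(row)) {
          feats[[length(feats) + 1L]] <- row
          n_day <- n_day + 1L
        }
      }
    }
    counts_by_day[[as.character(mx$day)]] <- n_day
    if (n_day < 150L || n_day > 200L) {
      warning(sprintf("%s day %d: %d accepted cells (outside the 150-200 band)",
                      modality, mx$day, n_day))
    }
  }
  features <- do.call(rbind, feats)
  features <- cbind(cell_id = seq_len(nrow(features)), features)
  utils::write.csv(features, file.path(out, "features.csv"), row.names = FALSE)

  # --- clustering -----------------------------------------------------------
  norm <- stage("normalize", normalize_features(features))
  jsonlite::write_json(norm$params, file.path(out, "normalization.json"),
                       digits = NA)
  cl <- stage("cluster",
              cluster_cells(norm$table, k = config$k,
                            seed = derive_seed(config$seed, mi, 0L, 0L),
                            k_range = config$k_range,
                            n_restarts = config$n_restarts))
  mapping <- stage("state assignment", assign_states(cl$model, features$day))
  ptab <- stage("proportion table",
                proportion_table(cl$model$assignments, features$day,
                                 features$field, k = cl$model$k))
  diff_clusters <- which(mapping != "undiff")
  combined <- combined_proportion(cl$model$assignments, features$day,
                                  features$field, diff_clusters)
  utils::write.csv(ptab, file.path(out, "proportions.csv"), row.names = FALSE)
  utils::write.csv(combined, file.path(out, "proportions_combined.csv"),
                   row.names = FALSE)
  model_json <- list(k = cl$model$k, wcss = cl$model$wcss,
                     seed = cl$model$seed,
                     centroids = unname(apply(cl$model$centroids, 1L,
                                              as.list, simplify = FALSE)),
                     feature_cols = attr(norm$table, "feature_cols"),
                     state_mapping = as.list(mapping))
  if (!is.null(cl$elbow)) {
    model_json$k_range <- cl$elbow$k_range
    model_json$wcss_curve <- cl$elbow$wcss_curve
    model_json$flat_elbow <- cl$elbow$flat
  }
  writeLines(canonical_json(model_json), file.path(out, "model.json"))

  # --- stats: primary feature between consecutive days ----------------------
  primary <- if (modality == "FLIM_A2") "a2_peak" else "mean_gray"
  days <- vapply(config$mixtures, function(m) m$day, integer(1))
  stat_rows <- list()
  for (i in seq_len(length(days) - 1L)) {
    g1 <- features[[primary]][features$day == days[i]]
    g2 <- features[[primary]][features$day == days[i + 1L]]
    zt <- ztest_two_means(mean(g1), stats::sd(g1), length(g1),
                          mean(g2), stats::sd(g2), length(g2))
    stat_rows[[i]] <- data.frame(
      feature = primary, day1 = days[i], day2 = days[i + 1L],
      mean1 = mean(g1), mean2 = mean(g2), z = zt$statistic,
      p_value = zt$p_value, label = significance_labels(zt$p_value))
  }
  stats_tab <- do.call(rbind, stat_rows)
  utils::write.csv(stats_tab, file.path(out, "stats.csv"), row.names = FALSE)

  list(
    n_fields = length(fields),
    n_true_cells = length(fields) * config$n_cells_per_field,
    n_detections = n_detected,
    n_feature_rows = nrow(features),
    n_excluded = length(excluded),
    excluded = excluded,
    accepted_per_day = counts_by_day,
    k = cl$model$k,
    wcss = cl$model$wcss,
    wcss_curve = if (!is.null(cl$elbow)) cl$elbow$wcss_curve else NULL,
    state_mapping = as.list(mapping),
    proportions = ptab,
    combined_differentiated = combined,
    stats = stats_tab
  )
}
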