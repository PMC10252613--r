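# TIFF / CSV / JSON / YAML interchange. FLIM a2 maps are written as 32-bit
# float TIFF (values already in [0, 1]); SRS count images as 16-bit TIFF.

#' Write an image field to disk
#'
#' Writes `<basename>.tif` (the pixels), and when ground truth is present
#' `<basename>_cells.csv` (one row per cell) and `<basename>_scene.json`
#' (cell and nucleus polygons, 0-based row/col).
#'
#' @param field an `image_field`.
#' @param dir output directory (created if needed).
#' @param basename file stem.
#' @return invisibly, the paths written.
#' @export
write_image_field <- function(field, dir, basename) {
  stopifnot(inherits(field, "image_field"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tif <- file.path(dir, paste0(basename, ".tif"))
  if (field$modality == "SRS") {
    tiff::writeTIFF(field$pixels / 65535, tif, bits.per.sample = 16L,
                    compression = "none")
  } else {
    tiff::writeTIFF(field$pixels, tif, bits.per.sample = 32L,
                    compression = "none")
  }
  paths <- tif
  if (!is.null(field$ground_truth)) {
    csv <- file.path(dir, paste0(basename, "_cells.csv"))
    utils::write.csv(field$ground_truth$cells, csv, row.names = FALSE)
    scene <- file.path(dir, paste0(basename, "_scene.json"))
    polys <- lapply(field$ground_truth$polygons, function(p) {
      list(cell = unname(apply(p$cell, 1L, function(r) round(r, 3), simplify = FALSE)),
           nucleus = unname(apply(p$nucleus, 1L, function(r) round(r, 3), simplify = FALSE)))
    })
    jsonlite::write_json(
      list(modality = field$modality, width = field$width,
           height = field$height, day = field$day, seed = field$seed,
           polygons = polys),
      scene, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, csv, scene)
  }
  invisible(paths)
}

#' Read a grayscale TIFF as an image field
#'
#' @param path TIFF path.
#' @param modality `"FLIM_A2"` (values kept as fractions) or `"SRS"`
#'   (values rescaled back to 16-bit counts).
#' @param day optional day label.
#' @return an `image_field` without ground truth.
#' @export
read_field_tiff <- function(path, modality = c("FLIM_A2", "SRS"), day = NA) {
  modality <- match.arg(modality)
  px <- tiff::readTIFF(path)
  if (length(dim(px)) == 3L) px <- px[, , 1L]
  if (modality == "SRS") px <- round(px * 65535)
  structure(list(pixels = px, modality = modality,
                 width = ncol(px), height = nrow(px),
                 day = day, seed = NA_integer_, ground_truth = NULL),
            class = "image_field")
}

# Serialize a run config (or any plain list) canonically for hashing.
#' @keywords internal
canonical_json <- function(x) {
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
}
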