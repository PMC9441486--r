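# Per-class binary region masks derived from a stitched prediction, mask
# I/O, physical areas, and a quantitative overlap QC gate for applying
# masks to serial-section images (no registration is attempted; the gate
# turns the manual visual triage of mask suitability into a number).

#' Per-class binary masks from a predicted annotation map
#'
#' @param labels Integer annotation matrix (0-based codes along
#'   `class_order`).
#' @param microns_per_px Physical resolution carried on the mask set.
#' @param class_order Class names (default [zone_classes()]).
#' @param provenance Optional list (slide id, model id) stored as
#'   metadata.
#' @return A `zone_mask_set`: named list of logical matrices for every
#'   non-ignore class, with attributes `microns_per_px`, `ignore`
#'   (logical matrix) and `provenance`. Masks are mutually exclusive and
#'   with the ignore mask partition the raster.
#' @export
masks_from_prediction <- function(labels, microns_per_px = 1 / 2.2,
                                  class_order = zone_classes(),
                                  provenance = list()) {
  codes <- seq_along(class_order) - 1L
  names(codes) <- class_order
  keep <- setdiff(class_order, "ignore")
  masks <- lapply(keep, function(cl) labels == codes[[cl]])
  names(masks) <- keep
  structure(masks, class = "zone_mask_set",
            microns_per_px = microns_per_px,
            ignore = labels == codes[["ignore"]],
            provenance = provenance)
}

#' Physical area of each zone mask
#' @param masks A `zone_mask_set`.
#' @return Named numeric vector of areas in mm^2 (pixel count x
#'   microns_per_px^2 / 1e6).
#' @export
mask_areas_mm2 <- function(masks) {
  mpp <- attr(masks, "microns_per_px")
  vapply(masks, function(m) sum(m) * mpp^2 / 1e6, numeric(1))
}

#' Overlap QC for applying zone masks to a serial-section image
#'
#' Masks defined on one section are applied to a serially cut,
#' differently stained section at identity placement (no registration).
#' The QC score is the fraction of detected tissue pixels in the target
#' (luminance below `luminance_threshold`, i.e. non-white) that fall
#' inside the union of the non-background zone masks; sections whose score
#' falls below `gate` are flagged FAIL, automating the manual triage of
#' displaced or distorted serial sections.
#'
#' @param masks A `zone_mask_set` from the reference section.
#' @param target h x w x 3 raster of the serial section.
#' @param gate PASS threshold on the score (default 0.8).
#' @param luminance_threshold Tissue detection: pixels with luminance
#'   below this fraction of white count as tissue (default 0.9).
#' @param dim_tolerance Maximum allowed dimension mismatch in pixels.
#' @return List with `score`, `pass`, `reason`, `n_tissue_px`.
#' @export
apply_masks <- function(masks, target, gate = 0.8,
                        luminance_threshold = 0.9, dim_tolerance = 0L) {
  md <- dim(masks[[1]])
  td <- dim(target)[1:2]
  if (any(abs(md - td) > dim_tolerance)) {
    return(list(score = 0, pass = FALSE, reason = "displaced/resized",
                n_tissue_px = NA_integer_))
  }
  lum <- 0.2126 * target[, , 1] + 0.7152 * target[, , 2] +
    0.0722 * target[, , 3]
  tissue <- lum < luminance_threshold
  n <- sum(tissue)
  if (n == 0) {
    return(list(score = 0, pass = FALSE, reason = "no tissue detected",
                n_tissue_px = 0L))
  }
  union <- Reduce(`|`, masks[setdiff(names(masks), "background")])
  score <- sum(tissue & union[seq_len(td[1]), seq_len(td[2])]) / n
  list(score = score, pass = score >= gate,
       reason = if (score >= gate) "ok" else "insufficient overlap",
       n_tissue_px = n)
}

#' Write a zone mask set as per-class binary PNGs plus a combined map
#'
#' @param masks A `zone_mask_set`.
#' @param dir Output directory.
#' @param palette Palette for the combined annotation PNG.
#' @return The directory, invisibly.
#' @export
write_mask_set <- function(masks, dir, palette = zone_palette()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (cl in names(masks)) {
    png::writePNG(masks[[cl]] * 1, file.path(dir, paste0("mask_", cl, ".png")))
  }
  combined <- combined_labels(masks)
  write_annotation_png(combined, file.path(dir, "mask_combined.png"), palette)
  invisible(dir)
}

# Recombine a mask set into a single annotation matrix.
combined_labels <- function(masks, class_order = zone_classes()) {
  codes <- seq_along(class_order) - 1L
  names(codes) <- class_order
  out <- matrix(codes[["ignore"]], nrow(masks[[1]]), ncol(masks[[1]]))
  for (cl in names(masks)) out[masks[[cl]]] <- codes[[cl]]
  storage.mode(out) <- "integer"
  out
}

#' Read a zone mask set written by [write_mask_set()]
#' @param dir Directory holding `mask_combined.png`.
#' @param microns_per_px Resolution to attach.
#' @return A `zone_mask_set`.
#' @export
read_mask_set <- function(dir, microns_per_px = 1 / 2.2) {
  labels <- read_annotation_png(file.path(dir, "mask_combined.png"))
  masks_from_prediction(labels, microns_per_px = microns_per_px)
}
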