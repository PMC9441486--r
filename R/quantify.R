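# Per-zone quantification: optical-density transform, stain unmixing
# (colour deconvolution), positive cell detection driven by the
# hematoxylin OD channel, DAB stained-area measurement, elastin/collagen
# pixel classification, and the per-zone report table.

#' Stain model for colour deconvolution
#'
#' A 3x3 matrix of unit optical-density vectors, one row per stain. The
#' `"h-dab"` preset uses the standard published unmixing basis for
#' hematoxylin + DAB (third row: orthogonal residual). The `"weigert"`
#' preset carries reference OD vectors for elastin (dark blue-black),
#' collagen (red) and ground substance, derived from the package's
#' rendering palette ([weigert_reference_colors()]).
#'
#' @param preset `"h-dab"` or `"weigert"`, or supply `vectors` directly.
#' @param vectors Optional 3x3 matrix (rows = stains) overriding the
#'   preset; rows are renormalised to unit length.
#' @param I0 White reference intensity per channel (default 1).
#' @return A `stain_model` object.
#' @export
stain_model <- function(preset = c("h-dab", "weigert"), vectors = NULL,
                        I0 = c(1, 1, 1)) {
  preset <- match.arg(preset)
  if (is.null(vectors)) {
    if (preset == "h-dab") {
      h <- c(0.650, 0.704, 0.286)
      d <- c(0.269, 0.568, 0.778)
      r <- c(h[2] * d[3] - h[3] * d[2], h[3] * d[1] - h[1] * d[3],
             h[1] * d[2] - h[2] * d[1])
      vectors <- rbind(hematoxylin = h, dab = d, residual = r)
    } else {
      cols <- weigert_reference_colors()
      od <- function(x) -log10(pmax(x, 1e-3))
      ground <- od(cols$zone1) / sqrt(sum(od(cols$zone1)^2)) +
        od(cols$zone2) / sqrt(sum(od(cols$zone2)^2)) +
        od(cols$thrombus) / sqrt(sum(od(cols$thrombus)^2))
      vectors <- rbind(elastin = od(cols$elastin), collagen = od(cols$collagen),
                       ground = ground)
    }
  }
  vectors <- t(apply(vectors, 1, function(v) v / sqrt(sum(v^2))))
  if (abs(det(vectors)) < 1e-8) stop("stain matrix is singular")
  structure(list(vectors = vectors, I0 = rep(I0, length.out = 3),
                 preset = preset), class = "stain_model")
}

#' @rdname stain_model
#' @param model A `stain_model`.
#' @export
stain_vectors <- function(model) model$vectors

#' Optical-density transform of an RGB raster
#'
#' OD_c = -log10(max(I_c, eps) / I0_c) per channel; stains mix additively
#' in OD space, which is what makes colour deconvolution linear.
#'
#' @param rgb h x w x 3 intensity array in `(0, 1]`.
#' @param I0 White reference per channel.
#' @param eps Guard against zero intensities.
#' @return h x w x 3 array of non-negative optical densities.
#' @export
od_transform <- function(rgb, I0 = c(1, 1, 1), eps = 1e-6) {
  od <- rgb
  for (ch in 1:3) {
    od[, , ch] <- -log10(pmax(rgb[, , ch], eps) / I0[ch])
  }
  od
}

#' Unmix an OD raster into per-stain concentration maps
#'
#' Solves the linear colour-deconvolution system: each pixel's OD vector
#' is expressed in the basis of the stain model's OD vectors. Re-mixing
#' the concentrations with the same basis reconstructs the OD raster.
#'
#' @param od h x w x 3 OD array (see [od_transform()]).
#' @param stains A [stain_model()].
#' @return h x w x 3 array of stain concentrations, third dimension
#'   named by stain.
#' @export
unmix <- function(od, stains) {
  V <- stain_vectors(stains)
  d <- dim(od)
  flat <- matrix(od, d[1] * d[2], 3)
  conc <- flat %*% solve(V)
  out <- array(conc, c(d[1], d[2], 3))
  dimnames(out) <- list(NULL, NULL, rownames(V))
  out
}

#' Positive cell detection parameters
#'
#' Presets mirror the published detection settings: both markers detect on
#' the hematoxylin OD channel; MPO uses an 8 um background radius and
#' thresholds the cytoplasm mean DAB OD at 0.2; CD8 uses a 10 um radius
#' and thresholds the whole-cell mean DAB OD at 0.1.
#'
#' @param marker `"cd8"` or `"mpo"`, or `NULL` with explicit values.
#' @param background_radius_um Rolling-ball-style background subtraction
#'   radius on the hematoxylin OD channel.
#' @param compartment Compartment whose mean DAB OD is thresholded:
#'   `"cell"` or `"cytoplasm"`.
#' @param positive_threshold Mean DAB OD at or above which a cell is
#'   positive.
#' @param min_area_um2,max_area_um2 Accepted nucleus area bounds.
#' @param nucleus_od_threshold Hematoxylin OD threshold forming nucleus
#'   candidates.
#' @param smooth_sigma_um Gaussian smoothing applied to the detection
#'   channel.
#' @param ring_um Cytoplasm ring expansion beyond the nucleus.
#' @return A `detection_params` list.
#' @export
detection_params <- function(marker = c("cd8", "mpo"),
                             background_radius_um = NULL,
                             compartment = NULL,
                             positive_threshold = NULL,
                             min_area_um2 = 10, max_area_um2 = 400,
                             nucleus_od_threshold = 0.3,
                             smooth_sigma_um = 1.5, ring_um = 3) {
  marker <- match.arg(marker)
  defaults <- list(
    cd8 = list(radius = 10.0, compartment = "cell", threshold = 0.1),
    mpo = list(radius = 8.0, compartment = "cytoplasm", threshold = 0.2))
  d <- defaults[[marker]]
  out <- list(marker = marker,
              background_radius_um = background_radius_um %||% d$radius,
              compartment = compartment %||% d$compartment,
              positive_threshold = positive_threshold %||% d$threshold,
              min_area_um2 = min_area_um2, max_area_um2 = max_area_um2,
              nucleus_od_threshold = nucleus_od_threshold,
              smooth_sigma_um = smooth_sigma_um, ring_um = ring_um)
  stopifnot(out$positive_threshold > 0, out$background_radius_um > 0)
  structure(out, class = "detection_params")
}

# Morphological opening-based background subtraction (rolling-ball style).
subtract_background <- function(channel, radius_px) {
  k <- 2 * max(1, round(radius_px)) + 1
  brush <- EBImage::makeBrush(k, shape = "disc")
  bg <- as.matrix(EBImage::opening(channel, brush))
  pmax(channel - bg, 0)
}

#' Detect cells and flag DAB positivity
#'
#' Pipeline: colour deconvolution; opening-based background subtraction on
#' the hematoxylin OD channel at the configured radius; Gaussian
#' smoothing; thresholding followed by a distance-transform watershed to
#' split touching nuclei; area filtering; construction of the cytoplasm
#' ring and whole-cell compartments; mean DAB OD per compartment; and the
#' positivity decision on the configured compartment.
#'
#' @param image h x w x 3 RGB raster.
#' @param params A [detection_params()].
#' @param stains A [stain_model()] (H-DAB).
#' @param microns_per_px Physical resolution.
#' @return A `cell_detections` data frame: centroid (`x_px`, `y_px`,
#'   `x_um`, `y_um`), `area_um2`, mean DAB OD per compartment
#'   (`dab_nucleus`, `dab_cytoplasm`, `dab_cell`) and `positive`.
#' @export
detect_cells <- function(image, params = detection_params("cd8"),
                         stains = stain_model("h-dab"),
                         microns_per_px = 1 / 2.2) {
  empty <- data.frame(x_px = numeric(0), y_px = numeric(0),
                      x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), dab_nucleus = numeric(0),
                      dab_cytoplasm = numeric(0), dab_cell = numeric(0),
                      positive = logical(0))
  class(empty) <- c("cell_detections", "data.frame")
  if (length(image) == 0) return(empty)
  conc <- unmix(od_transform(image, stains$I0), stains)
  hchan <- conc[, , 1]
  dab <- conc[, , 2]
  hbs <- subtract_background(hchan, params$background_radius_um / microns_per_px)
  sigma <- params$smooth_sigma_um / microns_per_px
  hsm <- as.matrix(EBImage::gblur(hbs, sigma = max(sigma, 0.5)))
  mask <- hsm > params$nucleus_od_threshold
  if (!any(mask)) return(empty)
  dm <- EBImage::distmap(EBImage::Image(mask * 1))
  labels <- as.matrix(EBImage::watershed(dm))
  px_area <- microns_per_px^2
  tab <- tabulate(labels[labels > 0])
  ok <- which(tab * px_area >= params$min_area_um2 &
                tab * px_area <= params$max_area_um2)
  if (length(ok) == 0) return(empty)
  relab <- matrix(0L, nrow(labels), ncol(labels))
  relab[labels %in% ok] <- match(labels[labels %in% ok], ok)
  n <- length(ok)
  # cytoplasm ring: greyscale dilation of the label map; ring pixels take
  # the label of the nearest (max-label on overlap) nucleus
  ring_px <- max(1, round(params$ring_um / microns_per_px))
  brush <- EBImage::makeBrush(2 * ring_px + 1, "disc")
  dil <- as.matrix(EBImage::dilate(relab, brush))
  ring <- dil
  ring[relab > 0] <- 0L
  idx_nuc <- relab > 0
  idx_ring <- ring > 0
  mean_by <- function(values, labs, n) {
    s <- rowsum(values, labs)
    cnt <- rowsum(rep(1, length(labs)), labs)
    out <- numeric(n)
    out[as.integer(rownames(s))] <- s / cnt
    out
  }
  dab_nuc <- mean_by(dab[idx_nuc], relab[idx_nuc], n)
  dab_ring <- if (any(idx_ring)) mean_by(dab[idx_ring], ring[idx_ring], n)
  else numeric(n)
  # whole cell = nucleus plus ring
  all_lab <- c(relab[idx_nuc], ring[idx_ring])
  all_val <- c(dab[idx_nuc], dab[idx_ring])
  dab_cell <- mean_by(all_val, all_lab, n)
  ys <- row(relab)[idx_nuc]; xs <- col(relab)[idx_nuc]; ls <- relab[idx_nuc]
  cy <- mean_by(ys, ls, n); cx <- mean_by(xs, ls, n)
  area <- tab[ok] * px_area
  comp <- switch(params$compartment, cell = dab_cell, cytoplasm = dab_ring)
  out <- data.frame(x_px = cx, y_px = cy,
                    x_um = cx * microns_per_px, y_um = cy * microns_per_px,
                    area_um2 = area, dab_nucleus = dab_nuc,
                    dab_cytoplasm = dab_ring, dab_cell = dab_cell,
                    positive = comp >= params$positive_threshold)
  class(out) <- c("cell_detections", "data.frame")
  out
}

#' Per-zone DAB-stained area
#'
#' Measures, inside every zone mask, the area of pixels whose DAB optical
#' density meets a threshold -- the area-based readout used for diffuse
#' markers (e.g. macrophage stains) where single-cell segmentation is not
#' meaningful.
#'
#' @param image h x w x 3 RGB raster.
#' @param stains An H-DAB [stain_model()].
#' @param od_threshold DAB OD at or above which a pixel counts as stained.
#' @param masks A `zone_mask_set`.
#' @return Data frame with `class`, `stained_mm2`, `zone_mm2`,
#'   `stained_pct`.
#' @export
stained_area <- function(image, stains = stain_model("h-dab"),
                         od_threshold = 0.2, masks) {
  stopifnot(od_threshold > 0)
  conc <- unmix(od_transform(image, stains$I0), stains)
  dabpos <- conc[, , 2] >= od_threshold
  mpp <- attr(masks, "microns_per_px")
  rows <- lapply(names(masks), function(cl) {
    m <- masks[[cl]]
    data.frame(class = cl,
               stained_mm2 = sum(dabpos & m) * mpp^2 / 1e6,
               zone_mm2 = sum(m) * mpp^2 / 1e6,
               stained_pct = if (sum(m) > 0) 100 * sum(dabpos & m) / sum(m)
               else 0)
  })
  do.call(rbind, rows)
}

#' Per-zone elastin and collagen area percentages
#'
#' Assigns every tissue pixel to exactly one of elastin, collagen or
#' neither: pixels whose total OD falls below `min_od` are background
#' (neither); the rest are classified by nearest reference stain direction
#' in OD space (elastin, collagen, or ground substance = neither).
#'
#' @param image h x w x 3 elastin-stained raster.
#' @param stains A `"weigert"`-mode [stain_model()].
#' @param masks A `zone_mask_set`.
#' @param min_od Minimum total OD for a pixel to be considered stained
#'   tissue.
#' @return Data frame with `class`, `elastin_pct`, `collagen_pct`,
#'   `zone_px`.
#' @export
classify_fibers <- function(image, stains = stain_model("weigert"), masks,
                            min_od = 0.25) {
  V <- stain_vectors(stains)
  d <- dim(image)
  od <- matrix(od_transform(image), d[1] * d[2], 3)
  tot <- sqrt(rowSums(od^2))
  dirs <- od / pmax(tot, 1e-9)
  # squared distance to each unit reference direction
  d2 <- sapply(seq_len(nrow(V)), function(i) {
    rowSums(sweep(dirs, 2, V[i, ])^2)
  })
  assign <- max.col(-d2, ties.method = "first")
  assign[tot < min_od] <- 0L           # background: neither
  elastin <- matrix(assign == 1L, d[1], d[2])
  collagen <- matrix(assign == 2L, d[1], d[2])
  rows <- lapply(names(masks), function(cl) {
    m <- masks[[cl]]
    npx <- sum(m)
    data.frame(class = cl,
               elastin_pct = if (npx > 0) 100 * sum(elastin & m) / npx else 0,
               collagen_pct = if (npx > 0) 100 * sum(collagen & m) / npx
               else 0,
               zone_px = npx)
  })
  do.call(rbind, rows)
}

#' Derived per-zone quantification columns
#'
#' Builds the per-zone report rows from raw counts: positive percentage
#' (100 x positives / detections, 0 when there are no detections) and
#' positives per mm^2 (positives / area, 0 when the area is 0).
#'
#' @param class Zone class names.
#' @param detections Total cell detections per zone.
#' @param positives Positive detections per zone.
#' @param area_mm2 Zone areas in mm^2.
#' @return A `zone_quant` data frame with the raw and derived columns.
#' @export
zone_quant_rows <- function(class, detections, positives, area_mm2) {
  stopifnot(all(positives <= detections))
  out <- data.frame(
    class = class, detections = detections, positives = positives,
    positive_pct = ifelse(detections > 0, 100 * positives / detections, 0),
    positives_per_mm2 = ifelse(area_mm2 > 0, positives / area_mm2, 0),
    area_mm2 = area_mm2, stringsAsFactors = FALSE)
  class(out) <- c("zone_quant", "data.frame")
  out
}

#' Per-zone cell quantification report
#'
#' Assigns every detection to the zone whose mask contains its centroid
#' (detections outside every zone mask, including those on ignore pixels,
#' are reported under background) and tabulates detections, positives and
#' the derived density columns per zone.
#'
#' @param detections A `cell_detections` data frame (pixel-frame
#'   centroids).
#' @param masks A `zone_mask_set` in the same pixel frame.
#' @return A `zone_quant` data frame, one row per zone class.
#' @export
zone_report <- function(detections, masks) {
  areas <- mask_areas_mm2(masks)
  classes <- names(masks)
  h <- nrow(masks[[1]]); w <- ncol(masks[[1]])
  n <- nrow(detections)
  assigned <- rep("background", n)
  if (n > 0) {
    iy <- pmin(pmax(round(detections$y_px), 1), h)
    ix <- pmin(pmax(round(detections$x_px), 1), w)
    lin <- cbind(iy, ix)
    for (cl in setdiff(classes, "background")) {
      inside <- masks[[cl]][lin]
      assigned[inside] <- cl
    }
  }
  det <- vapply(classes, function(cl) sum(assigned == cl), numeric(1))
  pos <- vapply(classes, function(cl)
    sum(assigned == cl & detections$positive), numeric(1))
  zone_quant_rows(classes, det, pos, areas[classes])
}

#' @export
print.zone_quant <- function(x, ...) {
  y <- as.data.frame(x)
  y$positive_pct <- round(y$positive_pct, 1)
  y$positives_per_mm2 <- round(y$positives_per_mm2)
  y$area_mm2 <- round(y$area_mm2, 1)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Write a per-zone quantification report as CSV
#'
#' One CSV per patient/stain, with the conventional column headings
#' (Detections, Positive, Positive %, Positive per mm^2, Area).
#'
#' @param report A `zone_quant` data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_zone_csv <- function(report, path) {
  out <- data.frame(Class = report$class, Detections = report$detections,
                    Positive = report$positives,
                    `Positive %` = round(report$positive_pct, 1),
                    `Positive per mm2` = round(report$positives_per_mm2),
                    `Area mm2` = report$area_mm2, check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
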