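# Synthetic slides with known ground truth: multi-zone tissue geometry,
# elastin/collagen fiber rendering, and forward-modelled H-DAB immunostains.
# Images are numeric arrays [row, col, channel] with intensities in [0, 1];
# annotations are integer matrices coded 0-based along zone_classes().

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so generators are deterministic without disturbing the
#' session stream.
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Specification of a synthetic slide
#'
#' Describes the geometry, resolution, fiber content and RNG seed of a
#' synthetic biopsy cross-section. The default geometry is three concentric
#' bands -- thrombus core, vascular wall (zone 1), perivascular tissue
#' (zone 2) -- on an annotated background field, with the unannotated
#' outer margin and thin bands at zone borders labelled `ignore`; the
#' `"blobs"` geometry perturbs the band radii angularly for irregular
#' morphology.
#'
#' @param width_px,height_px Slide dimensions in pixels (each >= 64).
#' @param microns_per_px Physical resolution; default 1/2.2 um/px
#'   (2.2 px/um).
#' @param geometry `"bands"` (concentric) or `"blobs"` (irregular bands).
#' @param fiber_fractions Named list per zone giving target `elastin` and
#'   `collagen` area fractions in `[0, 1]`; their per-zone sum must be <= 1.
#' @param band_radii Outer radii of thrombus, zone1, zone2 and annotated
#'   background as fractions of the largest inscribed radius.
#' @param boundary_ignore_px Width of the ignore band planted at each zone
#'   border.
#' @param noise_sd Additive Gaussian RGB noise (fraction of dynamic range)
#'   applied after rendering.
#' @param seed Integer RNG seed; all generator randomness derives from it.
#' @return A `slide_spec` object (list).
#' @export
slide_spec <- function(width_px, height_px, microns_per_px = 1 / 2.2,
                       geometry = c("bands", "blobs"),
                       fiber_fractions = list(
                         zone1 = c(elastin = 0.25, collagen = 0.35),
                         zone2 = c(elastin = 0.05, collagen = 0.20)),
                       band_radii = c(thrombus = 0.22, zone1 = 0.50,
                                      zone2 = 0.75, background = 0.92),
                       boundary_ignore_px = 3L,
                       noise_sd = 0.02, seed = 1L) {
  geometry <- match.arg(geometry)
  if (width_px < 64 || height_px < 64) {
    stop("slide dimensions must be at least 64 px")
  }
  for (z in names(fiber_fractions)) {
    ff <- fiber_fractions[[z]]
    if (any(ff < 0) || any(ff > 1) || sum(ff) > 1) {
      stop("fiber fractions for ", z,
           " must be in [0, 1] and sum to at most 1 (cannot fit ",
           "requested fractions)")
    }
  }
  if (is.unsorted(band_radii) || any(band_radii <= 0) || any(band_radii > 1)) {
    stop("`band_radii` must be increasing fractions in (0, 1]")
  }
  structure(list(width_px = as.integer(width_px),
                 height_px = as.integer(height_px),
                 microns_per_px = microns_per_px, geometry = geometry,
                 fiber_fractions = fiber_fractions, band_radii = band_radii,
                 boundary_ignore_px = as.integer(boundary_ignore_px),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "slide_spec")
}

#' Reference rendering colours for elastin-stained synthetic slides
#'
#' Elastin fibers render in a dark blue-black, collagen in red; zone ground
#' substance colours are chosen to give each class distinct colour
#' statistics. These are configuration, not biological ground truth.
#'
#' @return Named list of RGB triplets in `[0, 1]`.
#' @export
weigert_reference_colors <- function() {
  list(elastin = c(0.10, 0.10, 0.18), collagen = c(0.80, 0.25, 0.30),
       zone1 = c(0.78, 0.62, 0.66), zone2 = c(0.88, 0.82, 0.78),
       thrombus = c(0.62, 0.42, 0.45), background = c(0.96, 0.95, 0.96))
}

# Integer annotation matrix for a spec, 0-based codes along zone_classes().
make_zone_annotation <- function(spec) {
  h <- spec$height_px; w <- spec$width_px
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  rmax <- min(h, w) / 2
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  r <- sqrt((yy - cy)^2 + (xx - cx)^2)
  radii <- spec$band_radii * rmax
  if (spec$geometry == "blobs") {
    # smooth angular perturbation of band radii -> irregular morphology
    theta <- atan2(yy - cy, xx - cx)
    pert <- with_seed(spec$seed + 11L, {
      amp <- stats::runif(3, 0.05, 0.12)
      ph <- stats::runif(3, 0, 2 * pi)
      kf <- sample(2:5, 3, replace = TRUE)
      Reduce(`+`, lapply(1:3, function(i) amp[i] * sin(kf[i] * theta + ph[i])))
    })
    r <- r * (1 + pert)
  }
  codes <- match(c("ignore", "zone1", "zone2", "thrombus", "background"),
                 zone_classes()) - 1L
  names(codes) <- c("ignore", "zone1", "zone2", "thrombus", "background")
  ann <- matrix(codes[["ignore"]], h, w)
  ann[r <= radii[4]] <- codes[["background"]]
  ann[r <= radii[3]] <- codes[["zone2"]]
  ann[r <= radii[2]] <- codes[["zone1"]]
  ann[r <= radii[1]] <- codes[["thrombus"]]
  # thin ignore bands at the three tissue borders (uncertain boundaries)
  b <- spec$boundary_ignore_px
  if (b > 0) {
    for (rad in radii[1:3]) {
      ann[abs(r - rad) <= b / 2] <- codes[["ignore"]]
    }
  }
  storage.mode(ann) <- "integer"
  ann
}

# Smooth multiplicative texture field in [1-a, 1+a], deterministic.
texture_field <- function(h, w, sigma, amp) {
  f <- matrix(stats::rnorm(h * w), h, w)
  f <- as.matrix(EBImage::gblur(f, sigma = sigma))
  rng <- max(abs(f)); if (rng == 0) rng <- 1
  1 + amp * f / rng
}

#' Generate an elastin-stained synthetic slide with fiber ground truth
#'
#' Renders a multi-zone tissue cross-section with per-zone base colours and
#' texture, plants elastin (dark blue-black) and collagen (red) fiber pixels
#' at the requested per-zone area fractions (exact pixel counts before
#' noise), and returns the image together with a full `synthetic_truth`
#' record.
#'
#' @param spec A [slide_spec()].
#' @return List with `image` (h x w x 3 array in `[0, 1]`) and `truth`:
#'   `annotation` (integer matrix), `per_zone_fiber_px` (matrix
#'   zones x (elastin, collagen)), `zone_px` (named pixel counts) and
#'   `microns_per_px`.
#' @export
generate_weigert_slide <- function(spec) {
  stopifnot(inherits(spec, "slide_spec"))
  ann <- make_zone_annotation(spec)
  cols <- weigert_reference_colors()
  h <- spec$height_px; w <- spec$width_px
  rendered <- with_seed(spec$seed, {
    tex <- list(zone1 = texture_field(h, w, 3, 0.10),
                zone2 = texture_field(h, w, 8, 0.12),
                thrombus = texture_field(h, w, 2, 0.15),
                background = texture_field(h, w, 12, 0.02))
    base <- array(0, c(h, w, 3))
    code_of <- function(cl) match(cl, zone_classes()) - 1L
    for (cl in c("zone1", "zone2", "thrombus", "background")) {
      m <- ann == code_of(cl)
      for (ch in 1:3) {
        plane <- base[, , ch]
        plane[m] <- cols[[cl]][ch] * tex[[cl]][m]
        base[, , ch] <- plane
      }
    }
    # ignore pixels rendered like background (unannotated surroundings)
    m <- ann == code_of("ignore")
    for (ch in 1:3) {
      plane <- base[, , ch]
      plane[m] <- cols[["background"]][ch] * tex[["background"]][m]
      base[, , ch] <- plane
    }
    # plant fibers at exact per-zone pixel counts
    zones <- names(spec$fiber_fractions)
    fiber_px <- matrix(0L, length(zones), 2,
                       dimnames = list(zones, c("elastin", "collagen")))
    for (z in zones) {
      zpix <- which(ann == code_of(z))
      n <- length(zpix)
      ff <- spec$fiber_fractions[[z]]
      n_el <- round(ff[["elastin"]] * n)
      n_co <- round(ff[["collagen"]] * n)
      if (n_el + n_co > n) stop("cannot fit requested fiber fractions in ", z)
      pick <- sample(zpix, n_el + n_co)
      sel <- list(elastin = pick[seq_len(n_el)],
                  collagen = pick[n_el + seq_len(n_co)])
      for (f in c("elastin", "collagen")) {
        idx <- sel[[f]]
        if (length(idx)) {
          for (ch in 1:3) {
            plane <- base[, , ch]
            plane[idx] <- cols[[f]][ch]
            base[, , ch] <- plane
          }
        }
      }
      fiber_px[z, ] <- c(n_el, n_co)
    }
    if (spec$noise_sd > 0) {
      base <- base + array(stats::rnorm(length(base), 0, spec$noise_sd),
                           dim(base))
    }
    list(image = pmin(pmax(base, 0), 1), fiber_px = fiber_px)
  })
  img <- rendered$image
  fiber_px <- rendered$fiber_px
  zone_px <- table(factor(ann, levels = seq_along(zone_classes()) - 1L,
                          labels = zone_classes()))
  truth <- structure(list(annotation = ann, per_zone_fiber_px = fiber_px,
                          zone_px = c(zone_px),
                          microns_per_px = spec$microns_per_px),
                     class = "synthetic_truth")
  list(image = img, truth = truth)
}

#' Generate a synthetic H-DAB immunostained slide with planted cells
#'
#' Places non-overlapping nuclei inside the requested zones and renders
#' them through the forward optical-density stain model: every nucleus
#' carries hematoxylin, and positive cells additionally carry DAB chromogen
#' in the configured compartment (cytoplasmic ring or whole cell). At zero
#' noise, unmixing the rendered image with the same [stain_model()] is an
#' exact inverse of the rendering.
#'
#' @param spec A [slide_spec()].
#' @param cells_per_zone Named integer vector, cells to plant per zone
#'   (e.g. `c(zone1 = 100, zone2 = 40)`).
#' @param positive_fraction_per_zone Named numeric vector of DAB-positive
#'   fractions per zone (recycled from a scalar).
#' @param stain A `stain_model` (default H-DAB).
#' @param nucleus_diameter_um Nucleus disk diameter (default 8 um).
#' @param ring_um Cytoplasm ring width around the nucleus (default 3 um).
#' @param compartment Where positive cells carry DAB: `"cytoplasm"` ring or
#'   whole `"cell"`.
#' @param nucleus_od Hematoxylin OD rendered inside nuclei.
#' @param dab_od DAB OD rendered in the positive compartment.
#' @param tissue_od Faint hematoxylin OD over tissue (context staining).
#' @return List with `image` and `truth` (annotation, `planted_cells` data
#'   frame with columns x, y (px), zone, positive; `per_zone_counts`).
#' @export
generate_ihc_slide <- function(spec, cells_per_zone,
                               positive_fraction_per_zone = 0.5,
                               stain = stain_model("h-dab"),
                               nucleus_diameter_um = 8, ring_um = 3,
                               compartment = c("cell", "cytoplasm"),
                               nucleus_od = 0.8, dab_od = 0.5,
                               tissue_od = 0.04) {
  stopifnot(inherits(spec, "slide_spec"))
  compartment <- match.arg(compartment)
  ann <- make_zone_annotation(spec)
  h <- spec$height_px; w <- spec$width_px
  mpp <- spec$microns_per_px
  r_nuc <- max(1, nucleus_diameter_um / 2 / mpp)
  r_ring <- r_nuc + ring_um / mpp
  if (is.null(names(cells_per_zone))) stop("`cells_per_zone` must be named")
  pf <- positive_fraction_per_zone
  if (length(pf) == 1 && is.null(names(pf))) {
    pf <- stats::setNames(rep(pf, length(cells_per_zone)),
                          names(cells_per_zone))
  }
  code_of <- function(cl) match(cl, zone_classes()) - 1L
  # keep each nucleus clear of every neighbour's compartment, so that a
  # negative cell's compartment picks up at most a sliver of DAB
  min_dist <- r_nuc + r_ring + 2
  cells <- with_seed(spec$seed + 101L, {
    out <- list()
    placed <- matrix(numeric(0), 0, 2)
    for (z in names(cells_per_zone)) {
      n <- cells_per_zone[[z]]
      if (n <= 0) next
      # candidate centroids: zone pixels with full cell compartment inside
      zmask <- ann == code_of(z)
      er <- EBImage::erode(EBImage::Image(t(zmask)),
                           EBImage::makeBrush(2 * ceiling(r_ring) + 3, "disc"))
      cand <- which(t(as.matrix(er)) > 0)
      if (length(cand) < n) {
        stop("zone ", z, " too small for ", n, " cells")
      }
      got <- 0; tries <- 0
      pts <- matrix(0, n, 2)
      while (got < n) {
        tries <- tries + 1
        if (tries > 200 * n) {
          stop("cell density too high for non-overlapping placement in ", z)
        }
        i <- sample(cand, 1)
        y <- (i - 1) %% h + 1; x <- (i - 1) %/% h + 1
        all_pts <- rbind(placed, pts[seq_len(got), , drop = FALSE])
        if (nrow(all_pts) == 0 ||
            min((all_pts[, 1] - y)^2 + (all_pts[, 2] - x)^2) >= min_dist^2) {
          got <- got + 1
          pts[got, ] <- c(y, x)
        }
      }
      placed <- rbind(placed, pts)
      n_pos <- round(pf[[z]] * n)
      pos <- rep(FALSE, n)
      if (n_pos > 0) pos[sample.int(n, n_pos)] <- TRUE
      out[[z]] <- data.frame(y = pts[, 1], x = pts[, 2], zone = z,
                             positive = pos)
    }
    if (length(out) == 0) NULL else
      do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
  if (is.null(cells)) {
    cells <- data.frame(y = numeric(0), x = numeric(0), zone = character(0),
                        positive = logical(0))
  }
  # forward render: per-pixel hematoxylin and DAB OD concentration maps
  c_h <- matrix(0, h, w)
  tissue <- !(ann %in% c(code_of("background"), code_of("ignore")))
  c_h[tissue] <- tissue_od
  c_d <- matrix(0, h, w)
  yy <- matrix(seq_len(h), h, w); xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  for (i in seq_len(nrow(cells))) {
    d2 <- (yy - cells$y[i])^2 + (xx - cells$x[i])^2
    nuc <- d2 <= r_nuc^2
    c_h[nuc] <- nucleus_od
    if (cells$positive[i]) {
      comp <- if (compartment == "cell") d2 <= r_ring^2 else
        (d2 <= r_ring^2 & !nuc)
      c_d[comp] <- pmax(c_d[comp], dab_od)
    }
  }
  od <- array(0, c(h, w, 3))
  V <- stain_vectors(stain)
  for (ch in 1:3) od[, , ch] <- c_h * V[1, ch] + c_d * V[2, ch]
  img <- 10^(-od)
  if (spec$noise_sd > 0) {
    img <- with_seed(spec$seed + 202L, {
      img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
    })
  }
  img <- pmin(pmax(img, 0), 1)
  counts <- do.call(rbind, lapply(split(cells, cells$zone), function(d) {
    data.frame(zone = d$zone[1], n_cells = nrow(d),
               n_positive = sum(d$positive))
  }))
  rownames(counts) <- NULL
  truth <- structure(list(annotation = ann, planted_cells = cells,
                          per_zone_counts = counts,
                          microns_per_px = spec$microns_per_px,
                          compartment = compartment, dab_od = dab_od),
                     class = "synthetic_truth")
  list(image = img, truth = truth)
}

#' Write an RGB image as 24-bit PNG
#' @param image h x w x 3 array in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(image, path)
  invisible(path)
}

#' Read an RGB PNG into the package's array convention
#' @param path PNG path.
#' @return h x w x 3 numeric array in `[0, 1]`.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE][, , 1:3]
}

#' Write an annotation map as a palette-coloured PNG
#'
#' Each class code is rendered in its exact palette colour, so
#' [read_annotation_png()] recovers the label raster pixel-exactly.
#'
#' @param annotation Integer matrix, 0-based class codes.
#' @param path Output path.
#' @param palette Named colours, one per class (default [zone_palette()]).
#' @return `path`, invisibly.
#' @export
write_annotation_png <- function(annotation, path, palette = zone_palette()) {
  rgb <- grDevices::col2rgb(palette) / 255
  h <- nrow(annotation); w <- ncol(annotation)
  img <- array(0, c(h, w, 3))
  for (ch in 1:3) {
    img[, , ch] <- matrix(rgb[ch, annotation + 1L], h, w)
  }
  png::writePNG(img, path)
  invisible(path)
}

#' Read a palette-coloured annotation PNG back to class codes
#' @param path PNG path.
#' @param palette Named colours used when writing.
#' @return Integer matrix of 0-based class codes.
#' @export
read_annotation_png <- function(path, palette = zone_palette()) {
  img <- png::readPNG(path)
  rgb <- round(grDevices::col2rgb(palette))
  key <- rgb[1, ] * 65536 + rgb[2, ] * 256 + rgb[3, ]
  px <- round(img[, , 1] * 255) * 65536 + round(img[, , 2] * 255) * 256 +
    round(img[, , 3] * 255)
  code <- match(px, key) - 1L
  if (anyNA(code)) stop("annotation PNG contains colours outside the palette")
  matrix(code, nrow(px), ncol(px))
}
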