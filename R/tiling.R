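# Mosaic creation, ignore-based tile filtering, and probability stitching.
# Tile origins are 0-based pixel offsets, (x = column, y = row), top-left
# origin, matching the paired-PNG naming convention used on disk.

# Start offsets covering [0, total) with back-shifted final window.
tile_starts <- function(total, tile, stride) {
  s <- seq(0L, max(total - tile, 0L), by = stride)
  if (s[length(s)] + tile < total) s <- c(s, total - tile)
  as.integer(s)
}

#' Convert a slide and its annotation into a mosaic of paired tiles
#'
#' Cuts the slide into overlapping `tile_size` x `tile_size` tiles covering
#' every pixel at least once; the final row/column of tiles is back-shifted
#' to stay in bounds rather than padded. Tile dimensions must be divisible
#' by the network scaling factor S = 2^n (n pooling/strided-scaling
#' operations) to scale properly through the network.
#'
#' @param image h x w x 3 slide raster.
#' @param annotation Integer label matrix, same h x w.
#' @param tile_size Tile edge in pixels (default 384).
#' @param stride Step between tile origins; default `tile_size / 2`
#'   (50% overlap).
#' @param scaling_factor Divisibility requirement S (default 16, i.e.
#'   n = 4).
#' @param slide_id Identifier recorded on each tile.
#' @return A `zq_mosaic`: list of tile records, each with `input`,
#'   `target`, `origin` (x, y) and `slide_id`; attributes record the slide
#'   dimensions and tiling parameters.
#' @export
make_mosaic <- function(image, annotation, tile_size = 384L,
                        stride = tile_size %/% 2L, scaling_factor = 16L,
                        slide_id = "slide") {
  h <- dim(image)[1]; w <- dim(image)[2]
  if (!is.null(annotation) && !all(dim(annotation) == c(h, w))) {
    stop("annotation dimensions must match the slide")
  }
  if (tile_size %% scaling_factor != 0) {
    stop("tile_size ", tile_size, " is not divisible by the scaling factor S = ",
         scaling_factor)
  }
  if (stride <= 0 || stride > tile_size) {
    stop("stride must be in (0, tile_size]")
  }
  if (h < tile_size || w < tile_size) {
    stop("slide (", h, "x", w, ") is smaller than the tile size ", tile_size)
  }
  xs <- tile_starts(w, tile_size, stride)
  ys <- tile_starts(h, tile_size, stride)
  tiles <- vector("list", length(xs) * length(ys))
  k <- 0
  for (y0 in ys) for (x0 in xs) {
    k <- k + 1
    tiles[[k]] <- list(
      input = image[y0 + seq_len(tile_size), x0 + seq_len(tile_size), ,
                    drop = FALSE],
      target = if (is.null(annotation)) NULL else
        annotation[y0 + seq_len(tile_size), x0 + seq_len(tile_size)],
      origin = c(x = x0, y = y0), slide_id = slide_id)
  }
  structure(tiles, class = "zq_mosaic",
            slide_dim = c(h = h, w = w), tile_size = as.integer(tile_size),
            stride = as.integer(stride))
}

#' Fraction of ignore-labelled pixels in a target tile
#' @param target Integer label matrix.
#' @param ignore_code 0-based code of the ignore class (default 0).
#' @return Fraction in `[0, 1]`.
#' @export
tile_ignore_fraction <- function(target, ignore_code = 0L) {
  mean(target == ignore_code)
}

#' Decide whether a tile is kept or discarded
#'
#' Tiles with more than 90% of pixels labelled ignore are discarded; all
#' others are kept. Tiles under 10% ignore are additionally flagged as
#' "clean" -- metadata only, retained to avoid discarding scarce classes.
#'
#' @param target Integer label tile.
#' @param max_ignore Discard threshold on the ignore fraction (default
#'   0.9).
#' @param clean_ignore Clean-flag threshold (default 0.1).
#' @param ignore_code 0-based ignore code.
#' @return `"keep"` or `"discard"`, with attribute `clean`.
#' @export
filter_tile <- function(target, max_ignore = 0.9, clean_ignore = 0.1,
                        ignore_code = 0L) {
  f <- tile_ignore_fraction(target, ignore_code)
  structure(if (f > max_ignore) "discard" else "keep", clean = f < clean_ignore)
}

#' Filter a mosaic by ignore content
#'
#' @param mosaic A `zq_mosaic`.
#' @inheritParams filter_tile
#' @return The filtered `zq_mosaic`; each kept tile gains a `clean` flag.
#' @export
filter_mosaic <- function(mosaic, max_ignore = 0.9, clean_ignore = 0.1,
                          ignore_code = 0L) {
  keep <- vapply(mosaic, function(t) {
    tile_ignore_fraction(t$target, ignore_code) <= max_ignore
  }, logical(1))
  out <- mosaic[keep]
  out <- lapply(out, function(t) {
    t$clean <- tile_ignore_fraction(t$target, ignore_code) < clean_ignore
    t
  })
  attributes(out) <- c(attributes(out),
                       attributes(mosaic)[c("slide_dim", "tile_size",
                                            "stride")])
  class(out) <- "zq_mosaic"
  out
}

#' Stitch per-tile class probabilities back into a whole-slide map
#'
#' Overlapping probabilities are averaged per pixel, then the class with
#' the highest mean probability is taken (ties resolved to the earliest
#' class in the ordering), yielding a deterministic annotation map.
#'
#' @param tiles List of records with `origin` (x, y, 0-based) and `probs`
#'   (tile_h x tile_w x n_classes array).
#' @param slide_dim c(h, w) of the slide.
#' @param n_classes Number of classes (default 5).
#' @return List with `labels` (integer matrix of 0-based argmax codes) and
#'   `probs` (averaged h x w x n_classes array).
#' @export
stitch_predictions <- function(tiles, slide_dim, n_classes = 5L) {
  h <- slide_dim[[1]]; w <- slide_dim[[2]]
  acc <- array(0, c(h, w, n_classes))
  cnt <- matrix(0L, h, w)
  for (t in tiles) {
    p <- t$probs
    th <- dim(p)[1]; tw <- dim(p)[2]
    ys <- t$origin[["y"]] + seq_len(th); xs <- t$origin[["x"]] + seq_len(tw)
    if (max(ys) > h || max(xs) > w) stop("tile extends beyond the slide")
    acc[ys, xs, ] <- acc[ys, xs, , drop = FALSE] + p
    cnt[ys, xs] <- cnt[ys, xs] + 1L
  }
  if (any(cnt == 0)) {
    gap <- which(cnt == 0, arr.ind = TRUE)[1, ]
    stop("tiles do not cover the slide: first uncovered pixel at row ",
         gap[1], ", col ", gap[2])
  }
  for (k in seq_len(n_classes)) acc[, , k] <- acc[, , k] / cnt
  flat <- matrix(acc, h * w, n_classes)
  labels <- matrix(max.col(flat, ties.method = "first") - 1L, h, w)
  list(labels = labels, probs = acc)
}

#' Write a mosaic to disk as paired PNG tiles plus a CSV manifest
#'
#' Inputs are written as 24-bit PNG and targets as palette-coloured PNG,
#' with filenames encoding the slide id and the tile origin.
#'
#' @param mosaic A `zq_mosaic`.
#' @param dir Output directory (created if needed).
#' @return Path of the manifest CSV, invisibly.
#' @export
write_mosaic <- function(mosaic, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(mosaic, function(t) {
    stem <- sprintf("%s_x%05d_y%05d", t$slide_id, t$origin[["x"]],
                    t$origin[["y"]])
    write_image_png(t$input, file.path(dir, paste0(stem, "_input.png")))
    if (!is.null(t$target)) {
      write_annotation_png(t$target, file.path(dir, paste0(stem, "_target.png")))
    }
    data.frame(slide_id = t$slide_id, x = t$origin[["x"]], y = t$origin[["y"]],
               input = paste0(stem, "_input.png"),
               target = if (is.null(t$target)) NA else
                 paste0(stem, "_target.png"))
  })
  manifest <- file.path(dir, "mosaic_manifest.csv")
  utils::write.csv(do.call(rbind, rows), manifest, row.names = FALSE)
  invisible(manifest)
}
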