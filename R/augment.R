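# Dataset normalization and input/target-consistent augmentation.
# Arithmetic transforms (value shift, gain, pixel dropout) touch the input
# only; geometric transforms (flips, rotation, scaling, elastic warp) are
# applied identically to input and target, the target resampled
# nearest-neighbour, with "reflect" boundary handling throughout.

#' Per-channel normalization statistics over a tile dataset
#'
#' Streams over every pixel of every input tile and returns per-channel
#' means and (population) standard deviations, the values used to
#' standardise tiles at batch assembly.
#'
#' @param tiles A `zq_mosaic` or plain list of h x w x 3 arrays (tile
#'   records with an `input` element are unwrapped).
#' @param computed_over Dataset identifier stored with the stats.
#' @return List of class `normalization_stats`: `mean`, `sd` (3 each),
#'   `n_pixels`, `computed_over`.
#' @export
fit_normalization <- function(tiles, computed_over = "training") {
  if (length(tiles) == 0) stop("cannot fit normalization on an empty dataset")
  s <- s2 <- numeric(3)
  n <- 0
  for (t in tiles) {
    x <- if (is.list(t)) t$input else t
    m <- matrix(x, ncol = 3)
    s <- s + colSums(m)
    s2 <- s2 + colSums(m^2)
    n <- n + nrow(m)
  }
  mu <- s / n
  va <- s2 / n - mu^2
  sd <- sqrt(pmax(va, 0))
  if (any(sd <= 0)) {
    stop("degenerate dataset: zero standard deviation in channel(s) ",
         paste(which(sd <= 0), collapse = ", "))
  }
  structure(list(mean = mu, sd = sd, n_pixels = n,
                 computed_over = computed_over),
            class = "normalization_stats")
}

#' Standardise a tile with fitted normalization statistics
#' @param tile h x w x 3 array.
#' @param stats A `normalization_stats`.
#' @return Standardised array ((x - mean)/sd per channel).
#' @export
normalize_tile <- function(tile, stats) {
  for (ch in 1:3) {
    tile[, , ch] <- (tile[, , ch] - stats$mean[ch]) / stats$sd[ch]
  }
  tile
}

#' Persist / restore normalization statistics as YAML
#' @param stats A `normalization_stats`.
#' @param path YAML path.
#' @return `path` invisibly; `read_normalization()` returns the stats.
#' @export
write_normalization <- function(stats, path) {
  yaml::write_yaml(lapply(unclass(stats), as.vector), path)
  invisible(path)
}

#' @rdname write_normalization
#' @export
read_normalization <- function(path) {
  x <- yaml::read_yaml(path)
  structure(list(mean = as.numeric(x$mean), sd = as.numeric(x$sd),
                 n_pixels = x$n_pixels, computed_over = x$computed_over),
            class = "normalization_stats")
}

#' Sample a randomized augmentation plan
#'
#' Each transform on the menu is independently included with probability
#' `p`; parameters are drawn from the ranges: additive value in
#' `[-0.07, 0.07]`, multiplicative gain in `[0.8, 1.2]`, dropout fraction
#' in `[0.10, 0.50]`, rotation angle in `[-90, 90]` degrees, scale factor
#' in `[0.8, 1.2]`, elastic warp with sigma 40.0 and alpha in `[50, 200]`.
#' Arithmetic transforms are input-only; geometric ones are pair-applied.
#'
#' @param seed Integer seed; the plan and its application are fully
#'   deterministic given the seed.
#' @param p Independent inclusion probability per transform (default 0.5).
#' @param elastic_sigma Smoothing sigma of the elastic displacement field.
#' @return An `augmentation_plan` list; transforms not selected are
#'   `NULL`/`FALSE`.
#' @export
augmentation_plan <- function(seed = sample.int(.Machine$integer.max, 1),
                              p = 0.5, elastic_sigma = 40.0) {
  with_seed(as.integer(seed), {
    inc <- stats::runif(8) < p
    structure(list(
      add = if (inc[1]) stats::runif(1, -0.07, 0.07) else NULL,
      mult = if (inc[2]) stats::runif(1, 0.8, 1.2) else NULL,
      dropout = if (inc[3]) stats::runif(1, 0.10, 0.50) else NULL,
      flip_ud = inc[4], flip_lr = inc[5],
      rotate = if (inc[6]) stats::runif(1, -90, 90) else NULL,
      scale = if (inc[7]) stats::runif(1, 0.8, 1.2) else NULL,
      elastic_alpha = if (inc[8]) stats::runif(1, 50, 200) else NULL,
      elastic_sigma = elastic_sigma, seed = as.integer(seed)),
      class = "augmentation_plan")
  })
}

# Fold continuous coordinates into [1, n] by mirror reflection.
reflect_coord <- function(v, n) {
  if (n == 1) return(rep(1, length(v)))
  per <- 2 * (n - 1)
  m <- (v - 1) %% per
  m <- abs(m)
  ifelse(m <= n - 1, m, per - m) + 1
}

# Bilinear sample of a single-channel matrix at continuous (sy, sx);
# returns a vector in the order of the supplied coordinates.
bilinear_sample <- function(m, sy, sx) {
  h <- nrow(m); w <- ncol(m)
  sy <- reflect_coord(as.vector(sy), h)
  sx <- reflect_coord(as.vector(sx), w)
  y0 <- pmin(floor(sy), h - 1); x0 <- pmin(floor(sx), w - 1)
  if (h == 1) y0 <- rep(1, length(sy))
  if (w == 1) x0 <- rep(1, length(sx))
  fy <- sy - y0; fx <- sx - x0
  y1 <- pmin(y0 + 1, h); x1 <- pmin(x0 + 1, w)
  v00 <- m[cbind(y0, x0)]; v01 <- m[cbind(y0, x1)]
  v10 <- m[cbind(y1, x0)]; v11 <- m[cbind(y1, x1)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

# Nearest-neighbour sample of a matrix at continuous (sy, sx).
nearest_sample <- function(m, sy, sx) {
  h <- nrow(m); w <- ncol(m)
  out_dim <- dim(sy)
  iy <- pmin(pmax(round(reflect_coord(as.vector(sy), h)), 1), h)
  ix <- pmin(pmax(round(reflect_coord(as.vector(sx), w)), 1), w)
  matrix(m[cbind(iy, ix)], out_dim[1], out_dim[2])
}

# Source coordinates for the combined affine (rotation + scaling about the
# tile centre) followed by an elastic displacement.
source_coords <- function(h, w, angle, scale, disp) {
  cy <- (h + 1) / 2; cx <- (w + 1) / 2
  dy <- matrix(seq_len(h), h, w) - cy
  dx <- matrix(seq_len(w), h, w, byrow = TRUE) - cx
  th <- -angle * pi / 180              # inverse rotation for backward map
  sy <- (sin(th) * dx + cos(th) * dy) / scale + cy
  sx <- (cos(th) * dx - sin(th) * dy) / scale + cx
  if (!is.null(disp)) {
    sy <- sy + disp$dy
    sx <- sx + disp$dx
  }
  list(sy = sy, sx = sx)
}

# Smoothed random displacement fields for the elastic transform
# (uniform field, Gaussian-smoothed with sigma, scaled by alpha).
elastic_fields <- function(h, w, sigma, alpha) {
  smooth <- function() {
    f <- matrix(stats::runif(h * w, -1, 1), h, w)
    as.matrix(EBImage::gblur(f, sigma = min(sigma, max(h, w) / 4),
                             radius = min(2 * ceiling(3 * sigma) + 1,
                                          2 * floor((min(h, w) - 1) / 2) + 1)))
  }
  list(dy = smooth() * alpha, dx = smooth() * alpha)
}

#' Apply an augmentation plan to an input/target tile pair
#'
#' Geometric transforms (flips, rotation, scaling, elastic warp) are
#' applied identically to input and target; the input is resampled
#' bilinearly and the target nearest-neighbour, both with reflect boundary
#' handling. Arithmetic transforms (additive shift, gain, pixel dropout to
#' black) touch the input only, operating on the `[0, 1]` intensity scale
#' with clipping.
#'
#' @param input h x w x 3 array in `[0, 1]`.
#' @param target Integer label matrix (or `NULL`).
#' @param plan An [augmentation_plan()].
#' @return List with augmented `input` and `target`.
#' @export
apply_augmentation <- function(input, target, plan) {
  stopifnot(inherits(plan, "augmentation_plan"))
  h <- dim(input)[1]; w <- dim(input)[2]
  if (isTRUE(plan$flip_ud)) {
    input <- input[h:1, , , drop = FALSE]
    if (!is.null(target)) target <- target[h:1, , drop = FALSE]
  }
  if (isTRUE(plan$flip_lr)) {
    input <- input[, w:1, , drop = FALSE]
    if (!is.null(target)) target <- target[, w:1, drop = FALSE]
  }
  angle <- if (is.null(plan$rotate)) 0 else plan$rotate
  scale <- if (is.null(plan$scale)) 1 else plan$scale
  disp <- if (!is.null(plan$elastic_alpha)) {
    with_seed(plan$seed + 1000L,
              elastic_fields(h, w, plan$elastic_sigma, plan$elastic_alpha))
  } else NULL
  if (angle != 0 || scale != 1 || !is.null(disp)) {
    sc <- source_coords(h, w, angle, scale, disp)
    warped <- array(0, dim(input))
    for (ch in 1:3) {
      warped[, , ch] <- matrix(bilinear_sample(input[, , ch], sc$sy, sc$sx),
                               h, w)
    }
    input <- warped
    if (!is.null(target)) target <- nearest_sample(target, sc$sy, sc$sx)
  }
  if (!is.null(plan$add)) input <- pmin(pmax(input + plan$add, 0), 1)
  if (!is.null(plan$mult)) input <- pmin(pmax(input * plan$mult, 0), 1)
  if (!is.null(plan$dropout)) {
    n_drop <- round(plan$dropout * h * w)
    idx <- with_seed(plan$seed + 2000L, sample.int(h * w, n_drop))
    for (ch in 1:3) {
      plane <- input[, , ch]
      plane[idx] <- 0
      input[, , ch] <- plane
    }
  }
  list(input = input, target = target)
}
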