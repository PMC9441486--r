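test_that("exact tiling of a divisible slide gives non-overlapping tiles", {
  img <- array(runif(768 * 768 * 3), c(768, 768, 3))
  ann <- matrix(0L, 768, 768)
  mo <- make_mosaic(img, ann, tile_size = 384, stride = 384)
  expect_length(mo, 4)
  origins <- t(vapply(mo, function(t) t$origin, numeric(2)))
  expect_setequal(paste(origins[, 1], origins[, 2]),
                  c("0 0", "384 0", "0 384", "384 384"))
})

test_that("tile size must be divisible by the scaling factor S = 2^n", {
  img <- array(0, c(400, 400, 3)); ann <- matrix(0L, 400, 400)
  expect_equal(384 %% 16, 0)  # n = 4 -> S = 16 accepts 384
  expect_error(make_mosaic(img, ann, tile_size = 200, scaling_factor = 16),
               "S = 16")
  expect_error(make_mosaic(img, ann, tile_size = 512), "smaller")
  expect_error(make_mosaic(img, ann, tile_size = 64, stride = 0), "stride")
})

test_that("mosaics cover every pixel and match the closed-form tile count", {
  for (dims in list(c(500, 500, 384, 192), c(200, 300, 64, 48),
                    c(129, 191, 64, 64))) {
    h <- dims[1]; w <- dims[2]; ts <- dims[3]; s <- dims[4]
    img <- array(0, c(h, w, 3)); ann <- matrix(0L, h, w)
    mo <- make_mosaic(img, ann, tile_size = ts, stride = s,
                      scaling_factor = 16)
    cover <- matrix(FALSE, h, w)
    for (t in mo) {
      ys <- t$origin[["y"]] + seq_len(ts); xs <- t$origin[["x"]] + seq_len(ts)
      expect_true(max(ys) <= h && max(xs) <= w)
      cover[ys, xs] <- TRUE
    }
    expect_true(all(cover))
    expect_length(mo, ceiling((w - ts) / s + 1) * ceiling((h - ts) / s + 1))
  }
})

test_that("filtering keeps/discards by ignore fraction with the 90% rule", {
  mk <- function(frac) {
    t <- matrix(1L, 100, 100)
    t[seq_len(frac * 10000)] <- 0L
    t
  }
  expect_equal(as.character(filter_tile(mk(0.95))), "discard")
  expect_equal(as.character(filter_tile(mk(0.05))), "keep")
  expect_equal(as.character(filter_tile(mk(0))), "keep")
  # the 10-90% band is kept but not flagged clean
  mid <- filter_tile(mk(0.5))
  expect_equal(as.character(mid), "keep")
  expect_false(attr(mid, "clean"))
  expect_true(attr(filter_tile(mk(0.05)), "clean"))
})

test_that("filtering is monotone in the ignore fraction", {
  set.seed(4)
  fracs <- runif(50)
  kept <- vapply(fracs, function(f) {
    t <- matrix(1L, 50, 50)
    t[seq_len(round(f * 2500))] <- 0L
    as.character(filter_tile(t)) == "keep"
  }, logical(1))
  # if a tile is discarded, every tile with a higher fraction is too
  if (any(!kept)) {
    expect_true(all(fracs[!kept] >= max(0.9, max(fracs[kept]) - 1e-9) |
                      fracs[!kept] > 0.9))
    expect_true(min(fracs[!kept]) >= max(fracs[kept]))
  }
})

test_that("stitching averages overlaps and matches a dense accumulator oracle", {
  set.seed(5)
  h <- 96; w <- 96; C <- 3
  tiles <- list()
  for (o in list(c(0, 0), c(32, 0), c(0, 32), c(32, 32))) {
    tiles[[length(tiles) + 1]] <- list(
      origin = c(x = o[1], y = o[2]),
      probs = array(runif(64 * 64 * C), c(64, 64, C)))
  }
  st <- stitch_predictions(tiles, c(h, w), C)
  acc <- array(0, c(h, w, C)); cnt <- matrix(0, h, w)
  for (t in tiles) for (y in 1:64) for (x in 1:64) {
    yy <- t$origin[["y"]] + y; xx <- t$origin[["x"]] + x
    acc[yy, xx, ] <- acc[yy, xx, ] + t$probs[y, x, ]
    cnt[yy, xx] <- cnt[yy, xx] + 1
  }
  for (k in 1:C) acc[, , k] <- acc[, , k] / cnt
  expect_equal(st$probs, acc, tolerance = 1e-12)
  expect_equal(st$labels,
               matrix(max.col(matrix(acc, h * w, C), "first") - 1L, h, w))
})

test_that("stitching is idempotent for identical overlapping tiles", {
  p <- array(runif(64 * 64 * 5), c(64, 64, 5))
  single <- stitch_predictions(list(list(origin = c(x = 0, y = 0), probs = p)),
                               c(64, 64), 5)
  twice <- stitch_predictions(list(list(origin = c(x = 0, y = 0), probs = p),
                                   list(origin = c(x = 0, y = 0), probs = p)),
                              c(64, 64), 5)
  expect_equal(single$labels, twice$labels)
  expect_error(stitch_predictions(list(list(origin = c(x = 0, y = 0),
                                            probs = p)), c(100, 64), 5),
               "uncovered")
})

test_that("one-hot stitching of an unfiltered mosaic reproduces the annotation", {
  s <- fx_weigert()
  mo <- make_mosaic(s$image, s$truth$annotation, 64, 32, 16)
  oneh <- lapply(mo, function(t) {
    p <- array(0, c(64, 64, 5))
    for (k in 0:4) p[, , k + 1] <- (t$target == k) * 1
    list(origin = t$origin, probs = p)
  })
  st <- stitch_predictions(oneh, dim(s$truth$annotation), 5)
  expect_identical_array(st$labels, s$truth$annotation)
})

test_that("mosaics round trip through the paired-PNG layout", {
  s <- fx_weigert()
  mo <- make_mosaic(s$image, s$truth$annotation, 64, 64, 16,
                    slide_id = "fx")
  d <- tempfile()
  manifest <- write_mosaic(mo, d)
  rows <- read.csv(manifest)
  expect_equal(nrow(rows), length(mo))
  back <- read_annotation_png(file.path(d, rows$target[1]))
  expect_identical_array(back, mo[[1]]$target)
})
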