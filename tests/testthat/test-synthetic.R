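test_that("slide generation is deterministic in the seed", {
  sp <- slide_spec(96, 96, seed = 7)
  a <- generate_weigert_slide(sp)
  b <- generate_weigert_slide(sp)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$annotation, b$truth$annotation)
  other <- generate_weigert_slide(slide_spec(96, 96, seed = 8))
  expect_false(identical(a$image, other$image))
})

test_that("fiber fractions are rendered at the requested per-zone rates", {
  sp <- slide_spec(256, 256, seed = 9,
                   fiber_fractions = list(
                     zone1 = c(elastin = 0.2, collagen = 0.3),
                     zone2 = c(elastin = 0, collagen = 0)))
  s <- generate_weigert_slide(sp)
  n1 <- s$truth$zone_px[["zone1"]]
  frac <- s$truth$per_zone_fiber_px["zone1", ] / n1
  expect_true(all(abs(frac - c(0.2, 0.3)) <= 0.01))
  expect_equal(unname(s$truth$per_zone_fiber_px["zone2", ]), c(0, 0))
  # counting rendered reference-colour pixels directly (zero noise render)
  sp0 <- slide_spec(256, 256, seed = 9, noise_sd = 0,
                    fiber_fractions = list(zone1 = c(elastin = 0.2,
                                                     collagen = 0.3)))
  s0 <- generate_weigert_slide(sp0)
  cols <- weigert_reference_colors()
  z1 <- s0$truth$annotation == 1L
  is_col <- abs(s0$image[, , 1] - cols$collagen[1]) < 1e-9 &
    abs(s0$image[, , 2] - cols$collagen[2]) < 1e-9
  expect_true(abs(sum(is_col & z1) / sum(z1) - 0.3) <= 0.01)
})

test_that("infeasible fiber fractions raise an explicit error", {
  expect_error(slide_spec(96, 96, fiber_fractions =
                            list(zone1 = c(elastin = 0.6, collagen = 0.6))),
               "cannot fit")
  expect_error(slide_spec(32, 32), "64")
})

test_that("planted cell truth is consistent with the annotation", {
  fx <- fx_ihc()
  cells <- fx$slide$truth$planted_cells
  ann <- fx$slide$truth$annotation
  codes <- match(cells$zone, zone_classes()) - 1L
  at <- ann[cbind(cells$y, cells$x)]
  expect_equal(at, codes)   # every centroid lies inside its recorded zone
  counts <- fx$slide$truth$per_zone_counts
  tallied <- aggregate(positive ~ zone, cells,
                       function(p) c(n = length(p), pos = sum(p)))
  expect_equal(counts$n_cells,
               tallied$positive[, "n"][match(counts$zone, tallied$zone)])
  expect_equal(counts$n_positive,
               tallied$positive[, "pos"][match(counts$zone, tallied$zone)])
})

test_that("positive fractions are honoured exactly at construction", {
  sp <- slide_spec(576, 576, seed = 21, band_radii = fx_wide_radii)
  s <- generate_ihc_slide(sp, cells_per_zone = c(zone1 = 40),
                          positive_fraction_per_zone = 0.5)
  expect_equal(s$truth$per_zone_counts$n_positive, 20)
  empty <- generate_ihc_slide(sp, cells_per_zone = c(zone1 = 0))
  expect_equal(nrow(empty$truth$planted_cells), 0)
})

test_that("infeasible cell density raises an explicit error", {
  sp <- slide_spec(128, 128, seed = 2, band_radii = fx_wide_radii)
  expect_error(generate_ihc_slide(sp, cells_per_zone = c(zone1 = 500)),
               "density|too small")
})

test_that("forward OD rendering makes detection an exact inverse at zero noise", {
  sp <- slide_spec(384, 384, seed = 4, noise_sd = 0,
                   band_radii = fx_wide_radii)
  s <- generate_ihc_slide(sp, cells_per_zone = c(zone1 = 10),
                          positive_fraction_per_zone = 1, dab_od = 0.5)
  conc <- unmix(od_transform(s$image), stain_model("h-dab"))
  cells <- s$truth$planted_cells
  r_cell <- (4 + 3) / sp$microns_per_px   # nucleus radius + ring, in px
  for (i in seq_len(nrow(cells))) {
    yy <- row(conc[, , 2]); xx <- col(conc[, , 2])
    comp <- (yy - cells$y[i])^2 + (xx - cells$x[i])^2 <= r_cell^2
    expect_gte(mean(conc[, , 2][comp]), 0.1)  # CD8 whole-cell threshold
  }
})

test_that("annotation PNG round trip is pixel-exact", {
  s <- fx_weigert()
  f <- tempfile(fileext = ".png")
  write_annotation_png(s$truth$annotation, f)
  expect_identical_array(read_annotation_png(f), s$truth$annotation)
  f2 <- tempfile(fileext = ".png")
  write_image_png(s$image, f2)
  back <- read_image_png(f2)
  expect_lt(max(abs(back - s$image)), 1 / 255)  # 8-bit quantisation only
})

test_that("blob geometry produces irregular but valid annotations", {
  sp <- slide_spec(128, 128, seed = 5, geometry = "blobs")
  s <- generate_weigert_slide(sp)
  expect_true(all(s$truth$annotation %in% 0:4))
  bands <- generate_weigert_slide(slide_spec(128, 128, seed = 5))
  expect_false(identical(s$truth$annotation, bands$truth$annotation))
})
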