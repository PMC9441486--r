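test_that("optical density transform matches its definition", {
  img <- array(1, c(4, 4, 3))
  expect_equal(od_transform(img), array(0, c(4, 4, 3)))
  expect_equal(od_transform(array(0.1, c(2, 2, 3)))[1, 1, 1], 1)  # I0/10
  set.seed(14)
  r <- array(runif(5 * 5 * 3, 0.05, 1), c(5, 5, 3))
  od <- od_transform(r)
  for (i in 1:5) for (j in 1:5) for (k in 1:3) {
    expect_equal(od[i, j, k], -log10(r[i, j, k]), tolerance = 1e-9)
  }
})

test_that("unmixing is the exact inverse of forward mixing", {
  sm <- stain_model("h-dab")
  V <- stain_vectors(sm)
  expect_equal(unname(sqrt(rowSums(V^2))), rep(1, 3))   # unit OD vectors
  # pure hematoxylin pixel -> concentration (1, 0, 0)
  od <- array(rep(V[1, ], each = 4), c(2, 2, 3))
  conc <- unmix(od, sm)
  expect_equal(as.vector(conc[1, 1, ]), c(1, 0, 0), tolerance = 1e-9)
  expect_equal(unmix(array(0, c(2, 2, 3)), sm),
               array(0, c(2, 2, 3)), tolerance = 1e-12, ignore_attr = TRUE)
  # random non-negative mixtures recovered within 1e-6
  set.seed(15)
  c0 <- array(runif(6 * 6 * 3, 0, 1.5), c(6, 6, 3))
  od2 <- array(matrix(c0, 36, 3) %*% V, c(6, 6, 3))
  expect_equal(unmix(od2, sm), c0, tolerance = 1e-6, ignore_attr = TRUE)
  expect_error(stain_model(vectors = matrix(1, 3, 3)), "singular")
})

test_that("marker presets carry the published detection settings", {
  cd8 <- detection_params("cd8")
  expect_equal(cd8$background_radius_um, 10.0)
  expect_equal(cd8$compartment, "cell")
  expect_equal(cd8$positive_threshold, 0.1)
  mpo <- detection_params("mpo")
  expect_equal(mpo$background_radius_um, 8.0)
  expect_equal(mpo$compartment, "cytoplasm")
  expect_equal(mpo$positive_threshold, 0.2)
})

test_that("a blank white image yields no detections", {
  blank <- array(1, c(64, 64, 3))
  det <- detect_cells(blank, detection_params("cd8"))
  expect_equal(nrow(det), 0)
})

test_that("zero-noise detection inverts the forward model exactly", {
  sp <- slide_spec(480, 480, seed = 16, noise_sd = 0,
                   band_radii = fx_wide_radii)
  s <- generate_ihc_slide(sp, cells_per_zone = c(zone1 = 30),
                          positive_fraction_per_zone = 0.5)
  det <- detect_cells(s$image, detection_params("cd8"),
                      microns_per_px = sp$microns_per_px)
  expect_equal(nrow(det), 30)
  expect_equal(sum(det$positive), 15)
})

test_that("MPO parameters threshold the cytoplasm compartment", {
  sp <- slide_spec(480, 480, seed = 17, noise_sd = 0,
                   band_radii = fx_wide_radii)
  s <- generate_ihc_slide(sp, cells_per_zone = c(zone1 = 20),
                          positive_fraction_per_zone = 0.5,
                          compartment = "cytoplasm", dab_od = 0.5)
  det <- detect_cells(s$image, detection_params("mpo"),
                      microns_per_px = sp$microns_per_px)
  expect_equal(nrow(det), 20)
  expect_equal(sum(det$positive), 10)
  # the flagged cells are exactly those with high cytoplasm DAB
  expect_equal(det$positive, det$dab_cytoplasm >= 0.2)
})

test_that("stained area is monotone in the OD threshold and zero without DAB", {
  fx <- fx_ihc()
  masks <- masks_from_prediction(fx$slide$truth$annotation,
                                 microns_per_px = fx$spec$microns_per_px)
  a1 <- stained_area(fx$slide$image, od_threshold = 0.15, masks = masks)
  a2 <- stained_area(fx$slide$image, od_threshold = 0.3, masks = masks)
  expect_true(all(a2$stained_mm2 <= a1$stained_mm2))
  hi <- stained_area(fx$slide$image, od_threshold = 10, masks = masks)
  expect_true(all(hi$stained_mm2 == 0))
  blank <- array(1, dim(fx$slide$image))
  z <- stained_area(blank, od_threshold = 0.2, masks = masks)
  expect_true(all(z$stained_mm2 == 0))
})

test_that("fiber classification recovers planted fractions and is either/or", {
  sp <- slide_spec(256, 256, seed = 9,
                   fiber_fractions = list(
                     zone1 = c(elastin = 0.2, collagen = 0.3),
                     zone2 = c(elastin = 0.05, collagen = 0.15)))
  s <- generate_weigert_slide(sp)
  masks <- masks_from_prediction(s$truth$annotation,
                                 microns_per_px = sp$microns_per_px)
  fib <- classify_fibers(s$image, stain_model("weigert"), masks)
  z1 <- fib[fib$class == "zone1", ]
  expect_true(z1$collagen_pct >= 29 && z1$collagen_pct <= 31)
  expect_true(abs(z1$elastin_pct - 20) <= 1)
  expect_true(all(fib$elastin_pct >= 0 & fib$elastin_pct <= 100))
  expect_true(all(fib$elastin_pct + fib$collagen_pct <= 100))
})

test_that("pixels below the minimum OD are classified as neither fiber", {
  img <- array(0.97, c(16, 16, 3))       # near-white: total OD ~ 0
  masks <- masks_from_prediction(matrix(1L, 16, 16), microns_per_px = 1)
  fib <- classify_fibers(img, stain_model("weigert"), masks)
  expect_equal(fib$elastin_pct[fib$class == "zone1"], 0)
  expect_equal(fib$collagen_pct[fib$class == "zone1"], 0)
})

test_that("zone report assigns every detection exactly once", {
  fx <- fx_ihc()
  det <- detect_cells(fx$slide$image, detection_params("cd8"),
                      microns_per_px = fx$spec$microns_per_px)
  masks <- masks_from_prediction(fx$slide$truth$annotation,
                                 microns_per_px = fx$spec$microns_per_px)
  rep <- zone_report(det, masks)
  expect_equal(sum(rep$detections), nrow(det))
  expect_true(all(rep$positives <= rep$detections))
  f <- tempfile(fileext = ".csv")
  write_zone_csv(rep, f)
  expect_true(file.exists(f))
})

test_that("derived report columns follow their guarded definitions", {
  rows <- zone_quant_rows(class = c("a", "b"), detections = c(10, 0),
                          positives = c(4, 0), area_mm2 = c(2, 0))
  expect_equal(rows$positive_pct, c(40, 0))
  expect_equal(rows$positives_per_mm2, c(2, 0))
  expect_error(zone_quant_rows("a", 5, 6, 1))   # positives > detections
})
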