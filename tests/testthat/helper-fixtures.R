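# Shared fixtures, built once per test run and cached.

.fx <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fx[[name]])) .fx[[name]] <- build()
  .fx[[name]]
}

# Small elastin-stained slide with default geometry.
fx_weigert <- function() fixture("weigert", function() {
  generate_weigert_slide(slide_spec(128, 128, seed = 3))
})

# Geometry with a wide vascular-wall band, roomy enough for planted cells.
fx_wide_radii <- c(thrombus = 0.12, zone1 = 0.60, zone2 = 0.85,
                   background = 0.95)

# Immunostained slide with planted cells at moderate noise.
fx_ihc <- function() fixture("ihc", function() {
  sp <- slide_spec(576, 576, seed = 5, band_radii = fx_wide_radii)
  list(spec = sp,
       slide = generate_ihc_slide(sp, cells_per_zone = c(zone1 = 50,
                                                         zone2 = 30),
                                  positive_fraction_per_zone = 0.5))
})

# Training/validation mosaics for the learning tests (64-px tiles).
fx_mosaics <- function() fixture("mosaics", function() {
  tiles <- function(seed, stride) {
    s <- generate_weigert_slide(slide_spec(192, 192, seed = seed))
    filter_mosaic(make_mosaic(s$image, s$truth$annotation, tile_size = 64,
                              stride = stride, scaling_factor = 4))
  }
  tr <- c(unclass(tiles(11, 32)), unclass(tiles(12, 32)))
  class(tr) <- "zq_mosaic"
  list(train = tr, val = tiles(13, 32))
})

expect_identical_array <- function(a, b) {
  expect_identical(unname(a), unname(b))
}
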