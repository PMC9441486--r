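test_that("swish matches its closed form", {
  expect_equal(swish(0, 5), 0)
  x <- seq(-3, 3, by = 0.5)
  expect_equal(swish(x, 0), x / 2)                    # logistic(0) = 1/2
  expect_equal(swish(1, 1), 1 * plogis(1))
  expect_equal(swish(1, 1), 0.731059, tolerance = 1e-6)
})

test_that("network config validates tile size against depth", {
  cfg <- network_config(depth = 3, base_filters = 32, tile_size = 384)
  expect_equal(cfg$scaling, 8)
  expect_error(network_config(depth = 3, tile_size = 100), "divisible")
})

test_that("filter counts double per level: 32, 64, 128, 256 at depth 3", {
  cfg <- network_config(depth = 3, base_filters = 32, tile_size = 64)
  f <- cfg$base_filters * 2^(0:cfg$depth)
  expect_equal(f, c(32, 64, 128, 256))
  m <- build_unet(cfg, seed = 1)
  expect_equal(ncol(m$params[["enc3.c1.W"]]), 256)
  expect_equal(nrow(m$params[["enc3.c1.W"]]), 9 * 256)
})

test_that("convolution blocks preserve spatial dimensions", {
  cfg <- network_config(depth = 1, base_filters = 8, tile_size = 16)
  m <- build_unet(cfg, seed = 2)
  X <- matrix(runif(16 * 16 * 3), 256, 3)
  out <- zonequant:::cbs_fwd(m, "enc0.c1", X, 16, 16, B = 1, train = FALSE)
  expect_equal(c(out$h, out$w), c(16, 16))
  expect_equal(dim(out$Y), c(256, 8))
})

test_that("reflect padding keeps a constant field constant (no border falloff)", {
  cfg <- network_config(depth = 1, base_filters = 4, tile_size = 16)
  m <- build_unet(cfg, seed = 4)
  X <- matrix(1, 256, 3)
  cv <- zonequant:::conv_fwd(X, 16, 16, 1L, m$params[["enc0.c1.W"]])
  # with reflect padding every output pixel sees the same 3x3 patch
  expect_lt(max(apply(cv$Y, 2, function(col) diff(range(col)))), 1e-12)
})

test_that("output is a per-pixel distribution over classes", {
  cfg <- network_config(depth = 2, base_filters = 4, tile_size = 64)
  m <- build_unet(cfg, seed = 5)
  tile <- array(runif(64 * 64 * 3), c(64, 64, 3))
  p <- predict_tile(m, tile)
  expect_equal(dim(p), c(64, 64, 5))
  expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-5)
  # deterministic in inference mode
  expect_identical(p, predict_tile(m, tile))
  expect_error(predict_tile(m, tile[1:63, , ]), "divisible")
})

test_that("parameter count matches the closed form at depth 1", {
  f <- 4; cin <- 3; K <- 5
  cfg <- network_config(depth = 1, base_filters = f, tile_size = 16,
                        n_classes = K, in_channels = cin)
  m <- build_unet(cfg, seed = 6)
  cbs <- function(ci, co) 9 * ci * co + 2 * co + 1   # conv W + bn + swish
  expected <- cbs(cin, f) + cbs(f, f) +              # enc0
    cbs(f, 2 * f) +                                  # down1 (strided)
    cbs(2 * f, 2 * f) + cbs(2 * f, 2 * f) +          # enc1
    (2 * f) * (4 * f) + 2 * f + 1 +                  # up1 tconv + bn + swish
    cbs(2 * f, f) + cbs(f, f) +                      # dec1
    f * K + K                                        # softmax head
  expect_equal(n_parameters(m), expected)
  # doubling the base roughly quadruples convolution parameters
  m2 <- build_unet(network_config(depth = 1, base_filters = 2 * f,
                                  tile_size = 16, n_classes = K), seed = 6)
  expect_gt(n_parameters(m2) / n_parameters(m), 3)
})

test_that("a tiny forward+backward step runs within a second", {
  cfg <- network_config(depth = 2, base_filters = 4, tile_size = 64)
  m <- build_unet(cfg, seed = 7)
  X <- matrix(runif(4096 * 3), 4096, 3)
  labels <- sample(0:4, 4096, TRUE)
  g <- zonequant:::one_hot(labels, 5)
  elapsed <- system.time({
    fwd <- zonequant:::unet_fwd(m, X, 64, 64, B = 1, train = TRUE)
    sj <- zonequant:::soft_jaccard(fwd$probs, g, labels != 0, grad = TRUE)
    dlog <- fwd$probs * (sj$dP - rowSums(sj$dP * fwd$probs))
    zonequant:::unet_bwd(m, fwd, dlog)
  })[["elapsed"]]
  expect_lt(elapsed, 1)
})

test_that("backpropagation agrees with numerical differentiation", {
  set.seed(2)
  cfg <- network_config(depth = 1, base_filters = 2, tile_size = 8)
  m <- build_unet(cfg, seed = 3)
  B <- 2
  X <- matrix(runif(64 * B * 3), 64 * B, 3)
  labels <- sample(0:4, 64 * B, TRUE); labels[1:5] <- 0
  g <- zonequant:::one_hot(labels, 5)
  keep <- labels != 0
  fwd <- zonequant:::unet_fwd(m, X, 8, 8, B = B, train = TRUE)
  sj <- zonequant:::soft_jaccard(fwd$probs, g, keep, grad = TRUE)
  dlog <- fwd$probs * (sj$dP - rowSums(sj$dP * fwd$probs))
  gr <- zonequant:::unet_bwd(m, fwd, dlog)
  eps <- 1e-6
  loss_at <- function() {
    p <- zonequant:::unet_fwd(m, X, 8, 8, B, TRUE, FALSE)$probs
    zonequant:::soft_jaccard(p, g, keep)$loss
  }
  for (nm in sample(names(gr), 12)) {
    p0 <- m$params[[nm]]
    i <- sample(length(p0), 1)
    m$params[[nm]][i] <- p0[i] + eps; lp <- loss_at()
    m$params[[nm]][i] <- p0[i] - eps; lm <- loss_at()
    m$params[[nm]][i] <- p0[i]
    num <- (lp - lm) / (2 * eps)
    expect_lt(abs(num - gr[[nm]][i]) / max(1e-6, abs(num) + abs(gr[[nm]][i])),
              1e-3)
  }
})
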