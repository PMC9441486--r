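# A U-Net variant implemented natively: BSConv2 blocks (two repeats of a
# reflection-padded 3x3 convolution with linear activation, batch
# normalization, then a trainable Swish), strided-convolution down-scaling,
# transposed-convolution up-scaling, concatenation skip connections, He
# normal initialization, and a softmax head.
#
# Feature maps are carried as (B*HW x C) matrices: B tiles stacked
# tile-major, pixels in column-major raster order within each tile.
# Convolutions are im2col gather + BLAS matmul; convolutions feeding a
# batch-norm layer carry no bias (it would be absorbed by the
# normalization).

#' @useDynLib zonequant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

#' Swish activation
#'
#' The Swish activation x * logistic(beta * x); `beta` is a trainable
#' parameter of each activation layer (beta = 0 gives x/2, large beta
#' approaches ReLU).
#'
#' @param x Numeric input.
#' @param beta Slope parameter.
#' @return Numeric, same shape as `x`.
#' @export
swish <- function(x, beta = 1) {
  x / (1 + exp(-beta * x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- index caches for gather/scatter convolutions ----------------------

.zq_idx_cache <- new.env(parent = emptyenv())

# Mirror an integer coordinate into [1, n] (reflect-101 boundary).
reflect_int <- function(v, n) {
  v <- ifelse(v < 1, 2 - v, v)
  ifelse(v > n, 2 * n - v, v)
}

# Batched (B*HWo x 9) gather indices for a reflect-padded 3x3 convolution
# on an h x w raster with the given stride; cached per geometry.
conv3_idx <- function(h, w, stride, B) {
  key <- paste("c3", h, w, stride, B, sep = "_")
  if (!is.null(.zq_idx_cache[[key]])) return(.zq_idx_cache[[key]])
  ho <- if (stride == 1) h else h %/% stride
  wo <- if (stride == 1) w else w %/% stride
  yc <- rep(((seq_len(ho) - 1) * stride) + 1, times = wo)
  xc <- rep(((seq_len(wo) - 1) * stride) + 1, each = ho)
  idx <- matrix(0L, ho * wo, 9L)
  k <- 0
  for (kx in -1:1) for (ky in -1:1) {
    k <- k + 1
    yy <- reflect_int(yc + ky, h)
    xx <- reflect_int(xc + kx, w)
    idx[, k] <- as.integer((xx - 1) * h + yy)
  }
  if (B > 1) {
    idx <- idx[rep(seq_len(ho * wo), B), ] +
      rep((seq_len(B) - 1L) * h * w, each = ho * wo)
  }
  out <- list(idx = idx, ho = ho, wo = wo)
  .zq_idx_cache[[key]] <- out
  out
}

# Batched output indices of the 2x2-stride-2 transposed convolution:
# column k gives, for each input pixel, the output pixel receiving weight
# slice k.
tconv_idx <- function(h, w, B) {
  key <- paste("t2", h, w, B, sep = "_")
  if (!is.null(.zq_idx_cache[[key]])) return(.zq_idx_cache[[key]])
  ho <- 2L * h; wo <- 2L * w
  yi <- rep(seq_len(h), times = w)
  xi <- rep(seq_len(w), each = h)
  idx <- matrix(0L, h * w, 4L)
  k <- 0
  for (kx in 1:2) for (ky in 1:2) {
    k <- k + 1
    yy <- 2L * (yi - 1L) + ky
    xx <- 2L * (xi - 1L) + kx
    idx[, k] <- as.integer((xx - 1L) * ho + yy)
  }
  if (B > 1) {
    idx <- idx[rep(seq_len(h * w), B), ] +
      rep((seq_len(B) - 1L) * ho * wo, each = h * w)
  }
  out <- list(idx = idx, ho = ho, wo = wo)
  .zq_idx_cache[[key]] <- out
  out
}

# ---- primitive layers (forward returns a cache for backward) -----------

conv_fwd <- function(X, h, w, B, W, b = NULL, stride = 1L) {
  g <- conv3_idx(h, w, stride, B)
  P <- cpp_gather(X, g$idx)
  Y <- P %*% W
  if (!is.null(b)) Y <- Y + matrix(b, nrow(Y), length(b), byrow = TRUE)
  list(Y = Y, h = g$ho, w = g$wo,
       cache = list(P = P, idx = g$idx, HW = nrow(X), bias = !is.null(b)))
}

conv_bwd <- function(dY, cache, W) {
  dW <- crossprod(cache$P, dY)
  db <- if (cache$bias) colSums(dY) else NULL
  dP <- tcrossprod(dY, W)
  dX <- cpp_scatter_add(dP, cache$idx, cache$HW)
  list(dX = dX, dW = dW, db = db)
}

tconv_fwd <- function(X, h, w, B, W) {
  # W is (C_in x 4*C_out), slice k = columns (k-1)*C_out + 1 .. k*C_out
  g <- tconv_idx(h, w, B)
  co <- ncol(W) %/% 4L
  Y <- matrix(0, g$ho * g$wo * B, co)
  A <- X %*% W
  for (k in 1:4) {
    Y[g$idx[, k], ] <- A[, (k - 1) * co + seq_len(co), drop = FALSE]
  }
  list(Y = Y, h = g$ho, w = g$wo, cache = list(X = X, idx = g$idx, co = co))
}

tconv_bwd <- function(dY, cache, W) {
  co <- cache$co
  dA <- matrix(0, nrow(cache$X), 4 * co)
  for (k in 1:4) {
    dA[, (k - 1) * co + seq_len(co)] <- dY[cache$idx[, k], , drop = FALSE]
  }
  list(dX = tcrossprod(dA, W), dW = crossprod(cache$X, dA))
}

bn_fwd <- function(X, gamma, beta, state_key, model, train, eps = 1e-5,
                   momentum = 0.9) {
  if (train) {
    mu <- colMeans(X)
    va <- colMeans(X^2) - mu^2
    st <- model$state[[state_key]]
    model$state[[state_key]] <- list(
      mean = momentum * st$mean + (1 - momentum) * mu,
      var = momentum * st$var + (1 - momentum) * va)
  } else {
    st <- model$state[[state_key]]
    mu <- st$mean; va <- st$var
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- cpp_col_affine(X, inv, -mu * inv)
  Y <- cpp_col_affine(xhat, gamma, beta)
  list(Y = Y, cache = list(xhat = xhat, inv = inv))
}

bn_bwd <- function(dY, cache, gamma) {
  dgamma <- cpp_colsums_prod(dY, cache$xhat)
  dbeta <- colSums(dY)
  dX <- cpp_bn_bwd_dx(dY, cache$xhat, gamma, cache$inv, dgamma, dbeta)
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

swish_fwd <- function(X, beta) {
  s <- 1 / (1 + exp(-beta * X))
  list(Y = X * s, cache = list(X = X, s = s, beta = beta))
}

swish_bwd <- function(dY, cache) {
  s <- cache$s; X <- cache$X; b <- cache$beta
  sp <- s * (1 - s)
  dX <- dY * (s + b * X * sp)
  dbeta <- sum(dY * X^2 * sp)
  list(dX = dX, dbeta = dbeta)
}

# ---- network configuration and construction ----------------------------

#' Configuration of the segmentation network
#'
#' @param depth Number of levels below the surface level (default 3; the
#'   filter count doubles and the spatial dimensions halve at each level).
#' @param base_filters Filters per convolution at the surface level
#'   (default 32).
#' @param n_classes Output classes (default 5).
#' @param tile_size Input tile edge; must be divisible by 2^depth.
#' @param in_channels Input channels (RGB = 3).
#' @param swish_beta_init Initial value of every trainable Swish beta
#'   (default 1, recovering standard Swish).
#' @return A `network_config` list; `$scaling` carries S = 2^depth.
#' @export
network_config <- function(depth = 3L, base_filters = 32L, n_classes = 5L,
                           tile_size = 384L, in_channels = 3L,
                           swish_beta_init = 1.0) {
  if (tile_size %% 2^depth != 0) {
    stop("tile_size ", tile_size, " is incompatible with depth ", depth,
         ": must be divisible by 2^depth = ", 2^depth)
  }
  structure(list(depth = as.integer(depth),
                 base_filters = as.integer(base_filters),
                 n_classes = as.integer(n_classes),
                 tile_size = as.integer(tile_size),
                 in_channels = as.integer(in_channels),
                 swish_beta_init = swish_beta_init,
                 scaling = as.integer(2^depth)),
            class = "network_config")
}

he_normal <- function(fan_in, n) {
  stats::rnorm(n, 0, sqrt(2 / fan_in))
}

init_bn_swish <- function(model, prefix, c, cfg) {
  model$params[[paste0(prefix, ".gamma")]] <- rep(1, c)
  model$params[[paste0(prefix, ".beta")]] <- numeric(c)
  model$params[[paste0(prefix, ".sbeta")]] <- cfg$swish_beta_init
  model$state[[prefix]] <- list(mean = numeric(c), var = rep(1, c))
  model
}

# conv (no bias; batch norm follows) + bn + swish parameter block
init_cbs <- function(model, prefix, cin, cout, cfg) {
  model$params[[paste0(prefix, ".W")]] <-
    matrix(he_normal(9 * cin, 9 * cin * cout), 9 * cin, cout)
  init_bn_swish(model, prefix, cout, cfg)
}

#' Build the U-Net model
#'
#' Constructs the encoder/decoder with `depth` levels below the surface,
#' concatenation skip connections, stride-2 convolution down-scaling,
#' 2x2-stride-2 transposed-convolution up-scaling, and a 1x1 softmax head;
#' all weights drawn from the He normal scheme. Convolutions followed by
#' batch normalization carry no bias term (it would be absorbed by the
#' normalization); the head convolution keeps one.
#'
#' @param cfg A [network_config()].
#' @param seed Integer seed for weight initialization.
#' @return A `zq_unet` object (environment with `params`, `state`, `cfg`).
#' @export
build_unet <- function(cfg = network_config(), seed = 1L) {
  model <- new.env(parent = emptyenv())
  model$cfg <- cfg
  model$params <- list()
  model$state <- list()
  f <- cfg$base_filters * 2^(0:cfg$depth)
  with_seed(seed, {
    model <- init_cbs(model, "enc0.c1", cfg$in_channels, f[1], cfg)
    model <- init_cbs(model, "enc0.c2", f[1], f[1], cfg)
    for (k in seq_len(cfg$depth)) {
      model <- init_cbs(model, paste0("down", k), f[k], f[k + 1], cfg)
      model <- init_cbs(model, paste0("enc", k, ".c1"), f[k + 1], f[k + 1], cfg)
      model <- init_cbs(model, paste0("enc", k, ".c2"), f[k + 1], f[k + 1], cfg)
    }
    for (k in rev(seq_len(cfg$depth))) {
      # transposed conv: W is (C_in x 4*C_out), batch norm follows
      model$params[[paste0("up", k, ".W")]] <-
        matrix(he_normal(f[k + 1], f[k + 1] * 4 * f[k]), f[k + 1], 4 * f[k])
      model <- init_bn_swish(model, paste0("up", k), f[k], cfg)
      model <- init_cbs(model, paste0("dec", k, ".c1"), 2 * f[k], f[k], cfg)
      model <- init_cbs(model, paste0("dec", k, ".c2"), f[k], f[k], cfg)
    }
    model$params[["head.W"]] <-
      matrix(he_normal(f[1], f[1] * cfg$n_classes), f[1], cfg$n_classes)
    model$params[["head.b"]] <- numeric(cfg$n_classes)
  })
  class(model) <- "zq_unet"
  model
}

#' Number of trainable parameters of a model
#' @param object A `zq_unet`.
#' @param ... Unused.
#' @return Integer parameter count.
#' @export
n_parameters <- function(object, ...) {
  sum(vapply(object$params, length, integer(1)))
}

# conv(+bn+swish) unit; returns Y and a cache list.
cbs_fwd <- function(model, prefix, X, h, w, B, stride = 1L, train = TRUE) {
  p <- model$params
  cv <- conv_fwd(X, h, w, B, p[[paste0(prefix, ".W")]], stride = stride)
  bn <- bn_fwd(cv$Y, p[[paste0(prefix, ".gamma")]],
               p[[paste0(prefix, ".beta")]], prefix, model, train)
  sw <- swish_fwd(bn$Y, p[[paste0(prefix, ".sbeta")]])
  list(Y = sw$Y, h = cv$h, w = cv$w,
       cache = list(cv = cv$cache, bn = bn$cache, sw = sw$cache))
}

cbs_bwd <- function(model, prefix, dY, cache, grads) {
  p <- model$params
  sw <- swish_bwd(dY, cache$sw)
  grads[[paste0(prefix, ".sbeta")]] <-
    (grads[[paste0(prefix, ".sbeta")]] %||% 0) + sw$dbeta
  bn <- bn_bwd(sw$dX, cache$bn, p[[paste0(prefix, ".gamma")]])
  grads[[paste0(prefix, ".gamma")]] <-
    (grads[[paste0(prefix, ".gamma")]] %||% 0) + bn$dgamma
  grads[[paste0(prefix, ".beta")]] <-
    (grads[[paste0(prefix, ".beta")]] %||% 0) + bn$dbeta
  cv <- conv_bwd(bn$dX, cache$cv, p[[paste0(prefix, ".W")]])
  grads[[paste0(prefix, ".W")]] <- (grads[[paste0(prefix, ".W")]] %||% 0) + cv$dW
  list(dX = cv$dX, grads = grads)
}

# Full forward pass on a batch: X is (B*HW x C), tiles stacked tile-major.
unet_fwd <- function(model, X, h, w, B = 1L, train = TRUE,
                     keep_cache = train) {
  cfg <- model$cfg
  caches <- list()
  skips <- list()
  a <- cbs_fwd(model, "enc0.c1", X, h, w, B, train = train)
  caches$enc0.c1 <- a$cache
  b <- cbs_fwd(model, "enc0.c2", a$Y, a$h, a$w, B, train = train)
  caches$enc0.c2 <- b$cache
  cur <- b; skips[["0"]] <- b$Y
  for (k in seq_len(cfg$depth)) {
    d <- cbs_fwd(model, paste0("down", k), cur$Y, cur$h, cur$w, B,
                 stride = 2L, train = train)
    caches[[paste0("down", k)]] <- d$cache
    e1 <- cbs_fwd(model, paste0("enc", k, ".c1"), d$Y, d$h, d$w, B,
                  train = train)
    caches[[paste0("enc", k, ".c1")]] <- e1$cache
    e2 <- cbs_fwd(model, paste0("enc", k, ".c2"), e1$Y, e1$h, e1$w, B,
                  train = train)
    caches[[paste0("enc", k, ".c2")]] <- e2$cache
    cur <- e2
    if (k < cfg$depth) skips[[as.character(k)]] <- e2$Y
  }
  for (k in rev(seq_len(cfg$depth))) {
    p <- model$params
    up <- tconv_fwd(cur$Y, cur$h, cur$w, B, p[[paste0("up", k, ".W")]])
    bn <- bn_fwd(up$Y, p[[paste0("up", k, ".gamma")]],
                 p[[paste0("up", k, ".beta")]], paste0("up", k), model, train)
    sw <- swish_fwd(bn$Y, p[[paste0("up", k, ".sbeta")]])
    caches[[paste0("up", k)]] <- list(tc = up$cache, bn = bn$cache,
                                      sw = sw$cache)
    cat_in <- cbind(sw$Y, skips[[as.character(k - 1)]])
    caches[[paste0("cat", k)]] <- ncol(sw$Y)
    d1 <- cbs_fwd(model, paste0("dec", k, ".c1"), cat_in, up$h, up$w, B,
                  train = train)
    caches[[paste0("dec", k, ".c1")]] <- d1$cache
    d2 <- cbs_fwd(model, paste0("dec", k, ".c2"), d1$Y, d1$h, d1$w, B,
                  train = train)
    caches[[paste0("dec", k, ".c2")]] <- d2$cache
    cur <- d2
  }
  logits <- cur$Y %*% model$params[["head.W"]]
  logits <- logits + matrix(model$params[["head.b"]], nrow(logits),
                            ncol(logits), byrow = TRUE)
  caches$head <- list(X = cur$Y)
  ex <- exp(logits - apply(logits, 1, max))
  probs <- ex / rowSums(ex)
  list(logits = logits, probs = probs, h = cur$h, w = cur$w, B = B,
       caches = if (keep_cache) caches else NULL)
}

# Backward pass from dlogits; returns grads (named list, same shapes).
unet_bwd <- function(model, fwd, dlogits) {
  cfg <- model$cfg
  caches <- fwd$caches
  grads <- list()
  grads[["head.W"]] <- crossprod(caches$head$X, dlogits)
  grads[["head.b"]] <- colSums(dlogits)
  dX <- tcrossprod(dlogits, model$params[["head.W"]])
  skip_grads <- list()
  # decoder blocks, in reverse forward order: dec1/up1, dec2/up2, ...
  for (k in seq_len(cfg$depth)) {
    r <- cbs_bwd(model, paste0("dec", k, ".c2"), dX,
                 caches[[paste0("dec", k, ".c2")]], grads)
    grads <- r$grads
    r <- cbs_bwd(model, paste0("dec", k, ".c1"), r$dX,
                 caches[[paste0("dec", k, ".c1")]], grads)
    grads <- r$grads
    nup <- caches[[paste0("cat", k)]]
    d_up <- r$dX[, seq_len(nup), drop = FALSE]
    skip_grads[[as.character(k - 1)]] <-
      r$dX[, nup + seq_len(ncol(r$dX) - nup), drop = FALSE]
    uc <- caches[[paste0("up", k)]]
    sw <- swish_bwd(d_up, uc$sw)
    grads[[paste0("up", k, ".sbeta")]] <-
      (grads[[paste0("up", k, ".sbeta")]] %||% 0) + sw$dbeta
    bn <- bn_bwd(sw$dX, uc$bn, model$params[[paste0("up", k, ".gamma")]])
    grads[[paste0("up", k, ".gamma")]] <-
      (grads[[paste0("up", k, ".gamma")]] %||% 0) + bn$dgamma
    grads[[paste0("up", k, ".beta")]] <-
      (grads[[paste0("up", k, ".beta")]] %||% 0) + bn$dbeta
    tc <- tconv_bwd(bn$dX, uc$tc, model$params[[paste0("up", k, ".W")]])
    grads[[paste0("up", k, ".W")]] <-
      (grads[[paste0("up", k, ".W")]] %||% 0) + tc$dW
    dX <- tc$dX   # gradient at the output of the next-deeper block
  }
  # encoder levels in reverse, merging skip gradients collected above
  for (k in rev(seq_len(cfg$depth))) {
    if (k < cfg$depth) dX <- dX + skip_grads[[as.character(k)]]
    r <- cbs_bwd(model, paste0("enc", k, ".c2"), dX,
                 caches[[paste0("enc", k, ".c2")]], grads)
    grads <- r$grads
    r <- cbs_bwd(model, paste0("enc", k, ".c1"), r$dX,
                 caches[[paste0("enc", k, ".c1")]], grads)
    grads <- r$grads
    r <- cbs_bwd(model, paste0("down", k), r$dX,
                 caches[[paste0("down", k)]], grads)
    grads <- r$grads
    dX <- r$dX
  }
  r <- cbs_bwd(model, "enc0.c2", dX + skip_grads[["0"]],
               caches$enc0.c2, grads)
  grads <- r$grads
  r <- cbs_bwd(model, "enc0.c1", r$dX, caches$enc0.c1, grads)
  r$grads
}

#' Segment an image tile (or whole small raster) with a model
#'
#' Runs the forward pass in inference mode (batch-norm running statistics,
#' no caches) and returns per-pixel class probabilities.
#'
#' @param model A `zq_unet`.
#' @param tile h x w x 3 array (h, w divisible by the network scaling).
#' @param stats Optional `normalization_stats` applied before the forward
#'   pass.
#' @return h x w x n_classes array of class probabilities.
#' @export
predict_tile <- function(model, tile, stats = NULL) {
  if (!is.null(stats)) tile <- normalize_tile(tile, stats)
  h <- dim(tile)[1]; w <- dim(tile)[2]
  if (h %% model$cfg$scaling != 0 || w %% model$cfg$scaling != 0) {
    stop("tile dimensions must be divisible by the network scaling S = ",
         model$cfg$scaling)
  }
  X <- matrix(tile, h * w, dim(tile)[3])
  fwd <- unet_fwd(model, X, h, w, B = 1L, train = FALSE, keep_cache = FALSE)
  array(fwd$probs, c(h, w, model$cfg$n_classes))
}

#' @export
print.zq_unet <- function(x, ...) {
  cfg <- x$cfg
  f <- cfg$base_filters * 2^(0:cfg$depth)
  cat("U-Net variant (trainable Swish, reflection padding, strided scaling)\n")
  cat("  depth:", cfg$depth, " base filters:", cfg$base_filters,
      " classes:", cfg$n_classes, "\n")
  cat("  filters per level:", paste(f, collapse = ", "), "\n")
  cat("  trainable parameters:", n_parameters(x), "\n")
  invisible(x)
}
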