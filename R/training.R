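# Optimization loop: Adam on the squared soft-Jaccard loss with the ignore
# class masked out of numerator and denominator, per-epoch train/validation
# loss + Jaccard + F1 curves, and best-checkpoint selection by minimum
# validation loss.

# Loss and gradient on (HW x C) probability/one-hot matrices with a logical
# row keep-mask. L = 1 - I/U with I = sum(p*g), U = sum(p^2)+sum(g^2)-I.
soft_jaccard <- function(p, g, keep, grad = FALSE) {
  if (!any(keep)) stop("all pixels are ignored: loss undefined")
  pk <- p[keep, , drop = FALSE]
  gk <- g[keep, , drop = FALSE]
  I <- sum(pk * gk)
  U <- sum(pk^2) + sum(gk^2) - I
  loss <- 1 - I / U
  if (!grad) return(list(loss = loss))
  dP <- matrix(0, nrow(p), ncol(p))
  dP[keep, ] <- -(gk * U - I * (2 * pk - gk)) / U^2
  list(loss = loss, dP = dP)
}

#' Squared soft-Jaccard segmentation loss
#'
#' Computes 1 - I/U where I is the probability-weighted intersection
#' sum(p * g) and U = sum(p^2) + sum(g^2) - I, summed over every class and
#' every non-ignored pixel ("squared" refers to the squared terms in the
#' denominator of the soft Jaccard index). Pixels whose true label is the
#' ignore class are excluded from both numerator and denominator, so they
#' contribute no gradient.
#'
#' @param pred h x w x C array (or HW x C matrix) of class probabilities.
#' @param target Integer label matrix (0-based codes) or one-hot array of
#'   the same shape as `pred`.
#' @param ignore_class 0-based code of the class masked from the loss
#'   (default 0); `NULL` keeps every pixel.
#' @return Loss value in `[0, 1]`.
#' @export
squared_jaccard_loss <- function(pred, target, ignore_class = 0L) {
  C <- if (length(dim(pred)) == 3) dim(pred)[3] else ncol(pred)
  p <- matrix(pred, ncol = C)
  if (length(dim(target)) == 3 ||
      (is.matrix(target) && !is.null(dim(pred)) && length(dim(pred)) == 2 &&
       ncol(target) == C && nrow(target) == nrow(p))) {
    g <- matrix(target, ncol = C)
    labels <- max.col(g) - 1L
  } else {
    labels <- as.integer(target)
    g <- matrix(0, length(labels), C)
    g[cbind(seq_along(labels), labels + 1L)] <- 1
  }
  keep <- if (is.null(ignore_class)) rep(TRUE, nrow(p)) else
    labels != ignore_class
  soft_jaccard(p, g, keep)$loss
}

one_hot <- function(labels, C) {
  g <- matrix(0, length(labels), C)
  g[cbind(seq_along(labels), as.integer(labels) + 1L)] <- 1
  g
}

# Macro-averaged Jaccard and F1 over non-ignore classes with support,
# from pooled TP/FP/FN counts.
macro_metrics <- function(cm, ignore_code = 0L) {
  cm <- unclass(cm)
  keep <- seq_len(nrow(cm)) != (ignore_code + 1L)
  tp <- diag(cm)[keep]
  fp <- colSums(cm)[keep] - tp
  fn <- rowSums(cm)[keep] - tp
  has <- (tp + fn) > 0
  jac <- ifelse(tp + fp + fn > 0, tp / (tp + fp + fn), 0)
  f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), 0)
  c(jaccard = mean(jac[has]), f1 = mean(f1[has]))
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    m <- beta1 * (state$m[[nm]] %||% 0) + (1 - beta1) * g
    v <- beta2 * (state$v[[nm]] %||% 0) + (1 - beta2) * g^2
    state$m[[nm]] <- m
    state$v[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * (m / bc1) / (sqrt(v / bc2) + eps)
  }
  list(params = params, state = state)
}

# Stack a list of tiles (already normalized arrays) into a (B*HW x 3)
# matrix, tile-major.
stack_tiles <- function(arrays) {
  do.call(rbind, lapply(arrays, function(a) matrix(a, ncol = dim(a)[3])))
}

# Evaluate loss + macro metrics of a model over a mosaic (inference mode),
# processing tiles in batches.
evaluate_mosaic <- function(model, tiles, stats, n_classes,
                            ignore_code = 0L, batch_size = 8L) {
  total_loss <- 0; n_batches <- 0
  cm <- matrix(0L, n_classes, n_classes)
  cls <- as.character(seq_len(n_classes))
  h <- dim(tiles[[1]]$input)[1]; w <- dim(tiles[[1]]$input)[2]
  for (start in seq(1, length(tiles), by = batch_size)) {
    batch <- tiles[start:min(start + batch_size - 1, length(tiles))]
    X <- stack_tiles(lapply(batch, function(t)
      normalize_tile(t$input, stats)))
    labels <- unlist(lapply(batch, function(t) as.integer(t$target)))
    fwd <- unet_fwd(model, X, h, w, B = length(batch), train = FALSE,
                    keep_cache = FALSE)
    g <- one_hot(labels, n_classes)
    keep <- labels != ignore_code
    if (any(keep)) {
      total_loss <- total_loss + soft_jaccard(fwd$probs, g, keep)$loss
      n_batches <- n_batches + 1
    }
    pred <- max.col(fwd$probs, ties.method = "first") - 1L
    cm <- cm + unclass(confusion(matrix(pred[keep], ncol = 1),
                                 matrix(labels[keep], ncol = 1),
                                 class_order = cls))
  }
  mm <- macro_metrics(cm, ignore_code)
  list(loss = total_loss / max(n_batches, 1), jaccard = mm[["jaccard"]],
       f1 = mm[["f1"]], confusion = cm)
}

#' Fit the zone segmentation network
#'
#' Trains a U-Net variant ([build_unet()]) with the Adam optimizer on the
#' squared soft-Jaccard loss (ignore class masked out). After every epoch
#' the training and validation loss, macro Jaccard similarity index and
#' macro F1 (over non-ignore classes) are recorded, and the parameter set
#' with the lowest validation loss is retained as the fitted model.
#'
#' @param train_tiles Filtered `zq_mosaic` of training tile pairs.
#' @param val_tiles Filtered `zq_mosaic` used for validation.
#' @param cfg A [network_config()].
#' @param epochs Maximum training epochs (default 20).
#' @param lr Adam learning rate (default 1e-4).
#' @param batch_size Tiles per gradient step (default 8).
#' @param augment Apply randomized augmentation to training tiles
#'   (default `TRUE`).
#' @param p_augment Per-transform inclusion probability passed to
#'   [augmentation_plan()].
#' @param seed Seed controlling initialization, data order and
#'   augmentation.
#' @param target_val_jaccard Optional early-stop threshold: training ends
#'   once the validation macro Jaccard reaches it.
#' @param eval_train Also evaluate the training set after each epoch
#'   (default `TRUE`; disabling it halves the per-epoch evaluation cost
#'   and leaves the train metric columns `NA`).
#' @param verbose Print a line per epoch.
#' @return A `zoneseg_fit` object with elements `model` (best weights),
#'   `history` (per-epoch data frame), `best_epoch`, `normalization`,
#'   `cfg`.
#' @export
fit_zoneseg <- function(train_tiles, val_tiles, cfg = network_config(),
                        epochs = 20L, lr = 1e-4, batch_size = 8L,
                        augment = TRUE, p_augment = 0.5, seed = 1L,
                        target_val_jaccard = NULL, eval_train = TRUE,
                        verbose = FALSE) {
  if (length(train_tiles) == 0) stop("no training tiles")
  stats <- fit_normalization(train_tiles)
  model <- build_unet(cfg, seed = seed)
  C <- cfg$n_classes
  opt <- new.env(parent = emptyenv())
  opt$t <- 0; opt$m <- list(); opt$v <- list()
  history <- vector("list", epochs)
  best <- list(loss = Inf, epoch = NA_integer_)
  h <- dim(train_tiles[[1]]$input)[1]
  w <- dim(train_tiles[[1]]$input)[2]
  with_seed(seed + 7L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(length(train_tiles))
      tr_loss <- 0; n_steps <- 0
      for (start in seq(1, length(ord), by = batch_size)) {
        batch_ix <- ord[start:min(start + batch_size - 1, length(ord))]
        inputs <- vector("list", length(batch_ix))
        labels <- vector("list", length(batch_ix))
        for (j in seq_along(batch_ix)) {
          t <- train_tiles[[batch_ix[j]]]
          input <- t$input; target <- t$target
          if (augment) {
            plan <- augmentation_plan(sample.int(.Machine$integer.max, 1),
                                      p = p_augment)
            aug <- apply_augmentation(input, target, plan)
            input <- aug$input; target <- aug$target
          }
          inputs[[j]] <- normalize_tile(input, stats)
          labels[[j]] <- as.integer(target)
        }
        X <- stack_tiles(inputs)
        lab <- unlist(labels)
        keep <- lab != 0L
        if (!any(keep)) next
        B <- length(batch_ix)
        fwd <- unet_fwd(model, X, h, w, B = B, train = TRUE)
        g <- one_hot(lab, C)
        sj <- soft_jaccard(fwd$probs, g, keep, grad = TRUE)
        if (!is.finite(sj$loss)) {
          stop("training diverged: loss is not finite at epoch ", ep)
        }
        # softmax jacobian: dz = p * (dP - rowSums(dP * p))
        dlogits <- fwd$probs * (sj$dP - rowSums(sj$dP * fwd$probs))
        grads <- unet_bwd(model, fwd, dlogits)
        upd <- adam_step(model$params, grads, opt, lr)
        model$params <- upd$params
        tr_loss <- tr_loss + sj$loss
        n_steps <- n_steps + 1
      }
      tr <- if (eval_train) evaluate_mosaic(model, train_tiles, stats, C)
      else list(loss = tr_loss / max(n_steps, 1), jaccard = NA_real_,
                f1 = NA_real_)
      va <- evaluate_mosaic(model, val_tiles, stats, C)
      history[[ep]] <- data.frame(
        epoch = ep, train_loss = tr$loss, val_loss = va$loss,
        train_jaccard = tr$jaccard, val_jaccard = va$jaccard,
        train_f1 = tr$f1, val_f1 = va$f1)
      if (verbose) {
        message(sprintf(
          "epoch %3d  train loss %.4f  val loss %.4f  val JSI %.3f",
          ep, tr$loss, va$loss, va$jaccard))
      }
      if (va$loss < best$loss) {
        best <- list(loss = va$loss, epoch = ep,
                     params = model$params, state = model$state)
      }
      if (!is.null(target_val_jaccard) &&
          va$jaccard >= target_val_jaccard) break
    }
  })
  history <- do.call(rbind, history[!vapply(history, is.null, logical(1))])
  model$params <- best$params
  model$state <- best$state
  structure(list(model = model, history = history,
                 best_epoch = best$epoch, normalization = stats,
                 cfg = cfg, seed = seed, classes = zone_classes()),
            class = "zoneseg_fit")
}

#' @export
print.zoneseg_fit <- function(x, ...) {
  cat("Zone segmentation fit (U-Net variant)\n")
  cat("  epochs run:", nrow(x$history), "  best epoch:", x$best_epoch, "\n")
  b <- x$history[x$history$epoch == x$best_epoch, ]
  cat(sprintf("  best val loss %.4f  val JSI %.3f  val F1 %.3f\n",
              b$val_loss, b$val_jaccard, b$val_f1))
  invisible(x)
}

#' @export
summary.zoneseg_fit <- function(object, ...) {
  print(object)
  cat("  parameters:", n_parameters(object$model), "\n")
  cat("  normalization channel means:",
      paste(round(object$normalization$mean, 4), collapse = ", "), "\n")
  invisible(object$history)
}

#' Plot training and validation metric curves per epoch
#' @param x A `zoneseg_fit`.
#' @param ... Unused.
#' @export
plot.zoneseg_fit <- function(x, ...) {
  h <- x$history
  old <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "epoch",
                    ylab = "loss")
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "red"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_jaccard, h$val_jaccard),
                    type = "l", lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "macro Jaccard")
  graphics::abline(v = x$best_epoch, lty = 3)
  invisible(x)
}

#' Trainable Swish slopes of a fitted model
#' @param object A `zoneseg_fit`.
#' @param ... Unused.
#' @return Named numeric vector of fitted Swish beta parameters.
#' @export
coef.zoneseg_fit <- function(object, ...) {
  p <- object$model$params
  betas <- p[grepl("\\.sbeta$", names(p))]
  stats::setNames(unlist(betas), sub("\\.sbeta$", "", names(betas)))
}

#' Segment a whole slide with a fitted model
#'
#' Tiles the slide, runs inference per tile and stitches the per-class
#' probabilities back into a whole-slide annotation map (overlaps
#' averaged, then argmax).
#'
#' @param object A `zoneseg_fit`.
#' @param image h x w x 3 slide raster.
#' @param tile_size,stride Tiling parameters (default: the training tile
#'   size with 50% overlap).
#' @param ... Unused.
#' @return List with `labels` (integer annotation matrix) and `probs`.
#' @export
predict.zoneseg_fit <- function(object, image,
                                tile_size = object$cfg$tile_size,
                                stride = tile_size %/% 2L, ...) {
  mosaic <- make_mosaic(image, annotation = NULL, tile_size = tile_size,
                        stride = stride,
                        scaling_factor = object$cfg$scaling)
  preds <- lapply(mosaic, function(t) {
    list(origin = t$origin,
         probs = predict_tile(object$model, t$input,
                              stats = object$normalization))
  })
  stitch_predictions(preds, attr(mosaic, "slide_dim"),
                     n_classes = object$cfg$n_classes)
}

#' Write per-epoch training curves to CSV
#' @param fit A `zoneseg_fit`.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_training_log <- function(fit, path) {
  utils::write.csv(fit$history, path, row.names = FALSE)
  invisible(path)
}
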