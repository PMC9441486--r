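# Reproducible orchestration: a YAML-configurable pipeline running
# synthesize -> tile -> train -> segment -> masks -> quantify, with a run
# manifest recording seeds, parameters and output hashes. The thin command
# line wrapper in inst/cli/zonequant.R dispatches onto these functions.

#' Default pipeline configuration
#'
#' A small, fully synthetic configuration that runs end to end on one CPU:
#' three synthetic slides (two training, one validation), a compact
#' network, a short training schedule and CD8-style quantification.
#'
#' @param out_dir Output directory for all stages.
#' @param seed Master seed.
#' @return A `run_config` list (also writable/readable as YAML).
#' @export
default_run_config <- function(out_dir = tempfile("zonequant_run"),
                               seed = 1L) {
  structure(list(
    out_dir = out_dir, seed = as.integer(seed),
    slide = list(width_px = 256L, height_px = 256L, n_train = 2L,
                 noise_sd = 0.02,
                 band_radii = c(thrombus = 0.10, zone1 = 0.55,
                                zone2 = 0.90, background = 0.97)),
    tiling = list(tile_size = 64L, stride = 64L),
    network = list(depth = 2L, base_filters = 8L),
    training = list(epochs = 12L, lr = 1e-2, batch_size = 8L,
                    augment = FALSE),
    quantify = list(marker = "cd8", cells_per_zone = c(zone1 = 6, zone2 = 5),
                    positive_fraction = 0.5)),
    class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML path.
#' @return `read_run_config()` returns a `run_config`.
#' @export
read_run_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$quantify$cells_per_zone <- unlist(x$quantify$cells_per_zone)
  structure(x, class = "run_config")
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @return `write_run_config()` returns `path` invisibly.
#' @export
write_run_config <- function(config, path) {
  x <- unclass(config)
  # named atomic vectors lose names as YAML sequences; write maps instead
  x$quantify$cells_per_zone <- as.list(x$quantify$cells_per_zone)
  x$slide$band_radii <- as.list(x$slide$band_radii)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in order. Stage outputs are written under
#' `config$out_dir` and recorded in a manifest (`manifest.csv`) with file
#' hashes; a stage whose inputs are missing raises an error naming the
#' missing artifact. Identical configuration and seed give identical
#' outputs.
#'
#' @param config A `run_config`.
#' @param stages Character subset of
#'   `c("synthesize", "tile", "train", "segment", "masks", "quantify")`;
#'   default all, in order.
#' @return Invisibly, the manifest data frame.
#' @export
run_pipeline <- function(config = default_run_config(),
                         stages = c("synthesize", "tile", "train",
                                    "segment", "masks", "quantify")) {
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  env <- new.env(parent = emptyenv())
  manifest <- list()
  note <- function(stage, path) {
    manifest[[length(manifest) + 1]] <<- data.frame(
      stage = stage, path = path,
      md5 = if (file.exists(path)) unname(tools::md5sum(path)) else NA)
  }
  need <- function(stage, what, ok) {
    if (!ok) stop("stage '", stage, "' requires missing artifact: ", what)
  }
  sl <- config$slide
  if ("synthesize" %in% stages) {
    specs <- lapply(seq_len(sl$n_train + 1L), function(i) {
      slide_spec(sl$width_px, sl$height_px, noise_sd = sl$noise_sd,
                 band_radii = unlist(sl$band_radii),
                 seed = config$seed + i)
    })
    env$slides <- lapply(specs, generate_weigert_slide)
    env$specs <- specs
    for (i in seq_along(env$slides)) {
      p <- file.path(config$out_dir, sprintf("slide_%02d.png", i))
      write_image_png(env$slides[[i]]$image, p); note("synthesize", p)
      a <- file.path(config$out_dir, sprintf("slide_%02d_annotation.png", i))
      write_annotation_png(env$slides[[i]]$truth$annotation, a)
      note("synthesize", a)
    }
  }
  if ("tile" %in% stages) {
    need("tile", "synthetic slides", !is.null(env$slides))
    tl <- config$tiling
    env$mosaics <- lapply(seq_along(env$slides), function(i) {
      filter_mosaic(make_mosaic(env$slides[[i]]$image,
                                env$slides[[i]]$truth$annotation,
                                tile_size = tl$tile_size, stride = tl$stride,
                                scaling_factor = 2^config$network$depth,
                                slide_id = sprintf("slide_%02d", i)))
    })
    p <- write_mosaic(env$mosaics[[1]], file.path(config$out_dir, "tiles"))
    note("tile", p)
  }
  if ("train" %in% stages) {
    need("train", "tile mosaics", !is.null(env$mosaics))
    n_tr <- sl$n_train
    train_tiles <- do.call(c, lapply(env$mosaics[seq_len(n_tr)], unclass))
    class(train_tiles) <- "zq_mosaic"
    cfg <- network_config(depth = config$network$depth,
                          base_filters = config$network$base_filters,
                          tile_size = config$tiling$tile_size)
    tr <- config$training
    env$fit <- fit_zoneseg(train_tiles, env$mosaics[[n_tr + 1L]], cfg,
                           epochs = tr$epochs, lr = tr$lr,
                           batch_size = tr$batch_size, augment = tr$augment,
                           seed = config$seed)
    p <- write_training_log(env$fit,
                            file.path(config$out_dir, "training_log.csv"))
    note("train", p)
  }
  if ("segment" %in% stages) {
    need("segment", "fitted model", !is.null(env$fit))
    val <- env$slides[[length(env$slides)]]
    env$pred <- predict(env$fit, val$image,
                        tile_size = config$tiling$tile_size,
                        stride = config$tiling$stride)
    p <- file.path(config$out_dir, "prediction.png")
    write_annotation_png(env$pred$labels, p); note("segment", p)
    rep <- class_report(confusion(env$pred$labels, val$truth$annotation))
    p <- write_report_csv(rep, file.path(config$out_dir,
                                         "validation_report.csv"))
    note("segment", p)
  }
  if ("masks" %in% stages) {
    need("masks", "stitched prediction", !is.null(env$pred))
    env$masks <- masks_from_prediction(
      env$pred$labels,
      microns_per_px = env$specs[[1]]$microns_per_px)
    p <- write_mask_set(env$masks, file.path(config$out_dir, "masks"))
    note("masks", file.path(p, "mask_combined.png"))
  }
  if ("quantify" %in% stages) {
    need("quantify", "zone masks", !is.null(env$masks))
    q <- config$quantify
    ihc_spec <- env$specs[[length(env$specs)]]
    ihc <- generate_ihc_slide(ihc_spec, cells_per_zone = q$cells_per_zone,
                              positive_fraction_per_zone =
                                q$positive_fraction)
    det <- detect_cells(ihc$image, detection_params(q$marker),
                        microns_per_px = ihc_spec$microns_per_px)
    report <- zone_report(det, env$masks)
    p <- write_zone_csv(report, file.path(config$out_dir,
                                          "zone_quantification.csv"))
    note("quantify", p)
  }
  manifest <- do.call(rbind, manifest)
  utils::write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
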