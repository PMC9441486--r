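#' Class labels used throughout the package
#'
#' The canonical ordered set of semantic classes for aneurysm wall
#' segmentation: `ignore` (uncertain borders / unannotated surroundings),
#' `zone1` (vascular wall tissue), `zone2` (loose perivascular tissue),
#' `thrombus` (residual intraluminal thrombus) and `background`.
#'
#' @return Character vector of the five class names, in canonical order.
#' @export
zone_classes <- function() {
  c("ignore", "zone1", "zone2", "thrombus", "background")
}

#' Display palette for annotation maps
#'
#' Colours follow the convention used for zone annotation rendering:
#' zone 1 blue, zone 2 green, thrombus red, background purple, ignore gray.
#'
#' @return Named character vector of hex colours, one per class.
#' @export
zone_palette <- function() {
  c(ignore = "#808080", zone1 = "#0000FF", zone2 = "#00B000",
    thrombus = "#FF0000", background = "#A000A0")
}

#' Confusion matrix between predicted and true annotation maps
#'
#' Rows are true classes, columns predicted classes, following the usual
#' classification-report convention; a row-normalised view (each row summing
#' to one) is what confusion-matrix heatmaps display.
#'
#' @param pred Integer matrix of predicted labels (values index
#'   `class_order`, 0-based: 0 = first class).
#' @param truth Integer matrix of true labels, same shape and coding.
#' @param class_order Character vector naming the classes in label order.
#' @return A `zq_confusion` object: an integer C x C matrix with dimnames
#'   `truth` x `predicted`.
#' @export
confusion <- function(pred, truth, class_order = zone_classes()) {
  if (!all(dim(pred) == dim(truth))) {
    stop("`pred` and `truth` must have identical dimensions (",
         paste(dim(pred), collapse = "x"), " vs ",
         paste(dim(truth), collapse = "x"), ")")
  }
  k <- length(class_order)
  tt <- factor(as.vector(truth), levels = seq_len(k) - 1L, labels = class_order)
  pp <- factor(as.vector(pred), levels = seq_len(k) - 1L, labels = class_order)
  cm <- table(truth = tt, predicted = pp)
  cm <- matrix(as.integer(cm), nrow = k,
               dimnames = list(truth = class_order, predicted = class_order))
  structure(cm, class = c("zq_confusion", "matrix"))
}

#' Row-normalise a confusion matrix
#'
#' @param cm A `zq_confusion` matrix.
#' @return Numeric matrix whose rows sum to one (all-zero rows stay zero).
#' @export
normalize_confusion <- function(cm) {
  rs <- rowSums(cm)
  out <- sweep(unclass(cm), 1, pmax(rs, 1), "/")
  out[rs == 0, ] <- 0
  out
}

#' @export
print.zq_confusion <- function(x, normalized = FALSE, digits = 3, ...) {
  cat("Confusion matrix (rows = truth, cols = predicted)\n")
  if (normalized) {
    print(round(normalize_confusion(x), digits))
  } else {
    print(unclass(x))
  }
  invisible(x)
}

#' Plot a confusion matrix as a row-normalised heatmap
#'
#' @param x A `zq_confusion` matrix.
#' @param ... Passed to [graphics::image()].
#' @export
plot.zq_confusion <- function(x, ...) {
  nm <- normalize_confusion(x)
  k <- nrow(nm)
  graphics::image(seq_len(k), seq_len(k), t(nm[k:1, ]),
                  col = grDevices::hcl.colors(64, "Blues 3", rev = TRUE),
                  axes = FALSE, xlab = "Predicted", ylab = "True", ...)
  graphics::axis(1, at = seq_len(k), labels = colnames(nm), las = 2)
  graphics::axis(2, at = seq_len(k), labels = rev(rownames(nm)), las = 2)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    graphics::text(j, k - i + 1, sprintf("%.2f", nm[i, j]),
                   col = if (nm[i, j] > 0.5) "white" else "black", cex = 0.8)
  }
  invisible(x)
}

#' Per-class classification report from a confusion matrix
#'
#' Computes, for every class, precision TP/(TP+FP), recall TP/(TP+FN),
#' F1 = 2PR/(P+R), Jaccard index TP/(TP+FP+FN) and support (number of true
#' pixels). Cells with a zero denominator are reported as 0. Note the exact
#' identity Jaccard = F1/(2 - F1), which also links the DICE score to the
#' Jaccard index.
#'
#' @param cm A `zq_confusion` matrix (or plain square matrix with dimnames).
#' @return A `zq_class_report`: data frame with columns `class`, `precision`,
#'   `recall`, `f1`, `jaccard`, `support`.
#' @export
class_report <- function(cm) {
  cm <- unclass(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  safe <- function(num, den) ifelse(den > 0, num / den, 0)
  p <- safe(tp, tp + fp)
  r <- safe(tp, tp + fn)
  f1 <- safe(2 * p * r, p + r)
  j <- safe(tp, tp + fp + fn)
  report_rows(class = rownames(cm), precision = p, recall = r,
              f1 = f1, jaccard = j, support = rowSums(cm))
}

#' Assemble a classification report from per-class rows
#'
#' Used when the per-class metrics come from an external source (for
#' instance a published report) rather than a confusion matrix computed
#' here. If `jaccard` is missing it is derived from F1 through the identity
#' J = F/(2 - F).
#'
#' @param class Character vector of class names.
#' @param precision,recall,f1 Numeric per-class metrics in `[0, 1]`.
#' @param jaccard Optional numeric per-class Jaccard indices.
#' @param support Numeric per-class supports (true pixel counts).
#' @return A `zq_class_report` data frame.
#' @export
report_rows <- function(class, precision, recall, f1, jaccard = NULL,
                        support) {
  if (is.null(jaccard)) jaccard <- jaccard_from_dice(f1)
  out <- data.frame(class = as.character(class), precision = precision,
                    recall = recall, f1 = f1, jaccard = jaccard,
                    support = support, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("zq_class_report", "data.frame")
  out
}

#' Aggregate a classification report
#'
#' Computes the macro (unweighted mean) or weighted (support-weighted mean)
#' aggregate row, optionally after excluding classes (typically `ignore`,
#' under the assumption that uncertain-border pixels are irrelevant to
#' performance). Precision, recall and F1 are aggregated directly. For the
#' Jaccard column two conventions exist: the default, `"from_f1"`, converts
#' the aggregated F1 through J = F/(2 - F) -- the convention that reproduces
#' standard corrected whole-slide report tables -- while `"mean"` aggregates
#' the per-class Jaccard values themselves.
#'
#' @param report A `zq_class_report`.
#' @param mode `"macro"` or `"weighted"`.
#' @param exclude Character vector of class names to drop before
#'   aggregating.
#' @param jaccard `"from_f1"` (default) or `"mean"`.
#' @return One-row data frame with columns `precision`, `recall`, `f1`,
#'   `jaccard`, `support` (the summed support of included classes).
#' @export
aggregate_report <- function(report, mode = c("macro", "weighted"),
                             exclude = character(),
                             jaccard = c("from_f1", "mean")) {
  mode <- match.arg(mode)
  jaccard <- match.arg(jaccard)
  rows <- report[!(report$class %in% exclude), , drop = FALSE]
  if (nrow(rows) == 0) stop("no classes left to aggregate after exclusion")
  if (mode == "macro" && any(rows$support == 0)) {
    warning("dropping zero-support classes from macro average: ",
            paste(rows$class[rows$support == 0], collapse = ", "))
    rows <- rows[rows$support > 0, , drop = FALSE]
    if (nrow(rows) == 0) stop("all included classes have zero support")
  }
  w <- if (mode == "macro") rep(1, nrow(rows)) else rows$support
  agg <- function(x) stats::weighted.mean(x, w)
  jac <- if (jaccard == "from_f1") jaccard_from_dice(agg(rows$f1)) else
    agg(rows$jaccard)
  data.frame(precision = agg(rows$precision), recall = agg(rows$recall),
             f1 = agg(rows$f1), jaccard = jac, support = sum(rows$support))
}

#' Substitute an estimated background precision into a report
#'
#' Whole-slide validation against partially annotated ground truth
#' systematically understates background precision: empty regions labelled
#' `ignore` in the annotation are predicted (correctly) as background and
#' counted as errors. This correction replaces the background precision with
#' an externally estimated value, recomputes the background F1 from that
#' precision and the original recall, and re-derives the background Jaccard
#' via J = F/(2 - F). Aggregate rows should then be recomputed from the
#' corrected report with [aggregate_report()].
#'
#' @param report A `zq_class_report` containing a background row.
#' @param estimated_precision Estimated background precision in (0, 1].
#' @param class Name of the background class (default `"background"`).
#' @return The corrected `zq_class_report`.
#' @export
correct_background <- function(report, estimated_precision,
                               class = "background") {
  if (!(class %in% report$class)) {
    stop("class '", class, "' not present in report")
  }
  if (estimated_precision <= 0 || estimated_precision > 1) {
    stop("`estimated_precision` must be in (0, 1]")
  }
  i <- match(class, report$class)
  p <- estimated_precision
  r <- report$recall[i]
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  report$precision[i] <- p
  report$f1[i] <- f1
  report$jaccard[i] <- jaccard_from_dice(f1)
  report
}

#' Convert a DICE/F1 score to a Jaccard index
#'
#' The DICE coefficient (identical to the F1 score on sets) and the Jaccard
#' index are related by J = D/(2 - D); e.g. the common 0.7 DICE adequacy
#' threshold for biomedical segmentation corresponds to a Jaccard index of
#' 0.7/(2 - 0.7) = 0.538.
#'
#' @param d DICE score(s) in `[0, 1]`.
#' @return Jaccard index/indices.
#' @seealso [dice_from_jaccard()]
#' @export
jaccard_from_dice <- function(d) {
  stopifnot(all(d >= 0 & d <= 1))
  d / (2 - d)
}

#' Convert a Jaccard index to a DICE/F1 score
#'
#' Inverse of [jaccard_from_dice()]: D = 2J/(1 + J).
#'
#' @param j Jaccard index/indices in `[0, 1]`.
#' @return DICE score(s).
#' @export
dice_from_jaccard <- function(j) {
  stopifnot(all(j >= 0 & j <= 1))
  2 * j / (1 + j)
}

#' @export
print.zq_class_report <- function(x, digits = 3, ...) {
  cat("Per-class classification report\n")
  y <- as.data.frame(x)
  y[c("precision", "recall", "f1", "jaccard")] <-
    lapply(y[c("precision", "recall", "f1", "jaccard")], round, digits)
  print(y, row.names = FALSE)
  invisible(x)
}

#' Render a report with its aggregate rows, rounded for display
#'
#' Produces the conventional table layout: per-class rows, then macro and
#' weighted aggregates, then the same two aggregates excluding the ignore
#' class. Values are rounded to `digits` decimals for rendering; internal
#' values keep full precision.
#'
#' @param report A `zq_class_report`.
#' @param digits Decimals for display (default 3).
#' @param exclude Class excluded in the bottom aggregate block.
#' @return Data frame ready for printing or CSV export.
#' @export
full_report_table <- function(report, digits = 3, exclude = "ignore") {
  rows <- as.data.frame(report)
  add <- function(label, a) {
    data.frame(class = label, precision = a$precision, recall = a$recall,
               f1 = a$f1, jaccard = a$jaccard, support = a$support)
  }
  out <- rbind(
    rows,
    add("macro avg", aggregate_report(report, "macro")),
    add("weighted avg", aggregate_report(report, "weighted")),
    add(paste0("macro avg (excl. ", exclude, ")"),
        aggregate_report(report, "macro", exclude = exclude)),
    add(paste0("weighted avg (excl. ", exclude, ")"),
        aggregate_report(report, "weighted", exclude = exclude)))
  out[c("precision", "recall", "f1", "jaccard")] <-
    lapply(out[c("precision", "recall", "f1", "jaccard")], round, digits)
  out
}

#' Write a classification report (with aggregates) to CSV
#'
#' @param report A `zq_class_report`.
#' @param path Output CSV path.
#' @param digits Decimals used for rendering.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path, digits = 3) {
  utils::write.csv(full_report_table(report, digits = digits), path,
                   row.names = FALSE)
  invisible(path)
}

#' Reference whole-slide validation classification report
#'
#' Per-class precision, recall, F1, Jaccard and pixel support for a
#' reference validation run of a five-class aneurysm wall segmentation
#' network, as printed in the corresponding published report table. Bundled
#' so that the report-arithmetic routines ([aggregate_report()],
#' [correct_background()]) can be exercised and checked against the printed
#' aggregate rows without access to the original slides.
#'
#' @return A `zq_class_report` with one row per class.
#' @export
reference_validation_report <- function() {
  report_rows(
    class = c("ignore", "zone1", "zone2", "thrombus", "background"),
    precision = c(0.091, 0.766, 0.858, 0.969, 0.312),
    recall    = c(0.070, 0.903, 0.796, 0.887, 0.984),
    f1        = c(0.079, 0.829, 0.826, 0.926, 0.474),
    jaccard   = c(0.041, 0.708, 0.704, 0.862, 0.310),
    support   = c(41672692, 265953620, 306283491, 145997791, 760249363))
}

#' Reference per-zone cell detection counts
#'
#' Raw per-zone cell detection counts and zone areas for one reference
#' patient sample (CD8 immunostaining): total detections, positive
#' detections and zone area in mm^2 per class. The derived columns
#' (positive %, positives per mm^2) are recomputed by [zone_quant_rows()].
#'
#' @return Data frame with columns `class`, `detections`, `positives`,
#'   `area_mm2`.
#' @export
reference_cell_counts <- function() {
  data.frame(
    class = c("zone1", "zone2", "thrombus", "background"),
    detections = c(129824L, 48472L, 1920L, 80L),
    positives = c(12308L, 1680L, 148L, 0L),
    area_mm2 = c(22.6, 22.0, 0.4, 85.0),
    stringsAsFactors = FALSE)
}
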