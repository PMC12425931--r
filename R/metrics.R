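# Pixel-level segmentation metrics, dataset-level aggregation (mean +/- sd in
# percent) and the paired t-test used for model comparison.

#' Confusion counts between a predicted and a reference binary mask
#'
#' Class 1 is the foreground positive.
#'
#' @param pred,gt integer/numeric arrays of identical shape with values in
#'   `{0, 1}`.
#' @return A list of class `confusion_counts` with elements tp, fp, tn, fn.
#' @export
#' @examples
#' confusion_counts(matrix(1, 4, 4), matrix(1, 4, 4))$tp  # 16
confusion_counts <- function(pred, gt) {
  if (!identical(dim(pred), dim(gt)) || length(pred) != length(gt))
    stop("invalid input: mask shapes differ", call. = FALSE)
  if (length(pred) == 0L) stop("invalid input: empty masks", call. = FALSE)
  if (!all(pred %in% c(0, 1)) || !all(gt %in% c(0, 1)))
    stop("invalid input: masks must be binary (0/1)", call. = FALSE)
  p <- as.logical(pred)
  g <- as.logical(gt)
  structure(list(tp = sum(p & g), fp = sum(p & !g),
                 tn = sum(!p & !g), fn = sum(!p & g)),
            class = "confusion_counts")
}

#' Global pixel accuracy: (TP + TN) / (TP + FP + FN + TN)
#' @param c a [confusion_counts()] object.
#' @return Fraction in `[0, 1]`.
#' @export
gpa <- function(c) {
  total <- c$tp + c$fp + c$tn + c$fn
  if (total == 0) stop("invalid input: empty masks", call. = FALSE)
  (c$tp + c$tn) / total
}

#' Dice coefficient: 2TP / (2TP + FP + FN)
#'
#' Defined as 1 when both masks are empty (no foreground in either).
#' @param c a [confusion_counts()] object.
#' @return Fraction in `[0, 1]`.
#' @export
dice <- function(c) {
  denom <- 2 * c$tp + c$fp + c$fn
  if (denom == 0) return(1)
  2 * c$tp / denom
}

per_class_counts <- function(pred, gt) {
  fg <- confusion_counts(pred, gt)
  # background as the positive class: swap the roles
  bg <- structure(list(tp = fg$tn, fp = fg$fn, tn = fg$tp, fn = fg$fp),
                  class = "confusion_counts")
  list(background = bg, foreground = fg)
}

iou_one <- function(c) {
  denom <- c$tp + c$fp + c$fn
  if (denom == 0) return(1)  # class absent from both masks
  c$tp / denom
}

#' Mean intersection-over-union over the two classes
#'
#' One-vs-rest IoU `TP / (TP + FP + FN)` for background and foreground,
#' averaged. A class absent from both masks has IoU 1.
#'
#' @param c_per_class list of two [confusion_counts()] (as from the internal
#'   per-class tally), or a pair of binary masks via `miou_masks()`.
#' @return Fraction in `[0, 1]`.
#' @export
miou <- function(c_per_class) {
  mean(vapply(c_per_class, iou_one, 0))
}

#' @rdname miou
#' @param pred,gt binary masks.
#' @export
miou_masks <- function(pred, gt) miou(per_class_counts(pred, gt))

#' Sensitivity (foreground recall): TP / (TP + FN)
#' @param c a [confusion_counts()] object.
#' @return Fraction in `[0, 1]`.
#' @export
sensitivity <- function(c) {
  if (c$tp + c$fn == 0)
    stop("invalid input: no foreground in the reference mask", call. = FALSE)
  c$tp / (c$tp + c$fn)
}

#' Evaluate a set of predictions against reference masks
#'
#' Computes GPA, Dice, mean IoU and sensitivity per image, then aggregates as
#' mean and sample (n - 1) standard deviation over images, reported in
#' percent.
#'
#' @param preds,gts equal-length lists of binary masks (shape-matched
#'   pairwise).
#' @param ids optional character vector of image identifiers.
#' @return An object of class `mdwc_eval`: `list(per_image = tibble,
#'   summary = tibble)` with percentages.
#' @export
evaluate_dataset <- function(preds, gts, ids = NULL) {
  if (length(preds) == 0L || length(preds) != length(gts))
    stop("invalid input: prediction/reference lists must be equal-length and non-empty",
         call. = FALSE)
  if (is.null(ids)) ids <- sprintf("img%03d", seq_along(preds))
  rows <- lapply(seq_along(preds), function(i) {
    cc <- confusion_counts(preds[[i]], gts[[i]])
    tibble::tibble(id = ids[i],
                   gpa = 100 * gpa(cc),
                   dice = 100 * dice(cc),
                   miou = 100 * miou_masks(preds[[i]], gts[[i]]),
                   sensitivity = 100 * sensitivity(cc))
  })
  per_image <- do.call(rbind, rows)
  metrics <- c("gpa", "dice", "miou", "sensitivity")
  summary <- tibble::tibble(
    metric = metrics,
    mean = unname(vapply(metrics, function(m) mean(per_image[[m]]), 0)),
    sd = unname(vapply(metrics, function(m)
      if (nrow(per_image) > 1) stats::sd(per_image[[m]]) else 0, 0)))
  structure(list(per_image = per_image, summary = summary), class = "mdwc_eval")
}

#' @export
print.mdwc_eval <- function(x, ...) {
  cat("Segmentation metrics over", nrow(x$per_image), "images (percent):\n")
  for (i in seq_len(nrow(x$summary)))
    cat(sprintf("  %-12s %6.2f ± %.3f\n", x$summary$metric[i],
                x$summary$mean[i], x$summary$sd[i]))
  invisible(x)
}

#' Write a metric report as CSV and JSON
#'
#' The CSV holds one row per image plus a summary row; the JSON mirrors the
#' "mean +/- std" table formatting.
#'
#' @param x an `mdwc_eval` object.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return `x`, invisibly.
#' @export
write_metric_report <- function(x, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(x, "mdwc_eval"))
  if (!is.null(csv_path)) {
    per <- x$per_image
    summary_row <- tibble::tibble(id = "mean",
                                  gpa = x$summary$mean[1], dice = x$summary$mean[2],
                                  miou = x$summary$mean[3], sensitivity = x$summary$mean[4])
    utils::write.csv(rbind(per, summary_row), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    js <- stats::setNames(lapply(seq_len(nrow(x$summary)), function(i)
      list(mean = x$summary$mean[i], sd = x$summary$sd[i],
           formatted = sprintf("%.2f ± %.3f", x$summary$mean[i], x$summary$sd[i]))),
      x$summary$metric)
    jsonlite::write_json(js, json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(x)
}

#' Paired t-test between two per-image metric vectors
#'
#' Two-sided p-value of the paired t statistic on the differences `a - b`.
#'
#' @param a,b numeric vectors of equal length (n >= 2), one metric value per
#'   image for two models on the same images.
#' @return The two-sided p-value.
#' @export
#' @examples
#' paired_t_test(c(90, 91, 92, 88), c(89, 90, 90, 88.5))
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2L)
    stop("invalid input: need two equal-length vectors with n >= 2", call. = FALSE)
  d <- a - b
  if (stats::sd(d) == 0)
    stop("degenerate input: zero variance of paired differences", call. = FALSE)
  stats::t.test(a, b, paired = TRUE)$p.value
}
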