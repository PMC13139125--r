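# Detection-quality protocol: one-to-one IoU matching of predictions to
# manually annotated ground truth, per-image confusion counts and
# precision/recall/F1, and reporting stratified by nodule-count bins
# (<=5, 6-10, 11-20, 21-30, >=31) with an unweighted mean across bins.

#' Evaluation configuration
#'
#' @param match_iou Minimum IoU for a prediction to match a ground-truth
#'   box (one-to-one greedy matching on descending IoU).
#' @param bin_edges Strictly increasing integer cut points; counts are
#'   binned as `<= e1`, `e1+1 .. e2`, ..., `> e_last`. The default gives
#'   the bins <=5, 6-10, 11-20, 21-30, >=31.
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(match_iou = 0.5, bin_edges = c(5L, 10L, 20L, 30L)) {
  stopifnot(match_iou > 0, match_iou <= 1,
            length(bin_edges) >= 1L, all(diff(bin_edges) > 0))
  structure(list(match_iou = match_iou, bin_edges = as.integer(bin_edges)),
            class = "eval_config")
}

bin_labels <- function(edges) {
  k <- length(edges)
  lo <- c(sprintf("<=%d", edges[1L]))
  mid <- if (k >= 2L) sprintf("%d-%d", edges[-k] + 1L, edges[-1L]) else character(0)
  c(lo, mid, sprintf(">=%d", edges[k] + 1L))
}

assign_bin <- function(count, edges) {
  findInterval(count, edges + 1L) + 1L # 1-based bin index
}

#' Match predictions against ground truth
#'
#' One-to-one greedy matching: the highest-IoU (prediction, ground
#' truth) pair is matched first and both boxes retired, repeating while
#' the best remaining IoU is at least `match_iou`. Matched pairs are
#' true positives; unmatched predictions false positives; unmatched
#' ground truth false negatives.
#'
#' @param predictions,ground_truth Box tables in the same (image-global)
#'   frame; `ground_truth` may be an [annotation_set()].
#' @param config An [eval_config()].
#' @return A list of class `confusion_counts` with integer elements
#'   `tp`, `fp`, `fn`; `tp + fn` equals the ground-truth count and
#'   `tp + fp` the prediction count.
#' @export
match_detections <- function(predictions, ground_truth,
                             config = eval_config()) {
  if (inherits(ground_truth, "annotation_set")) ground_truth <- ground_truth$boxes
  n_pred <- nrow(predictions)
  n_gt <- nrow(ground_truth)
  if (n_pred == 0L || n_gt == 0L) {
    return(confusion_counts(tp = 0L, fp = n_pred, fn = n_gt))
  }
  M <- iou_matrix(predictions, ground_truth)
  tp <- 0L
  while (TRUE) {
    best <- which.max(M)
    if (length(best) == 0L || M[best] < config$match_iou) break
    ij <- arrayInd(best, dim(M))
    tp <- tp + 1L
    M[ij[1L], ] <- -1
    M[, ij[2L]] <- -1
  }
  confusion_counts(tp = tp, fp = n_pred - tp, fn = n_gt - tp)
}

confusion_counts <- function(tp, fp, fn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0)
  structure(list(tp = as.integer(tp), fp = as.integer(fp),
                 fn = as.integer(fn)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %d, FP %d, FN %d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Precision, recall and F1 from confusion counts
#'
#' `precision = tp / (tp + fp)`, `recall = tp / (tp + fn)`,
#' `f1 = 2PR / (P + R)`. Zero-denominator conventions: an image with no
#' ground truth and no predictions scores 1/1/1 (vacuous perfection);
#' otherwise an undefined precision or recall is 0, and F1 is 0 when
#' `P + R = 0`.
#'
#' @param counts A `confusion_counts` object (or list with tp/fp/fn).
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
image_metrics <- function(counts) {
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn
  if (tp == 0L && fp == 0L && fn == 0L) {
    return(c(precision = 1, recall = 1, f1 = 1))
  }
  p <- if (tp + fp > 0L) tp / (tp + fp) else 0
  r <- if (tp + fn > 0L) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Bin-stratified evaluation report
#'
#' Images are grouped by their manually labeled nodule count into the
#' configured bins; within each bin the per-image precision, recall and
#' F1 are averaged (unweighted). The final `overall` row is the
#' unweighted mean of the per-bin means — every occupied bin counts
#' equally regardless of how many images it holds. Empty bins are
#' omitted from the report and from the overall average.
#'
#' @param per_image Data frame with columns `gt_count`, `precision`,
#'   `recall`, `f1`, one row per image, all computed at a single
#'   `match_iou`.
#' @param config An [eval_config()].
#' @return Data frame with columns `bin`, `n_images`, `precision`,
#'   `recall`, `f1`: one row per occupied bin plus the `overall` row.
#' @export
bin_report <- function(per_image, config = eval_config()) {
  need <- c("gt_count", "precision", "recall", "f1")
  stopifnot(all(need %in% names(per_image)), nrow(per_image) >= 1L)
  labels <- bin_labels(config$bin_edges)
  idx <- assign_bin(per_image$gt_count, config$bin_edges)
  rows <- lapply(seq_along(labels), function(b) {
    sel <- idx == b
    if (!any(sel)) return(NULL)
    data.frame(bin = labels[b], n_images = sum(sel),
               precision = mean(per_image$precision[sel]),
               recall = mean(per_image$recall[sel]),
               f1 = mean(per_image$f1[sel]))
  })
  rows <- do.call(rbind, rows)
  overall <- data.frame(bin = "overall", n_images = sum(rows$n_images),
                        precision = mean(rows$precision),
                        recall = mean(rows$recall),
                        f1 = mean(rows$f1))
  out <- rbind(rows, overall)
  rownames(out) <- NULL
  out
}

#' Evaluate many images end to end
#'
#' Convenience wrapper: matches each image's predictions to its ground
#' truth, computes per-image metrics, and returns both the per-image
#' table and the bin report.
#'
#' @param predictions Named list of per-image prediction tables.
#' @param ground_truth Named list of per-image [annotation_set()]s (or
#'   box tables), with the same names.
#' @param config An [eval_config()].
#' @return A list with `per_image` (data frame: image_id, gt_count, tp,
#'   fp, fn, precision, recall, f1) and `bins` (the [bin_report()]).
#' @export
evaluate_images <- function(predictions, ground_truth,
                            config = eval_config()) {
  stopifnot(is.list(predictions), is.list(ground_truth),
            setequal(names(predictions), names(ground_truth)))
  ids <- names(predictions)
  rows <- lapply(ids, function(id) {
    gt <- ground_truth[[id]]
    gt_boxes <- if (inherits(gt, "annotation_set")) gt$boxes else gt
    cc <- match_detections(predictions[[id]], gt_boxes, config)
    m <- image_metrics(cc)
    data.frame(image_id = id, gt_count = nrow(gt_boxes), tp = cc$tp,
               fp = cc$fp, fn = cc$fn, precision = m["precision"],
               recall = m["recall"], f1 = m["f1"])
  })
  per_image <- do.call(rbind, rows)
  rownames(per_image) <- NULL
  list(per_image = per_image, bins = bin_report(per_image, config))
}
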