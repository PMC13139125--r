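# Stitch-back and detection refinement.
#
# Patch-wise inference over an overlapping grid detects a nodule near a
# patch boundary several times at slightly different positions. Two
# refinement steps restore one detection per nodule: (1) an edge filter
# drops boxes lying within a few pixels of a patch boundary — those are
# partially visible there and fully visible in a neighboring patch — and
# (2) greedy non-maximum suppression on the stitched full image removes
# the remaining duplicates, keeping the highest-confidence box.

#' Post-processing configuration
#'
#' @param edge_threshold Distance in pixels; a detection with any box
#'   side strictly closer than this to a patch boundary is removed.
#' @param nms_confidence Confidence floor applied before suppression;
#'   deliberately low so weak but valid detections survive.
#' @param nms_iou IoU at or above which two boxes are considered
#'   duplicates; deliberately low because true nodules rarely overlap in
#'   2D projection.
#' @param exempt_image_border If `TRUE` (default), patch boundaries that
#'   coincide with the outer image border do not trigger the edge
#'   filter: a nodule touching the photo's edge exists only in a border
#'   patch and would otherwise be unrecoverable.
#' @return A list of class `postprocess_config`.
#' @export
postprocess_config <- function(edge_threshold = 5, nms_confidence = 0.2,
                               nms_iou = 0.2, exempt_image_border = TRUE) {
  stopifnot(edge_threshold >= 0,
            nms_confidence >= 0, nms_confidence <= 1,
            nms_iou >= 0, nms_iou <= 1)
  structure(list(edge_threshold = edge_threshold,
                 nms_confidence = nms_confidence,
                 nms_iou = nms_iou,
                 exempt_image_border = isTRUE(exempt_image_border)),
            class = "postprocess_config")
}

#' Remove detections too close to a patch edge
#'
#' Operates in the patch-local frame, where "patch edge" is
#' well-defined. A detection is removed iff any of its four sides lies
#' strictly within `edge_threshold` pixels of a patch boundary —
#' excluding boundaries that coincide with the outer image border when
#' `exempt_image_border` is set.
#'
#' @param detections Patch-local detection table.
#' @param spec The patch's row from the plan.
#' @param image_w,image_h Full-image dimensions (needed to recognize
#'   image-border patch edges).
#' @param config A [postprocess_config()].
#' @return The filtered detection table.
#' @export
edge_filter <- function(detections, spec, image_w, image_h,
                        config = postprocess_config()) {
  detections <- as_detections(detections, frame = NULL)
  stopifnot(nrow(spec) == 1L)
  if (nrow(detections) == 0L) return(detections)
  if (any(detections$frame != "patch")) {
    stop("frame error: edge_filter operates on patch-local detections")
  }
  t <- config$edge_threshold
  # which patch boundaries are interior (shared with a neighboring patch)?
  chk_left   <- !(config$exempt_image_border && spec$x0 <= 0)
  chk_top    <- !(config$exempt_image_border && spec$y0 <= 0)
  chk_right  <- !(config$exempt_image_border && spec$x0 + spec$width >= image_w)
  chk_bottom <- !(config$exempt_image_border && spec$y0 + spec$height >= image_h)
  near <- rep(FALSE, nrow(detections))
  if (chk_left)   near <- near | detections$x_min < t
  if (chk_top)    near <- near | detections$y_min < t
  if (chk_right)  near <- near | spec$width - detections$x_max < t
  if (chk_bottom) near <- near | spec$height - detections$y_max < t
  detections[!near, , drop = FALSE]
}

#' Translate patch-local detections into the full-image frame
#'
#' @param detections Patch-local detection table.
#' @param spec The patch's row from the plan.
#' @return The same table shifted by the patch origin, with `frame`
#'   flipped to `"global"`; confidences unchanged.
#' @export
translate_to_global <- function(detections, spec) {
  detections <- as_detections(detections, frame = NULL)
  stopifnot(nrow(spec) == 1L)
  if (nrow(detections) > 0L && any(detections$frame != "patch")) {
    stop("frame error: detections are already image-global")
  }
  detections$x_min <- detections$x_min + spec$x0
  detections$x_max <- detections$x_max + spec$x0
  detections$y_min <- detections$y_min + spec$y0
  detections$y_max <- detections$y_max + spec$y0
  detections$frame <- rep_len("global", nrow(detections))
  detections
}

#' Greedy non-maximum suppression
#'
#' Detections below the confidence floor are dropped first. The
#' remainder are sorted by confidence descending (ties broken by `x_min`
#' then `y_min` ascending, making the output deterministic); the top box
#' is kept and every remaining box with IoU >= `nms_iou` against it is
#' suppressed, repeating until no boxes remain. Output rows appear in
#' acceptance order.
#'
#' @param detections Image-global detection table for a single image.
#' @param config A [postprocess_config()].
#' @return The deduplicated detection table.
#' @export
nms <- function(detections, config = postprocess_config()) {
  detections <- as_detections(detections, frame = NULL)
  det <- detections[detections$confidence >= config$nms_confidence, ,
                    drop = FALSE]
  if (nrow(det) <= 1L) { rownames(det) <- NULL; return(det) }
  ord <- order(-det$confidence, det$x_min, det$y_min)
  det <- det[ord, , drop = FALSE]
  M <- iou_matrix(det, det)
  n <- nrow(det)
  alive <- rep(TRUE, n)
  keep <- logical(n)
  for (i in seq_len(n)) {
    if (!alive[i]) next
    keep[i] <- TRUE
    sup <- alive & M[i, ] >= config$nms_iou
    sup[i] <- FALSE
    alive[sup] <- FALSE
    alive[i] <- FALSE
  }
  out <- det[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Refine per-patch detections into the final per-image detection list
#'
#' The full stitch-back chain: per-patch edge filtering, translation to
#' image-global coordinates, then one global NMS pass over the pooled
#' detections. Deterministic given its inputs.
#'
#' @param detections Patch-local detection table carrying `row`/`col`
#'   patch indices (as produced by [detect_patches()]).
#' @param plan The image's patch plan ([plan_patches()]).
#' @param image_w,image_h Full-image dimensions.
#' @param config A [postprocess_config()].
#' @return Image-global detection table after NMS.
#' @export
refine_image <- function(detections, plan, image_w, image_h,
                         config = postprocess_config()) {
  detections <- as_detections(detections, frame = NULL)
  if (nrow(detections) > 0L) {
    if (!all(c("row", "col") %in% names(detections))) {
      stop("consistency error: per-patch detections need row/col columns")
    }
    det_keys <- paste(detections$row, detections$col)
    plan_keys <- paste(plan$row, plan$col)
    if (!all(det_keys %in% plan_keys)) {
      stop("consistency error: detections reference patches absent from the plan")
    }
  }
  pooled <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    d <- detections[detections$row == p$row & detections$col == p$col, ,
                    drop = FALSE]
    if (nrow(d) == 0L) next
    d <- edge_filter(d, p, image_w, image_h, config)
    if (nrow(d) == 0L) next
    pooled[[i]] <- translate_to_global(d, p)
  }
  pooled <- do.call(rbind, pooled)
  if (is.null(pooled)) return(empty_detections())
  out <- nms(pooled, config)
  out$row <- NULL
  out$col <- NULL
  rownames(out) <- NULL
  out
}
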