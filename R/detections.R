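# Detection tables: boxes plus confidence plus coordinate frame.
#
# A detection table is a data.frame with the four box corner columns, a
# `confidence` column in [0, 1], and a `frame` column that is either
# "patch" (patch-local coordinates) or "global" (full-image coordinates).
# Patch-local tables additionally carry the `row`/`col` grid indices of
# the patch they belong to, so stitching is self-describing.

#' Build or validate a detection table
#'
#' @param boxes Box table, optionally already carrying `confidence` and
#'   `frame` columns.
#' @param confidence Confidence scores in \[0, 1\], recycled; ignored if
#'   `boxes` already has a `confidence` column.
#' @param frame `"patch"` or `"global"`. When `NULL`, the existing
#'   `frame` column is kept (and required).
#' @param row,col Patch grid indices for patch-local detections.
#' @return A validated detection `data.frame`.
#' @export
as_detections <- function(boxes, confidence = 1, frame = "global",
                          row = NULL, col = NULL) {
  det <- as.data.frame(boxes)
  if (nrow(det) > 0L) validate_boxes(det)
  if (!"confidence" %in% names(det)) {
    det$confidence <- rep_len(as.numeric(confidence), nrow(det))
  }
  if (nrow(det) > 0L &&
      (anyNA(det$confidence) || any(det$confidence < 0 | det$confidence > 1))) {
    stop("confidence must lie in [0, 1]")
  }
  if (!is.null(frame)) {
    det$frame <- rep_len(frame, nrow(det))
  } else if (!"frame" %in% names(det)) {
    stop("frame error: detection table has no 'frame' column")
  }
  if (nrow(det) > 0L && !all(det$frame %in% c("patch", "global"))) {
    stop("frame error: frame must be 'patch' or 'global'")
  }
  if (!is.null(row)) det$row <- rep_len(as.integer(row), nrow(det))
  if (!is.null(col)) det$col <- rep_len(as.integer(col), nrow(det))
  rownames(det) <- NULL
  det
}

empty_detections <- function(frame = "global") {
  data.frame(x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
             y_max = numeric(0), confidence = numeric(0),
             frame = character(0))
}
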