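# Box algebra on axis-aligned rectangles in continuous pixel coordinates.
#
# Convention used throughout the package: 0-based continuous coordinates,
# origin at the image top-left, x increasing rightward, y increasing
# downward. A box is the closed rectangle [x_min, x_max] x [y_min, y_max]
# and must have strictly positive extent on both axes. Pixel (i, j) of a
# raster (row i, column j, 1-based) covers [j-1, j] x [i-1, i].

#' Construct a table of pixel boxes
#'
#' Boxes are the universal geometry of the package: annotations, detections
#' and ground truth are all tables with (at least) the four corner columns.
#' All arguments are recycled to a common length.
#'
#' @param x_min,y_min,x_max,y_max Numeric vectors of box corners in pixel
#'   coordinates (top-left origin, y downward). Each box must satisfy
#'   `x_max > x_min` and `y_max > y_min`.
#' @return A `data.frame` with columns `x_min`, `y_min`, `x_max`, `y_max`.
#' @examples
#' pixel_box(0, 0, 2, 2)
#' pixel_box(c(0, 10), c(0, 10), c(2, 12), c(2, 12))
#' @export
pixel_box <- function(x_min, y_min, x_max, y_max) {
  b <- data.frame(x_min = as.numeric(x_min), y_min = as.numeric(y_min),
                  x_max = as.numeric(x_max), y_max = as.numeric(y_max))
  validate_boxes(b)
  b
}

#' Validate box geometry
#'
#' Checks that a data frame carries the four corner columns and that every
#' box has strictly positive width and height. Degenerate (zero-area) boxes
#' are rejected: they have no well-defined IoU and cannot arise from a
#' rectangle annotation.
#'
#' @param boxes A data frame with columns `x_min`, `y_min`, `x_max`, `y_max`.
#' @return `boxes`, invisibly.
#' @export
validate_boxes <- function(boxes) {
  need <- c("x_min", "y_min", "x_max", "y_max")
  miss <- setdiff(need, names(boxes))
  if (length(miss) > 0L) {
    stop("invalid geometry: missing box column(s): ", paste(miss, collapse = ", "))
  }
  for (col in need) {
    if (!is.numeric(boxes[[col]]) || anyNA(boxes[[col]])) {
      stop("invalid geometry: non-numeric or missing values in '", col, "'")
    }
  }
  bad <- boxes$x_max <= boxes$x_min | boxes$y_max <= boxes$y_min
  if (any(bad)) {
    stop("invalid geometry: ", sum(bad),
         " box(es) with non-positive extent (x_max <= x_min or y_max <= y_min)")
  }
  invisible(boxes)
}

#' Box areas, widths, heights and centers
#'
#' @param boxes A box table (see [pixel_box()]).
#' @return `box_area()` returns a numeric vector of areas (px^2);
#'   `box_center()` a two-column data frame with the center `x` and `y` of
#'   each box.
#' @export
box_area <- function(boxes) {
  validate_boxes(boxes)
  (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min)
}

#' @rdname box_area
#' @export
box_center <- function(boxes) {
  validate_boxes(boxes)
  data.frame(x = (boxes$x_min + boxes$x_max) / 2,
             y = (boxes$y_min + boxes$y_max) / 2)
}

#' Intersection over union of two boxes
#'
#' IoU is the ratio of the intersection area to the union area of two
#' boxes. It is symmetric, lies in \[0, 1\], equals 1 only for identical
#' boxes and 0 for disjoint ones (boxes sharing only an edge have
#' intersection area 0 and hence IoU 0).
#'
#' @param a,b Single-row box tables, or anything accepted by
#'   [validate_boxes()] with exactly one row.
#' @return IoU score in \[0, 1\].
#' @examples
#' iou(pixel_box(0, 0, 2, 2), pixel_box(1, 0, 3, 2)) # 1/3
#' @export
iou <- function(a, b) {
  validate_boxes(a); validate_boxes(b)
  if (nrow(a) != 1L || nrow(b) != 1L) {
    stop("iou() expects single boxes; use iou_matrix() for sets")
  }
  iou_matrix(a, b)[1L, 1L]
}

#' Pairwise IoU between two sets of boxes
#'
#' @param a,b Box tables with `m` and `n` rows.
#' @return An `m x n` numeric matrix of IoU scores.
#' @export
iou_matrix <- function(a, b) {
  validate_boxes(a); validate_boxes(b)
  m <- nrow(a); n <- nrow(b)
  if (m == 0L || n == 0L) return(matrix(numeric(0), nrow = m, ncol = n))
  iw <- pmax(outer(a$x_max, b$x_max, pmin) - outer(a$x_min, b$x_min, pmax), 0)
  ih <- pmax(outer(a$y_max, b$y_max, pmin) - outer(a$y_min, b$y_min, pmax), 0)
  inter <- iw * ih
  union <- outer(box_area(a), box_area(b), `+`) - inter
  inter / union
}

#' Convert a pixel box to normalized center/size coordinates
#'
#' Produces the normalized representation used by YOLO-style label files:
#' box center and size expressed as fractions of the image width and
#' height, so labels generalize across image resolutions.
#'
#' @param boxes Box table in pixel coordinates.
#' @param image_w,image_h Image dimensions in pixels (positive scalars).
#' @param class_id Integer class label for every box (single class 0 =
#'   nodule by default).
#' @param tol Bounds tolerance in normalized units; boxes exceeding the
#'   image by more than `tol` are rejected.
#' @return A data frame with columns `class_id`, `cx`, `cy`, `w`, `h`,
#'   each of the last four in \[0, 1\].
#' @export
to_normalized <- function(boxes, image_w, image_h, class_id = 0L, tol = 1e-6) {
  validate_boxes(boxes)
  stopifnot(is.numeric(image_w), image_w > 0, is.numeric(image_h), image_h > 0)
  out_x <- boxes$x_min < -tol * image_w | boxes$x_max > image_w * (1 + tol)
  out_y <- boxes$y_min < -tol * image_h | boxes$y_max > image_h * (1 + tol)
  if (any(out_x | out_y)) {
    stop("out of bounds: ", sum(out_x | out_y), " box(es) exceed the ",
         image_w, "x", image_h, " image beyond tolerance")
  }
  ctr <- box_center(boxes)
  data.frame(class_id = rep_len(as.integer(class_id), nrow(boxes)),
             cx = ctr$x / image_w,
             cy = ctr$y / image_h,
             w  = (boxes$x_max - boxes$x_min) / image_w,
             h  = (boxes$y_max - boxes$y_min) / image_h)
}

#' Convert normalized center/size coordinates back to a pixel box
#'
#' Exact algebraic inverse of [to_normalized()].
#'
#' @param nboxes Data frame with columns `cx`, `cy`, `w`, `h` in \[0, 1\].
#' @param image_w,image_h Image dimensions in pixels.
#' @return A box table in pixel coordinates.
#' @export
from_normalized <- function(nboxes, image_w, image_h) {
  need <- c("cx", "cy", "w", "h")
  if (!all(need %in% names(nboxes))) {
    stop("normalized boxes need columns: ", paste(need, collapse = ", "))
  }
  if (any(nboxes$w <= 0 | nboxes$h <= 0)) {
    stop("invalid geometry: normalized width/height must be positive")
  }
  pixel_box(x_min = (nboxes$cx - nboxes$w / 2) * image_w,
            y_min = (nboxes$cy - nboxes$h / 2) * image_h,
            x_max = (nboxes$cx + nboxes$w / 2) * image_w,
            y_max = (nboxes$cy + nboxes$h / 2) * image_h)
}
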