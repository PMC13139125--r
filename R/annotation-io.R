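# Readers and writers for the three concrete annotation/detection formats
# the pipeline touches: LabelMe JSON (rectangle shapes), YOLO label text
# files (normalized class cx cy w h), and the final detections CSV.

#' Create an image annotation set
#'
#' The container tying a set of nodule bounding boxes to the image they
#' annotate. Boxes falling outside the image are clamped to the image
#' bounds with a warning (annotation tools occasionally emit corners a
#' fraction of a pixel outside the canvas).
#'
#' @param image_id Non-empty string identifying the image.
#' @param image_w,image_h Image dimensions in pixels.
#' @param boxes Box table ([pixel_box()]); may have zero rows.
#' @return An object of class `annotation_set`: a list with elements
#'   `image_id`, `image_w`, `image_h`, `boxes`.
#' @export
annotation_set <- function(image_id, image_w, image_h,
                           boxes = pixel_box(numeric(0), numeric(0),
                                             numeric(0), numeric(0))) {
  stopifnot(is.character(image_id), length(image_id) == 1L, nzchar(image_id),
            image_w > 0, image_h > 0)
  if (nrow(boxes) > 0L) {
    validate_boxes(boxes)
    eps <- 1e-6 * max(image_w, image_h)
    out <- boxes$x_min < -eps | boxes$y_min < -eps |
           boxes$x_max > image_w + eps | boxes$y_max > image_h + eps
    clip <- boxes$x_min < 0 | boxes$y_min < 0 |
            boxes$x_max > image_w | boxes$y_max > image_h
    if (any(out)) {
      warning(sum(out), " box(es) exceed the image bounds; clamping")
    }
    if (any(clip)) {
      boxes$x_min <- pmax(boxes$x_min, 0)
      boxes$y_min <- pmax(boxes$y_min, 0)
      boxes$x_max <- pmin(boxes$x_max, image_w)
      boxes$y_max <- pmin(boxes$y_max, image_h)
      validate_boxes(boxes)
    }
  }
  structure(list(image_id = image_id, image_w = image_w, image_h = image_h,
                 boxes = boxes[, c("x_min", "y_min", "x_max", "y_max")]),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> image '%s' (%g x %g px), %d box(es)\n",
              x$image_id, x$image_w, x$image_h, nrow(x$boxes)))
  invisible(x)
}

#' Read a LabelMe JSON annotation document
#'
#' Parses the JSON produced by the LabelMe annotation tool: image
#' dimensions from the `imageWidth`/`imageHeight` metadata (authoritative
#' even when an image payload is embedded) and one box per rectangle
#' shape, given as two opposite corner points in either order.
#' Non-rectangle shapes (polygons, points, ...) are skipped with a
#' warning. A document with zero shapes is a valid empty set.
#'
#' @param path Path to a LabelMe `.json` file, or a JSON string.
#' @param image_id Identifier for the image; defaults to the `imagePath`
#'   basename without extension, falling back to the file name.
#' @return An [annotation_set()].
#' @export
read_labelme <- function(path, image_id = NULL) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(doc$imageWidth) || is.null(doc$imageHeight)) {
    stop("LabelMe format error: missing imageWidth/imageHeight metadata")
  }
  w <- as.numeric(doc$imageWidth); h <- as.numeric(doc$imageHeight)
  if (is.null(image_id)) {
    src <- if (!is.null(doc$imagePath)) doc$imagePath
           else if (file.exists(path)) path else "image"
    image_id <- tools::file_path_sans_ext(basename(src))
  }
  shapes <- doc$shapes %||% list()
  rects <- Filter(function(s) identical(s$shape_type, "rectangle"), shapes)
  n_skip <- length(shapes) - length(rects)
  if (n_skip > 0L) {
    warning("skipping ", n_skip, " non-rectangle shape(s) in '", image_id, "'")
  }
  if (length(rects) == 0L) {
    return(annotation_set(image_id, w, h))
  }
  corners <- t(vapply(rects, function(s) {
    p <- s$points
    if (length(p) != 2L) stop("LabelMe format error: rectangle without 2 points")
    c(as.numeric(p[[1L]]), as.numeric(p[[2L]]))
  }, numeric(4)))
  boxes <- pixel_box(x_min = pmin(corners[, 1L], corners[, 3L]),
                     y_min = pmin(corners[, 2L], corners[, 4L]),
                     x_max = pmax(corners[, 1L], corners[, 3L]),
                     y_max = pmax(corners[, 2L], corners[, 4L]))
  annotation_set(image_id, w, h, boxes)
}

#' Write an annotation set as a LabelMe JSON document
#'
#' Inverse of [read_labelme()]; one rectangle shape per box, labeled
#' `"nodule"`.
#'
#' @param set An [annotation_set()].
#' @param path Output file path, or `NULL` to return the JSON text.
#' @return The JSON text, invisibly when written to a file.
#' @export
write_labelme <- function(set, path = NULL) {
  stopifnot(inherits(set, "annotation_set"))
  shapes <- lapply(seq_len(nrow(set$boxes)), function(i) {
    b <- set$boxes[i, ]
    list(label = "nodule",
         points = list(c(b$x_min, b$y_min), c(b$x_max, b$y_max)),
         group_id = NULL, shape_type = "rectangle", flags = c())
  })
  doc <- list(version = "5.0.0", flags = c(), shapes = shapes,
              imagePath = paste0(set$image_id, ".png"), imageData = NULL,
              imageHeight = set$image_h, imageWidth = set$image_w)
  txt <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null", digits = NA,
                          pretty = TRUE)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Write YOLO label lines for an annotation set
#'
#' One line per box, `"class cx cy w h"`, normalized to the source image
#' dimensions with six-decimal fixed formatting; single object class 0
#' (nodule).
#'
#' @param set An [annotation_set()].
#' @param path Output file path, or `NULL` to return the lines.
#' @return Character vector of label lines, invisibly when written.
#' @export
write_yolo_labels <- function(set, path = NULL) {
  stopifnot(inherits(set, "annotation_set"))
  if (nrow(set$boxes) == 0L) {
    lines <- character(0)
  } else {
    nb <- to_normalized(set$boxes, set$image_w, set$image_h)
    lines <- sprintf("%d %.6f %.6f %.6f %.6f", nb$class_id, nb$cx, nb$cy,
                     nb$w, nb$h)
  }
  if (is.null(path)) return(lines)
  writeLines(lines, path)
  invisible(lines)
}

#' Read YOLO label lines into an annotation set
#'
#' @param text Character vector of label lines, or a path to a `.txt`
#'   file. Blank lines are ignored.
#' @param image_w,image_h Dimensions of the source image the normalized
#'   coordinates refer to.
#' @param image_id Identifier for the resulting set.
#' @return An [annotation_set()].
#' @export
read_yolo_labels <- function(text, image_w, image_h, image_id = "image") {
  if (length(text) == 1L && file.exists(text)) text <- readLines(text)
  text <- trimws(text)
  keep <- nzchar(text)
  lines <- text[keep]
  if (length(lines) == 0L) return(annotation_set(image_id, image_w, image_h))
  orig_line <- which(keep)
  fields <- strsplit(lines, "[[:space:]]+")
  n_ok <- vapply(fields, length, integer(1)) == 5L
  vals <- suppressWarnings(lapply(fields, as.numeric))
  bad <- !n_ok | vapply(vals, anyNA, logical(1))
  if (any(bad)) {
    stop("YOLO parse error at line ", orig_line[which(bad)[1L]],
         ": expected 5 numeric fields, got '", lines[which(bad)[1L]], "'")
  }
  m <- do.call(rbind, vals)
  nb <- data.frame(class_id = as.integer(m[, 1L]), cx = m[, 2L], cy = m[, 3L],
                   w = m[, 4L], h = m[, 5L])
  annotation_set(image_id, image_w, image_h,
                 from_normalized(nb, image_w, image_h))
}

#' Write final detections as a CSV table
#'
#' The pipeline's primary structured output: the coordinates and
#' confidence of every refined nodule detection in full-resolution image
#' coordinates. Rows are ordered by `y_min`, then `x_min`, then
#' confidence descending, so repeated runs diff cleanly.
#'
#' @param detections Detection table in the image-global frame (see
#'   [as_detections()]).
#' @param image_id Identifier written in the first column.
#' @param path Output file path, or `NULL` to return the CSV data frame.
#' @return The ordered data frame written, invisibly when `path` given.
#' @export
write_detections_csv <- function(detections, image_id, path = NULL) {
  detections <- as_detections(detections, frame = NULL)
  if (nrow(detections) > 0L && any(detections$frame != "global")) {
    stop("frame error: detections must be image-global before CSV export")
  }
  ord <- order(detections$y_min, detections$x_min, -detections$confidence)
  out <- data.frame(image_id = rep_len(image_id, nrow(detections)),
                    detections[ord, c("x_min", "y_min", "x_max", "y_max",
                                      "confidence")])
  rownames(out) <- NULL
  if (is.null(path)) return(out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' Read a detections CSV written by [write_detections_csv()]
#'
#' @param path CSV file path.
#' @return A detection table in the image-global frame, with an
#'   `image_id` column.
#' @export
read_detections_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("image_id", "x_min", "y_min", "x_max", "y_max", "confidence")
  if (!all(need %in% names(df))) {
    stop("detections CSV format error: expected columns ",
         paste(need, collapse = ", "))
  }
  df$frame <- rep_len("global", nrow(df))
  if (nrow(df) > 0L) validate_boxes(df)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
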