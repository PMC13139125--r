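# Overlap tiling of full-resolution root images into fixed-size patches.
#
# Full images (~2300 x 4600 px) are decomposed into 512 x 512 patches
# with a 64-px overlap between neighbors, chosen so that the overlap
# exceeds the largest nodule: any box with both sides <= overlap is then
# fully contained, unclipped, in at least one patch, which is what makes
# stitch-back with duplicate suppression lossless for whole nodules.

#' Tiling configuration
#'
#' @param patch_size Patch side length in pixels.
#' @param overlap Overlap between adjacent patches in pixels; must be
#'   smaller than `patch_size`. The stride between patch origins is
#'   `patch_size - overlap`.
#' @return A list of class `tiler_config`.
#' @export
tiler_config <- function(patch_size = 512, overlap = 64) {
  stopifnot(patch_size > 0, overlap >= 0, overlap < patch_size)
  structure(list(patch_size = patch_size, overlap = overlap,
                 stride = patch_size - overlap),
            class = "tiler_config")
}

#' Plan the patch grid for an image
#'
#' Patch origins are laid at 0, stride, 2*stride, ... along each axis,
#' with the final origin clamped to `dim - patch_size` so the last patch
#' ends exactly at the image border (every patch is full-size and the
#' union covers every pixel). Images smaller than the patch get a single
#' origin at 0; the crop is zero-padded on the bottom/right.
#'
#' @param image_w,image_h Image dimensions in pixels.
#' @param config A [tiler_config()].
#' @param image_id Identifier carried into each patch spec.
#' @return A data frame of patch specs with columns `image_id`, `row`,
#'   `col` (0-based grid indices), `x0`, `y0` (patch origin in image
#'   coordinates) and `width`, `height` (always `patch_size`).
#' @examples
#' nrow(plan_patches(2300, 4600)) # 5 columns x 11 rows = 55 patches
#' @export
plan_patches <- function(image_w, image_h, config = tiler_config(),
                         image_id = "image") {
  stopifnot(image_w > 0, image_h > 0, inherits(config, "tiler_config"))
  origins <- function(dim) {
    if (dim <= config$patch_size) return(0)
    o <- seq(0, dim - config$patch_size + config$stride - 1e-9,
             by = config$stride)
    o <- unique(pmin(o, dim - config$patch_size))
    o
  }
  xo <- origins(image_w)
  yo <- origins(image_h)
  grid <- expand.grid(col = seq_along(xo) - 1L, row = seq_along(yo) - 1L)
  data.frame(image_id = image_id,
             row = grid$row, col = grid$col,
             x0 = xo[grid$col + 1L], y0 = yo[grid$row + 1L],
             width = config$patch_size, height = config$patch_size)
}

#' Crop one patch out of a raster image
#'
#' Images are numeric arrays indexed `[row, col]` (optionally with a
#' third channel dimension), values on any scale. The crop is
#' pixel-exact; regions beyond the image (possible only when the image is
#' smaller than the patch) are filled with zeros.
#'
#' @param image Numeric matrix `[h, w]` or array `[h, w, channels]`.
#' @param spec One row of a [plan_patches()] table.
#' @return A `patch_size x patch_size` matrix/array.
#' @export
crop_patch <- function(image, spec) {
  stopifnot(nrow(spec) == 1L)
  d <- dim(image)
  h <- d[1L]; w <- d[2L]; ch <- if (length(d) == 3L) d[3L] else 1L
  if (spec$x0 + 1 > w || spec$y0 + 1 > h) {
    stop("patch spec does not belong to this image: origin outside raster")
  }
  ph <- spec$height; pw <- spec$width
  out <- array(0, dim = if (length(d) == 3L) c(ph, pw, ch) else c(ph, pw))
  rows <- seq_len(min(ph, h - spec$y0))
  cols <- seq_len(min(pw, w - spec$x0))
  if (length(d) == 3L) {
    out[rows, cols, ] <- image[spec$y0 + rows, spec$x0 + cols, , drop = FALSE]
  } else {
    out[rows, cols] <- image[spec$y0 + rows, spec$x0 + cols, drop = FALSE]
  }
  out
}

#' Remap full-image annotations into one patch's local frame
#'
#' Boxes intersecting the patch are translated by `(-x0, -y0)` and
#' clipped to the patch square; boxes with empty intersection are
#' dropped, so the result lists exactly the nodules (or nodule parts)
#' visible within that patch.
#'
#' @param set An [annotation_set()] in full-image coordinates.
#' @param spec One row of the patch plan for the same image.
#' @return An [annotation_set()] in patch-local coordinates whose
#'   `image_id` is `{image_id}_r{row}_c{col}`.
#' @export
remap_labels <- function(set, spec) {
  stopifnot(inherits(set, "annotation_set"), nrow(spec) == 1L)
  if (!identical(set$image_id, spec$image_id)) {
    stop("annotation set and patch spec refer to different images ('",
         set$image_id, "' vs '", spec$image_id, "')")
  }
  pid <- patch_id(spec)
  b <- set$boxes
  if (nrow(b) > 0L) {
    x_min <- pmax(b$x_min - spec$x0, 0)
    y_min <- pmax(b$y_min - spec$y0, 0)
    x_max <- pmin(b$x_max - spec$x0, spec$width)
    y_max <- pmin(b$y_max - spec$y0, spec$height)
    keep <- x_max > x_min & y_max > y_min
    b <- pixel_box(x_min[keep], y_min[keep], x_max[keep], y_max[keep])
  }
  annotation_set(pid, spec$width, spec$height, b)
}

#' Patch naming convention
#'
#' @param spec One or more rows of a patch plan.
#' @return `"{image_id}_r{row}_c{col}"` for each row.
#' @export
patch_id <- function(spec) {
  sprintf("%s_r%d_c%d", spec$image_id, spec$row, spec$col)
}

#' Write a patch-plan manifest CSV
#'
#' The manifest (`image_id,row,col,x0,y0,width,height`) makes stitching
#' self-describing: downstream stages need only the manifest and the
#' per-patch detections.
#'
#' @param plan A [plan_patches()] table (one or several images).
#' @param path Output CSV path, or `NULL` to return the data frame.
#' @return The manifest data frame, invisibly when written.
#' @export
write_patch_manifest <- function(plan, path = NULL) {
  cols <- c("image_id", "row", "col", "x0", "y0", "width", "height")
  stopifnot(all(cols %in% names(plan)))
  out <- plan[, cols]
  if (is.null(path)) return(out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

#' @rdname write_patch_manifest
#' @param path_in Manifest CSV path to read.
#' @export
read_patch_manifest <- function(path_in) {
  df <- utils::read.csv(path_in, stringsAsFactors = FALSE)
  cols <- c("image_id", "row", "col", "x0", "y0", "width", "height")
  if (!all(cols %in% names(df))) {
    stop("patch manifest format error: expected columns ",
         paste(cols, collapse = ", "))
  }
  df
}
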