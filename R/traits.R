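# The 24 nodulation traits computed from one image's final detections.
#
# Six scalar descriptors — nodule count, the vertical (height) and
# horizontal (width) extent of the nodulated zone measured between
# extreme box centers, the dispersions sdx/sdy of the center
# coordinates, and their ratio sdxy = sdx/sdy — plus nine order/moment
# statistics (min, max, sd, mean, median, p5, p25, p75, p95) over the
# per-box areas and the same nine over the center y-coordinates, which
# proxy the depth distribution of nodulation along the root.

#' The fixed 24-trait schema
#'
#' @return Character vector of the 24 trait names, in the order used for
#'   every phenotype table the package writes.
#' @export
trait_names <- function() {
  stats9 <- c("min", "max", "std", "mean", "median", "p5", "p25", "p75", "p95")
  c("count", "height", "width", "sdx", "sdy", "sdxy",
    paste0("box_area_", stats9), paste0("y_center_", stats9))
}

# nine order/moment statistics over a numeric vector; percentiles use
# linear interpolation between closest ranks (quantile type 7)
nine_stats <- function(x, ddof = 0) {
  q <- stats::quantile(x, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE,
                       type = 7)
  c(min = min(x), max = max(x), std = sd_ddof(x, ddof), mean = mean(x),
    median = q[3L], p5 = q[1L], p25 = q[2L], p75 = q[4L], p95 = q[5L])
}

sd_ddof <- function(x, ddof = 0) {
  n <- length(x)
  if (n - ddof <= 0) return(0)
  sqrt(sum((x - mean(x))^2) / (n - ddof))
}

#' Extract the 24 nodulation traits from an image's detections
#'
#' @param detections Image-global detection table (or any box table);
#'   typically the output of [refine_image()].
#' @param ddof Delta degrees of freedom for every standard deviation
#'   (0 = population, the default; 1 = sample).
#' @return A named numeric vector with exactly the 24 entries of
#'   [trait_names()]. Degenerate inputs never error: with no detections
#'   every trait except `count = 0` is `NA`; with a single detection the
#'   dispersion statistics are 0 and `sdxy` is `NA` (0/0); `sdxy` is
#'   also `NA` (with a warning) when `sdy = 0` while `sdx > 0`.
#' @examples
#' d <- as_detections(pixel_box(95, 195, 105, 205))
#' extract_traits(d)[c("count", "box_area_mean", "y_center_mean")]
#' @export
extract_traits <- function(detections, ddof = 0) {
  out <- stats::setNames(rep(NA_real_, 24L), trait_names())
  n <- nrow(detections)
  out["count"] <- n
  if (n == 0L) return(out)
  validate_boxes(detections)
  ctr <- box_center(detections)
  area <- box_area(detections)
  out["height"] <- max(ctr$y) - min(ctr$y)
  out["width"] <- max(ctr$x) - min(ctr$x)
  sdx <- sd_ddof(ctr$x, ddof)
  sdy <- sd_ddof(ctr$y, ddof)
  out["sdx"] <- sdx
  out["sdy"] <- sdy
  if (sdy > 0) {
    out["sdxy"] <- sdx / sdy
  } else if (sdx > 0) {
    warning("sdy = 0 with sdx > 0: sdxy undefined, set to NA")
  } # else 0/0: NA without warning (single nodule or perfectly aligned)
  out[paste0("box_area_", names(nine_stats(area)))] <- nine_stats(area, ddof)
  out[paste0("y_center_", names(nine_stats(ctr$y)))] <- nine_stats(ctr$y, ddof)
  out
}

#' Extract traits for many images into a phenotype table
#'
#' @param detection_list Named list of per-image detection tables; names
#'   become the `image_id` column.
#' @param ddof Passed to [extract_traits()].
#' @return A data frame with `image_id` plus the 24 trait columns in
#'   [trait_names()] order.
#' @export
extract_trait_table <- function(detection_list, ddof = 0) {
  stopifnot(is.list(detection_list), !is.null(names(detection_list)),
            all(nzchar(names(detection_list))))
  rows <- lapply(detection_list, extract_traits, ddof = ddof)
  out <- as.data.frame(do.call(rbind, rows))
  out <- cbind(image_id = names(detection_list), out)
  rownames(out) <- NULL
  out
}

#' Write a phenotype CSV
#'
#' One row per image, `image_id` plus the 24 trait columns in fixed
#' order; missing values are written as empty fields.
#'
#' @param trait_table Output of [extract_trait_table()].
#' @param path Output CSV path, or `NULL` to return the data frame.
#' @return The data frame written, invisibly when `path` given.
#' @export
write_phenotype_csv <- function(trait_table, path = NULL) {
  stopifnot(all(c("image_id", trait_names()) %in% names(trait_table)))
  out <- trait_table[, c("image_id", trait_names())]
  if (is.null(path)) return(out)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(out)
}

#' Read a phenotype CSV written by [write_phenotype_csv()]
#'
#' @param path CSV path.
#' @return Data frame with `image_id` plus the 24 trait columns.
#' @export
read_phenotype_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  if (!all(c("image_id", trait_names()) %in% names(df))) {
    stop("phenotype CSV format error: expected image_id + 24 trait columns")
  }
  df
}
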