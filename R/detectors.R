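# Pluggable detector backends.
#
# The pipeline is detector-agnostic: any function that maps a patch to a
# list of patch-local boxes with confidences can drive it. Three backends
# are provided:
#   * "mock" — corrupts attached ground truth with configurable jitter,
#     miss rate and spurious boxes; the test oracle for every
#     post-processing and evaluation stage.
#   * "blob" — classical thresholding + connected components + size
#     filter (via EBImage), so the pipeline can run on actual rasters
#     without any trained model.
#   * "external" — adapter slot for a trained detector (e.g. a YOLO
#     model served from another process); the caller supplies the
#     prediction function, nothing is re-implemented here.

#' Detector specification
#'
#' @param backend One of `"mock"`, `"blob"`, `"external"`.
#' @param params Backend-specific parameter list:
#'   * mock: `ground_truth` (patch-local [annotation_set()]),
#'     `jitter_sd` (px, default 0), `fn_rate` (default 0),
#'     `fp_per_image` (mean spurious boxes per patch, default 0),
#'     `confidence_range` (default `c(1, 1)`).
#'   * blob: `threshold` (intensity below which a pixel is foreground,
#'     default 0.35), `min_area`/`max_area` (px^2 component size filter,
#'     defaults 20 and 1e4), `confidence` (assigned score, default 0.9).
#'   * external: `predict_fn(patch)` returning a data frame with columns
#'     `x_min,y_min,x_max,y_max,confidence` in patch-local pixels, plus
#'     any passthrough settings (weights path, epochs, batch size, ...)
#'     your adapter consumes.
#' @param seed Integer seed for stochastic backends.
#' @return A list of class `detector_spec`.
#' @export
detector_spec <- function(backend = c("mock", "blob", "external"),
                          params = list(), seed = 1L) {
  backend <- match.arg(backend)
  structure(list(backend = backend, params = params, seed = as.integer(seed)),
            class = "detector_spec")
}

#' Run a detector backend on one patch
#'
#' @param patch Numeric matrix/array raster (`patch_size` square), or
#'   `NULL` for the mock backend (which reads its attached ground truth,
#'   not pixels).
#' @param spec A [detector_spec()].
#' @return A patch-local detection table ([as_detections()]).
#' @export
detect <- function(patch, spec) {
  stopifnot(inherits(spec, "detector_spec"))
  switch(spec$backend,
         mock = detect_mock(spec),
         blob = detect_blob(patch, spec),
         external = detect_external(patch, spec))
}

detect_mock <- function(spec) {
  p <- spec$params
  gt <- p$ground_truth
  if (is.null(gt) || !inherits(gt, "annotation_set")) {
    stop("configuration error: mock backend needs params$ground_truth ",
         "(a patch-local annotation_set)")
  }
  cfg <- mock_detector_config(jitter_sd = p$jitter_sd %||% 0,
                              fn_rate = p$fn_rate %||% 0,
                              fp_per_image = p$fp_per_image %||% 0,
                              confidence_range = p$confidence_range %||% c(1, 1),
                              seed = spec$seed)
  det <- mock_detect(gt, cfg)
  det$frame <- rep_len("patch", nrow(det))
  det
}

detect_blob <- function(patch, spec) {
  if (!requireNamespace("EBImage", quietly = TRUE)) {
    stop("configuration error: blob backend requires the EBImage package")
  }
  if (is.null(patch)) stop("blob backend needs a raster patch")
  p <- spec$params
  threshold <- p$threshold %||% 0.35
  min_area <- p$min_area %||% 20
  max_area <- p$max_area %||% 1e4
  confid <- p$confidence %||% 0.9
  img <- if (length(dim(patch)) == 3L) {
    # luminance of an RGB raster
    0.299 * patch[, , 1L] + 0.587 * patch[, , 2L] + 0.114 * patch[, , 3L]
  } else patch
  mask <- img < threshold
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0L) return(as_detections(empty_detections(), frame = "patch"))
  idx <- which(lab > 0, arr.ind = TRUE)
  labs <- lab[lab > 0]
  rows <- split(idx[, 1L], labs)
  cols <- split(idx[, 2L], labs)
  # pixel (i, j) covers [j-1, j] x [i-1, i] in continuous coordinates
  boxes <- data.frame(
    x_min = vapply(cols, min, numeric(1)) - 1,
    y_min = vapply(rows, min, numeric(1)) - 1,
    x_max = vapply(cols, max, numeric(1)),
    y_max = vapply(rows, max, numeric(1)))
  area <- (boxes$x_max - boxes$x_min) * (boxes$y_max - boxes$y_min)
  boxes <- boxes[area >= min_area & area <= max_area, , drop = FALSE]
  as_detections(boxes, confidence = confid, frame = "patch")
}

detect_external <- function(patch, spec) {
  p <- spec$params
  if (is.null(p$predict_fn)) {
    if (!is.null(p$weights) && !file.exists(p$weights)) {
      stop("configuration error: external detector weights file not found: ",
           p$weights)
    }
    stop("configuration error: external backend needs params$predict_fn ",
         "(and typically params$weights for the adapter it wraps)")
  }
  out <- p$predict_fn(patch)
  as_detections(out, frame = "patch")
}

#' Run a detector over a whole patch plan
#'
#' Convenience driver used by the pipeline: for every patch in the plan
#' it extracts the patch inputs (raster crop and/or remapped ground
#' truth), calls the backend, and tags the detections with the patch's
#' `row`/`col` so they can be stitched back.
#'
#' @param plan Patch plan for one image ([plan_patches()]).
#' @param spec A [detector_spec()]. For the mock backend, supply the
#'   full-image ground truth via `ground_truth` here; it is remapped per
#'   patch automatically.
#' @param image Full-image raster (required for blob/external backends).
#' @param ground_truth Full-image [annotation_set()] (mock backend).
#' @return A patch-local detection table with `row`/`col` columns.
#' @export
detect_patches <- function(plan, spec, image = NULL, ground_truth = NULL) {
  stopifnot(inherits(spec, "detector_spec"))
  out <- vector("list", nrow(plan))
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    spec_i <- spec
    # per-patch seed: reproducible and independent across patches
    spec_i$seed <- spec$seed + 7919L * i
    if (spec$backend == "mock") {
      gt <- ground_truth %||% spec$params$ground_truth
      if (is.null(gt)) {
        stop("configuration error: mock backend needs ground truth")
      }
      spec_i$params$ground_truth <- remap_labels(gt, p)
      det <- detect(NULL, spec_i)
    } else {
      if (is.null(image)) stop("backend '", spec$backend, "' needs a raster image")
      det <- detect(crop_patch(image, p), spec_i)
    }
    det$row <- rep_len(p$row, nrow(det))
    det$col <- rep_len(p$col, nrow(det))
    out[[i]] <- det
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- as_detections(empty_detections(), frame = "patch", row = integer(0),
                         col = integer(0))
  }
  rownames(res) <- NULL
  res
}
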