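# Synthetic root scenes and a mock detector with controlled errors.
#
# Emulates the imaging setup the pipeline targets: a washed root system
# spread on blue blotter paper and photographed at ~2300 x 4600 px, with
# sparse, non-overlapping, roughly elliptical nodules strung along a
# vertical taproot. Nodule sizes follow a truncated lognormal whose mean
# matches the testing-set average nodule length (19.93 px) with a hard
# cap at the largest observed length (57 px). Every random draw is a
# pure function of the configured seed.

#' Scene configuration
#'
#' @param image_w,image_h Scene dimensions in pixels.
#' @param n_nodules Number of nodules to place.
#' @param size_mean Target mean of the larger box side, px.
#' @param size_max Hard cap on box sides, px. The cap is treated as the
#'   ~99.9th percentile of the size distribution when calibrating its
#'   spread, i.e. as the maximum one expects to observe over a
#'   testing set of roughly a thousand nodules.
#' @param min_separation Minimum gap between nodule boxes, px; any
#'   positive value guarantees pairwise IoU 0 among ground-truth boxes.
#' @param along_root_layout If `TRUE`, nodule centers cluster around a
#'   simulated vertical taproot curve instead of scattering uniformly.
#' @param root_stripe If `TRUE`, rasterized scenes include the dark
#'   taproot stripe; disable for plain-background fixtures.
#' @param qr_decoys If `TRUE`, stamp QR-code-like dot patterns on the
#'   background (negative controls for raster-based detectors).
#' @param seed Integer seed; scenes are reproducible from it.
#' @return A list of class `scene_config`.
#' @export
scene_config <- function(image_w = 2300, image_h = 4600, n_nodules = 25,
                         size_mean = 19.93, size_max = 57,
                         min_separation = 10, along_root_layout = TRUE,
                         root_stripe = TRUE, qr_decoys = FALSE, seed = 1L) {
  stopifnot(image_w > 0, image_h > 0, n_nodules >= 0,
            size_mean > 0, size_max >= size_mean, min_separation >= 0)
  structure(list(image_w = image_w, image_h = image_h,
                 n_nodules = as.integer(n_nodules), size_mean = size_mean,
                 size_max = size_max, min_separation = min_separation,
                 along_root_layout = isTRUE(along_root_layout),
                 root_stripe = isTRUE(root_stripe),
                 qr_decoys = isTRUE(qr_decoys), seed = as.integer(seed)),
            class = "scene_config")
}

#' Mock detector configuration
#'
#' Error model used to corrupt ground truth: each true box is missed
#' independently with probability `fn_rate`; surviving boxes are
#' re-centered with Gaussian noise of sd `jitter_sd` and given a
#' confidence drawn uniformly from `confidence_range`; spurious boxes
#' are added with a Poisson(`fp_per_image`) count, placed disjoint from
#' all ground truth.
#'
#' @param jitter_sd Center jitter sd, px.
#' @param fn_rate Miss probability in \[0, 1\].
#' @param fp_per_image Mean number of spurious boxes.
#' @param confidence_range Length-2 interval within \[0, 1\].
#' @param seed Integer seed.
#' @return A list of class `mock_detector_config`.
#' @export
mock_detector_config <- function(jitter_sd = 0, fn_rate = 0,
                                 fp_per_image = 0,
                                 confidence_range = c(1, 1), seed = 1L) {
  stopifnot(jitter_sd >= 0, fn_rate >= 0, fn_rate <= 1, fp_per_image >= 0,
            length(confidence_range) == 2L,
            confidence_range[1L] <= confidence_range[2L],
            confidence_range[1L] >= 0, confidence_range[2L] <= 1)
  structure(list(jitter_sd = jitter_sd, fn_rate = fn_rate,
                 fp_per_image = fp_per_image,
                 confidence_range = confidence_range, seed = as.integer(seed)),
            class = "mock_detector_config")
}

# evaluate code under a temporary RNG state seeded from `seed`
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# sigma of a lognormal with mean `size_mean` whose `size_max` falls at
# the `p`-th quantile; meanlog is then log(size_mean) - sigma^2 / 2
calibrate_sdlog <- function(size_mean, size_max, p = 0.999) {
  zp <- stats::qnorm(p)
  f <- function(s) log(size_max) - (log(size_mean) - s^2 / 2) - zp * s
  root <- tryCatch(stats::uniroot(f, c(1e-3, 1.5))$root, error = function(e) NA)
  if (is.na(root)) 0.36 else root
}

draw_sizes <- function(n, size_mean, size_max) {
  if (n == 0L) return(numeric(0))
  sdlog <- calibrate_sdlog(size_mean, size_max)
  meanlog <- log(size_mean) - sdlog^2 / 2
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rlnorm(n, meanlog, sdlog)
    out <- c(out, x[x <= size_max & x >= 2])
  }
  out[seq_len(n)]
}

#' Generate a synthetic root scene
#'
#' Places `n_nodules` non-overlapping elliptical nodules (tight
#' ground-truth box per nodule) on a blue-toned background with a dark
#' taproot stripe. Placement is rejection sampling under the
#' `min_separation` gap; an infeasible packing raises an error after the
#' retry budget.
#'
#' @param config A [scene_config()].
#' @param image_id Identifier for the scene.
#' @param render If `TRUE`, also rasterize the scene as an RGB array
#'   `[h, w, 3]` in \[0, 1\]; with `FALSE` only geometry is generated,
#'   which is all the box-level pipeline stages need and is far cheaper
#'   for full-size scenes.
#' @return A list with `image` (array or `NULL`) and `annotations` (the
#'   ground-truth [annotation_set()]).
#' @export
generate_scene <- function(config = scene_config(), image_id = "scene",
                           render = FALSE) {
  stopifnot(inherits(config, "scene_config"))
  with_seed(config$seed, {
    n <- config$n_nodules
    w <- config$image_w; h <- config$image_h
    root_x <- root_curve(h, w)
    boxes <- place_nodules(n, config, root_x)
    set <- annotation_set(image_id, w, h, boxes)
    img <- if (render) render_scene(set, config, root_x) else NULL
    list(image = img, annotations = set)
  })
}

# taproot center line: gentle sinusoidal drift around the image midline
root_curve <- function(image_h, image_w) {
  y <- seq_len(image_h)
  amp <- image_w * 0.06 * stats::runif(1, 0.5, 1.5)
  phase <- stats::runif(1, 0, 2 * pi)
  image_w / 2 + amp * sin(2 * pi * y / image_h * stats::runif(1, 1, 2) + phase)
}

place_nodules <- function(n, config, root_x) {
  w <- config$image_w; h <- config$image_h
  gap <- config$min_separation
  if (n == 0L) {
    return(pixel_box(numeric(0), numeric(0), numeric(0), numeric(0)))
  }
  sizes <- draw_sizes(n, config$size_mean, config$size_max)
  aspect <- stats::runif(n, 0.65, 1)
  swap <- stats::runif(n) < 0.5
  wx <- ifelse(swap, sizes * aspect, sizes)
  wy <- ifelse(swap, sizes, sizes * aspect)
  placed <- matrix(numeric(0), ncol = 4L)
  budget <- 200L * n
  for (i in seq_len(n)) {
    ok <- FALSE
    while (budget > 0L) {
      budget <- budget - 1L
      cy <- stats::runif(1, wy[i] / 2, h - wy[i] / 2)
      cx <- if (config$along_root_layout) {
        rx <- root_x[max(1L, min(h, round(cy)))]
        min(max(rx + stats::rnorm(1, 0, w / 8), wx[i] / 2), w - wx[i] / 2)
      } else {
        stats::runif(1, wx[i] / 2, w - wx[i] / 2)
      }
      cand <- c(cx - wx[i] / 2, cy - wy[i] / 2, cx + wx[i] / 2, cy + wy[i] / 2)
      if (nrow(placed) == 0L ||
          all(cand[1L] - gap >= placed[, 3L] | cand[3L] + gap <= placed[, 1L] |
              cand[2L] - gap >= placed[, 4L] | cand[4L] + gap <= placed[, 2L])) {
        placed <- rbind(placed, cand)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      stop("packing error: could not place ", n, " nodules at min_separation ",
           gap, " within the retry budget")
    }
  }
  pixel_box(placed[, 1L], placed[, 2L], placed[, 3L], placed[, 4L])
}

render_scene <- function(set, config, root_x) {
  w <- config$image_w; h <- config$image_h
  base <- c(0.42, 0.55, 0.78) # blue blotter paper
  img <- array(0, dim = c(h, w, 3L))
  noise <- matrix(stats::rnorm(h * w, 0, 0.015), h, w)
  for (ch in 1:3) img[, , ch] <- base[ch] + noise
  if (config$root_stripe) {
    # dark taproot stripe along the curve
    half_w <- 12
    root_col <- c(0.30, 0.22, 0.15)
    for (i in seq_len(h)) {
      j0 <- max(1L, floor(root_x[i] - half_w))
      j1 <- min(w, ceiling(root_x[i] + half_w))
      if (j0 <= j1) for (ch in 1:3) img[i, j0:j1, ch] <- root_col[ch]
    }
  }
  if (config$qr_decoys) img <- stamp_qr_decoys(img)
  # nodules: filled dark ellipses tightly inscribed in their boxes
  nod_col <- c(0.25, 0.18, 0.12)
  b <- set$boxes
  for (k in seq_len(nrow(b))) {
    cx <- (b$x_min[k] + b$x_max[k]) / 2
    cy <- (b$y_min[k] + b$y_max[k]) / 2
    a <- (b$x_max[k] - b$x_min[k]) / 2
    bb <- (b$y_max[k] - b$y_min[k]) / 2
    rows <- max(1L, ceiling(b$y_min[k])):min(h, ceiling(b$y_max[k]))
    cols <- max(1L, ceiling(b$x_min[k])):min(w, ceiling(b$x_max[k]))
    # pixel centers
    px <- cols - 0.5; py <- rows - 0.5
    inside <- outer((py - cy)^2 / bb^2, (px - cx)^2 / a^2, `+`) <= 1
    for (ch in 1:3) {
      sub <- img[rows, cols, ch]
      sub[inside] <- nod_col[ch]
      img[rows, cols, ch] <- sub
    }
  }
  img[img < 0] <- 0; img[img > 1] <- 1
  img
}

stamp_qr_decoys <- function(img) {
  h <- dim(img)[1L]; w <- dim(img)[2L]
  # 3 blocks of dense 3-px dot grids near the top-right corner
  for (blk in 0:2) {
    y0 <- 20 + blk * 40
    x0 <- w - 80
    if (y0 + 30 > h || x0 < 1) next
    for (r in seq(0, 27, by = 6)) for (cc in seq(0, 27, by = 6)) {
      if (stats::runif(1) < 0.5) next
      rows <- (y0 + r):(y0 + r + 2)
      cols <- (x0 + cc):(x0 + cc + 2)
      img[rows, cols, ] <- 0.05
    }
  }
  img
}

#' Corrupt ground truth with a configurable detector error model
#'
#' @param gt An [annotation_set()] (any coordinate frame).
#' @param config A [mock_detector_config()].
#' @return An image-global detection table; with `jitter_sd = 0`,
#'   `fn_rate = 0`, `fp_per_image = 0` and `confidence_range = c(1, 1)`
#'   it is exactly the ground truth at confidence 1 (the oracle limit).
#' @export
mock_detect <- function(gt, config = mock_detector_config()) {
  stopifnot(inherits(gt, "annotation_set"),
            inherits(config, "mock_detector_config"))
  with_seed(config$seed, {
    b <- gt$boxes
    n <- nrow(b)
    keep <- if (n > 0L) stats::runif(n) >= config$fn_rate else logical(0)
    b <- b[keep, , drop = FALSE]
    if (nrow(b) > 0L && config$jitter_sd > 0) {
      dx <- stats::rnorm(nrow(b), 0, config$jitter_sd)
      dy <- stats::rnorm(nrow(b), 0, config$jitter_sd)
      b$x_min <- b$x_min + dx; b$x_max <- b$x_max + dx
      b$y_min <- b$y_min + dy; b$y_max <- b$y_max + dy
    }
    conf <- stats::runif(nrow(b), config$confidence_range[1L],
                         config$confidence_range[2L])
    det <- as_detections(b, confidence = conf, frame = "global")
    n_fp <- stats::rpois(1, config$fp_per_image)
    if (n_fp > 0L) {
      fp <- place_false_positives(n_fp, gt)
      fp_conf <- stats::runif(n_fp, config$confidence_range[1L],
                              config$confidence_range[2L])
      det <- rbind(det, as_detections(fp, confidence = fp_conf,
                                      frame = "global"))
    }
    rownames(det) <- NULL
    det
  })
}

place_false_positives <- function(n_fp, gt) {
  w <- gt$image_w; h <- gt$image_h
  b <- gt$boxes
  out <- matrix(numeric(0), ncol = 4L)
  budget <- 500L * n_fp
  while (nrow(out) < n_fp && budget > 0L) {
    budget <- budget - 1L
    side <- stats::runif(2, 8, 40)
    side <- pmin(side, c(w, h) / 2)
    cx <- stats::runif(1, side[1L] / 2, w - side[1L] / 2)
    cy <- stats::runif(1, side[2L] / 2, h - side[2L] / 2)
    cand <- c(cx - side[1L] / 2, cy - side[2L] / 2,
              cx + side[1L] / 2, cy + side[2L] / 2)
    clear_gt <- nrow(b) == 0L ||
      all(cand[1L] >= b$x_max | cand[3L] <= b$x_min |
          cand[2L] >= b$y_max | cand[4L] <= b$y_min)
    clear_prev <- nrow(out) == 0L ||
      all(cand[1L] >= out[, 3L] | cand[3L] <= out[, 1L] |
          cand[2L] >= out[, 4L] | cand[4L] <= out[, 2L])
    if (clear_gt && clear_prev) out <- rbind(out, cand)
  }
  if (nrow(out) < n_fp) {
    stop("packing error: could not place ", n_fp,
         " false positives disjoint from ground truth")
  }
  pixel_box(out[, 1L], out[, 2L], out[, 3L], out[, 4L])
}

#' Construct the worked confusion-matrix fixture
#'
#' A deterministic scene with 559 pairwise-disjoint ground-truth boxes;
#' the prediction list contains verbatim copies of 515 of them plus 62
#' boxes disjoint from every ground-truth box. Scored with
#' [match_detections()] this yields TP 515, FP 62, FN 44 at any
#' matching IoU threshold in (0, 1], since the copied boxes match at
#' IoU 1 and the spurious boxes overlap nothing.
#'
#' @return A list with `ground_truth` (an [annotation_set()]) and
#'   `predictions` (an image-global detection table).
#' @export
make_paper_confusion_fixture <- function() {
  n_gt <- 559L; n_tp <- 515L; n_fp <- 62L
  pitch <- 40; side <- 10
  ncol_grid <- 24L
  k <- seq_len(n_gt) - 1L
  gx <- (k %% ncol_grid) * pitch
  gy <- (k %/% ncol_grid) * pitch
  gt_boxes <- pixel_box(gx, gy, gx + side, gy + side)
  canvas <- ncol_grid * pitch + pitch
  gt <- annotation_set("confusion_fixture", canvas,
                       (ceiling(n_gt / ncol_grid) + 1L) * pitch, gt_boxes)
  j <- seq_len(n_fp) - 1L
  fx <- (j %% ncol_grid) * pitch + pitch / 2
  fy <- (j %/% ncol_grid) * pitch + pitch / 2
  fp_boxes <- pixel_box(fx, fy, fx + side, fy + side)
  preds <- rbind(gt_boxes[seq_len(n_tp), ], fp_boxes)
  list(ground_truth = gt,
       predictions = as_detections(preds, confidence = 0.9, frame = "global"))
}
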