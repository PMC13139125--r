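# Independent brute-force oracles the unit tests check the package
# implementations against. These deliberately share no code with R/.

# IoU estimated by counting unit pixels (centers at half-integers)
# inside each box; exact for integer-corner boxes.
raster_iou <- function(a, b) {
  x0 <- floor(min(a$x_min, b$x_min)); x1 <- ceiling(max(a$x_max, b$x_max))
  y0 <- floor(min(a$y_min, b$y_min)); y1 <- ceiling(max(a$y_max, b$y_max))
  px <- seq(x0 + 0.5, x1 - 0.5, by = 1)
  py <- seq(y0 + 0.5, y1 - 0.5, by = 1)
  gx <- rep(px, times = length(py))
  gy <- rep(py, each = length(px))
  in_a <- gx > a$x_min & gx < a$x_max & gy > a$y_min & gy < a$y_max
  in_b <- gx > b$x_min & gx < b$x_max & gy > b$y_min & gy < b$y_max
  sum(in_a & in_b) / sum(in_a | in_b)
}

# percentile by explicit sort + linear interpolation between closest ranks
percentile_oracle <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p
  lo <- floor(h)
  if (lo + 1 >= n) return(x[n])
  x[lo + 1] + (h - lo) * (x[lo + 2] - x[lo + 1])
}

# maximum one-to-one matching count at IoU >= thr, by exhaustive
# recursion over predictions (feasible for <= 8 boxes per side)
optimal_match_count <- function(M, thr) {
  ok <- M >= thr
  recurse <- function(i, used) {
    if (i > nrow(ok)) return(0L)
    best <- recurse(i + 1L, used) # leave prediction i unmatched
    for (j in seq_len(ncol(ok))) {
      if (ok[i, j] && !used[j]) {
        used[j] <- TRUE
        best <- max(best, 1L + recurse(i + 1L, used))
        used[j] <- FALSE
      }
    }
    best
  }
  if (nrow(ok) == 0L || ncol(ok) == 0L) return(0L)
  recurse(1L, rep(FALSE, ncol(ok)))
}

# minimal LabelMe document text
labelme_doc <- function(w, h, rects = list(), extra_shapes = list()) {
  shapes <- c(lapply(rects, function(r) {
    list(label = "nodule", points = list(r[1:2], r[3:4]),
         shape_type = "rectangle")
  }), extra_shapes)
  jsonlite::toJSON(list(version = "5.0.0", shapes = shapes,
                        imagePath = "root_plate.png",
                        imageHeight = h, imageWidth = w),
                   auto_unbox = TRUE, null = "null", digits = NA)
}

random_boxes <- function(n, w = 1000, h = 2000, max_side = 60) {
  x0 <- runif(n, 0, w - max_side)
  y0 <- runif(n, 0, h - max_side)
  pixel_box(x0, y0, x0 + runif(n, 1, max_side), y0 + runif(n, 1, max_side))
}
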