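boxes_from_centers <- function(cx, cy, side = 10) {
  pixel_box(cx - side / 2, cy - side / 2, cx + side / 2, cy + side / 2)
}

test_that("extract_traits always emits exactly the 24 named traits", {
  inputs <- list(
    as_detections(boxes_from_centers(numeric(0), numeric(0))),
    as_detections(boxes_from_centers(100, 200)),
    as_detections(boxes_from_centers(c(100, 200, 300), c(100, 300, 500))),
    as_detections(random_boxes(50)))
  for (d in inputs) {
    tr <- extract_traits(d)
    expect_length(tr, 24L)
    expect_named(tr, trait_names())
  }
})

test_that("degenerate inputs give defined missing values, never errors", {
  none <- extract_traits(as_detections(boxes_from_centers(numeric(0),
                                                          numeric(0))))
  expect_equal(unname(none["count"]), 0)
  expect_true(all(is.na(none[setdiff(trait_names(), "count")])))

  one <- extract_traits(as_detections(boxes_from_centers(100, 200)))
  expect_equal(unname(one[c("count", "height", "width", "sdx", "sdy")]),
               c(1, 0, 0, 0, 0))
  expect_true(is.na(one["sdxy"]))
  expect_true(all(one[paste0("box_area_", c("min", "max", "mean", "median",
                                            "p5", "p95"))] == 100))
  expect_equal(unname(one["y_center_std"]), 0)
  expect_true(all(one[paste0("y_center_", c("min", "max", "mean", "median",
                                            "p5", "p25", "p75", "p95"))] == 200))

  # horizontally collinear centers: sdy = 0 with sdx > 0
  flat <- as_detections(boxes_from_centers(c(100, 200, 300), c(50, 50, 50)))
  expect_warning(tr <- extract_traits(flat), "sdxy undefined")
  expect_true(is.na(tr["sdxy"]))
})

test_that("the three-box worked example matches its closed forms", {
  d <- as_detections(boxes_from_centers(c(100, 200, 300), c(100, 300, 500)))
  tr <- extract_traits(d)
  expect_equal(unname(tr["count"]), 3)
  expect_equal(unname(tr["height"]), 400)
  expect_equal(unname(tr["width"]), 200)
  expect_equal(unname(tr["sdx"]), sqrt(20000 / 3), tolerance = 1e-9)
  expect_equal(unname(tr["sdy"]), sqrt(80000 / 3), tolerance = 1e-9)
  expect_equal(unname(tr["sdxy"]), 0.5, tolerance = 1e-9)
  expect_true(all(tr[paste0("box_area_", c("min", "max", "mean", "median",
                                           "p5", "p25", "p75", "p95"))] == 100))
  expect_equal(unname(tr["box_area_std"]), 0)
  expect_equal(unname(tr[c("y_center_min", "y_center_p5", "y_center_p25",
                           "y_center_median", "y_center_mean", "y_center_p75",
                           "y_center_p95", "y_center_max")]),
               c(100, 120, 200, 300, 300, 400, 480, 500), tolerance = 1e-9)
  expect_equal(unname(tr["y_center_std"]), sqrt(80000 / 3), tolerance = 1e-9)
})

test_that("order statistics agree with an explicit sort-and-interpolate oracle", {
  set.seed(19)
  for (k in 1:1000) {
    n <- sample(1:40, 1)
    d <- as_detections(random_boxes(n))
    tr <- extract_traits(d)
    areas <- (d$x_max - d$x_min) * (d$y_max - d$y_min)
    ys <- (d$y_min + d$y_max) / 2
    for (p in c(0.05, 0.25, 0.5, 0.75, 0.95)) {
      lbl <- c("p5", "p25", "median", "p75", "p95")[match(p, c(0.05, 0.25, 0.5,
                                                               0.75, 0.95))]
      expect_equal(unname(tr[paste0("box_area_", lbl)]),
                   percentile_oracle(areas, p), tolerance = 1e-9)
      expect_equal(unname(tr[paste0("y_center_", lbl)]),
                   percentile_oracle(ys, p), tolerance = 1e-9)
    }
  }
})

test_that("percentile chains are ordered for every input", {
  set.seed(23)
  chain <- function(prefix) paste0(prefix, c("min", "p5", "p25", "median",
                                             "p75", "p95", "max"))
  for (k in 1:200) {
    tr <- extract_traits(as_detections(random_boxes(sample(1:30, 1))))
    expect_true(!is.unsorted(tr[chain("box_area_")]))
    expect_true(!is.unsorted(tr[chain("y_center_")]))
    expect_equal(unname(tr["height"]),
                 unname(tr["y_center_max"] - tr["y_center_min"]))
  }
})

test_that("traits are translation-invariant and scale-covariant", {
  set.seed(29)
  shift_free <- c("count", "height", "width", "sdx", "sdy", "sdxy",
                  paste0("box_area_", c("min", "max", "std", "mean", "median",
                                        "p5", "p25", "p75", "p95")),
                  "y_center_std")
  y_loc <- paste0("y_center_", c("min", "max", "mean", "median", "p5", "p25",
                                 "p75", "p95"))
  for (k in 1:500) {
    d <- as_detections(random_boxes(sample(2:25, 1)))
    tr <- extract_traits(d)
    dx <- runif(1, -50, 50); dy <- runif(1, -50, 50)
    shifted <- d
    shifted$x_min <- d$x_min + dx; shifted$x_max <- d$x_max + dx
    shifted$y_min <- d$y_min + dy; shifted$y_max <- d$y_max + dy
    tr_s <- extract_traits(shifted)
    expect_equal(tr_s[shift_free], tr[shift_free], tolerance = 1e-9)
    expect_equal(tr_s[y_loc], tr[y_loc] + dy, tolerance = 1e-9)
  }
  for (k in 1:500) {
    d <- as_detections(random_boxes(sample(2:25, 1)))
    tr <- extract_traits(d)
    s <- runif(1, 0.2, 4)
    scaled <- d
    for (col in c("x_min", "y_min", "x_max", "y_max")) {
      scaled[[col]] <- d[[col]] * s
    }
    tr_sc <- extract_traits(scaled)
    lin <- c("height", "width", "sdx", "sdy", "y_center_std", y_loc)
    expect_equal(tr_sc[lin], tr[lin] * s, tolerance = 1e-8)
    area_stats <- paste0("box_area_", c("min", "max", "std", "mean", "median",
                                        "p5", "p25", "p75", "p95"))
    expect_equal(tr_sc[area_stats], tr[area_stats] * s^2, tolerance = 1e-8)
    expect_equal(tr_sc[c("count", "sdxy")], tr[c("count", "sdxy")],
                 tolerance = 1e-9)
  }
})

test_that("phenotype CSV round-trips the trait table with empty missings", {
  dets <- list(plate_a = as_detections(random_boxes(5)),
               plate_b = as_detections(boxes_from_centers(numeric(0),
                                                          numeric(0))))
  tab <- extract_trait_table(dets)
  expect_equal(dim(tab), c(2L, 25L))
  expect_equal(tab$count, c(5, 0))
  path <- withr::local_tempfile(fileext = ".csv")
  write_phenotype_csv(tab, path)
  txt <- readLines(path)
  expect_length(txt, 3L)
  expect_match(txt[3], "^plate_b,0,,", perl = TRUE)
  back <- read_phenotype_csv(path)
  expect_equal(back$sdxy, tab$sdxy)
  expect_true(all(is.na(back[2, setdiff(trait_names(), "count")])))
})
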