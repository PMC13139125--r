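interior_patch <- function() {
  plan <- plan_patches(2300, 4600, image_id = "im")
  plan[plan$x0 == 448 & plan$y0 == 896, ]
}

test_that("edge_filter removes boxes near interior patch edges only", {
  sp <- interior_patch()
  det <- as_detections(pixel_box(c(3, 6, 100), c(100, 6, 509 - 1),
                                 c(20, 506, 120), c(120, 506, 511)),
                       frame = "patch")
  kept <- edge_filter(det, sp, 2300, 4600)
  # x_min = 3 < 5 removed; (6,6,506,506) kept; y_max within 5 of 512 removed
  expect_equal(nrow(kept), 1L)
  expect_equal(kept$x_min, 6)
})

test_that("image-border patch edges are exempt from the edge filter", {
  plan <- plan_patches(2300, 4600, image_id = "im")
  border <- plan[plan$x0 == 0 & plan$y0 == 896, ]
  det <- as_detections(pixel_box(2, 100, 20, 120), frame = "patch")
  expect_equal(nrow(edge_filter(det, border, 2300, 4600)), 1L)
  # same box in an interior patch is removed
  expect_equal(nrow(edge_filter(det, interior_patch(), 2300, 4600)), 0L)
  # with the exemption off, border patches filter uniformly
  cfg <- postprocess_config(exempt_image_border = FALSE)
  expect_equal(nrow(edge_filter(det, border, 2300, 4600, cfg)), 0L)
})

test_that("translate_to_global shifts boxes and flips the frame", {
  sp <- interior_patch()
  det <- as_detections(pixel_box(10, 20, 30, 40), confidence = 0.8,
                       frame = "patch")
  glob <- translate_to_global(det, sp)
  expect_equal(unlist(glob[, c("x_min", "y_min", "x_max", "y_max")]),
               c(x_min = 458, y_min = 916, x_max = 478, y_max = 936))
  expect_equal(glob$frame, "global")
  expect_equal(glob$confidence, 0.8)
  expect_error(translate_to_global(glob, sp), "already image-global")

  origin <- plan_patches(2300, 4600, image_id = "im")[1, ]
  same <- translate_to_global(det, origin)
  expect_equal(same$x_min, det$x_min)
})

test_that("nms keeps the highest-confidence box among duplicates", {
  d <- as_detections(pixel_box(c(0, 1), c(0, 1), c(10, 11), c(10, 11)),
                     confidence = c(0.9, 0.8))
  out <- nms(d)
  expect_equal(nrow(out), 1L)
  expect_equal(out$confidence, 0.9)
  # hand check: IoU = 81/119 > 0.2 so the pair collapses
  expect_gt(iou(d[1, 1:4], d[2, 1:4]), 0.2)

  disjoint <- as_detections(pixel_box(c(0, 50), c(0, 50), c(10, 60), c(10, 60)),
                            confidence = c(0.9, 0.8))
  expect_equal(nrow(nms(disjoint)), 2L)

  weak <- as_detections(pixel_box(0, 0, 10, 10), confidence = 0.15)
  expect_equal(nrow(nms(weak)), 0L)
})

test_that("nms is idempotent, pairwise-separated, and monotone in thresholds", {
  set.seed(13)
  d <- as_detections(random_boxes(80, 400, 400, 60),
                     confidence = runif(80, 0.05, 1))
  cfg <- postprocess_config()
  out <- nms(d, cfg)
  expect_equal(nms(out, cfg), out)
  if (nrow(out) > 1L) {
    M <- iou_matrix(out, out)
    diag(M) <- 0
    expect_lt(max(M), cfg$nms_iou)
  }
  # tightening IoU or raising the floor never yields more boxes
  for (iou_thr in c(0.1, 0.3, 0.5)) {
    expect_lte(nrow(nms(d, postprocess_config(nms_iou = iou_thr))),
               nrow(nms(d, postprocess_config(nms_iou = iou_thr + 0.2))))
  }
  for (conf in c(0.1, 0.4, 0.7)) {
    expect_gte(nrow(nms(d, postprocess_config(nms_confidence = conf))),
               nrow(nms(d, postprocess_config(nms_confidence = conf + 0.2))))
  }
})

test_that("a nodule detected in two overlapping patches collapses to one", {
  # box centered in the 64-px overlap band between columns 0 and 1,
  # clear of both patches' filtered margins
  plan <- plan_patches(2300, 4600, image_id = "im")
  p_left <- plan[plan$x0 == 0 & plan$y0 == 0, ]
  p_right <- plan[plan$x0 == 448 & plan$y0 == 0, ]
  gbox <- pixel_box(460, 100, 490, 130)
  d <- rbind(
    as_detections(pixel_box(460, 100, 490, 130), confidence = 0.9,
                  frame = "patch", row = p_left$row, col = p_left$col),
    as_detections(pixel_box(460 - 448, 100, 490 - 448, 130), confidence = 0.7,
                  frame = "patch", row = p_right$row, col = p_right$col))
  out <- refine_image(d, plan, 2300, 4600)
  expect_equal(nrow(out), 1L)
  expect_equal(out$confidence, 0.9)
  expect_equal(iou(out[, 1:4], gbox), 1)
})

test_that("refine_image validates patch references and handles empties", {
  plan <- plan_patches(2300, 4600, image_id = "im")
  expect_equal(nrow(refine_image(as_detections(data.frame(
    x_min = numeric(0), y_min = numeric(0), x_max = numeric(0),
    y_max = numeric(0)), frame = "patch", row = integer(0), col = integer(0)),
    plan, 2300, 4600)), 0L)
  stray <- as_detections(pixel_box(10, 10, 20, 20), frame = "patch",
                         row = 99L, col = 99L)
  expect_error(refine_image(stray, plan, 2300, 4600), "consistency error")
})

test_that("a perfect oracle round-trips a separated scene exactly", {
  cfg <- scene_config(n_nodules = 30, seed = 5)
  scene <- generate_scene(cfg, image_id = "s")
  plan <- plan_patches(cfg$image_w, cfg$image_h, image_id = "s")
  raw <- detect_patches(plan, detector_spec("mock"),
                        ground_truth = scene$annotations)
  out <- refine_image(raw, plan, cfg$image_w, cfg$image_h)
  expect_equal(nrow(out), 30L)
  M <- iou_matrix(out, scene$annotations$boxes)
  expect_true(all(apply(M, 2, max) >= 0.99))
})
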