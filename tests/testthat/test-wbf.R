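two_box_case <- function() {
  data.frame(
    image_id = "img1", label = 0L,
    cx = c(0.40, 0.50), cy = 0.40, w = 0.20, h = 0.20,
    confidence = c(0.9, 0.3), model_id = c("a", "b")
  )
}

test_that("fused confidence is the clipped average of member scores", {
  expect_equal(fuse_confidence(c(0.9, 0.3)), 0.6)
  expect_equal(fuse_confidence(0.37), 0.37)
  expect_equal(fuse_confidence(c(1, 1, 1)), 1)
  # weight-scaled scores can exceed 1; the fused value is clipped
  expect_equal(fuse_confidence(c(1.4, 1.2)), 1)
  expect_error(fuse_confidence(numeric(0)), "empty")
  # weighted mean leans toward the stronger member
  expect_equal(fuse_confidence(c(0.9, 0.3), "weighted_mean"),
               (0.9^2 + 0.3^2) / 1.2)
})

test_that("fused coordinates are the confidence-weighted average", {
  m <- data.frame(cx = c(0.40, 0.50), cy = 0.40, w = 0.20, h = 0.20,
                  confidence = c(0.9, 0.3))
  fused <- fuse_coordinates(m)
  expect_equal(fused$cx, 0.425)
  expect_equal(fused$cy, 0.40)
  expect_equal(fused$w, 0.20)
  expect_equal(fused$h, 0.20)
  # identical boxes fuse to themselves whatever the confidences
  mm <- data.frame(cx = 0.3, cy = 0.7, w = 0.1, h = 0.12,
                   confidence = c(0.2, 0.9, 0.55))
  expect_equal(fuse_coordinates(mm)[, c("cx", "cy", "w", "h")],
               mm[1, c("cx", "cy", "w", "h")])
  # single member passes through
  expect_equal(fuse_coordinates(mm[2, ])$cy, 0.7)
  expect_error(fuse_coordinates(transform(m, confidence = 0)), "zero")
})

test_that("two overlapping boxes fuse below the IoU threshold and not above", {
  p30 <- fusion_params(iou_thr = 0.30, model_weights = c(a = 1, b = 1))
  fused <- weighted_boxes_fusion(two_box_case(), p30) # pairwise IoU = 1/3
  expect_equal(nrow(fused), 1)
  expect_equal(fused$cx, 0.425)
  expect_equal(fused$confidence, 0.6)
  expect_equal(fused$cluster_size, 2L)
  expect_equal(fused$model_id, "fused")

  p40 <- fusion_params(iou_thr = 0.40, model_weights = c(a = 1, b = 1))
  kept <- weighted_boxes_fusion(two_box_case(), p40)
  expect_equal(nrow(kept), 2)
  expect_equal(sort(kept$cx), c(0.40, 0.50)) # coordinates unchanged
})

test_that("fusion of a single model with weight 1 is the identity", {
  set.seed(20)
  det <- random_detections(8, n_models = 1)
  det$confidence <- sort(runif(8, 0.3, 1), decreasing = TRUE)
  det$cx <- seq(0.1, 0.9, length.out = 8) # disjoint: no clustering
  det$w <- 0.05
  p <- fusion_params(iou_thr = 0.5, skip_box_thr = 0,
                     model_weights = c(m1 = 1))
  fused <- weighted_boxes_fusion(det, p)
  expect_equal(fused[, c("cx", "cy", "w", "h", "confidence")],
               det[, c("cx", "cy", "w", "h", "confidence")])
  # idempotence: fusing fused output again changes nothing
  fused$model_id <- "m1"
  again <- weighted_boxes_fusion(fused[, names(det)], p)
  expect_equal(again[, c("cx", "cy", "w", "h", "confidence")],
               fused[, c("cx", "cy", "w", "h", "confidence")])
})

test_that("skip threshold drops boxes on raw confidence, before weighting", {
  det <- two_box_case()
  # model b has weight 9: its scaled confidence is large, but skip uses raw
  p <- fusion_params(iou_thr = 0.3, skip_box_thr = 0.35,
                     model_weights = c(a = 1, b = 9))
  fused <- weighted_boxes_fusion(det, p)
  expect_equal(nrow(fused), 1)
  expect_equal(fused$cx, 0.40) # only model a's box survived
})

test_that("model weights scale confidences and shift the fused box", {
  det <- two_box_case()
  p <- fusion_params(iou_thr = 0.3, model_weights = c(a = 1, b = 3))
  fused <- weighted_boxes_fusion(det, p)
  # scaled: a = 0.9*1/2 = 0.45, b = 0.3*3/2 = 0.45 -> equal pull
  expect_equal(fused$cx, 0.45)
  expect_equal(fused$confidence, 0.45)
  expect_error(
    weighted_boxes_fusion(det, fusion_params(model_weights = c(a = 1))),
    "without a configured weight"
  )
})

test_that("fused boxes stay inside the member hull and counts never grow", {
  for (seed in 1:25) {
    det <- random_detections(sample(2:12, 1), n_models = sample(1:3, 1),
                             seed = seed)
    p <- fusion_params(iou_thr = runif(1, 0.2, 0.7),
                       skip_box_thr = runif(1, 0, 0.1),
                       model_weights = equal_weights(paste0("m", 1:3)))
    fused <- weighted_boxes_fusion(det, p)
    expect_lte(nrow(fused), nrow(det))
    kept <- det[det$confidence >= p$skip_box_thr, ]
    for (col in c("cx", "cy", "w", "h")) {
      if (nrow(fused) == 0) next
      expect_true(all(fused[[col]] >= min(kept[[col]]) - 1e-12))
      expect_true(all(fused[[col]] <= max(kept[[col]]) + 1e-12))
    }
  }
})

test_that("raising the IoU threshold never shrinks the output", {
  for (seed in 26:40) {
    det <- random_detections(10, n_models = 2, seed = seed)
    counts <- vapply(c(0.2, 0.35, 0.5, 0.65, 0.8), function(thr) {
      nrow(weighted_boxes_fusion(
        det, fusion_params(iou_thr = thr,
                           model_weights = equal_weights(c("m1", "m2")))))
    }, 1L)
    expect_true(all(diff(counts) >= 0))
  }
})

test_that("input order does not matter when confidences are distinct", {
  set.seed(41)
  det <- random_detections(9, n_models = 3)
  det$confidence <- sample(seq(0.1, 0.9, length.out = 9)) # strictly distinct
  p <- fusion_params(iou_thr = 0.4,
                     model_weights = c(m1 = 2, m2 = 1, m3 = 1.5))
  ref <- weighted_boxes_fusion(det, p)
  for (rep in 1:5) {
    shuffled <- det[sample(nrow(det)), ]
    rownames(shuffled) <- NULL
    expect_equal(weighted_boxes_fusion(shuffled, p), ref)
  }
})

test_that("fusion matches the brute-force oracle", {
  n_match <- 0
  for (seed in 100:179) {
    det <- random_detections(sample(2:10, 1), n_models = sample(2:3, 1),
                             seed = seed, labels = 0:1)
    p <- fusion_params(
      iou_thr = runif(1, 0.15, 0.75),
      skip_box_thr = runif(1, 0, 0.1),
      model_weights = stats::setNames(runif(3, 1, 10), paste0("m", 1:3)),
      conf_mode = sample(c("mean", "weighted_mean"), 1),
      rescale_by_model_count = sample(c(TRUE, FALSE), 1)
    )
    fused <- weighted_boxes_fusion(det, p)
    ref <- oracle_wbf(det, p)
    expect_equal(nrow(fused), nrow(ref))
    for (col in c("cx", "cy", "w", "h", "confidence")) {
      expect_lt(max(abs(fused[[col]] - ref[[col]]), 0), 1e-9)
    }
    expect_equal(fused$cluster_size, ref$cluster_size)
    n_match <- n_match + 1
  }
  expect_equal(n_match, 80)
})

test_that("fuse_dataset applies per image and tolerates missing models", {
  set.seed(50)
  det <- rbind(
    random_detections(5, n_models = 2, image_id = "a"),
    random_detections(4, n_models = 1, image_id = "b") # model m2 absent
  )
  p <- fusion_params(iou_thr = 0.4, model_weights = equal_weights(c("m1", "m2")))
  fused <- fuse_dataset(det, p)
  expect_setequal(unique(fused$image_id), c("a", "b"))
  expect_lte(nrow(fused), nrow(det))
  # empty input -> empty output with the right columns
  empty <- fuse_dataset(det[0, ], p)
  expect_equal(nrow(empty), 0)
  expect_true(all(c("cx", "confidence", "cluster_size") %in% names(empty)))
})
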