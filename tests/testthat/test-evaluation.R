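gt_at <- function(cx, cy = 0.5, image_id = "a", label = 0L, w = 0.2, h = 0.2) {
  data.frame(image_id = image_id, label = label, cx = cx, cy = cy, w = w, h = h)
}

test_that("greedy one-to-one matching traces the textbook case", {
  # two ground truths; three predictions with decreasing confidence:
  # .9 overlaps GT1 at 0.6, .8 overlaps GT1 only at ~0.55, .7 overlaps GT2
  # at ~0.4 (< 0.5) -> exactly one TP
  gts <- rbind(gt_at(0.2), gt_at(0.7))
  preds <- data.frame(
    image_id = "a", label = 0L,
    cx = c(0.2, 0.2 + 0.0580, 0.7 + 0.085), cy = 0.5,
    w = 0.2, h = 0.2,
    confidence = c(0.9, 0.8, 0.7), model_id = "m"
  )
  ious <- iou_matrix(preds, gts)
  expect_gt(ious[1, 1], 0.5)
  expect_gt(ious[2, 1], 0.5)
  expect_lt(ious[2, 2], 0.5)
  expect_lt(ious[3, 2], 0.5)
  m <- match_detections(preds, gts)
  expect_equal(m$tp, 1)
  expect_equal(m$fp, 2)
  expect_equal(m$fn, 1)
  expect_equal(m$matched_pairs$pred_index, 1)
  expect_equal(m$matched_pairs$gt_index, 1)
  # accounting identities
  expect_equal(m$tp + m$fn, nrow(gts))
  expect_equal(m$tp + m$fp, nrow(preds))
})

test_that("matching identities hold on random instances", {
  for (seed in 1:15) {
    set.seed(seed)
    gts <- data.frame(image_id = sample(c("a", "b"), 6, TRUE), label = 0L,
                      random_boxes(6))
    preds <- random_detections(8, image_id = NULL, seed = seed + 100)
    preds$image_id <- sample(c("a", "b"), 8, TRUE)
    m <- match_detections(preds, gts)
    expect_equal(m$tp + m$fn, nrow(gts))
    expect_equal(m$tp + m$fp, nrow(preds))
    expect_equal(m$tp, nrow(m$matched_pairs))
    expect_true(all(m$matched_pairs$iou >= 0.5))
    expect_false(anyDuplicated(m$matched_pairs$gt_index) > 0)
  }
})

test_that("perfect and empty predictions give the boundary counts", {
  gts <- rbind(gt_at(0.2), gt_at(0.7))
  perfect <- data.frame(gts, confidence = 1, model_id = "m")
  m <- match_detections(perfect, gts)
  expect_equal(c(m$tp, m$fp, m$fn), c(2, 0, 0))
  m0 <- match_detections(perfect[0, ], gts)
  expect_equal(c(m0$tp, m0$fp, m0$fn), c(0, 0, 2))
})

test_that("precision/recall/F1 formulas and conventions", {
  expect_equal(precision_recall_f1(6, 2, 4),
               c(precision = 0.75, recall = 0.6, f1 = 2 / 3))
  expect_equal(precision_recall_f1(0, 0, 5),
               c(precision = 0, recall = 0, f1 = 0))
  expect_equal(precision_recall_f1(0, 3, 0)[["f1"]], 0)
  x <- 0.77
  pr <- precision_recall_f1(77, 23, 23)
  expect_equal(pr[["f1"]], x) # harmonic mean of equals is the value itself
  expect_error(precision_recall_f1(-1, 0, 0), "non-negative")
})

test_that("PR curve sweeps thresholds with non-decreasing recall", {
  gts <- gt_at(0.5)
  preds <- data.frame(
    image_id = "a", label = 0L,
    cx = c(0.9, 0.5), cy = c(0.9, 0.5), w = 0.2, h = 0.2,
    confidence = c(0.95, 0.90), model_id = "m"
  )
  cv <- pr_curve(preds, gts)
  expect_equal(cv$threshold, c(0.95, 0.90))
  expect_equal(cv$recall, c(0, 1))
  expect_equal(cv$precision, c(0, 0.5))
  expect_equal(average_precision(cv), 0.5)

  # duplicate confidences collapse to one sweep point
  preds2 <- rbind(preds, transform(preds[1, ], cx = 0.1, cy = 0.1))
  preds2$confidence <- c(0.95, 0.90, 0.95)
  cv2 <- pr_curve(preds2, gts)
  expect_equal(nrow(cv2), 2)

  expect_error(pr_curve(preds, gts[0, ]), "no ground truth")
})

test_that("recall is monotone and metrics bounded on random curves", {
  for (seed in 1:10) {
    set.seed(seed)
    gts <- data.frame(image_id = sample(c("a", "b", "c"), 10, TRUE),
                      label = 0L, random_boxes(10))
    preds <- data.frame(image_id = sample(c("a", "b", "c"), 15, TRUE),
                        label = 0L, random_boxes(15),
                        confidence = runif(15), model_id = "m")
    cv <- pr_curve(preds, gts)
    expect_true(all(diff(cv$recall) >= 0))
    expect_true(all(cv$recall >= 0 & cv$recall <= 1))
    expect_true(all(cv$precision >= 0 & cv$precision <= 1))
  }
})

test_that("AP boundary values: perfect detector 1, no TPs 0", {
  gts <- rbind(gt_at(0.2), gt_at(0.7))
  perfect <- data.frame(gts, confidence = 1, model_id = "m")
  expect_equal(average_precision(pr_curve(perfect, gts)), 1)
  far <- transform(perfect, cx = c(0.45, 0.45), cy = 0.9, confidence = c(0.9, 0.8))
  expect_equal(average_precision(pr_curve(far[1, ], gts)), 0)
})

test_that("AP equals brute-force threshold enumeration on small instances", {
  for (seed in 1:30) {
    set.seed(seed)
    n_gt <- sample(1:8, 1)
    n_pred <- sample(1:20, 1)
    imgs <- c("a", "b")
    gts <- data.frame(image_id = sample(imgs, n_gt, TRUE), label = 0L,
                      random_boxes(n_gt))
    # mix of near-GT boxes and noise so TPs exist at various confidences
    near <- gts[sample(n_gt, min(n_pred, n_gt)), ]
    near$cx <- pmin(pmax(near$cx + rnorm(nrow(near), 0, 0.02), 0.05), 0.95)
    noise <- random_noise_preds(n_pred - nrow(near), imgs)
    preds <- rbind(near, noise)
    preds$confidence <- round(runif(n_pred), 2) # induces ties too
    preds$model_id <- "m"
    ap <- average_precision(pr_curve(preds, gts))
    expect_equal(ap, oracle_ap(preds, gts), tolerance = 1e-9)
  }
})

test_that("AP never increases when an FP outranks every TP", {
  set.seed(60)
  gts <- rbind(gt_at(0.2), gt_at(0.7))
  preds <- data.frame(gts, confidence = c(0.8, 0.7), model_id = "m")
  ap0 <- average_precision(pr_curve(preds, gts))
  fp <- data.frame(gt_at(0.45, 0.9), confidence = 0.99, model_id = "m")
  ap1 <- average_precision(pr_curve(rbind(preds, fp), gts))
  expect_lt(ap1, ap0)
})

test_that("mAP averages per-class AP", {
  expect_equal(map50(c(`0` = 0.983)), 0.983)
  expect_equal(map50(c(a = 1, b = 0)), 0.5)
  set.seed(61)
  aps <- runif(7)
  expect_equal(map50(aps), sum(aps) / 7)
  expect_error(map50(numeric(0)), "no classes")
})

test_that("operating point maximizes F1 and honors fixed thresholds", {
  curve <- structure(
    data.frame(threshold = c(0.9, 0.6, 0.3),
               recall = c(0.3, 0.8, 0.9),
               precision = c(1.0, 0.9, 0.5)),
    class = c("pr_curve", "data.frame")
  )
  op <- operating_point(curve)
  f1s <- 2 * curve$precision * curve$recall / (curve$precision + curve$recall)
  expect_equal(op[["f1"]], max(f1s)) # exhaustive-scan agreement
  expect_equal(op[["threshold"]], 0.6)
  fixed <- operating_point(curve, "fixed_threshold", threshold = 0.5)
  expect_equal(fixed[["recall"]], 0.8)
  # ties go to the higher recall
  tied <- structure(
    data.frame(threshold = c(0.9, 0.5), recall = c(0.5, 0.8),
               precision = c(0.8, 0.5)),
    class = c("pr_curve", "data.frame")
  )
  f1t <- 2 * tied$precision * tied$recall / (tied$precision + tied$recall)
  expect_equal(f1t[1], f1t[2], tolerance = 1e-12)
  expect_equal(operating_point(tied)[["recall"]], 0.8)
})

test_that("self-evaluation of any ground truth scores all ones", {
  for (seed in 1:5) {
    cfg <- simulator_config(12, seed = seed)
    d <- generate_ground_truth(cfg)
    preds <- data.frame(d$ground_truth, confidence = 1, model_id = "self")
    rep <- evaluate_detections(preds, d$ground_truth)
    expect_equal(rep$map50, 1)
    expect_equal(rep$precision, 1)
    expect_equal(rep$recall, 1)
    expect_equal(rep$f1, 1)
  }
})

test_that("evaluation report structure is internally consistent", {
  set.seed(62)
  gts <- data.frame(image_id = sample(c("a", "b"), 12, TRUE),
                    label = sample(0:1, 12, TRUE), random_boxes(12))
  near <- gts
  near$cx <- pmin(pmax(near$cx + rnorm(12, 0, 0.03), 0.05), 0.95)
  preds <- data.frame(near[, c("image_id", "label")],
                      near[, c("cx", "cy", "w", "h")],
                      confidence = runif(12, 0.2, 1), model_id = "m")
  rep <- evaluate_detections(preds, gts)
  expect_equal(rep$map50, mean(rep$per_class_ap), tolerance = 1e-12)
  if (rep$precision + rep$recall > 0) {
    expect_equal(rep$f1,
                 2 * rep$precision * rep$recall / (rep$precision + rep$recall),
                 tolerance = 1e-12)
  }
  expect_named(rep$per_class_ap, c("0", "1"))

  f <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, json_path = f)
  back <- jsonlite::fromJSON(f)
  expect_equal(back$map50, rep$map50)
})

test_that("eleven-point AP stays close to all-point AP and within bounds", {
  set.seed(63)
  gts <- data.frame(image_id = "a", label = 0L, random_boxes(6))
  near <- gts
  near$cx <- near$cx + rnorm(6, 0, 0.02)
  preds <- data.frame(clip_boxes(near, warn = FALSE),
                      confidence = runif(6, 0.3, 1), model_id = "m")
  cv <- pr_curve(preds, gts)
  ap11 <- average_precision(cv, "eleven_point")
  expect_gte(ap11, 0)
  expect_lte(ap11, 1)
})
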