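# Synthetic detection benchmarks: ground-truth layouts plus simulated
# detector outputs with configurable miss rate, Poisson false positives,
# Gaussian localization jitter and IoU-linked confidences. The simulator
# emulates detector BEHAVIOR (error statistics), never image pixels.

#' Configure the ground-truth generator
#'
#' Ground-truth layouts mimic the geometry of an impacted-tooth detection
#' task on panoramic radiographs: 1-4 smallish boxes per image whose centers
#' fall in two horizontal bands (upper and lower jaw), never overlapping
#' each other strongly.
#'
#' @param n_images number of images.
#' @param boxes_per_image integer range `c(min, max)` of boxes per image.
#' @param box_size_mean,box_size_sd mean and sd of box width/height as
#'   fractions of the image (defaults 0.08 and 0.02).
#' @param placement_regions matrix with columns `x1, y1, x2, y2`: rectangles
#'   where box centers may fall. Default: two horizontal bands.
#' @param max_gt_iou maximum IoU allowed between two ground-truth boxes of
#'   one image; overlapping draws are resampled.
#' @param image_width,image_height nominal pixel sizes recorded for COCO
#'   interoperability (coordinates stay normalized throughout).
#' @param seed RNG seed; every image gets its own deterministic substream.
#' @return object of class `simulator_config`.
#' @export
simulator_config <- function(n_images, boxes_per_image = c(1L, 4L),
                             box_size_mean = 0.08, box_size_sd = 0.02,
                             placement_regions = default_placement_regions(),
                             max_gt_iou = 0.3,
                             image_width = 1280L, image_height = 640L,
                             seed = 1) {
  stopifnot(n_images >= 0, length(boxes_per_image) == 2,
            boxes_per_image[1] >= 1, boxes_per_image[1] <= boxes_per_image[2],
            box_size_mean > 0, box_size_sd >= 0, max_gt_iou > 0)
  placement_regions <- rbind(placement_regions)
  if (ncol(placement_regions) != 4) {
    stop("placement_regions must have columns x1, y1, x2, y2", call. = FALSE)
  }
  structure(
    list(n_images = as.integer(n_images),
         boxes_per_image = as.integer(boxes_per_image),
         box_size_mean = box_size_mean, box_size_sd = box_size_sd,
         placement_regions = placement_regions, max_gt_iou = max_gt_iou,
         image_width = as.integer(image_width),
         image_height = as.integer(image_height),
         seed = as.integer(seed)),
    class = "simulator_config"
  )
}

#' @rdname simulator_config
#' @export
default_placement_regions <- function() {
  matrix(c(0.08, 0.15, 0.92, 0.42,
           0.08, 0.58, 0.92, 0.85),
         ncol = 4, byrow = TRUE,
         dimnames = list(NULL, c("x1", "y1", "x2", "y2")))
}

#' Detector error profile
#'
#' Describes a simulated detector by its error statistics. Each ground-truth
#' box is detected with probability `1 - miss_rate`; detected boxes get
#' independent Gaussian jitter (sd `loc_jitter`) on all four coordinates;
#' false positives arrive as a Poisson count per image (`fp_rate`) placed
#' uniformly in the placement regions. Confidence is linked to localization
#' quality: `conf = clip(conf_a * IoU + conf_b + N(0, conf_sd), 0, 1)` with
#' IoU measured against the source ground-truth box (0 for false
#' positives, which therefore sit in the low tail).
#'
#' @param name model identifier attached to the predictions.
#' @param miss_rate probability a ground-truth box goes undetected.
#' @param fp_rate expected false positives per image.
#' @param loc_jitter sd of the coordinate noise (normalized units).
#' @param conf_a,conf_b,conf_sd confidence model parameters.
#' @return object of class `detector_profile`.
#' @seealso [detector_profiles()] for the two stock profiles.
#' @export
detector_profile <- function(name, miss_rate, fp_rate, loc_jitter,
                             conf_a = 0.7, conf_b = 0.2, conf_sd = 0.08) {
  stopifnot(miss_rate >= 0, miss_rate <= 1, fp_rate >= 0, loc_jitter >= 0,
            conf_sd >= 0)
  structure(
    list(name = name, miss_rate = miss_rate, fp_rate = fp_rate,
         loc_jitter = loc_jitter,
         conf_a = conf_a, conf_b = conf_b, conf_sd = conf_sd),
    class = "detector_profile"
  )
}

#' Stock detector profiles
#'
#' Two complementary error profiles shaped like the detector families an
#' ensemble typically combines:
#'
#' * `recall_heavy` — finds nearly everything (miss rate 0.05) but localizes
#'   sloppily (jitter 0.008) and hallucinates about one false positive per
#'   image; qualitatively a fast one-stage CNN detector.
#' * `precision_heavy` — misses a quarter of the boxes but places the rest
#'   tightly (jitter 0.005) with few false positives (0.15 per image);
#'   qualitatively a conservative transformer detector.
#'
#' Fusing the two is where Weighted Boxes Fusion earns its keep: the
#' recall-heavy model supplies coverage, the precision-heavy one accuracy.
#'
#' @param names which profiles to return.
#' @return named list of [detector_profile()] objects.
#' @export
detector_profiles <- function(names = c("recall_heavy", "precision_heavy")) {
  all <- list(
    recall_heavy = detector_profile(
      "recall_heavy", miss_rate = 0.05, fp_rate = 1.0, loc_jitter = 0.008,
      conf_a = 0.7, conf_b = 0.2, conf_sd = 0.08),
    precision_heavy = detector_profile(
      "precision_heavy", miss_rate = 0.25, fp_rate = 0.15, loc_jitter = 0.005,
      conf_a = 0.7, conf_b = 0.2, conf_sd = 0.05)
  )
  unknown <- setdiff(names, names(all))
  if (length(unknown)) {
    stop("unknown profile(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  all[names]
}

# Deterministic per-image substream: independent of image count and of how
# many draws other images consumed, so datasets are reproducible per seed.
image_stream_seed <- function(seed, image_index, salt) {
  (as.integer(seed) + salt * image_index) %% 2147483562L + 1L
}

sample_box_in_regions <- function(regions, size_mean, size_sd) {
  k <- sample.int(nrow(regions), 1)
  r <- regions[k, ]
  data.frame(
    cx = stats::runif(1, r[1], r[3]),
    cy = stats::runif(1, r[2], r[4]),
    w = min(max(stats::rnorm(1, size_mean, size_sd), 0.02), 0.30),
    h = min(max(stats::rnorm(1, size_mean, size_sd), 0.02), 0.30)
  )
}

#' Generate synthetic ground truth
#'
#' Draws a deterministic, seeded set of ground-truth boxes per image
#' according to the [simulator_config()]: box counts uniform over the
#' configured range, sizes Gaussian (truncated to \[0.02, 0.30\]), centers
#' uniform in the placement regions, and no two boxes of an image with IoU
#' above `max_gt_iou` (offending draws are resampled, up to 1000 times).
#'
#' @param config a [simulator_config()].
#' @return list with `ground_truth` (data frame: `image_id`, `label`, box
#'   columns) and `images` (data frame: `image_id`, `width`, `height`).
#' @export
generate_ground_truth <- function(config) {
  stopifnot(inherits(config, "simulator_config"))
  ids <- sprintf("img_%04d", seq_len(config$n_images))
  parts <- vector("list", config$n_images)
  for (i in seq_len(config$n_images)) {
    set.seed(image_stream_seed(config$seed, i, 9973L))
    n_boxes <- sample(seq(config$boxes_per_image[1], config$boxes_per_image[2]), 1)
    boxes <- NULL
    for (b in seq_len(n_boxes)) {
      ok <- FALSE
      for (try in seq_len(1000)) {
        cand <- sample_box_in_regions(config$placement_regions,
                                      config$box_size_mean, config$box_size_sd)
        cand <- clip_boxes(cand, warn = FALSE)
        if (is.null(boxes) ||
            all(iou_pairwise(boxes, cand) <= config$max_gt_iou)) {
          ok <- TRUE
          break
        }
      }
      if (!ok) {
        stop("could not place a non-overlapping box after 1000 resamples; ",
             "placement regions too small for the box size", call. = FALSE)
      }
      boxes <- rbind(boxes, cand)
    }
    parts[[i]] <- data.frame(image_id = ids[i], label = 0L, boxes)
  }
  gt <- do.call(rbind, parts)
  if (is.null(gt)) {
    gt <- data.frame(image_id = character(), label = integer(),
                     cx = numeric(), cy = numeric(),
                     w = numeric(), h = numeric())
  }
  rownames(gt) <- NULL
  list(
    ground_truth = gt,
    images = data.frame(image_id = ids,
                        width = rep(config$image_width, config$n_images),
                        height = rep(config$image_height, config$n_images))
  )
}

#' Simulate a detector's predictions
#'
#' Emits predictions for every image of a ground-truth set according to a
#' [detector_profile()]: each ground-truth box is detected with probability
#' `1 - miss_rate`, jittered, clipped to the image, and scored by the
#' IoU-linked confidence model; Poisson false positives are placed
#' uniformly in the placement regions with confidences from the low tail of
#' the same model (IoU = 0).
#'
#' @param gt ground truth as returned by [generate_ground_truth()] (the
#'   list, or just its `ground_truth` data frame plus an `image_ids`
#'   vector).
#' @param profile a [detector_profile()].
#' @param seed RNG seed (per-image substreams; independent of the
#'   ground-truth seed).
#' @param config the [simulator_config()] used for the ground truth (for
#'   placement regions and box sizes of false positives).
#' @param image_ids roster of images to simulate (defaults to those in
#'   `gt`).
#' @return data frame of detections (`image_id`, `label`, box columns,
#'   `confidence`, `model_id`).
#' @export
simulate_detector <- function(gt, profile, seed, config, image_ids = NULL) {
  stopifnot(inherits(profile, "detector_profile"),
            inherits(config, "simulator_config"))
  if (is.list(gt) && !is.data.frame(gt) && "ground_truth" %in% names(gt)) {
    if (is.null(image_ids)) image_ids <- gt$images$image_id
    gt <- gt$ground_truth
  }
  gt <- as.data.frame(gt)
  if (is.null(image_ids)) image_ids <- unique(gt$image_id)
  parts <- vector("list", length(image_ids))
  for (i in seq_along(image_ids)) {
    set.seed(image_stream_seed(seed, i, 7919L))
    g <- gt[gt$image_id == image_ids[i], , drop = FALSE]
    det <- NULL
    for (b in seq_len(nrow(g))) {
      if (stats::runif(1) < profile$miss_rate) next
      noisy <- g[b, c("cx", "cy", "w", "h")]
      if (profile$loc_jitter > 0) {
        noisy <- noisy + stats::rnorm(4, 0, profile$loc_jitter)
      }
      noisy$w <- max(noisy$w, 0.01)
      noisy$h <- max(noisy$h, 0.01)
      noisy$cx <- min(max(noisy$cx, 0), 1)
      noisy$cy <- min(max(noisy$cy, 0), 1)
      noisy <- clip_boxes(noisy, warn = FALSE)
      realized_iou <- iou_pairwise(g[b, , drop = FALSE], noisy)
      conf <- profile$conf_a * realized_iou + profile$conf_b +
        stats::rnorm(1, 0, profile$conf_sd)
      det <- rbind(det, data.frame(
        label = g$label[b], noisy,
        confidence = min(max(conf, 0), 1)
      ))
    }
    n_fp <- stats::rpois(1, profile$fp_rate)
    for (f in seq_len(n_fp)) {
      fb <- clip_boxes(
        sample_box_in_regions(config$placement_regions,
                              config$box_size_mean, config$box_size_sd),
        warn = FALSE)
      conf <- profile$conf_b + stats::rnorm(1, 0, profile$conf_sd)
      det <- rbind(det, data.frame(
        label = 0L, fb, confidence = min(max(conf, 0), 1)
      ))
    }
    if (!is.null(det)) {
      parts[[i]] <- data.frame(image_id = image_ids[i], det,
                               model_id = profile$name)
    }
  }
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(image_id = character(), label = integer(),
                      cx = numeric(), cy = numeric(), w = numeric(),
                      h = numeric(), confidence = numeric(),
                      model_id = character())
  }
  rownames(out) <- NULL
  out
}

#' Build a complete benchmark on disk
#'
#' Generates ground truth, simulates every detector profile, splits the
#' images, and writes the directory layout the fusion/evaluation/optimize
#' phases consume: `ground_truth/` and `predictions/<model>/` as YOLO label
#' directories plus a `split.txt` manifest. Fully deterministic per seed.
#'
#' @param config a [simulator_config()].
#' @param profiles list of [detector_profile()]s (at least two).
#' @param dir output directory (created).
#' @param split_fractions train/val/test fractions for [split_dataset()].
#' @param seed RNG seed for the detector simulations and the split (the
#'   ground truth uses `config$seed`).
#' @return invisibly, a list with the in-memory `ground_truth`, `images`,
#'   `predictions`, `split` and the written `paths`.
#' @export
make_benchmark <- function(config, profiles = detector_profiles(), dir,
                           split_fractions = c(0.80, 0.05, 0.15), seed = 1) {
  if (length(profiles) < 2) stop("need at least two detector profiles", call. = FALSE)
  data <- generate_ground_truth(config)
  preds <- do.call(rbind, lapply(seq_along(profiles), function(k) {
    simulate_detector(data, profiles[[k]], seed = seed + 104729L * k,
                      config = config)
  }))
  split <- split_dataset(data$images$image_id, split_fractions, seed = seed)

  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gt_dir <- file.path(dir, "ground_truth")
  write_yolo_dir(data$ground_truth, gt_dir, with_confidence = FALSE,
                 image_ids = data$images$image_id)
  pred_dirs <- character(0)
  for (p in profiles) {
    pd <- file.path(dir, "predictions", p$name)
    write_yolo_dir(preds[preds$model_id == p$name, , drop = FALSE], pd,
                   with_confidence = TRUE, image_ids = data$images$image_id)
    pred_dirs[p$name] <- pd
  }
  manifest <- file.path(dir, "split.txt")
  write_split_manifest(split, manifest)
  utils::write.csv(data$images, file.path(dir, "images.csv"), row.names = FALSE)

  invisible(list(
    ground_truth = data$ground_truth, images = data$images,
    predictions = preds, split = split,
    paths = list(root = dir, ground_truth = gt_dir, predictions = pred_dirs,
                 manifest = manifest)
  ))
}
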