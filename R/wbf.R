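# Weighted Boxes Fusion: greedy IoU clustering of multi-model detections,
# each cluster replaced by a confidence-weighted average box.

#' Fusion hyperparameters
#'
#' Bundles the Weighted Boxes Fusion hyperparameters: the IoU threshold above
#' which boxes join an existing cluster, the minimum raw confidence a
#' detection needs to participate at all, and a positive trust weight per
#' model. Weights enter by scaling each detection's confidence by
#' `weight / mean(weights)`, so they influence both the clustering order and
#' the weighted coordinate averages while keeping scores in a comparable
#' range.
#'
#' @param iou_thr clustering IoU threshold, in (0,1). The optimizer searches
#'   \[0.1, 0.9\]; any value in (0,1) is accepted when user-supplied.
#' @param skip_box_thr minimum raw (pre-weighting) confidence; detections
#'   below it are discarded before fusion.
#' @param model_weights named numeric vector of positive per-model weights.
#' @param conf_mode how the fused confidence is computed from the
#'   (weight-scaled) member confidences: `"mean"` (their arithmetic mean) or
#'   `"weighted_mean"` (mean weighted by the confidences themselves, which
#'   leans toward the stronger members).
#' @param rescale_by_model_count if `TRUE`, the fused confidence is further
#'   multiplied by `min(T, M) / M` with `T` the cluster size and `M` the
#'   number of models, down-weighting boxes that only some models found.
#'   Off by default, so the fused score is the plain average.
#' @return object of class `fusion_params`.
#' @examples
#' fusion_params(iou_thr = 0.55, skip_box_thr = 0.01,
#'               model_weights = c(yolo = 2, detr = 1))
#' @export
fusion_params <- function(iou_thr = 0.55, skip_box_thr = 0.001,
                          model_weights = c(model = 1),
                          conf_mode = c("mean", "weighted_mean"),
                          rescale_by_model_count = FALSE) {
  conf_mode <- match.arg(conf_mode)
  stopifnot(is.numeric(iou_thr), length(iou_thr) == 1,
            is.numeric(skip_box_thr), length(skip_box_thr) == 1)
  if (iou_thr <= 0 || iou_thr >= 1) stop("iou_thr must lie in (0,1)", call. = FALSE)
  if (skip_box_thr < 0 || skip_box_thr > 1) {
    stop("skip_box_thr must lie in [0,1]", call. = FALSE)
  }
  if (is.null(names(model_weights)) || any(!nzchar(names(model_weights)))) {
    stop("model_weights must be a named vector (names = model ids)", call. = FALSE)
  }
  if (any(model_weights <= 0)) stop("model weights must be > 0", call. = FALSE)
  structure(
    list(iou_thr = iou_thr, skip_box_thr = skip_box_thr,
         model_weights = model_weights, conf_mode = conf_mode,
         rescale_by_model_count = rescale_by_model_count),
    class = "fusion_params"
  )
}

#' @export
print.fusion_params <- function(x, ...) {
  cat("WBF fusion parameters\n")
  cat(sprintf("  iou_thr:      %.4f\n", x$iou_thr))
  cat(sprintf("  skip_box_thr: %.4f\n", x$skip_box_thr))
  cat(sprintf("  weights:      %s\n",
              paste(sprintf("%s=%.4f", names(x$model_weights), x$model_weights),
                    collapse = ", ")))
  cat(sprintf("  conf_mode: %s, rescale_by_model_count: %s\n",
              x$conf_mode, x$rescale_by_model_count))
  invisible(x)
}

#' Fused confidence of a cluster
#'
#' The combined score of a fused box is the average of its members'
#' (weight-scaled) confidence scores, clipped to \[0,1\];
#' `conf_mode = "weighted_mean"` weights that average by the confidences
#' themselves.
#'
#' @param confidences numeric vector of member confidences (already
#'   weight-scaled when called from [weighted_boxes_fusion()]).
#' @param conf_mode `"mean"` or `"weighted_mean"`.
#' @return a single score in \[0,1\].
#' @examples
#' fuse_confidence(c(0.9, 0.3)) # 0.6
#' @export
fuse_confidence <- function(confidences, conf_mode = c("mean", "weighted_mean")) {
  conf_mode <- match.arg(conf_mode)
  if (length(confidences) == 0) stop("empty cluster", call. = FALSE)
  val <- switch(conf_mode,
    mean = mean(confidences),
    weighted_mean = sum(confidences^2) / sum(confidences)
  )
  min(max(val, 0), 1)
}

#' Fused coordinates of a cluster
#'
#' Each coordinate of the fused box is the confidence-weighted average of the
#' members' coordinates: `sum(C_i * v_i) / sum(C_i)` for v in
#' (cx, cy, w, h). The fused box therefore always lies inside the
#' coordinate-wise hull of its members.
#'
#' @param members data frame of member detections (`cx`, `cy`, `w`, `h`,
#'   `confidence`).
#' @return one-row data frame with the fused `cx`, `cy`, `w`, `h`.
#' @examples
#' m <- data.frame(cx = c(0.40, 0.50), cy = 0.40, w = 0.20, h = 0.20,
#'                 confidence = c(0.9, 0.3))
#' fuse_coordinates(m)$cx # 0.425
#' @export
fuse_coordinates <- function(members) {
  members <- as.data.frame(members)
  if (nrow(members) == 0) stop("empty cluster", call. = FALSE)
  check_detections(members)
  ctot <- sum(members$confidence)
  if (ctot <= 0) stop("total cluster confidence is zero", call. = FALSE)
  data.frame(
    cx = sum(members$confidence * members$cx) / ctot,
    cy = sum(members$confidence * members$cy) / ctot,
    w = sum(members$confidence * members$w) / ctot,
    h = sum(members$confidence * members$h) / ctot
  )
}

#' Weighted Boxes Fusion of one image's detections
#'
#' Merges the detections of several models on a single image. The algorithm:
#'
#' 1. discard detections with raw confidence below `skip_box_thr`;
#' 2. scale each remaining confidence by its model's weight divided by the
#'    mean model weight;
#' 3. per class, walk the detections in descending scaled confidence; each
#'    detection joins the existing cluster whose *current fused box* it
#'    overlaps with IoU above `iou_thr` (highest IoU wins, ties to the
#'    earlier-created cluster), otherwise it opens a new cluster;
#' 4. after every join the cluster's fused coordinates
#'    ([fuse_coordinates()]) and confidence ([fuse_confidence()]) are
#'    recomputed;
#' 5. the fused detections are returned sorted by descending confidence.
#'
#' The output never has more boxes than the input.
#'
#' @param detections data frame with columns `image_id` (all equal),
#'   `label`, `cx`, `cy`, `w`, `h`, `confidence`, `model_id`; every
#'   `model_id` must appear in `params$model_weights`.
#' @param params a [fusion_params()] object.
#' @return data frame of fused detections with `model_id = "fused"` and a
#'   `cluster_size` column recording how many boxes merged into each.
#' @examples
#' det <- data.frame(
#'   image_id = "img1", label = 0L,
#'   cx = c(0.40, 0.50), cy = 0.40, w = 0.20, h = 0.20,
#'   confidence = c(0.9, 0.3), model_id = c("a", "b")
#' )
#' p <- fusion_params(iou_thr = 0.30, model_weights = c(a = 1, b = 1))
#' weighted_boxes_fusion(det, p) # one box, cx 0.425, confidence 0.6
#' @export
weighted_boxes_fusion <- function(detections, params) {
  stopifnot(inherits(params, "fusion_params"))
  detections <- as.data.frame(detections)
  empty <- data.frame(
    image_id = character(), label = integer(),
    cx = numeric(), cy = numeric(), w = numeric(), h = numeric(),
    confidence = numeric(), model_id = character(), cluster_size = integer()
  )
  if (nrow(detections) == 0) return(empty)
  check_detections(detections)
  if (!all(c("image_id", "label", "model_id") %in% names(detections))) {
    stop("detections need image_id, label and model_id columns", call. = FALSE)
  }
  if (length(unique(detections$image_id)) > 1) {
    stop("weighted_boxes_fusion works on one image at a time; see fuse_dataset()",
         call. = FALSE)
  }
  unknown <- setdiff(unique(detections$model_id), names(params$model_weights))
  if (length(unknown)) {
    stop("model_id without a configured weight: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }

  det <- detections[detections$confidence >= params$skip_box_thr, , drop = FALSE]
  if (nrow(det) == 0) return(empty)
  w <- params$model_weights
  det$scaled_conf <- det$confidence * unname(w[det$model_id]) / mean(w)
  n_models <- length(w)

  out <- list()
  for (cl in sort(unique(det$label))) {
    d <- det[det$label == cl, , drop = FALSE]
    # stable, reproducible processing order: scaled confidence desc, then
    # model id, then original input order
    ord <- order(-d$scaled_conf, as.character(d$model_id), seq_len(nrow(d)),
                 method = "radix")
    d <- d[ord, , drop = FALSE]

    # running sums per cluster: fused coordinates are sum(C*v)/sum(C)
    cl_sum_c <- numeric(0)       # sum of scaled confidences
    cl_sum <- matrix(numeric(0), ncol = 4)  # sums of C*(cx,cy,w,h)
    cl_confs <- list()           # member scaled confidences (for fuse_confidence)
    fused_boxes <- data.frame(cx = numeric(0), cy = numeric(0),
                              w = numeric(0), h = numeric(0))
    for (i in seq_len(nrow(d))) {
      bi <- d[i, c("cx", "cy", "w", "h")]
      ci <- d$scaled_conf[i]
      join <- 0L
      if (nrow(fused_boxes) > 0) {
        ious <- iou_pairwise(fused_boxes, bi)
        best <- which(ious == max(ious))[1]  # earlier cluster wins ties
        if (ious[best] > params$iou_thr) join <- best
      }
      contrib <- ci * as.numeric(bi)
      if (join > 0) {
        cl_sum_c[join] <- cl_sum_c[join] + ci
        cl_sum[join, ] <- cl_sum[join, ] + contrib
        cl_confs[[join]] <- c(cl_confs[[join]], ci)
        fused_boxes[join, ] <- cl_sum[join, ] / cl_sum_c[join]
      } else {
        cl_sum_c <- c(cl_sum_c, ci)
        cl_sum <- rbind(cl_sum, contrib)
        cl_confs[[length(cl_confs) + 1L]] <- ci
        fused_boxes <- rbind(fused_boxes, bi)
        rownames(fused_boxes) <- NULL
      }
    }

    conf <- vapply(cl_confs, fuse_confidence, 1, conf_mode = params$conf_mode)
    sizes <- lengths(cl_confs)
    if (params$rescale_by_model_count) {
      conf <- conf * pmin(sizes, n_models) / n_models
    }
    out[[length(out) + 1L]] <- data.frame(
      image_id = detections$image_id[1],
      label = cl,
      cx = fused_boxes$cx, cy = fused_boxes$cy,
      w = fused_boxes$w, h = fused_boxes$h,
      confidence = pmin(pmax(conf, 0), 1),
      model_id = "fused",
      cluster_size = as.integer(sizes)
    )
  }
  res <- do.call(rbind, out)
  res <- res[order(-res$confidence, res$label, seq_len(nrow(res)),
                   method = "radix"), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Fuse a whole dataset image by image
#'
#' Applies [weighted_boxes_fusion()] independently to every image present in
#' `detections`. Images where only some models produced output are fused
#' with the models present.
#'
#' @param detections data frame of detections over many images (columns as
#'   in [weighted_boxes_fusion()]).
#' @param params a [fusion_params()] object.
#' @param image_ids optional roster; defaults to the images present.
#' @return data frame of fused detections over all images.
#' @export
fuse_dataset <- function(detections, params, image_ids = NULL) {
  detections <- as.data.frame(detections)
  if (is.null(image_ids)) image_ids <- unique(as.character(detections$image_id))
  parts <- lapply(image_ids, function(id) {
    weighted_boxes_fusion(detections[detections$image_id == id, , drop = FALSE],
                          params)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- weighted_boxes_fusion(detections[0, , drop = FALSE], params)
  }
  rownames(out) <- NULL
  out
}
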