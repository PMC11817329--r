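# Detection metrics: greedy one-to-one matching at IoU >= 0.5, precision /
# recall / F1, PR curves, all-point-interpolated AP and mAP@0.5.

#' Match predictions to ground truth
#'
#' Greedy one-to-one matching, the standard PASCAL/COCO discipline:
#' predictions are visited in descending confidence; each claims the not yet
#' matched same-class ground-truth box with the highest IoU, provided that
#' IoU is at least `iou_threshold` (inclusive). Unmatched predictions count
#' as false positives, unmatched ground truths as false negatives.
#'
#' @param preds data frame of detections (`image_id`, `label`, box columns,
#'   `confidence`).
#' @param gts data frame of ground-truth boxes (`image_id`, `label`, box
#'   columns).
#' @param iou_threshold minimum IoU for a true positive (default 0.5).
#' @return list of class `match_result`: counts `tp`, `fp`, `fn` and a
#'   `matched_pairs` data frame (`pred_index`, `gt_index`, `iou`). Always
#'   `tp + fn = nrow(gts)` and `tp + fp = nrow(preds)`.
#' @export
match_detections <- function(preds, gts, iou_threshold = 0.5) {
  preds <- as.data.frame(preds)
  gts <- as.data.frame(gts)
  if (nrow(preds) > 0) check_detections(preds)
  if (nrow(gts) > 0) check_boxes(gts, "ground-truth box")
  flags <- match_flags(preds, gts, iou_threshold)
  tp <- sum(flags$tp)
  out <- list(
    tp = tp, fp = nrow(preds) - tp, fn = nrow(gts) - tp,
    matched_pairs = data.frame(
      pred_index = which(flags$tp),
      gt_index = flags$gt_index[flags$tp],
      iou = flags$iou[flags$tp]
    )
  )
  class(out) <- "match_result"
  out
}

# Core greedy matcher. Returns, for each prediction in the original row
# order: tp flag, matched gt row index (NA if none) and the matching IoU.
# Matching is per image and per class; visiting order is descending
# confidence with deterministic tie-breaks.
match_flags <- function(preds, gts, iou_threshold) {
  np <- nrow(preds)
  tp <- logical(np)
  gt_index <- rep(NA_integer_, np)
  iou <- rep(NA_real_, np)
  if (np == 0) return(list(tp = tp, gt_index = gt_index, iou = iou))
  ord <- order(-preds$confidence, as.character(preds$image_id),
               seq_len(np), method = "radix")
  gt_taken <- logical(nrow(gts))
  gt_img <- as.character(gts$image_id)
  gt_lab <- gts$label
  for (i in ord) {
    cand <- which(gt_img == as.character(preds$image_id[i]) &
                    gt_lab == preds$label[i] & !gt_taken)
    if (length(cand) == 0) next
    ious <- iou_pairwise(gts[cand, , drop = FALSE], preds[i, , drop = FALSE])
    best <- which.max(ious)
    if (ious[best] >= iou_threshold) {
      tp[i] <- TRUE
      gt_index[i] <- cand[best]
      iou[i] <- ious[best]
      gt_taken[cand[best]] <- TRUE
    }
  }
  list(tp = tp, gt_index = gt_index, iou = iou)
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match result: TP %d, FP %d, FN %d\n", x$tp, x$fp, x$fn))
  invisible(x)
}

#' Precision, recall and F1 from matching counts
#'
#' `P = TP / (TP + FP)`, `R = TP / (TP + FN)`, `F1 = 2PR / (P + R)`.
#' Conventions for empty denominators: P = 0 when there are no predictions,
#' R = 0 when there is no ground truth, F1 = 0 when P + R = 0.
#'
#' @param tp,fp,fn non-negative counts.
#' @return named numeric vector `(precision, recall, f1)`.
#' @examples
#' precision_recall_f1(59, 4, 1)
#' @export
precision_recall_f1 <- function(tp, fp, fn) {
  if (any(c(tp, fp, fn) < 0)) stop("counts must be non-negative", call. = FALSE)
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f1 = f1)
}

#' Precision-recall curve over a confidence sweep
#'
#' Sweeps the confidence threshold over every distinct prediction confidence
#' (descending) and records cumulative precision and recall against the
#' fixed ground truth, with per-image, per-class greedy matching. Recall is
#' non-decreasing along the curve; duplicate confidences collapse to a
#' single threshold.
#'
#' @param preds detections pooled over all images (and classes, for a
#'   micro-averaged curve; subset to one class for a per-class curve).
#' @param gts the corresponding ground-truth boxes; must be non-empty
#'   (recall is undefined otherwise).
#' @param iou_threshold true-positive IoU criterion (default 0.5).
#' @return object of class `pr_curve`: data frame with columns `threshold`,
#'   `recall`, `precision`.
#' @export
pr_curve <- function(preds, gts, iou_threshold = 0.5) {
  preds <- as.data.frame(preds)
  gts <- as.data.frame(gts)
  if (nrow(gts) == 0) stop("no ground truth: recall is undefined", call. = FALSE)
  check_boxes(gts, "ground-truth box")
  if (nrow(preds) == 0) {
    out <- data.frame(threshold = numeric(), recall = numeric(),
                      precision = numeric())
    class(out) <- c("pr_curve", "data.frame")
    return(out)
  }
  check_detections(preds)
  flags <- match_flags(preds, gts, iou_threshold)
  ord <- order(-preds$confidence, as.character(preds$image_id),
               seq_len(nrow(preds)), method = "radix")
  conf_sorted <- preds$confidence[ord]
  tp_cum <- cumsum(flags$tp[ord])
  fp_cum <- cumsum(!flags$tp[ord])
  # keep the last entry of each run of equal confidences: the sweep point
  # "threshold = c" includes every prediction with confidence >= c
  keep <- c(conf_sorted[-1] != conf_sorted[-length(conf_sorted)], TRUE)
  out <- data.frame(
    threshold = conf_sorted[keep],
    recall = tp_cum[keep] / nrow(gts),
    precision = tp_cum[keep] / (tp_cum[keep] + fp_cum[keep])
  )
  rownames(out) <- NULL
  class(out) <- c("pr_curve", "data.frame")
  out
}

#' Average precision (area under the PR curve)
#'
#' All-point interpolation: the precision envelope
#' `p~(r) = max over r' >= r of p(r')` is integrated over recall. The
#' envelope is piecewise constant between the sweep's recall values, so the
#' integral is an exact finite sum. An 11-point variant (mean of the
#' envelope at recalls 0, 0.1, ..., 1) is available for comparison with
#' older benchmarks.
#'
#' @param curve a [pr_curve()] object.
#' @param interpolation `"all_point"` (default) or `"eleven_point"`.
#' @return AP in \[0,1\]; 0 for an empty curve (no predictions).
#' @export
average_precision <- function(curve, interpolation = c("all_point", "eleven_point")) {
  interpolation <- match.arg(interpolation)
  stopifnot(inherits(curve, "pr_curve") || all(c("recall", "precision") %in% names(curve)))
  if (nrow(curve) == 0) return(0)
  # envelope at each sweep point: running max of precision from the right
  env <- rev(cummax(rev(curve$precision)))
  if (interpolation == "eleven_point") {
    rec_grid <- seq(0, 1, by = 0.1)
    p_at <- vapply(rec_grid, function(r) {
      idx <- which(curve$recall >= r)
      if (length(idx) == 0) 0 else max(env[idx])
    }, 1)
    return(mean(p_at))
  }
  r <- curve$recall
  sum(diff(c(0, r)) * env)
}

#' Mean average precision over classes
#'
#' The unweighted mean of per-class AP values; at an IoU criterion of 0.5
#' this is the usual mAP@0.5.
#'
#' @param per_class_ap named numeric vector (or list) of AP values, one per
#'   class.
#' @return the mean AP.
#' @export
map50 <- function(per_class_ap) {
  per_class_ap <- unlist(per_class_ap)
  if (length(per_class_ap) == 0) stop("no classes: mAP is undefined", call. = FALSE)
  mean(per_class_ap)
}

#' Pick an operating point on a PR curve
#'
#' The single precision/recall/F1 numbers a detector reports correspond to
#' one confidence cutoff. `mode = "max_f1"` picks the sweep point with the
#' highest F1 (ties broken toward higher recall); `mode = "fixed_threshold"`
#' evaluates at a given cutoff.
#'
#' @param curve a [pr_curve()] object.
#' @param mode `"max_f1"` or `"fixed_threshold"`.
#' @param threshold the cutoff for `mode = "fixed_threshold"`.
#' @return named vector `(precision, recall, f1, threshold)`.
#' @export
operating_point <- function(curve, mode = c("max_f1", "fixed_threshold"),
                            threshold = NULL) {
  mode <- match.arg(mode)
  if (nrow(curve) == 0) stop("empty PR curve", call. = FALSE)
  f1 <- ifelse(curve$precision + curve$recall > 0,
               2 * curve$precision * curve$recall / (curve$precision + curve$recall),
               0)
  if (mode == "max_f1") {
    best <- which(f1 == max(f1))
    i <- best[which.max(curve$recall[best])]
  } else {
    if (is.null(threshold)) stop("fixed_threshold mode needs a threshold", call. = FALSE)
    ok <- which(curve$threshold >= threshold)
    if (length(ok) == 0) {
      return(c(precision = 0, recall = 0, f1 = 0, threshold = threshold))
    }
    i <- max(ok) # lowest sweep confidence still above the cutoff
  }
  c(precision = curve$precision[i], recall = curve$recall[i], f1 = f1[i],
    threshold = curve$threshold[i])
}

#' Full evaluation report
#'
#' Computes per-class AP (each class's PR curve against its own ground
#' truth), their mean (mAP@0.5 at the default IoU criterion), and the
#' operating-point precision/recall/F1 from the pooled, micro-averaged
#' curve. Classes present in the ground truth but never predicted score
#' AP 0; predicted classes without ground truth are ignored for AP (they
#' still cost precision at the operating point).
#'
#' @param preds detections over the evaluation images.
#' @param gts ground-truth boxes over the same images (non-empty).
#' @param iou_threshold true-positive IoU criterion (default 0.5).
#' @param mode,threshold operating-point selection, see [operating_point()].
#' @return object of class `eval_report`: list with `per_class_ap`, `map50`,
#'   `precision`, `recall`, `f1`, `operating_threshold`, `n_predictions`,
#'   `n_ground_truth`, and the pooled `curve`.
#' @examples
#' gt <- data.frame(image_id = "a", label = 0L, cx = 0.5, cy = 0.5,
#'                  w = 0.2, h = 0.2)
#' pred <- transform(gt, confidence = 0.9, model_id = "m")
#' evaluate_detections(pred, gt)
#' @export
evaluate_detections <- function(preds, gts, iou_threshold = 0.5,
                                mode = c("max_f1", "fixed_threshold"),
                                threshold = NULL) {
  mode <- match.arg(mode)
  preds <- as.data.frame(preds)
  gts <- as.data.frame(gts)
  if (nrow(gts) == 0) stop("no ground truth: evaluation is undefined", call. = FALSE)
  classes <- sort(unique(gts$label))
  ap <- vapply(classes, function(cl) {
    average_precision(pr_curve(preds[preds$label == cl, , drop = FALSE],
                               gts[gts$label == cl, , drop = FALSE],
                               iou_threshold))
  }, 1)
  names(ap) <- as.character(classes)
  pooled <- pr_curve(preds, gts, iou_threshold)
  op <- if (nrow(pooled) > 0) {
    operating_point(pooled, mode, threshold)
  } else {
    c(precision = 0, recall = 0, f1 = 0, threshold = NA_real_)
  }
  out <- list(
    per_class_ap = ap,
    map50 = map50(ap),
    precision = unname(op["precision"]),
    recall = unname(op["recall"]),
    f1 = unname(op["f1"]),
    operating_threshold = unname(op["threshold"]),
    iou_threshold = iou_threshold,
    n_predictions = nrow(preds),
    n_ground_truth = nrow(gts),
    curve = pooled
  )
  class(out) <- "eval_report"
  out
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("detection evaluation (IoU >= %.2f, %d predictions vs %d ground-truth boxes)\n",
              x$iou_threshold, x$n_predictions, x$n_ground_truth))
  cat(sprintf("  mAP@%.2f:   %.4f\n", x$iou_threshold, x$map50))
  cat(sprintf("  precision: %.4f  recall: %.4f  F1: %.4f  (at confidence >= %.4f)\n",
              x$precision, x$recall, x$f1, x$operating_threshold))
  invisible(x)
}

#' Write an evaluation report to JSON and/or CSV
#'
#' @param report an `eval_report` from [evaluate_detections()].
#' @param json_path,csv_path,curve_csv_path output files (`NULL` to skip).
#' @return invisibly, the report.
#' @export
write_eval_report <- function(report, json_path = NULL, csv_path = NULL,
                              curve_csv_path = NULL) {
  stopifnot(inherits(report, "eval_report"))
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(
        map50 = report$map50,
        precision = report$precision,
        recall = report$recall,
        f1 = report$f1,
        operating_threshold = report$operating_threshold,
        iou_threshold = report$iou_threshold,
        per_class_ap = as.list(report$per_class_ap),
        n_predictions = report$n_predictions,
        n_ground_truth = report$n_ground_truth
      ),
      json_path, auto_unbox = TRUE, digits = NA
    )
  }
  if (!is.null(csv_path)) {
    utils::write.csv(
      data.frame(
        metric = c("map50", "precision", "recall", "f1", "operating_threshold"),
        value = c(report$map50, report$precision, report$recall, report$f1,
                  report$operating_threshold)
      ),
      csv_path, row.names = FALSE
    )
  }
  if (!is.null(curve_csv_path)) {
    utils::write.csv(as.data.frame(report$curve), curve_csv_path, row.names = FALSE)
  }
  invisible(report)
}
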