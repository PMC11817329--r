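# Independent brute-force oracles. These re-derive the same quantities the
# package computes, but directly from the definitions with plain loops and
# no shared code paths (beyond the IoU primitive, checked separately).

# Corner-form IoU from first principles, scalar.
oracle_iou <- function(a, b) {
  ax1 <- a$cx - a$w / 2; ax2 <- a$cx + a$w / 2
  ay1 <- a$cy - a$h / 2; ay2 <- a$cy + a$h / 2
  bx1 <- b$cx - b$w / 2; bx2 <- b$cx + b$w / 2
  by1 <- b$cy - b$h / 2; by2 <- b$cy + b$h / 2
  iw <- max(0, min(ax2, bx2) - max(ax1, bx1))
  ih <- max(0, min(ay2, by2) - max(ay1, by1))
  inter <- iw * ih
  inter / (a$w * a$h + b$w * b$h - inter)
}

# Brute-force Weighted Boxes Fusion: enumerates the greedy cluster
# assignment directly from the definition, recomputing every fused box from
# its member list from scratch at each step (no running sums).
oracle_wbf <- function(detections, params) {
  det <- detections[detections$confidence >= params$skip_box_thr, , drop = FALSE]
  if (nrow(det) == 0) return(NULL)
  w <- params$model_weights
  det$sc <- det$confidence * unname(w[as.character(det$model_id)]) / mean(w)
  result <- NULL
  for (cl in sort(unique(det$label))) {
    d <- det[det$label == cl, , drop = FALSE]
    d <- d[order(-d$sc, as.character(d$model_id), seq_len(nrow(d)),
                 method = "radix"), , drop = FALSE]
    clusters <- list() # each: vector of member row indices into d
    fused_of <- function(members) {
      m <- d[members, , drop = FALSE]
      data.frame(cx = sum(m$sc * m$cx) / sum(m$sc),
                 cy = sum(m$sc * m$cy) / sum(m$sc),
                 w = sum(m$sc * m$w) / sum(m$sc),
                 h = sum(m$sc * m$h) / sum(m$sc))
    }
    for (i in seq_len(nrow(d))) {
      best_j <- 0; best_iou <- -1
      for (j in seq_along(clusters)) {
        v <- oracle_iou(fused_of(clusters[[j]]), d[i, ])
        if (v > best_iou + 1e-15) { best_iou <- v; best_j <- j }
      }
      if (best_j > 0 && best_iou > params$iou_thr) {
        clusters[[best_j]] <- c(clusters[[best_j]], i)
      } else {
        clusters[[length(clusters) + 1]] <- i
      }
    }
    for (j in seq_along(clusters)) {
      m <- d[clusters[[j]], , drop = FALSE]
      conf <- if (params$conf_mode == "mean") mean(m$sc) else sum(m$sc^2) / sum(m$sc)
      conf <- min(max(conf, 0), 1) # the fused score is clipped...
      if (params$rescale_by_model_count) {
        # ...and only then down-weighted by cluster coverage
        conf <- conf * min(nrow(m), length(w)) / length(w)
      }
      result <- rbind(result, data.frame(
        label = cl, fused_of(clusters[[j]]),
        confidence = conf, cluster_size = nrow(m)
      ))
    }
  }
  result[order(-result$confidence, result$label, seq_len(nrow(result)),
               method = "radix"), , drop = FALSE]
}

# Brute-force AP: enumerate every distinct confidence as a threshold,
# recompute matching from scratch at each, then integrate the precision
# envelope over the recall step function.
oracle_ap <- function(preds, gts, iou_threshold = 0.5) {
  if (nrow(preds) == 0) return(0)
  thresholds <- sort(unique(preds$confidence), decreasing = TRUE)
  rec <- numeric(0); prec <- numeric(0)
  for (t in thresholds) {
    sub <- preds[preds$confidence >= t, , drop = FALSE]
    # greedy matching from the definition
    ord <- order(-sub$confidence, as.character(sub$image_id),
                 seq_len(nrow(sub)), method = "radix")
    taken <- rep(FALSE, nrow(gts))
    tp <- 0
    for (i in ord) {
      best_j <- 0; best_iou <- -1
      for (j in seq_len(nrow(gts))) {
        if (taken[j]) next
        if (gts$image_id[j] != sub$image_id[i] || gts$label[j] != sub$label[i]) next
        v <- oracle_iou(gts[j, ], sub[i, ])
        if (v > best_iou) { best_iou <- v; best_j <- j }
      }
      if (best_j > 0 && best_iou >= iou_threshold) {
        tp <- tp + 1
        taken[best_j] <- TRUE
      }
    }
    rec <- c(rec, tp / nrow(gts))
    prec <- c(prec, tp / nrow(sub))
  }
  # precision envelope, then exact integral of the piecewise-constant
  # envelope over recall
  env <- prec
  for (i in rev(seq_along(env))) {
    if (i < length(env)) env[i] <- max(env[i], env[i + 1])
  }
  ap <- 0
  prev_r <- 0
  for (i in seq_along(rec)) {
    ap <- ap + (rec[i] - prev_r) * env[i]
    prev_r <- rec[i]
  }
  ap
}
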