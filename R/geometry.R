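# Boxes are normalized center-form rectangles: cx, cy in [0,1], w, h > 0,
# all as fractions of image width/height. Continuous real rectangles —
# no pixel quantization anywhere.

#' Convert center-form boxes to corner form
#'
#' @param boxes data frame (or list) with numeric columns `cx`, `cy`, `w`, `h`
#'   in normalized coordinates.
#' @return data frame with columns `x1`, `y1`, `x2`, `y2` where
#'   `x1 = cx - w/2`, `x2 = cx + w/2`, and analogously for y.
#' @seealso [corner_to_center()]
#' @examples
#' center_to_corner(data.frame(cx = 0.5, cy = 0.5, w = 1, h = 1))
#' @export
center_to_corner <- function(boxes) {
  check_boxes(boxes)
  data.frame(
    x1 = boxes$cx - boxes$w / 2,
    y1 = boxes$cy - boxes$h / 2,
    x2 = boxes$cx + boxes$w / 2,
    y2 = boxes$cy + boxes$h / 2
  )
}

#' Convert corner-form boxes to center form
#'
#' Inverse of [center_to_corner()].
#'
#' @param corners data frame with numeric columns `x1`, `y1`, `x2`, `y2`,
#'   requiring `x1 < x2` and `y1 < y2` row-wise.
#' @return data frame with columns `cx`, `cy`, `w`, `h`.
#' @examples
#' corner_to_center(data.frame(x1 = 0.3, y1 = 0.3, x2 = 0.5, y2 = 0.5))
#' @export
corner_to_center <- function(corners) {
  stopifnot(is.list(corners), all(c("x1", "y1", "x2", "y2") %in% names(corners)))
  if (any(corners$x1 >= corners$x2) || any(corners$y1 >= corners$y2)) {
    stop("invalid corner box: need x1 < x2 and y1 < y2", call. = FALSE)
  }
  data.frame(
    cx = (corners$x1 + corners$x2) / 2,
    cy = (corners$y1 + corners$y2) / 2,
    w = corners$x2 - corners$x1,
    h = corners$y2 - corners$y1
  )
}

#' Intersection over union of bounding boxes
#'
#' Computes |a and b| / |a or b| on the corner-form rectangles, the overlap
#' measure used both for clustering boxes during fusion and for deciding
#' true positives during evaluation.
#'
#' `iou_pairwise()` compares two box sets row by row (recycling a single
#' row); `iou_matrix()` returns the full cross matrix.
#'
#' @param a,b data frames of center-form boxes (`cx`, `cy`, `w`, `h`).
#' @return `iou_pairwise()`: numeric vector in \[0,1\], 0 for disjoint boxes.
#'   `iou_matrix()`: `nrow(a)` x `nrow(b)` matrix.
#' @examples
#' a <- data.frame(cx = 0.40, cy = 0.40, w = 0.20, h = 0.20)
#' b <- data.frame(cx = 0.50, cy = 0.40, w = 0.20, h = 0.20)
#' iou_pairwise(a, b) # 1/3
#' @export
iou_pairwise <- function(a, b) {
  check_boxes(a)
  check_boxes(b)
  ca <- center_to_corner(a)
  cb <- center_to_corner(b)
  ix <- pmax(0, pmin(ca$x2, cb$x2) - pmax(ca$x1, cb$x1))
  iy <- pmax(0, pmin(ca$y2, cb$y2) - pmax(ca$y1, cb$y1))
  inter <- ix * iy
  union <- a$w * a$h + b$w * b$h - inter
  inter / union
}

#' @rdname iou_pairwise
#' @export
iou_matrix <- function(a, b) {
  check_boxes(a)
  check_boxes(b)
  ca <- center_to_corner(a)
  cb <- center_to_corner(b)
  ix <- pmax(0, outer(ca$x2, cb$x2, pmin) - outer(ca$x1, cb$x1, pmax))
  iy <- pmax(0, outer(ca$y2, cb$y2, pmin) - outer(ca$y1, cb$y1, pmax))
  inter <- ix * iy
  union <- outer(a$w * a$h, b$w * b$h, `+`) - inter
  inter / union
}

#' Clip boxes to the unit image
#'
#' Boxes whose corner form extends past the [0,1] image borders are clipped
#' back to the border (a warning reports how many). Jittered synthetic boxes
#' and real detector output both overflow occasionally; clipping keeps them
#' rather than rejecting.
#'
#' @param boxes data frame with columns `cx`, `cy`, `w`, `h` (extra columns
#'   pass through untouched).
#' @param warn emit a warning when any box was clipped?
#' @return the data frame with clipped coordinates.
#' @export
clip_boxes <- function(boxes, warn = TRUE) {
  if (nrow(as.data.frame(boxes)) == 0) return(boxes)
  cc <- data.frame(
    x1 = boxes$cx - boxes$w / 2, y1 = boxes$cy - boxes$h / 2,
    x2 = boxes$cx + boxes$w / 2, y2 = boxes$cy + boxes$h / 2
  )
  clipped <- cc$x1 < 0 | cc$y1 < 0 | cc$x2 > 1 | cc$y2 > 1
  if (any(clipped)) {
    if (warn) warning(sum(clipped), " box(es) extended past the image border and were clipped")
    cc$x1 <- pmin(pmax(cc$x1, 0), 1)
    cc$y1 <- pmin(pmax(cc$y1, 0), 1)
    cc$x2 <- pmin(pmax(cc$x2, 0), 1)
    cc$y2 <- pmin(pmax(cc$y2, 0), 1)
    # a box fully outside degenerates to zero extent; keep a sliver so it
    # stays a valid rectangle
    cc$x2 <- pmax(cc$x2, cc$x1 + 1e-6)
    cc$y2 <- pmax(cc$y2, cc$y1 + 1e-6)
    cc$x1 <- pmin(cc$x1, 1 - 1e-6)
    cc$y1 <- pmin(cc$y1, 1 - 1e-6)
    boxes$cx <- (cc$x1 + cc$x2) / 2
    boxes$cy <- (cc$y1 + cc$y2) / 2
    boxes$w <- cc$x2 - cc$x1
    boxes$h <- cc$y2 - cc$y1
  }
  boxes
}

# Shared validation for anything carrying box columns.
check_boxes <- function(boxes, what = "box") {
  stopifnot(is.list(boxes))
  missing_cols <- setdiff(c("cx", "cy", "w", "h"), names(boxes))
  if (length(missing_cols)) {
    stop(what, " data must have columns cx, cy, w, h (missing: ",
         paste(missing_cols, collapse = ", "), ")", call. = FALSE)
  }
  vals <- c(boxes$cx, boxes$cy, boxes$w, boxes$h)
  if (anyNA(vals) || !is.numeric(vals)) {
    stop("non-numeric or missing ", what, " coordinates", call. = FALSE)
  }
  if (any(boxes$w <= 0) || any(boxes$h <= 0)) {
    stop("degenerate ", what, ": width and height must be > 0", call. = FALSE)
  }
  if (any(boxes$cx < 0 | boxes$cx > 1 | boxes$cy < 0 | boxes$cy > 1)) {
    stop(what, " centers must lie in [0,1]", call. = FALSE)
  }
  invisible(boxes)
}

# Detections additionally carry confidence (and usually label/model_id/image_id).
check_detections <- function(det) {
  check_boxes(det, what = "detection")
  if (!"confidence" %in% names(det)) {
    stop("detections must have a confidence column", call. = FALSE)
  }
  if (any(det$confidence < 0 | det$confidence > 1)) {
    stop("confidences must lie in [0,1]", call. = FALSE)
  }
  invisible(det)
}
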