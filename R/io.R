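# Readers/writers for YOLO-format label files, COCO detection-results JSON,
# split manifests and evaluation reports. YOLO dialect: whitespace-separated
# "class cx cy w h [conf]" per line, 0-based class indices, normalized
# center coordinates (the darknet/ultralytics convention).

#' Read a YOLO-format label file
#'
#' Each non-empty line is `class cx cy w h` (ground truth) or
#' `class cx cy w h confidence` (predictions), all coordinates normalized to
#' \[0,1\]. Boxes that overhang the image border are clipped with a warning;
#' coordinates out of range beyond a small tolerance are a format error that
#' names the offending line.
#'
#' @param path label file.
#' @param image_id identifier attached to every box (default: file name
#'   without extension).
#' @param has_confidence does each line carry a trailing confidence score?
#' @param tolerance slack allowed on the \[0,1\] range before a line is
#'   rejected.
#' @return data frame with columns `image_id`, `label`, `cx`, `cy`, `w`, `h`
#'   and, when `has_confidence`, `confidence`. Zero rows for an empty file.
#' @seealso [write_yolo_labels()], [read_yolo_dir()]
#' @export
read_yolo_labels <- function(path, image_id = NULL,
                             has_confidence = FALSE, tolerance = 1e-6) {
  if (!file.exists(path)) stop("no such label file: ", path, call. = FALSE)
  if (is.null(image_id)) {
    image_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  n_fields <- if (has_confidence) 6L else 5L
  if (length(lines) == 0) {
    out <- data.frame(
      image_id = character(), label = integer(),
      cx = numeric(), cy = numeric(), w = numeric(), h = numeric()
    )
    if (has_confidence) out$confidence <- numeric()
    return(out)
  }
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- vapply(fields, length, 1L) != n_fields
  if (any(bad)) {
    stop(sprintf("%s line %d: expected %d fields, got %d",
                 path, line_no[which(bad)[1]], n_fields,
                 length(fields[[which(bad)[1]]])), call. = FALSE)
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(fields))),
                ncol = n_fields, byrow = TRUE)
  if (anyNA(mat)) {
    stop(sprintf("%s line %d: non-numeric field",
                 path, line_no[which(rowSums(is.na(mat)) > 0)[1]]), call. = FALSE)
  }
  coords <- mat[, 2:5, drop = FALSE]
  out_of_range <- coords > 1 + tolerance | coords < 0 - tolerance
  if (any(out_of_range)) {
    stop(sprintf("%s line %d: coordinate out of [0,1] range",
                 path, line_no[which(rowSums(out_of_range) > 0)[1]]), call. = FALSE)
  }
  out <- data.frame(
    image_id = image_id,
    label = as.integer(mat[, 1]),
    cx = pmin(pmax(mat[, 2], 0), 1),
    cy = pmin(pmax(mat[, 3], 0), 1),
    w = pmax(mat[, 4], 1e-9),
    h = pmax(mat[, 5], 1e-9)
  )
  if (has_confidence) {
    conf <- mat[, 6]
    if (any(conf < -tolerance | conf > 1 + tolerance)) {
      stop(sprintf("%s line %d: confidence out of [0,1]",
                   path, line_no[which(conf < -tolerance | conf > 1 + tolerance)[1]]),
           call. = FALSE)
    }
    out$confidence <- pmin(pmax(conf, 0), 1)
  }
  clip_boxes(out)
}

#' Write boxes to a YOLO-format label file
#'
#' Inverse of [read_yolo_labels()]: numeric fields round-trip within 1e-6.
#'
#' @param boxes data frame with `label`, `cx`, `cy`, `w`, `h` and optionally
#'   `confidence`.
#' @param path output file.
#' @param with_confidence append the confidence column? Requires it present.
#' @return `path`, invisibly.
#' @export
write_yolo_labels <- function(boxes, path, with_confidence = FALSE) {
  boxes <- as.data.frame(boxes)
  if (nrow(boxes) == 0) {
    writeLines(character(), path)
    return(invisible(path))
  }
  check_boxes(boxes)
  if (with_confidence && !"confidence" %in% names(boxes)) {
    stop("with_confidence = TRUE but boxes carry no confidence column", call. = FALSE)
  }
  lab <- if ("label" %in% names(boxes)) boxes$label else 0L
  lines <- sprintf("%d %.6f %.6f %.6f %.6f", lab,
                   boxes$cx, boxes$cy, boxes$w, boxes$h)
  if (with_confidence) {
    lines <- paste(lines, sprintf("%.6f", boxes$confidence))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a directory of YOLO label files
#'
#' One file per image, `<image_id>.txt`. Images listed in `image_ids` but
#' lacking a file contribute zero boxes (a detector may output nothing for
#' an image).
#'
#' @param dir directory of `.txt` label files.
#' @param has_confidence passed to [read_yolo_labels()].
#' @param model_id if given, attached as a `model_id` column.
#' @param image_ids optional full roster of image ids.
#' @return row-bound data frame over all images.
#' @export
read_yolo_dir <- function(dir, has_confidence = FALSE, model_id = NULL,
                          image_ids = NULL) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  parts <- lapply(files, read_yolo_labels, has_confidence = has_confidence)
  out <- do.call(rbind, parts)
  if (is.null(out)) {
    out <- data.frame(
      image_id = character(), label = integer(),
      cx = numeric(), cy = numeric(), w = numeric(), h = numeric()
    )
    if (has_confidence) out$confidence <- numeric()
  }
  if (!is.null(model_id)) out$model_id <- if (nrow(out)) model_id else character()
  if (!is.null(image_ids)) {
    unknown <- setdiff(unique(out$image_id), image_ids)
    if (length(unknown)) {
      stop("label files for images not in the roster: ",
           paste(utils::head(unknown, 3), collapse = ", "), call. = FALSE)
    }
  }
  out
}

#' Write detections as one YOLO file per image
#'
#' @param boxes data frame with `image_id` plus YOLO columns.
#' @param dir output directory (created if needed).
#' @param with_confidence write the confidence column?
#' @param image_ids optional roster; images with no boxes get an empty file
#'   so readers see an explicit "nothing detected".
#' @return `dir`, invisibly.
#' @export
write_yolo_dir <- function(boxes, dir, with_confidence = FALSE, image_ids = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ids <- unique(c(as.character(boxes$image_id), image_ids))
  for (id in ids) {
    write_yolo_labels(boxes[boxes$image_id == id, , drop = FALSE],
                      file.path(dir, paste0(id, ".txt")),
                      with_confidence = with_confidence)
  }
  invisible(dir)
}

#' Read COCO-style detection results
#'
#' Parses the standard detection-results JSON: an array of objects with
#' `image_id`, `category_id`, `bbox = [x, y, width, height]` in pixels with
#' top-left origin, and `score`. Pixel boxes are converted to normalized
#' center form via the image-size registry.
#'
#' @param json_path detection-results file.
#' @param image_sizes data frame with columns `image_id`, `width`, `height`
#'   (pixels); every `image_id` in the JSON must appear here.
#' @return data frame of detections in normalized center form.
#' @examples
#' \dontrun{
#' sizes <- data.frame(image_id = "1", width = 200, height = 200)
#' read_coco_detections("dets.json", sizes)
#' }
#' @export
read_coco_detections <- function(json_path, image_sizes) {
  stopifnot(all(c("image_id", "width", "height") %in% names(image_sizes)))
  if (any(image_sizes$width <= 0) || any(image_sizes$height <= 0)) {
    stop("image sizes must be positive", call. = FALSE)
  }
  raw <- jsonlite::fromJSON(json_path, simplifyDataFrame = FALSE)
  if (length(raw) == 0) {
    return(data.frame(
      image_id = character(), label = integer(),
      cx = numeric(), cy = numeric(), w = numeric(), h = numeric(),
      confidence = numeric()
    ))
  }
  ids <- vapply(raw, function(r) as.character(r$image_id), "")
  reg <- match(ids, as.character(image_sizes$image_id))
  if (anyNA(reg)) {
    stop("unknown image_id in detection results: ",
         paste(utils::head(unique(ids[is.na(reg)]), 3), collapse = ", "),
         call. = FALSE)
  }
  bb <- t(vapply(raw, function(r) as.numeric(r$bbox), numeric(4)))
  W <- image_sizes$width[reg]
  H <- image_sizes$height[reg]
  out <- data.frame(
    image_id = ids,
    label = vapply(raw, function(r) as.integer(r$category_id), 1L),
    cx = (bb[, 1] + bb[, 3] / 2) / W,
    cy = (bb[, 2] + bb[, 4] / 2) / H,
    w = bb[, 3] / W,
    h = bb[, 4] / H,
    confidence = vapply(raw, function(r) as.numeric(r$score), 1)
  )
  clip_boxes(out)
}

#' Split image ids into train/validation/test partitions
#'
#' Shuffles the ids with a seeded RNG and cuts them by the floor rule:
#' `|train| = floor(f_train * n)`, `|test| = floor(f_test * n)`, and the
#' remainder goes to validation. For 407 ids at fractions (0.80, 0.05, 0.15)
#' this yields partitions of 325 / 21 / 61.
#'
#' @param image_ids character or numeric vector of unique ids.
#' @param fractions length-3 numeric `(train, val, test)`, positive, summing
#'   to 1 within 1e-9.
#' @param seed RNG seed; the split is deterministic given the seed.
#' @param stratify_by optional factor of the same length as `image_ids`;
#'   when given, the floor rule is applied within each stratum (the global
#'   floor identity then holds only approximately).
#' @return object of class `dataset_split`: a list with `train_ids`,
#'   `val_ids`, `test_ids` and `fractions`.
#' @examples
#' sp <- split_dataset(sprintf("img%03d", 1:407), c(0.80, 0.05, 0.15), seed = 1)
#' lengths(sp[c("train_ids", "val_ids", "test_ids")]) # 325 21 61
#' @export
split_dataset <- function(image_ids, fractions = c(0.80, 0.05, 0.15),
                          seed = 1, stratify_by = NULL) {
  image_ids <- as.character(image_ids)
  n <- length(image_ids)
  if (anyDuplicated(image_ids)) stop("image ids must be unique", call. = FALSE)
  if (length(fractions) != 3 || any(fractions <= 0)) {
    stop("fractions must be three positive numbers", call. = FALSE)
  }
  if (abs(sum(fractions) - 1) > 1e-9) {
    stop("fractions must sum to 1", call. = FALSE)
  }
  if (n < 3) stop("need at least as many images as partitions", call. = FALSE)
  if (!is.null(stratify_by)) {
    stopifnot(length(stratify_by) == n)
    strata <- split(image_ids, stratify_by)
    parts <- lapply(seq_along(strata), function(k) {
      split_dataset(strata[[k]], fractions, seed = seed + k - 1L)
    })
    out <- list(
      train_ids = unlist(lapply(parts, `[[`, "train_ids"), use.names = FALSE),
      val_ids = unlist(lapply(parts, `[[`, "val_ids"), use.names = FALSE),
      test_ids = unlist(lapply(parts, `[[`, "test_ids"), use.names = FALSE),
      fractions = fractions
    )
    class(out) <- "dataset_split"
    return(out)
  }
  set.seed(seed)
  shuffled <- sample(image_ids)
  n_train <- floor(fractions[1] * n + 1e-9)
  n_test <- floor(fractions[3] * n + 1e-9)
  n_val <- n - n_train - n_test
  out <- list(
    train_ids = shuffled[seq_len(n_train)],
    val_ids = shuffled[n_train + seq_len(n_val)],
    test_ids = shuffled[n_train + n_val + seq_len(n_test)],
    fractions = fractions
  )
  class(out) <- "dataset_split"
  out
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("dataset split: %d train / %d val / %d test (fractions %s)\n",
              length(x$train_ids), length(x$val_ids), length(x$test_ids),
              paste(x$fractions, collapse = "/")))
  invisible(x)
}

#' Read or write a split manifest
#'
#' The manifest is a plain-text file with one `partition image_id` pair per
#' line (partitions `train`, `val`, `test`). A split is performed once and
#' persisted; downstream phases consume the manifest so every experiment
#' sees the same partitions.
#'
#' @param split a `dataset_split` from [split_dataset()].
#' @param path manifest file.
#' @return `write_split_manifest()`: `path` invisibly;
#'   `read_split_manifest()`: a `dataset_split`.
#' @export
write_split_manifest <- function(split, path) {
  stopifnot(inherits(split, "dataset_split"))
  lines <- c(
    paste("train", split$train_ids),
    paste("val", split$val_ids),
    paste("test", split$test_ids)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  parts <- strsplit(trimws(lines), "[[:space:]]+")
  bad <- vapply(parts, length, 1L) != 2L
  if (any(bad)) stop("malformed manifest line: ", lines[which(bad)[1]], call. = FALSE)
  partition <- vapply(parts, `[[`, "", 1L)
  id <- vapply(parts, `[[`, "", 2L)
  if (!all(partition %in% c("train", "val", "test"))) {
    stop("manifest partitions must be train/val/test", call. = FALSE)
  }
  out <- list(
    train_ids = id[partition == "train"],
    val_ids = id[partition == "val"],
    test_ids = id[partition == "test"],
    fractions = NULL
  )
  class(out) <- "dataset_split"
  out
}
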