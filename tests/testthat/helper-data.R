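# Random fixture generators used across test files.

random_boxes <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  w <- runif(n, 0.05, 0.3)
  h <- runif(n, 0.05, 0.3)
  data.frame(
    cx = runif(n, 0.2, 0.8),
    cy = runif(n, 0.2, 0.8),
    w = w, h = h
  )
}

random_detections <- function(n, n_models = 2, image_id = "img", seed = NULL,
                              labels = 0L) {
  if (!is.null(seed)) set.seed(seed)
  models <- paste0("m", seq_len(n_models))
  out <- data.frame(
    label = sample(labels, n, replace = TRUE),
    random_boxes(n),
    confidence = runif(n, 0.05, 1),
    model_id = sample(models, n, replace = TRUE)
  )
  if (!is.null(image_id)) out <- cbind(image_id = image_id, out)
  out
}

# noise boxes for evaluation fixtures; safe for n = 0
random_noise_preds <- function(n, imgs) {
  if (n == 0) {
    return(data.frame(image_id = character(), label = integer(),
                      cx = numeric(), cy = numeric(),
                      w = numeric(), h = numeric()))
  }
  data.frame(image_id = sample(imgs, n, TRUE), label = 0L, random_boxes(n))
}

equal_weights <- function(model_ids) {
  stats::setNames(rep(1, length(model_ids)), model_ids)
}
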