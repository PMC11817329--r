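# Gaussian-process Bayesian optimization with the Expected Improvement
# acquisition. The surrogate is a Matern-5/2 GP on inputs min-max scaled to
# the unit hypercube; length-scale is refit each round by profiled marginal
# likelihood over a small grid.

#' Define a hyperparameter search space
#'
#' A named list of closed intervals, one per dimension. The default is the
#' four-parameter WBF space: clustering IoU threshold in \[0.1, 0.9\],
#' skip-box threshold in \[0.001, 0.1\] and two model weights in \[1, 10\].
#'
#' @param ... named length-2 numeric vectors `c(lower, upper)`.
#' @return object of class `search_space`.
#' @examples
#' search_space() # the default WBF space
#' search_space(x = c(0, 1), y = c(-5, 5))
#' @export
search_space <- function(...) {
  dims <- list(...)
  if (length(dims) == 0) {
    dims <- list(
      iou_thr = c(0.1, 0.9),
      skip_box_thr = c(0.001, 0.1),
      weight1 = c(1, 10),
      weight2 = c(1, 10)
    )
  }
  if (is.null(names(dims)) || any(!nzchar(names(dims)))) {
    stop("every search dimension must be named", call. = FALSE)
  }
  for (nm in names(dims)) {
    d <- dims[[nm]]
    if (!is.numeric(d) || length(d) != 2 || d[1] >= d[2]) {
      stop("dimension ", nm, " must be c(lower, upper) with lower < upper",
           call. = FALSE)
    }
  }
  structure(dims, class = "search_space")
}

space_lower <- function(space) vapply(space, `[`, 1, 1L)
space_upper <- function(space) vapply(space, `[`, 1, 2L)

# unit hypercube <-> native units
space_to_native <- function(space, U) {
  U <- rbind(U)
  lo <- space_lower(space)
  hi <- space_upper(space)
  X <- sweep(sweep(U, 2, hi - lo, `*`), 2, lo, `+`)
  colnames(X) <- names(space)
  X
}
space_to_unit <- function(space, X) {
  X <- rbind(X)
  lo <- space_lower(space)
  hi <- space_upper(space)
  sweep(sweep(X, 2, lo, `-`), 2, hi - lo, `/`)
}

# Matern-5/2 correlation from a Euclidean-distance matrix and length-scale.
matern52 <- function(d, lengthscale) {
  s <- sqrt(5) * d / lengthscale
  (1 + s + s^2 / 3) * exp(-s)
}

cross_dist <- function(A, B) {
  # Euclidean distances between rows of A and rows of B
  an <- rowSums(A^2)
  bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * A %*% t(B)
  sqrt(pmax(d2, 0))
}

#' Fit a Gaussian-process surrogate
#'
#' Conditions a GP with constant prior mean (the sample mean of `y`) and a
#' Matern-5/2 kernel with one shared length-scale on observed
#' (point, score) pairs. The length-scale is chosen from a grid by profiled
#' marginal likelihood (the signal variance has a closed-form profile
#' optimum); a small diagonal jitter keeps the covariance factorization
#' stable.
#'
#' @param X numeric matrix of observed points, rows in the unit hypercube.
#' @param y numeric vector of observed objective values.
#' @param jitter relative diagonal nugget (default 1e-6).
#' @param lengthscales candidate grid for the shared length-scale.
#' @return object of class `gp_state` with the chosen kernel
#'   hyperparameters and cached factorization.
#' @export
gp_fit <- function(X, y, jitter = 1e-6,
                   lengthscales = c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6)) {
  X <- rbind(X)
  stopifnot(nrow(X) == length(y), length(y) >= 1)
  n <- length(y)
  m <- mean(y)
  r <- y - m
  D <- cross_dist(X, X)
  best <- NULL
  for (ls in lengthscales) {
    R <- matern52(D, ls) + diag(jitter, n)
    L <- tryCatch(chol(R), error = function(e) NULL)
    if (is.null(L)) next
    alpha <- backsolve(L, forwardsolve(t(L), r))
    s2 <- max(sum(r * alpha) / n, 1e-12)
    loglik <- -0.5 * n * log(s2) - sum(log(diag(L)))
    if (is.null(best) || loglik > best$loglik) {
      best <- list(ls = ls, s2 = s2, L = L, alpha = alpha, loglik = loglik)
    }
  }
  if (is.null(best)) {
    stop("GP covariance is singular beyond jitter repair (n = ", n, ")",
         call. = FALSE)
  }
  structure(
    list(X = X, y = y, prior_mean = m, lengthscale = best$ls,
         signal_var = best$s2, jitter = jitter,
         chol_R = best$L, alpha = best$alpha),
    class = "gp_state"
  )
}

#' GP posterior mean and standard deviation
#'
#' Standard GP regression posterior at the query points. At an observed
#' point the mean reproduces the observation up to the jitter; far from all
#' observations (relative to the length-scale) it reverts to the prior mean
#' with the prior signal standard deviation.
#'
#' @param state a `gp_state` from [gp_fit()].
#' @param Xq query points, rows in the unit hypercube.
#' @return list with numeric vectors `mean` and `sd`.
#' @export
gp_posterior <- function(state, Xq) {
  stopifnot(inherits(state, "gp_state"))
  Xq <- rbind(Xq)
  k <- matern52(cross_dist(Xq, state$X), state$lengthscale) # correlations
  mean <- state$prior_mean + as.numeric(k %*% state$alpha)
  v <- forwardsolve(t(state$chol_R), t(k))
  var <- state$signal_var * pmax(1 + state$jitter - colSums(v^2), 0)
  list(mean = mean, sd = sqrt(var))
}

#' Expected Improvement acquisition
#'
#' Closed form of `E[max(f(theta) - f_best, 0)]` under the GP posterior:
#' `EI = delta * Phi(z) + sd * phi(z)` with `delta = mean - best` and
#' `z = delta / sd`; when `sd = 0` it degenerates to `max(delta, 0)`.
#' Always non-negative.
#'
#' @param mean,sd posterior mean(s) and standard deviation(s).
#' @param best_so_far the best observed objective value.
#' @return EI value(s), same length as `mean`.
#' @examples
#' expected_improvement(0, 1, 0) # dnorm(0) = 0.3989
#' @export
expected_improvement <- function(mean, sd, best_so_far) {
  if (any(sd < 0)) stop("sd must be non-negative", call. = FALSE)
  delta <- mean - best_so_far
  ei <- pmax(delta, 0)
  pos <- sd > 0
  if (any(pos)) {
    z <- delta[pos] / sd[pos]
    ei[pos] <- delta[pos] * stats::pnorm(z) + sd[pos] * stats::dnorm(z)
  }
  pmax(ei, 0)
}

#' Propose the next evaluation point
#'
#' Maximizes Expected Improvement over a seeded space-filling candidate set
#' (Latin-hypercube, default 2048 points) augmented with local refinements:
#' Gaussian perturbations of the incumbent at several shrinking scales.
#' If every candidate has zero EI (a degenerate flat posterior), the
#' highest-posterior-variance candidate is returned instead, preserving
#' exploration.
#'
#' @param state a `gp_state`.
#' @param space a [search_space()].
#' @param n_candidates size of the global candidate set.
#' @param local_scales perturbation standard deviations (unit-cube scale)
#'   used around the incumbent, 64 candidates each.
#' @return list with `theta` (named, native units), `theta_unit` and `ei`.
#'   Uses (and advances) the current RNG stream; seed it for determinism.
#' @export
propose_next <- function(state, space, n_candidates = 2048,
                         local_scales = c(0.1, 0.03, 0.01, 0.003)) {
  d <- length(space)
  cand <- lhs::randomLHS(n_candidates, d)
  inc <- state$X[which.max(state$y), , drop = FALSE]
  for (s in local_scales) {
    loc <- matrix(rep(inc, each = 64), nrow = 64) +
      matrix(stats::rnorm(64 * d, 0, s), nrow = 64)
    cand <- rbind(cand, pmin(pmax(loc, 0), 1))
  }
  post <- gp_posterior(state, cand)
  ei <- expected_improvement(post$mean, post$sd, max(state$y))
  if (max(ei) > 1e-12) {
    i <- which.max(ei)
  } else {
    i <- which.max(post$sd)
  }
  theta_unit <- cand[i, , drop = FALSE]
  theta <- space_to_native(space, theta_unit)[1, ]
  list(theta = theta, theta_unit = theta_unit[1, ], ei = ei[i])
}

#' Bayesian optimization of a black-box objective
#'
#' Maximizes `objective` over `space`: `n_init` Latin-hypercube evaluations,
#' then repeatedly fit the GP surrogate, maximize Expected Improvement
#' ([propose_next()]) and evaluate the proposal, until the evaluation
#' budget is exhausted or `patience` consecutive proposals fail to improve
#' the best score by more than `tol`. Fully reproducible for a fixed seed.
#'
#' An objective that throws an error is recorded as a failed trial and
#' penalized (worst observed score minus one signal standard deviation) so
#' the surrogate steers away from the region; the run continues.
#'
#' @param objective function taking a named numeric vector (native units)
#'   and returning a scalar score to maximize.
#' @param space a [search_space()].
#' @param budget total number of objective evaluations (> `n_init`, or equal
#'   for pure space-filling search).
#' @param n_init number of initial Latin-hypercube points (>= 2).
#' @param seed RNG seed.
#' @param patience,tol early-stopping rule: stop after `patience`
#'   consecutive iterations without improvement greater than `tol`.
#' @param n_candidates candidate-set size for the acquisition maximization.
#' @return object of class `bo_trace`: list with `trace` (data frame:
#'   iteration, native parameters, `score`, `ei`, `failed`), `best_theta`
#'   (named, native units), `best_score`, and `n_evals`.
#' @examples
#' sp <- search_space(x = c(0, 1), y = c(0, 1))
#' obj <- function(th) -sum((th - c(0.3, 0.7))^2)
#' res <- bo_optimize(obj, sp, budget = 20, n_init = 5, seed = 1)
#' res$best_theta
#' @export
bo_optimize <- function(objective, space, budget = 50, n_init = 10, seed = 1,
                        patience = 15, tol = 1e-4, n_candidates = 2048) {
  stopifnot(inherits(space, "search_space"))
  if (n_init < 2) stop("n_init must be at least 2", call. = FALSE)
  if (budget < n_init) stop("budget must be >= n_init", call. = FALSE)
  d <- length(space)
  set.seed(seed)

  U <- lhs::randomLHS(n_init, d)
  X <- matrix(numeric(0), ncol = d)
  y_gp <- numeric(0)     # scores as the surrogate sees them (failures penalized)
  rows <- list()
  best_score <- -Inf
  best_theta <- NULL
  stall <- 0L

  eval_point <- function(u, ei) {
    theta <- space_to_native(space, u)[1, ]
    score <- tryCatch(as.numeric(objective(theta)), error = function(e) NA_real_)
    failed <- is.na(score)
    if (failed) {
      penalty_sd <- if (length(y_gp) > 1) stats::sd(y_gp) else 1
      score_gp <- if (length(y_gp)) min(y_gp) - penalty_sd else -1
    } else {
      score_gp <- score
    }
    X <<- rbind(X, u)
    y_gp <<- c(y_gp, score_gp)
    improved <- !failed && score > best_score + tol
    if (!failed && score > best_score) {
      best_score <<- score
      best_theta <<- theta
    }
    stall <<- if (improved) 0L else stall + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      iteration = length(rows) + 1L,
      as.list(theta),
      score = if (failed) NA_real_ else score,
      ei = ei,
      failed = failed
    )
  }

  for (i in seq_len(n_init)) {
    eval_point(U[i, , drop = FALSE], NA_real_)
  }
  while (nrow(X) < budget && stall < patience) {
    state <- gp_fit(X, y_gp)
    prop <- propose_next(state, space, n_candidates = n_candidates)
    eval_point(rbind(prop$theta_unit), prop$ei)
  }

  trace <- do.call(rbind, rows)
  structure(
    list(trace = trace, best_theta = best_theta, best_score = best_score,
         n_evals = nrow(trace), space = space, seed = seed),
    class = "bo_trace"
  )
}

#' @export
print.bo_trace <- function(x, ...) {
  cat(sprintf("Bayesian optimization: %d evaluations, best score %.6f\n",
              x$n_evals, x$best_score))
  cat("  best parameters:\n")
  for (nm in names(x$best_theta)) {
    cat(sprintf("    %s = %.4f\n", nm, x$best_theta[[nm]]))
  }
  invisible(x)
}

#' Tune WBF hyperparameters by Bayesian optimization
#'
#' Optimizes the fusion hyperparameters (IoU threshold, skip-box threshold,
#' one weight per model) to maximize an evaluation metric of the fused
#' detections on the validation partition, then re-evaluates the best
#' parameters on the held-out test partition.
#'
#' @param predictions detections from two or more models (`model_id`
#'   column distinguishes them) over at least the validation and test
#'   images.
#' @param ground_truth the matching ground-truth boxes.
#' @param split a `dataset_split` (see [split_dataset()],
#'   [read_split_manifest()]).
#' @param space optional [search_space()]; dimensions `iou_thr`,
#'   `skip_box_thr`, then one `weight_<model_id>` per model. Defaults to
#'   \[0.1, 0.9\], \[0.001, 0.1\] and \[1, 10\] per weight.
#' @param objective validation metric to maximize: `"map50"` (default) or
#'   `"f1"` (at the max-F1 operating point).
#' @param budget,n_init,seed,patience,tol passed to [bo_optimize()].
#' @param conf_mode,rescale_by_model_count passed to [fusion_params()].
#' @param iou_threshold evaluation IoU criterion (default 0.5).
#' @return list with `params` (the best [fusion_params()]), `result` (the
#'   `bo_trace`), `val_report` and `test_report` (`eval_report`s of the best
#'   parameters on each partition).
#' @export
optimize_wbf <- function(predictions, ground_truth, split, space = NULL,
                         objective = c("map50", "f1"), budget = 50,
                         n_init = 10, seed = 1, patience = 15, tol = 1e-4,
                         conf_mode = "mean", rescale_by_model_count = FALSE,
                         iou_threshold = 0.5) {
  objective <- match.arg(objective)
  predictions <- as.data.frame(predictions)
  ground_truth <- as.data.frame(ground_truth)
  model_ids <- sort(unique(as.character(predictions$model_id)))
  if (length(model_ids) < 2) {
    stop("optimize_wbf needs predictions from at least two models", call. = FALSE)
  }
  if (is.null(space)) {
    dims <- c(
      list(iou_thr = c(0.1, 0.9), skip_box_thr = c(0.001, 0.1)),
      stats::setNames(rep(list(c(1, 10)), length(model_ids)),
                      paste0("weight_", model_ids))
    )
    space <- do.call(search_space, dims)
  }
  needed <- c("iou_thr", "skip_box_thr", paste0("weight_", model_ids))
  if (!setequal(names(space), needed)) {
    stop("space dimensions must be: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }

  val_pred <- predictions[predictions$image_id %in% split$val_ids, , drop = FALSE]
  val_gt <- ground_truth[ground_truth$image_id %in% split$val_ids, , drop = FALSE]
  test_pred <- predictions[predictions$image_id %in% split$test_ids, , drop = FALSE]
  test_gt <- ground_truth[ground_truth$image_id %in% split$test_ids, , drop = FALSE]
  if (nrow(val_gt) == 0) stop("no ground truth on the validation partition", call. = FALSE)

  theta_to_params <- function(theta) {
    fusion_params(
      iou_thr = theta[["iou_thr"]],
      skip_box_thr = theta[["skip_box_thr"]],
      model_weights = stats::setNames(
        unlist(theta[paste0("weight_", model_ids)]), model_ids),
      conf_mode = conf_mode,
      rescale_by_model_count = rescale_by_model_count
    )
  }
  score_fun <- function(theta) {
    fused <- fuse_dataset(val_pred, theta_to_params(theta),
                          image_ids = split$val_ids)
    rep <- evaluate_detections(fused, val_gt, iou_threshold)
    if (objective == "map50") rep$map50 else rep$f1
  }

  result <- bo_optimize(score_fun, space, budget = budget, n_init = n_init,
                        seed = seed, patience = patience, tol = tol)
  best <- theta_to_params(as.list(result$best_theta))
  val_report <- evaluate_detections(
    fuse_dataset(val_pred, best, image_ids = split$val_ids), val_gt, iou_threshold)
  test_report <- if (nrow(test_gt) > 0) {
    evaluate_detections(
      fuse_dataset(test_pred, best, image_ids = split$test_ids),
      test_gt, iou_threshold)
  } else NULL
  list(params = best, result = result, val_report = val_report,
       test_report = test_report)
}
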