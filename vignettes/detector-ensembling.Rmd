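---
title: "Ensembling object detectors: weighted boxes fusion, tuning, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensembling object detectors: weighted boxes fusion, tuning, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup}
library(wbfusion)
```

## The problem

Modern object detectors disagree. A fast one-stage CNN detector tends to
find almost every object but localizes loosely and hallucinates spurious
boxes; a transformer-style detector is usually tighter and more conservative
but misses more. On tasks where both error types are costly — the motivating
case is flagging impacted teeth on dental panoramic radiographs, where a
missed tooth delays treatment and a false alarm wastes a clinician's
attention — combining detectors is more attractive than picking one.

`wbfusion` implements the post-processing side of that combination. It takes
the *outputs* of two or more trained detectors (bounding boxes with
confidence scores, in the normalized YOLO text format or COCO results JSON),
merges them with Weighted Boxes Fusion, tunes the fusion hyperparameters by
Gaussian-process Bayesian optimization against a validation split, and
scores everything with the standard detection metrics. Training detectors,
and any image-level preprocessing such as super-resolution enhancement, are
deliberately out of scope: the package begins where detector inference ends.
(`run_phase()` accepts a `preprocess_cmd` config key purely as a documented
hook; it records the command in the run manifest and never executes it.)

## Weighted boxes fusion

Non-maximum suppression resolves duplicate detections by deletion: keep the
most confident box, discard its overlapping rivals. Weighted Boxes Fusion
(WBF) instead treats overlapping boxes from different models as noisy
measurements of one object and averages them.

For a cluster of $T$ boxes with confidences $C_i$ and center-form
coordinates $(x_i, y_i, w_i, h_i)$, the fused box is

$$C = \frac{1}{T}\sum_{i=1}^{T} C_i, \qquad
  v = \frac{\sum_{i=1}^{T} C_i\, v_i}{\sum_{i=1}^{T} C_i}
  \quad\text{for } v \in \{x, y, w, h\},$$

i.e. the confidence is the plain average of the member scores and each
coordinate is their confidence-weighted mean. Clusters are built greedily:
detections are visited in descending confidence, and each joins the
existing cluster whose *current fused box* it overlaps with IoU above
`iou_thr` (ties go to the earlier cluster), otherwise it founds a new one.
After every join the fused box is recomputed, so a cluster's effective
position drifts toward its high-confidence members as it grows.

Three design points deserve explanation because the underlying formulation
leaves them open:

* **How model weights enter.** The coordinate and confidence formulas above
  contain no per-model weight, yet trusting one detector more than another
  is the whole point of *weighted* fusion. We scale each detection's
  confidence by $w_m / \bar{w}$ (its model's weight over the mean weight)
  before anything else happens. Weights therefore influence the processing
  order, the coordinate averages, and the fused scores, while the mean
  normalization keeps scaled scores in a comparable range — a weight
  configuration of all-equal weights is exactly the unweighted algorithm.
* **Where the skip threshold applies.** `skip_box_thr` filters on *raw*
  confidence, before weight scaling. It is a per-detector quality floor; a
  detector's trust weight should not rescue (or doom) its weakest boxes.
* **Cluster-coverage rescaling.** Some fusion implementations multiply the
  fused score by $\min(T, M)/M$ ($M$ = number of models), punishing boxes
  only one model saw. That is available behind
  `rescale_by_model_count = TRUE` but defaults off, keeping the fused score
  the plain clipped average; when enabled, the rescale applies *after* the
  average is clipped to $[0,1]$.

Fusion is per class throughout. With equal weights, a single model and a
zero skip threshold the operation is the identity on non-overlapping boxes,
which the test suite asserts, along with convexity (every fused coordinate
lies in the hull of its members) and equivalence with a brute-force
implementation of the same greedy definition.

```{r wbf-example}
det <- data.frame(
  image_id = "img1", label = 0L,
  cx = c(0.40, 0.50), cy = 0.40, w = 0.20, h = 0.20,
  confidence = c(0.9, 0.3), model_id = c("cnn", "detr")
)
params <- fusion_params(iou_thr = 0.30, model_weights = c(cnn = 1, detr = 1))
weighted_boxes_fusion(det, params)
```

The two boxes overlap with IoU $1/3 > 0.30$, so they fuse: the center is
pulled to $x = (0.9\cdot0.40 + 0.3\cdot0.50)/1.2 = 0.425$ and the score is
$(0.9+0.3)/2 = 0.6$. At `iou_thr = 0.40` they would stay separate.

## Evaluation: matching, PR curves, AP

A prediction is a true positive when it overlaps a same-class ground-truth
box with IoU at least 0.5 (inclusive). Matching is greedy and one-to-one in
descending confidence — the PASCAL/COCO discipline: each prediction claims
the unmatched ground truth with the highest IoU, and each ground truth can
be claimed once. `pr_curve()` sweeps the confidence threshold over every
distinct predicted confidence and records cumulative precision and recall;
`average_precision()` integrates the precision envelope
$\tilde p(r) = \max_{r' \ge r} p(r')$ over recall. Because the envelope is
piecewise constant between sweep points the integral is an exact finite
sum, and the test suite checks it against an independent implementation
that re-enumerates every threshold from scratch. An 11-point interpolation
variant exists behind a flag for comparison with older benchmarks, but the
envelope integral is the default because it is the modern estimator of the
true area under the curve. `map50()` averages per-class AP.

One reporting convention matters: a detector's single precision/recall/F1
numbers depend on an (often unstated) confidence cutoff. `operating_point()`
defaults to the cutoff maximizing F1, with ties broken toward higher recall,
and also supports a fixed threshold. When comparing against published
operating points, remember that max-F1 is a convention, not a universal
rule.

## Tuning fusion by Bayesian optimization

The four fusion hyperparameters — `iou_thr` $\in [0.1, 0.9]$,
`skip_box_thr` $\in [0.001, 0.1]$, and one weight per model in $[1, 10]$ —
interact non-smoothly with mAP, and each objective evaluation costs a full
fuse-and-evaluate pass. Bayesian optimization suits this regime: a
Gaussian-process surrogate $f(\theta) \sim \mathcal{GP}(\mu, k)$ is fit to
the observed (hyperparameter, score) pairs, and the next trial maximizes
Expected Improvement
$a(\theta) = \mathbb{E}\left[\max(f(\theta) - f(\theta^+), 0)\right]$,
which has the closed form $\Delta\Phi(z) + \sigma\phi(z)$ with
$\Delta = \mu(\theta) - f(\theta^+)$, $z = \Delta/\sigma$.

Concrete choices, each made once:

* **Kernel**: Matérn-5/2 with a single shared length-scale on inputs
  min-max scaled to the unit hypercube — a robust default for
  low-dimensional hyperparameter surfaces, smoother than Matérn-3/2 but
  without the over-smoothness of the squared exponential.
* **Hyperparameter refit**: the length-scale is chosen each round from the
  grid $\{0.05, 0.1, 0.2, 0.4, 0.8, 1.6\}$ by marginal likelihood, with the
  signal variance profiled in closed form; the diagonal jitter is $10^{-6}$.
  A grid is deliberately preferred to gradient optimization of the marginal
  likelihood: with at most a few dozen observations the likelihood surface
  is multimodal and a coarse grid is both cheaper and more stable.
* **Acquisition maximization**: EI is evaluated on a seeded Latin-hypercube
  candidate set (2048 points) plus Gaussian perturbations of the incumbent
  at scales $\{0.1, 0.03, 0.01, 0.003\}$; the local candidates let runs
  converge to $10^{-3}$-level accuracy that a pure space-filling set of
  this size cannot reach in 4-D. If the posterior is flat (all EI zero),
  the highest-variance candidate is taken, preserving exploration.
* **Initialization and stopping**: 10 Latin-hypercube points, then EI
  iterations up to a 50-evaluation budget, stopping early after 15
  consecutive improvements below $10^{-4}$.
* **Objective**: validation-set mAP@0.5 by default; `objective = "f1"`
  switches to the max-F1 operating point, for workflows that care about a
  deployable single threshold more than ranking quality.
* **Failures**: an objective error becomes a penalized observation (worst
  observed score minus one standard deviation), steering the surrogate away
  without aborting the run.

`optimize_wbf()` wires this to fusion: the objective fuses the validation
images and scores them against validation ground truth; the returned best
parameters are then re-evaluated on the untouched test partition, which is
the only number worth quoting.

## The synthetic benchmark

Real detector ensembling needs GPUs, training runs and a labeled image
corpus. To make every stage of this package testable at desk scale,
`simulator_config()` + `generate_ground_truth()` + `simulate_detector()`
emulate the *statistical behavior* of detectors, not images:

* Ground truth: 1–4 boxes per image, sizes $0.08 \pm 0.02$ (fractions of
  image size, truncated to $[0.02, 0.30]$), centers uniform in two
  horizontal bands mimicking the upper and lower jaw of a panoramic
  radiograph, resampled so no two boxes of an image overlap with IoU
  above 0.3.
* Detector errors: each ground-truth box is missed with probability
  `miss_rate`; survivors get i.i.d. Gaussian jitter (`loc_jitter`) on all
  four coordinates; `Poisson(fp_rate)` false boxes per image land uniformly
  in the placement bands.
* Confidence: `clip(0.7 * IoU + 0.2 + N(0, sd), 0, 1)`, where IoU is
  measured against the source ground-truth box and is 0 for false
  positives. Linear-in-IoU with additive noise is the simplest model that
  makes confidence informative, which is precisely what WBF's weighted
  averages assume.

The two stock profiles encode the complementary failure modes fusion
exploits: `recall_heavy` (miss 0.05, jitter 0.008, 1 FP/image) and
`precision_heavy` (miss 0.25, jitter 0.005, 0.15 FP/image). The jitter of
the recall-heavy profile was calibrated so that its measured recall exceeds
the precision-heavy profile's while its precision is lower — the
qualitative pattern the simulator is meant to reproduce; at much larger
jitter the IoU $\ge$ 0.5 criterion itself destroys measured recall and the
profile stops being recall-heavy in any measured sense.

Per-image RNG substreams (a fixed affine function of the seed and image
index) make datasets bit-reproducible regardless of how many draws any
single image consumes.

What the simulator does *not* model: correlated errors between detectors on
hard images, confidence miscalibration drift, object-size-dependent error
rates, class confusion, and anything pixel-level. Passing tests on this
benchmark therefore demonstrate algorithmic correctness and the qualitative
value of optimized fusion — not clinical performance on radiographs.

## Worked pipeline

```{r pipeline, eval = FALSE}
bench_dir <- file.path(tempdir(), "bench")
run_phase("simulate", list(out = bench_dir, n_images = 200, seed = 1))

pred_dirs <- list(
  recall_heavy = file.path(bench_dir, "predictions", "recall_heavy"),
  precision_heavy = file.path(bench_dir, "predictions", "precision_heavy")
)
opt_dir <- file.path(tempdir(), "opt")
run_phase("optimize", list(
  out = opt_dir, pred_dirs = pred_dirs,
  gt_dir = file.path(bench_dir, "ground_truth"),
  split_manifest = file.path(bench_dir, "split.txt"),
  budget = 50, seed = 1
))
run_phase("report", list(
  out = file.path(tempdir(), "report"), pred_dirs = pred_dirs,
  gt_dir = file.path(bench_dir, "ground_truth"),
  split_manifest = file.path(bench_dir, "split.txt"),
  params_file = file.path(opt_dir, "best_params.yaml")
))
```

The same pipeline runs from a shell through the thin script in
`inst/cli/wbfusion`. Problem sizes in the shipped checks were chosen to
keep a full run comfortable on a laptop CPU: 200 synthetic images with a
50-evaluation optimization budget take a few seconds per seed, and the
oracle-equivalence suites use hundreds of instances of at most ten boxes,
where brute force is exact and instant.

## Numerical conventions and edge cases

* Split rounding: `floor` for train and test, remainder to validation —
  the one integer rule consistent with an 80/5/15 split of 407 items
  giving 325/21/61. The split is persisted to a manifest and reused, never
  recomputed per phase.
* Degenerate boxes (non-positive width/height) are errors; boxes
  overhanging the image border are clipped with a warning on ingest, since
  jittered and real detector boxes both overflow occasionally.
* Clustering compares a candidate against the cluster's current fused box
  with strict `> iou_thr`; evaluation matching uses inclusive `>= 0.5`.
  These follow the respective definitions and the tests pin both.
* Metric conventions at empty denominators: precision 0 with no
  predictions, recall 0 with no ground truth, F1 0 when both are 0;
  evaluating against an empty ground-truth set is an error rather than a
  silent 1.0.
* Ties everywhere (equal confidences, equal IoUs, equal F1) break
  deterministically (input order, earlier cluster, higher recall), so
  identical seeds give byte-identical artifacts.

## Limitations

The package fuses and evaluates axis-aligned single-frame boxes only: no
rotated boxes, masks, tracking, or mAP@[.5:.95]. The optimizer is
single-objective and sequential (no batch acquisition). The GP surrogate
assumes a box-constrained continuous space; categorical fusion options
(`conf_mode`, rescaling) are fixed per run, not searched. And conclusions
drawn on the synthetic benchmark transfer to real detector pairs only to
the extent that their error statistics resemble the simulated ones —
measuring that on a held-out labeled set remains the user's job.
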