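#' Confusion counts between a prediction and a truth mask
#'
#' Counts (or soft sums) of true/false positives/negatives over an
#' evaluation mask. With `soft = TRUE`, `pred` is a probability field and
#' TP = sum(p t), FP = sum(p (1-t)), FN = sum((1-p) t), TN = sum((1-p)(1-t)).
#'
#' @param pred binary mask or, when `soft`, a probability field `vol_grid`.
#' @param truth binary `vol_grid`.
#' @param eval_mask binary `vol_grid` restricting the evaluation (brain).
#' @param soft use soft (probabilistic) sums?
#' @return A `confusion_counts` list with elements `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(pred, truth, eval_mask, soft = FALSE) {
  check_geometry(pred, truth, eval_mask, .names = c("pred", "truth", "eval_mask"))
  sel <- eval_mask$values > 0.5
  p <- pred$values[sel]
  t <- as.numeric(truth$values[sel] > 0.5)
  if (soft) {
    if (any(p < 0 | p > 1)) stop("soft predictions must lie in [0, 1]")
  } else {
    p <- as.numeric(p > 0.5)
  }
  structure(
    list(
      tp = sum(p * t), fp = sum(p * (1 - t)),
      fn = sum((1 - p) * t), tn = sum((1 - p) * (1 - t))
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> TP %.6g  FP %.6g  FN %.6g  TN %.6g\n",
              x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Tversky index
#'
#' `TP / (TP + alpha FP + beta FN)`, the asymmetric generalization of the
#' Dice coefficient (`alpha = beta = 0.5` recovers Dice exactly). The
#' corresponding loss is `1 - tversky_index(...)`.
#'
#' @param counts a `confusion_counts` object.
#' @param alpha false-positive weight, >= 0.
#' @param beta false-negative weight, >= 0.
#' @param smooth additive smoothing guarding the empty-mask limit.
#' @export
tversky_index <- function(counts, alpha, beta, smooth = 1e-6) {
  stopifnot(alpha >= 0, beta >= 0)
  (counts$tp + smooth) / (counts$tp + alpha * counts$fp + beta * counts$fn + smooth)
}

#' @rdname tversky_index
#' @export
dice_coefficient <- function(counts, smooth = 1e-6) {
  (2 * counts$tp + smooth) / (2 * counts$tp + counts$fp + counts$fn + smooth)
}

#' Size-adaptive Tversky weights from the lesion-to-brain fraction
#'
#' The per-case rule at the core of the Progression Coverage Coefficient:
#' with lesion fraction `f = n_lesion / n_brain`, the false-negative weight
#' is `beta = 1 / (f + 1)` and the false-positive weight `alpha = 1 - beta`.
#' Smaller lesions (stronger class imbalance) therefore get a larger
#' `beta`, punishing missed lesion voxels harder. The algebraically
#' identical form `beta = n_brain / (n_brain + n_lesion)` is reported
#' alongside as `beta_ratio_form`.
#'
#' @param n_lesion_voxels number of lesion voxels, >= 0.
#' @param n_brain_voxels number of brain voxels, > 0.
#' @return A `tversky_params` list: `alpha`, `beta`, `f`, `beta_ratio_form`.
#' @examples
#' size_adaptive_params(2, 100) # f = 0.02 -> alpha 0.02, beta 0.98
#' @export
size_adaptive_params <- function(n_lesion_voxels, n_brain_voxels) {
  if (n_brain_voxels <= 0) stop("`n_brain_voxels` must be positive")
  if (n_lesion_voxels < 0) stop("`n_lesion_voxels` must be >= 0")
  f <- n_lesion_voxels / n_brain_voxels
  beta <- 1 / (f + 1)
  structure(
    list(
      alpha = 1 - beta, beta = beta, f = f,
      beta_ratio_form = n_brain_voxels / (n_brain_voxels + n_lesion_voxels)
    ),
    class = "tversky_params"
  )
}

#' @export
print.tversky_params <- function(x, ...) {
  cat(sprintf("<tversky_params> f = %.4g, alpha = %.4g, beta = %.4g\n",
              x$f, x$alpha, x$beta))
  invisible(x)
}

#' Progression Coverage Coefficient (PCC)
#'
#' Tversky index with per-case size-adaptive weights: the weights are
#' induced by the lesion-to-brain voxel fraction of `lesion_reference`
#' (by default the truth mask itself), and the evaluation mask is the
#' brain. `1 - pcc_score(...)` is the PCC loss.
#'
#' @inheritParams confusion_counts
#' @param brain binary brain `vol_grid`; evaluation mask and denominator
#'   of the lesion fraction.
#' @param lesion_reference mask whose voxel count defines the lesion
#'   fraction `f`; defaults to `truth`. At pure inference time, when no
#'   truth exists, pass the pre-RT lesion.
#' @param smooth additive smoothing constant.
#' @export
pcc_score <- function(pred, truth, brain, lesion_reference = NULL,
                      soft = FALSE, smooth = 1e-6) {
  if (is.null(lesion_reference)) lesion_reference <- truth
  n_les <- n_voxels(lesion_reference)
  if (n_les == 0) stop("`lesion_reference` is empty: lesion fraction undefined")
  pars <- size_adaptive_params(n_les, n_voxels(brain))
  cc <- confusion_counts(pred, truth, brain, soft = soft)
  tversky_index(cc, pars$alpha, pars$beta, smooth = smooth)
}

#' Mean binary cross-entropy over a mask
#' @inheritParams pcc_score
#' @param eps probability clipping bound applied before the logarithm.
#' @export
bce_mean <- function(pred, truth, brain, eps = 1e-7) {
  check_geometry(pred, truth, brain, .names = c("pred", "truth", "brain"))
  sel <- brain$values > 0.5
  p <- pmin(pmax(pred$values[sel], eps), 1 - eps)
  t <- as.numeric(truth$values[sel] > 0.5)
  mean(-(t * log(p) + (1 - t) * log(1 - p)))
}

#' Compound PCC + BCE loss
#'
#' `(1 - soft PCC) + lambda * mean BCE` over the brain mask, the clinically motivated
#' fourth loss option; `lambda = 0` recovers the pure PCC loss.
#'
#' @inheritParams pcc_score
#' @param bce_weight the BCE mixing weight lambda, >= 0.
#' @export
compound_loss <- function(pred, truth, brain, lesion_reference = NULL,
                          bce_weight = 0.5, smooth = 1e-6, eps = 1e-7) {
  loss <- 1 - pcc_score(pred, truth, brain, lesion_reference,
                        soft = TRUE, smooth = smooth)
  if (bce_weight > 0) loss <- loss + bce_weight * bce_mean(pred, truth, brain, eps)
  loss
}

# gradient of (1 - soft Tversky) + lambda * BCE w.r.t. the probability
# field, on the flattened brain voxels; used by the trainer.
tversky_bce_grad <- function(p, t, alpha, beta, bce_weight, smooth = 1e-6,
                             eps = 1e-7) {
  tp <- sum(p * t)
  fp <- sum(p * (1 - t))
  fn <- sum((1 - p) * t)
  num <- tp + smooth
  den <- tp + alpha * fp + beta * fn + smooth
  dnum <- t
  dden <- t + alpha * (1 - t) - beta * t
  g <- -(dnum * den - num * dden) / (den * den)
  if (bce_weight > 0) {
    pc <- pmin(pmax(p, eps), 1 - eps)
    g <- g + bce_weight * (-t / pc + (1 - t) / (1 - pc)) / length(p)
  }
  g
}

# ---- surface distances ------------------------------------------------

#' 95th percentile Hausdorff distance between two masks, in mm
#'
#' Surface voxels (6-connectivity) of each mask are extracted; the two
#' directed surface-to-surface distance sets are pooled and the 95th
#' percentile of the pooled set returned. `method = "max_direction"`
#' instead takes the maximum of the two per-direction percentiles.
#'
#' @param a,b nonempty binary `vol_grid`s on one grid.
#' @param percentile percentile of the distance set, default 95.
#' @param method `"pooled"` (default) or `"max_direction"`.
#' @export
hd95 <- function(a, b, percentile = 95, method = c("pooled", "max_direction")) {
  method <- match.arg(method)
  check_geometry(a, b, .names = c("a", "b"))
  if (n_voxels(a) == 0 || n_voxels(b) == 0) {
    stop("hd95 is undefined for an empty mask")
  }
  sa <- surface_voxels(a)
  sb <- surface_voxels(b)
  da <- distance_map_mm(sb)$values[sa$values > 0.5] # a-surface -> b-surface
  db <- distance_map_mm(sa)$values[sb$values > 0.5]
  if (method == "pooled") {
    unname(stats::quantile(c(da, db), percentile / 100))
  } else {
    max(stats::quantile(da, percentile / 100), stats::quantile(db, percentile / 100))
  }
}

# ---- per-case evaluation ---------------------------------------------

#' Evaluate a CTV against the progression target
#'
#' The six per-case metrics used throughout: sensitivity, specificity
#' (within brain), Dice, 95\% Hausdorff distance (mm), Tversky at the
#' fixed imbalance weights (0.02, 0.98), and the size-adaptive PCC.
#'
#' @param ctv binary `vol_grid`, the candidate target volume.
#' @param target binary `vol_grid`, the composite progression lesion.
#' @param brain binary `vol_grid` brain mask.
#' @param lesion_reference mask defining the PCC lesion fraction; default
#'   `target`.
#' @return A one-row tibble with columns `sensitivity`, `specificity`,
#'   `dice`, `hd95_mm`, `tversky_002_098`, `pcc`.
#' @export
evaluate_pair <- function(ctv, target, brain, lesion_reference = NULL) {
  if (n_voxels(target) == 0) stop("empty progression target")
  cc <- confusion_counts(ctv, target, brain, soft = FALSE)
  tibble::tibble(
    sensitivity = cc$tp / (cc$tp + cc$fn),
    specificity = cc$tn / (cc$tn + cc$fp),
    dice = dice_coefficient(cc),
    hd95_mm = hd95(ctv, target),
    tversky_002_098 = tversky_index(cc, 0.02, 0.98),
    pcc = pcc_score(ctv, target, brain, lesion_reference)
  )
}

#' Band a p-value the way clinical reports print it
#' @param p numeric p-value(s).
#' @return `"<0.0001"`, `"<0.001"`, `"<0.01"`, `"<0.05"` or `"ns"`.
#' @export
p_band <- function(p) {
  cut(p,
      breaks = c(-Inf, 1e-4, 1e-3, 1e-2, 5e-2, Inf),
      labels = c("<0.0001", "<0.001", "<0.01", "<0.05", "ns"),
      right = FALSE
  ) |> as.character()
}
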