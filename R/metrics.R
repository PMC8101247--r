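# Per-layer segmentation validation: area-error percentages (false positive
# plus false negative relative to an evaluation region), pixel precision and
# sensitivity, and the clipping-induced guaranteed-false-negative share.

#' Pixel-level layer metrics against ground truth
#'
#' Within `eval_region`: `TP = |pred & gt|`, `FP = |pred & !gt|`,
#' `FN = |!pred & gt|`; `fp_pct` and `fn_pct` are percentages of the
#' evaluation-region area and `total_area_error_pct` is exactly their sum.
#' `precision_pct = 100 TP/(TP+FP)` (absent when no positives are
#' predicted), `sensitivity_pct = 100 TP/(TP+FN)` (absent when the class is
#' absent from the ground truth).
#'
#' @param pred,gt logical matrices (prediction and ground truth).
#' @param eval_region logical matrix: the reference area percentages are
#'   normalized by (the layer's parent annotation-region analogue). Must be
#'   non-empty.
#' @param parent_pred optional parent-layer prediction; when supplied,
#'   `clipped_fn_pct` is the share of ground-truth pixels outside it
#'   (guaranteed false negatives for any child predictor), else 0.
#' @return object of class `layer_metrics`: list with `fp_pct`, `fn_pct`,
#'   `total_area_error_pct`, `precision_pct`, `sensitivity_pct`,
#'   `clipped_fn_pct`, and raw counts `tp`, `fp`, `fn`, `n_eval`.
#' @export
layer_metrics <- function(pred, gt, eval_region, parent_pred = NULL) {
  pred <- as_mask(pred); gt <- as_mask(gt); eval_region <- as_mask(eval_region)
  if (!all(dim(pred) == dim(gt)) || !all(dim(pred) == dim(eval_region)))
    stop("pred, gt and eval_region shapes differ")
  n_eval <- sum(eval_region)
  if (n_eval == 0L) stop("empty eval_region")
  p <- pred & eval_region; g <- gt & eval_region
  tp <- sum(p & g); fp <- sum(p & !g); fn <- sum(!p & g)
  fp_pct <- 100 * fp / n_eval
  fn_pct <- 100 * fn / n_eval
  clipped <- if (is.null(parent_pred)) 0 else
    clipping_fn(parent_pred, gt, eval_region)
  structure(list(
    fp_pct = fp_pct, fn_pct = fn_pct,
    total_area_error_pct = fp_pct + fn_pct,
    precision_pct = if (tp + fp > 0) 100 * tp / (tp + fp) else NA_real_,
    sensitivity_pct = if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_,
    clipped_fn_pct = clipped,
    tp = tp, fp = fp, fn = fn, n_eval = n_eval),
    class = "layer_metrics")
}

#' Clipping-induced false-negative share
#'
#' Percentage of ground-truth pixels of a child layer lying outside the
#' parent layer's predicted mask, normalized by the same evaluation region.
#' These pixels are unreachable — guaranteed false negatives — for any
#' child predictor, because the parent clips the child's search region.
#'
#' @param parent_pred logical parent-layer prediction.
#' @param child_gt logical child-layer ground truth.
#' @param eval_region logical normalization region (defaults to the full
#'   frame).
#' @return numeric percentage.
#' @export
clipping_fn <- function(parent_pred, child_gt, eval_region = NULL) {
  parent_pred <- as_mask(parent_pred); child_gt <- as_mask(child_gt)
  if (!all(dim(parent_pred) == dim(child_gt)))
    stop("parent_pred and child_gt shapes differ")
  if (is.null(eval_region))
    eval_region <- matrix(TRUE, nrow(child_gt), ncol(child_gt))
  eval_region <- as_mask(eval_region)
  n_eval <- sum(eval_region)
  if (n_eval == 0L) stop("empty eval_region")
  100 * sum(child_gt & !parent_pred & eval_region) / n_eval
}

#' Tabulate layer metrics
#'
#' @param metrics named list of [layer_metrics()] objects (names = layer
#'   labels); at least one.
#' @return data frame with columns `layer`, `fp_pct`, `fn_pct`,
#'   `total_area_error_pct`, `precision_pct`, `sensitivity_pct`,
#'   `clipped_fn_pct`.
#' @export
validation_report <- function(metrics) {
  stopifnot(length(metrics) >= 1L, !is.null(names(metrics)))
  rows <- lapply(names(metrics), function(nm) {
    m <- metrics[[nm]]
    data.frame(layer = nm, fp_pct = m$fp_pct, fn_pct = m$fn_pct,
               total_area_error_pct = m$total_area_error_pct,
               precision_pct = m$precision_pct,
               sensitivity_pct = m$sensitivity_pct,
               clipped_fn_pct = m$clipped_fn_pct)
  })
  do.call(rbind, rows)
}

#' Validate a full pipeline run against ground-truth masks
#'
#' Builds the standard four-row report. Evaluation regions default to the
#' ground-truth parent layer: the whole frame for tissue, the ground-truth
#' tissue for the portal and parenchyma classes, and the ground-truth
#' parenchyma for the K7 layer. Clipped false negatives are computed from
#' the predicted parent masks.
#'
#' @param pred,gt [layer_masks()] objects (prediction, ground truth).
#' @return data frame from [validation_report()].
#' @export
validate_layers <- function(pred, gt) {
  stopifnot(inherits(pred, "layer_masks"), inherits(gt, "layer_masks"))
  full <- matrix(TRUE, nrow(gt$tissue), ncol(gt$tissue))
  m <- list(
    tissue = layer_metrics(pred$tissue, gt$tissue, full),
    portal = layer_metrics(pred$portal, gt$portal, gt$tissue,
                           parent_pred = pred$tissue),
    parenchyma = layer_metrics(pred$parenchyma, gt$parenchyma, gt$tissue,
                               parent_pred = pred$tissue),
    k7 = layer_metrics(pred$k7, gt$k7, gt$parenchyma,
                       parent_pred = pred$parenchyma))
  validation_report(m)
}
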