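# Segmentation agreement and group-comparison metrics.

#' Dice similarity coefficient
#'
#' `DSC(X, Y) = 2 |X n Y| / (|X| + |Y|)` over voxel sets.  Symmetric and
#' bounded in `[0, 1]`.  Two empty masks agree on absence; by default this
#' returns 1 with a warning (set `both_empty = "error"` to forbid it).
#'
#' @param x,y `lc_mask` objects on the same grid.
#' @param both_empty `"one"` (default) or `"error"`.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(x, y, both_empty = c("one", "error")) {
  both_empty <- match.arg(both_empty)
  if (!same_grid(x, y))
    lcseg_error("lcseg_argument_error", "masks must share a grid")
  nx <- mask_count(x); ny <- mask_count(y)
  if (nx == 0L && ny == 0L) {
    if (both_empty == "error")
      lcseg_error("lcseg_metric_error", "DSC of two empty masks is undefined")
    warning("DSC of two empty masks; returning 1 (agreement on absence)")
    return(1)
  }
  2 * sum(x$data & y$data) / (nx + ny)
}

#' Voxel-wise sensitivity, specificity and their mean
#'
#' `sensitivity = TP / (TP + FN)`, `specificity = TN / (TN + FP)`, and the
#' accuracy metric defined as their mean.
#'
#' @param pred,ref `lc_mask` objects on the same grid; `ref` must be
#'   neither empty nor the full grid.
#' @return Named list with `sensitivity`, `specificity`, `accuracy`.
#' @export
sens_spec <- function(pred, ref) {
  if (!same_grid(pred, ref))
    lcseg_error("lcseg_argument_error", "masks must share a grid")
  n <- length(ref$data)
  nref <- mask_count(ref)
  if (nref == 0L || nref == n)
    lcseg_error("lcseg_metric_error",
                "reference mask empty or covering the whole grid")
  tp <- sum(pred$data & ref$data)
  fp <- mask_count(pred) - tp
  fn <- nref - tp
  tn <- n - tp - fp - fn
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(sensitivity = sens, specificity = spec, accuracy = (sens + spec) / 2)
}

#' Probabilistic template from aligned masks
#'
#' Per-voxel fraction of masks covering the voxel, binarized at a
#' threshold.  The 50% boundary is inclusive: with an even number of masks
#' a voxel covered by exactly half of them is part of the binary template.
#' Masks are assumed already spatially aligned on a common grid.
#'
#' @param masks list of `lc_mask` objects on one grid.
#' @param threshold binarization fraction, default 0.5.
#' @return List with `probability` (`lc_volume`) and `binary` (`lc_mask`).
#' @export
probabilistic_template <- function(masks, threshold = 0.5) {
  if (length(masks) < 1L)
    lcseg_error("lcseg_argument_error", "need at least one mask")
  ref <- masks[[1]]
  for (m in masks) if (!same_grid(m, ref))
    lcseg_error("lcseg_argument_error", "masks must share a grid")
  acc <- Reduce(`+`, lapply(masks, function(m) m$data))
  prob <- acc / length(masks)
  pvol <- as_volume(prob, voxel_size = ref$voxel_size, affine = ref$affine,
                    axis_convention = ref$axis_convention)
  bin <- as_mask(array(as.integer(prob > threshold - 1e-12), dim(prob)),
                 voxel_size = ref$voxel_size, affine = ref$affine,
                 axis_convention = ref$axis_convention)
  list(probability = pvol, binary = bin)
}

#' Cohen's d effect size
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled` with the
#' pooled standard deviation from the two sample variances.
#'
#' @param group_a,group_b numeric vectors with at least 2 values each.
#' @return Effect size (sign follows `group_a - group_b`).
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L)
    lcseg_error("lcseg_argument_error", "each group needs >= 2 values")
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 <= 0)
    lcseg_error("lcseg_metric_error", "pooled standard deviation is zero")
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}

#' Per-subject segmentation evaluation
#'
#' DSC per hemisphere plus the bilateral convention used for reporting:
#' the mean of the left and right DSC (not the DSC of the union).
#'
#' @param pred,ref `lc_hemipair` objects on the same grid.
#' @param ... passed to [dsc()] (e.g. `both_empty`).
#' @return List with `left`, `right`, `bilateral` DSC values.
#' @export
evaluate_subject <- function(pred, ref, ...) {
  stopifnot(inherits(pred, "lc_hemipair"), inherits(ref, "lc_hemipair"))
  l <- dsc(pred$left, ref$left, ...)
  r <- dsc(pred$right, ref$right, ...)
  list(left = l, right = r, bilateral = (l + r) / 2)
}
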