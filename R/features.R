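# LC MRI feature extraction: contrast ratios (max/median), subregional
# contrast ratios (halves and thirds along the axial dimension), signal
# length and volume, and bilateral averaging.

# axial (inferior-superior) grid axis of a mask/volume, and whether low
# index means caudal (axis aligned with world +z) or rostral (anti-aligned)
axial_axis_info <- function(obj) {
  ax <- obj$axis_convention
  sup <- obj$affine[3, ax]
  list(axis = ax, low_is_caudal = sup >= 0)
}

# 0-based occupied axial slice index per mask voxel
mask_axial_slices <- function(mask) {
  ax <- mask$axis_convention
  idx <- which(mask$data != 0L, arr.ind = TRUE)
  idx[, ax] - 1L
}

#' Contrast ratio of an LC mask against a reference region
#'
#' `CR = (stat(LC voxels) - median(REF voxels)) / median(REF voxels)` with
#' `stat` the maximum or the median.  Medians of an even count are the mean
#' of the two central values.
#'
#' @param lc_mask,ref_mask nonempty `lc_mask` objects on the volume's grid.
#' @param volume the intensity `lc_volume`.
#' @param statistic `"max"` or `"median"`.
#' @return Dimensionless ratio.
#' @export
contrast_ratio <- function(lc_mask, volume, ref_mask,
                           statistic = c("max", "median")) {
  statistic <- match.arg(statistic)
  if (mask_count(lc_mask) == 0L)
    lcseg_error("lcseg_feature_error", "LC mask is empty")
  if (mask_count(ref_mask) == 0L)
    lcseg_error("lcseg_feature_error", "reference mask is empty")
  lc_vals <- volume$data[lc_mask$data != 0L]
  ref_med <- median(volume$data[ref_mask$data != 0L])
  if (ref_med == 0)
    lcseg_error("lcseg_division_error", "reference median is zero")
  stat <- if (statistic == "max") max(lc_vals) else median(lc_vals)
  (stat - ref_med) / ref_med
}

#' Split a mask into rostrocaudal sections of equal axial extent
#'
#' The occupied axial slice range `s_min..s_max` (length `S`, gaps
#' included) is cut at `s_min + round(S * j / n)` for `j = 1..n-1`
#' (round half away from zero).  Sections are contiguous, disjoint,
#' ordered caudal to rostral, and their union is the input mask.
#'
#' @param mask a nonempty `lc_mask`.
#' @param n_sections 2 or 3.
#' @return List of `lc_mask` sections, caudal first.
#' @export
split_rostrocaudal <- function(mask, n_sections) {
  if (!n_sections %in% c(2L, 3L))
    lcseg_error("lcseg_argument_error", "n_sections must be 2 or 3")
  if (mask_count(mask) == 0L)
    lcseg_error("lcseg_feature_error", "cannot split an empty mask")
  sl <- mask_axial_slices(mask)
  s_min <- min(sl); s_max <- max(sl)
  S <- s_max - s_min + 1L
  if (S < n_sections)
    lcseg_error("lcseg_feature_error",
                sprintf("mask spans %d axial slices, too short to split into %d",
                        S, n_sections))
  bounds <- s_min + round_half_up(S * seq_len(n_sections - 1L) / n_sections)
  lims <- cbind(c(s_min, bounds), c(bounds, s_max + 1L))  # half-open
  ax <- mask$axis_convention
  info <- axial_axis_info(mask)
  sections <- lapply(seq_len(n_sections), function(s) {
    keep <- array(0L, dim(mask$data))
    idx <- which(mask$data != 0L, arr.ind = TRUE)
    slice0 <- idx[, ax] - 1L
    sel <- slice0 >= lims[s, 1] & slice0 < lims[s, 2]
    keep[idx[sel, , drop = FALSE]] <- 1L
    as_mask(keep, voxel_size = mask$voxel_size, affine = mask$affine,
            axis_convention = mask$axis_convention)
  })
  if (!info$low_is_caudal) sections <- rev(sections)
  sections
}

#' LC signal length
#'
#' Number of distinct axial slices containing at least one mask voxel,
#' times the axial voxel size.  Occupied slices are counted, not the
#' extent, so interior gaps do not contribute.  Empty masks have length 0.
#'
#' @param mask an `lc_mask`.
#' @param voxel_size mm per axis; defaults to the mask's.
#' @return Length in mm.
#' @export
lc_length_mm <- function(mask, voxel_size = mask$voxel_size) {
  if (mask_count(mask) == 0L) return(0)
  length(unique(mask_axial_slices(mask))) *
    rep_len(voxel_size, 3L)[mask$axis_convention]
}

#' LC signal volume
#'
#' Voxel count times the voxel volume.
#'
#' @inheritParams lc_length_mm
#' @return Volume in mm^3.
#' @export
lc_volume_mm3 <- function(mask, voxel_size = mask$voxel_size) {
  mask_count(mask) * prod(rep_len(voxel_size, 3L))
}

side_features <- function(lc, ref, volume) {
  if (mask_count(lc) == 0L) {
    na2 <- setNames(rep(NA_real_, 2), c("caudal", "rostral"))
    na3 <- setNames(rep(NA_real_, 3), c("caudal", "medial", "rostral"))
    return(list(cr_max = NA_real_, cr_median = NA_real_,
                sub2_cr_max = na2, sub2_cr_median = na2,
                sub3_cr_max = na3, sub3_cr_median = na3,
                length_mm = 0, volume_mm3 = 0, empty = TRUE))
  }
  cr <- function(m, stat) contrast_ratio(m, volume, ref, stat)
  s2 <- split_rostrocaudal(lc, 2L)
  s3 <- split_rostrocaudal(lc, 3L)
  list(cr_max = cr(lc, "max"), cr_median = cr(lc, "median"),
       sub2_cr_max = setNames(vapply(s2, cr, numeric(1), stat = "max"),
                              c("caudal", "rostral")),
       sub2_cr_median = setNames(vapply(s2, cr, numeric(1), stat = "median"),
                                 c("caudal", "rostral")),
       sub3_cr_max = setNames(vapply(s3, cr, numeric(1), stat = "max"),
                              c("caudal", "medial", "rostral")),
       sub3_cr_median = setNames(vapply(s3, cr, numeric(1), stat = "median"),
                                 c("caudal", "medial", "rostral")),
       length_mm = lc_length_mm(lc), volume_mm3 = lc_volume_mm3(lc),
       empty = FALSE)
}

#' Extract the full LC feature set
#'
#' Computes every feature per hemisphere (contrast ratios against the
#' same-side reference median) and the bilateral feature set as the
#' unweighted field-wise mean of the two hemispheres.  An empty hemisphere
#' yields NA contrast features for that side and marks the bilateral
#' values as partial (computed from the remaining side).
#'
#' @param volume the intensity `lc_volume`.
#' @param lc an `lc_hemipair` of LC masks.
#' @param ref an `lc_hemipair` of reference regions.
#' @return List of class `lc_features` with elements `left`, `right`,
#'   `bilateral` (each with `cr_max`, `cr_median`, `sub2_cr_max`,
#'   `sub2_cr_median`, `sub3_cr_max`, `sub3_cr_median`, `length_mm`,
#'   `volume_mm3`) and a logical `partial` flag.
#' @export
extract_features <- function(volume, lc, ref) {
  stopifnot(inherits(volume, "lc_volume"), inherits(lc, "lc_hemipair"),
            inherits(ref, "lc_hemipair"))
  for (m in list(lc$left, lc$right, ref$left, ref$right))
    if (!all(dim(m$data) == dim(volume$data)))
      lcseg_error("lcseg_argument_error", "masks must live on the volume grid")
  left <- side_features(lc$left, ref$left, volume)
  right <- side_features(lc$right, ref$right, volume)
  fields <- c("cr_max", "cr_median", "sub2_cr_max", "sub2_cr_median",
              "sub3_cr_max", "sub3_cr_median", "length_mm", "volume_mm3")
  partial <- isTRUE(left$empty) || isTRUE(right$empty)
  bilateral <- lapply(fields, function(f) {
    v <- rbind(left[[f]], right[[f]])
    out <- colMeans(v, na.rm = partial)
    if (length(out) == 1L) out <- unname(out)
    out
  })
  names(bilateral) <- fields
  structure(list(left = left[fields], right = right[fields],
                 bilateral = bilateral, partial = partial),
            class = "lc_features")
}

#' Flatten features into a data frame
#'
#' One row per scope (left, right, bilateral) with stable column names;
#' contrast ratios are dimensionless, length in mm, volume in mm^3.
#'
#' @param x an `lc_features` object.
#' @param ... unused.
#' @export
as.data.frame.lc_features <- function(x, ...) {
  row <- function(scope) {
    f <- x[[scope]]
    data.frame(scope = scope, cr_max = f$cr_max, cr_median = f$cr_median,
               sub2_cr_max_caudal = f$sub2_cr_max[["caudal"]],
               sub2_cr_max_rostral = f$sub2_cr_max[["rostral"]],
               sub2_cr_median_caudal = f$sub2_cr_median[["caudal"]],
               sub2_cr_median_rostral = f$sub2_cr_median[["rostral"]],
               sub3_cr_max_caudal = f$sub3_cr_max[["caudal"]],
               sub3_cr_max_medial = f$sub3_cr_max[["medial"]],
               sub3_cr_max_rostral = f$sub3_cr_max[["rostral"]],
               sub3_cr_median_caudal = f$sub3_cr_median[["caudal"]],
               sub3_cr_median_medial = f$sub3_cr_median[["medial"]],
               sub3_cr_median_rostral = f$sub3_cr_median[["rostral"]],
               length_mm = f$length_mm, volume_mm3 = f$volume_mm3,
               stringsAsFactors = FALSE)
  }
  out <- rbind(row("left"), row("right"), row("bilateral"))
  out$partial <- x$partial
  out
}
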