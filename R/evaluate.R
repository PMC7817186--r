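# Segmentation-quality metrics: 3D Pearson correlation of volumetric masks
# and the boundary displacement error.

#' 3D Pearson correlation of two binary masks (percent)
#'
#' Pearson correlation of the two binary indicator fields over the full
#' common grid, times 100.
#'
#' @param pred,ref logical 3D arrays of one shape; neither may be constant.
#' @return Correlation in percent.
#' @export
pearson_masks <- function(pred, ref) {
  assert_volume(pred)
  assert_same_shape(pred, ref, "prediction and reference masks")
  a <- as.numeric(pred)
  b <- as.numeric(ref)
  if (sd(a) == 0 || sd(b) == 0)
    stop_istomo("correlation undefined for a constant mask",
                "istomo_degenerate_error")
  100 * cor(a, b)
}

# A boundary voxel is a mask voxel 6-adjacent to an in-grid background
# voxel; the field-of-view walls are not boundaries.
boundary_voxels <- function(mask) {
  mask & binary_dilate(!mask, cross_offsets(1L))
}

#' Boundary displacement error between two masks
#'
#' Boundary voxels are each mask minus its 6-connected erosion. The error
#' is the symmetric mean of nearest-boundary Euclidean distances
#' (pred-to-ref and ref-to-pred, averaged). With anisotropic pitch the nm
#' value uses physical-space distances.
#'
#' @param pred,ref nonempty logical 3D arrays of one shape.
#' @param pitch voxel size in nm.
#' @param direction `"symmetric"` (default), `"pred_to_ref"` or
#'   `"ref_to_pred"` for sensitivity analyses.
#' @return List `(voxels, nm)`.
#' @export
boundary_displacement_error <- function(pred, ref, pitch = 218.5,
                                        direction = c("symmetric",
                                                      "pred_to_ref",
                                                      "ref_to_pred")) {
  direction <- match.arg(direction)
  assert_volume(pred)
  assert_same_shape(pred, ref, "prediction and reference masks")
  if (!any(pred) || !any(ref))
    stop_istomo("both masks must be nonempty", "istomo_empty_error")
  pitch <- expand_pitch(pitch)
  bp <- boundary_voxels(pred)
  br <- boundary_voxels(ref)
  one_way <- function(from, to, spacing) {
    d <- feature_distance(to, spacing = spacing)
    mean(d[from])
  }
  measure <- function(spacing) {
    switch(direction,
      symmetric = (one_way(bp, br, spacing) + one_way(br, bp, spacing)) / 2,
      pred_to_ref = one_way(bp, br, spacing),
      ref_to_pred = one_way(br, bp, spacing))
  }
  list(voxels = measure(c(1, 1, 1)), nm = measure(pitch))
}

#' Aggregate segmentation metrics over a matched dataset
#'
#' @param pred_set,ref_set matched lists of [cell_mask_pair()]s.
#' @param pitch voxel size in nm.
#' @return List with `per_case` (data frame: per-case Pearson for each cell
#'   and BDE) and `summary` (mean, SD, quartiles per metric).
#' @export
evaluate_dataset <- function(pred_set, ref_set, pitch = 218.5) {
  if (length(pred_set) != length(ref_set))
    stop_istomo("prediction and reference lists must be matched",
                "istomo_pairing_error")
  rows <- lapply(seq_along(pred_set), function(i) {
    p <- pred_set[[i]]
    r <- ref_set[[i]]
    bde <- boundary_displacement_error(p$effector | p$target,
                                       r$effector | r$target, pitch)
    data.frame(case = i,
               pearson_effector = pearson_masks(p$effector, r$effector),
               pearson_target = pearson_masks(p$target, r$target),
               bde_voxels = bde$voxels, bde_nm = bde$nm)
  })
  per_case <- do.call(rbind, rows)
  summarize <- function(v)
    c(mean = mean(v), sd = if (length(v) > 1) sd(v) else 0,
      q25 = unname(quantile(v, 0.25)), median = unname(quantile(v, 0.5)),
      q75 = unname(quantile(v, 0.75)))
  summary <- t(vapply(per_case[-1], summarize, numeric(5)))
  list(per_case = per_case, summary = as.data.frame(summary))
}
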