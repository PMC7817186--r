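# From a regressed signed distance map to cell, synapse, surface and
# interior masks.

#' Cell masks from a signed distance map
#'
#' Thresholds the distance map at `threshold_nm` (default 54.5 nm,
#' approximately a quarter of the 218.5 nm voxel pitch): effector where
#' `y * pitch > +threshold`, target where `y * pitch < -threshold`. Each
#' mask is optionally reduced to its largest 26-connected component; the
#' number of removed voxels is attached as attribute `removed`.
#'
#' @param y a `signed_distance_map` (voxel units).
#' @param threshold_nm threshold in nm.
#' @param keep_largest drop all but the largest connected component.
#' @return A [cell_mask_pair()] (attribute `removed`: voxels dropped).
#' @export
masks_from_distmap <- function(y, threshold_nm = 54.5,
                               keep_largest = TRUE) {
  stopifnot(inherits(y, "signed_distance_map"))
  pitch_nm <- mean(y$pitch)
  eff <- y$values * pitch_nm > threshold_nm
  tar <- y$values * pitch_nm < -threshold_nm
  removed <- 0L
  if (keep_largest) {
    if (any(eff)) {
      k <- keep_largest_component(eff)
      eff <- k$mask
      removed <- removed + k$removed
    }
    if (any(tar)) {
      k <- keep_largest_component(tar)
      tar <- k$mask
      removed <- removed + k$removed
    }
  }
  if (!any(eff) && !any(tar))
    warning("empty segmentation: no voxel exceeds the distance threshold")
  out <- cell_mask_pair(eff, tar, pitch = y$pitch)
  attr(out, "removed") <- removed
  out
}

#' Synapse mask by mutual dilation overlap
#'
#' The immunological synapse is the overlap of the two cell masks after
#' dilating each by a Euclidean ball of `dilation_voxels` (default 2
#' voxels, comparable to the 437 nm axial resolution).
#'
#' @param pair a [cell_mask_pair()].
#' @param dilation_voxels ball radius in voxels.
#' @return Logical 3D IS mask.
#' @export
synapse_mask <- function(pair, dilation_voxels = 2L) {
  stopifnot(inherits(pair, "cell_mask_pair"))
  if (dilation_voxels == 0L) return(pair$effector & pair$target)
  se <- ball_offsets(dilation_voxels)
  binary_dilate(pair$effector, se) & binary_dilate(pair$target, se)
}

#' Split a cell mask into surface and interior
#'
#' Interior = erosion by the 6-connected cross of radius `erosion_voxels`
#' (default 1 voxel, 218 nm); surface = mask minus interior. The two parts
#' partition the mask exactly.
#'
#' @param mask nonempty logical 3D array.
#' @param erosion_voxels erosion radius in voxels.
#' @return List `(surface, interior)`.
#' @export
surface_interior <- function(mask, erosion_voxels = 1L) {
  assert_volume(mask)
  if (!any(mask))
    stop_istomo("mask is empty", "istomo_empty_error")
  interior <- binary_erode(mask, cross_offsets(erosion_voxels))
  list(surface = mask & !interior, interior = interior)
}
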