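#' Mean uptake over one atlas region
#'
#' Arithmetic mean of the finite voxels carrying `region_id`. `NaN`/`NA`
#' voxels are excluded; negative voxels (reconstruction artifacts) are
#' retained, with a warning when they exceed 1\% of the region.
#'
#' @param volume A [volume_image()].
#' @param atlas A [label_atlas()] of the same shape.
#' @param region_id Integer region label present in the atlas.
#' @return Mean uptake (scalar).
#' @export
regional_mean <- function(volume, atlas, region_id) {
  check_same_shape(volume, atlas)
  vals <- volume$data[atlas$labels == region_id]
  if (length(vals) == 0) stopf("region %d has no voxels", region_id)
  ok <- is.finite(vals)
  if (!any(ok)) stopf("region %d has no finite voxels", region_id)
  neg <- sum(vals[ok] < 0)
  if (neg > 0.01 * sum(ok))
    warnf("region %d: %.1f%% negative voxels", region_id,
          100 * neg / sum(ok))
  mean(vals[ok])
}

reference_mean <- function(volume, atlas) {
  ref_ids <- atlas$regions$region_id[atlas$regions$is_reference]
  if (!length(ref_ids)) stopf("atlas has no reference region")
  vals <- volume$data[atlas$labels %in% ref_ids]
  vals <- vals[is.finite(vals)]
  if (!length(vals)) stopf("reference region has no finite voxels")
  m <- mean(vals)
  if (m <= 0) stopf("reference mean uptake is not positive (%.4g)", m)
  m
}

#' Regional specific binding ratios
#'
#' Computes, for every region present in the atlas, the specific binding
#' ratio `SBR = mean(target) / mean(reference) - 1`, the semi-quantitative
#' DAT-availability measure. The reference is the union of all atlas
#' regions flagged `is_reference` (the lateral superior occipital cortex in
#' the default atlas); its SBR is 0 by construction. SBR is invariant to
#' global intensity scaling.
#'
#' @inheritParams regional_mean
#' @return An `sbr_table` `data.frame`: `region_id`, `region`, `n_voxels`,
#'   `mean_uptake`, `sbr`.
#' @examples
#' reg <- data.frame(region_id = 1:2, name = c("target", "ref"),
#'                   hemisphere = "left", pathway = "none",
#'                   is_reference = c(FALSE, TRUE),
#'                   is_striatal = FALSE)
#' lab <- array(rep(1:2, each = 4), c(2, 2, 2))
#' vol <- volume_image(array(c(rep(2, 4), rep(1, 4)), c(2, 2, 2)))
#' compute_sbr(vol, label_atlas(lab, reg))  # target SBR = 1
#' @export
compute_sbr <- function(volume, atlas) {
  check_same_shape(volume, atlas)
  ref_m <- reference_mean(volume, atlas)
  present <- sort(setdiff(unique(as.vector(atlas$labels)), 0L))
  reg <- atlas$regions
  rows <- lapply(present, function(id) {
    m <- regional_mean(volume, atlas, id)
    data.frame(region_id = id, region = reg$name[match(id, reg$region_id)],
               n_voxels = sum(atlas$labels == id),
               mean_uptake = m,
               sbr = if (reg$is_reference[match(id, reg$region_id)]) 0
                     else m / ref_m - 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("sbr_table", "data.frame")
  out
}

#' Voxel-wise SBR parametric image
#'
#' Replaces every voxel `v` by `v / mean(reference) - 1`, so the regional
#' mean of the parametric image over region *r* equals that region's SBR
#' from [compute_sbr()] (up to floating point). Spatial metadata is
#' preserved.
#'
#' @inheritParams regional_mean
#' @return A [volume_image()].
#' @export
parametric_sbr_image <- function(volume, atlas) {
  check_same_shape(volume, atlas)
  ref_m <- reference_mean(volume, atlas)
  volume_image(volume$data / ref_m - 1, voxel_size = volume$voxel_size,
               meta = volume$meta)
}
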