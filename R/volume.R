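#' 3-D uptake volume
#'
#' Lightweight container for a 3-D grid of tracer uptake values, the voxel
#' size in millimetres, and any spatial metadata carried opaquely from the
#' source file.
#'
#' @param data Numeric 3-D array of uptake values (arbitrary units).
#' @param voxel_size Numeric length-3 (or scalar, recycled) voxel edge
#'   lengths in mm.
#' @param meta Optional list of opaque metadata (e.g. a NIfTI header).
#' @return An object of class `volume_image`.
#' @examples
#' v <- volume_image(array(1, c(4, 4, 4)), voxel_size = 3)
#' dim(v$data)
#' @export
volume_image <- function(data, voxel_size = c(1, 1, 1), meta = list()) {
  if (!is.array(data) || length(dim(data)) != 3L)
    stopf("`data` must be a 3-D array")
  storage.mode(data) <- "double"
  if (!any(is.finite(data)))
    stopf("volume has no finite voxels")
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  if (length(voxel_size) != 3L || any(!is.finite(voxel_size)) ||
      any(voxel_size <= 0))
    stopf("`voxel_size` must be 3 positive numbers (mm)")
  structure(list(data = data, voxel_size = as.numeric(voxel_size),
                 meta = meta), class = "volume_image")
}

#' @export
print.volume_image <- function(x, ...) {
  cat(sprintf("<volume_image> %s voxels, %s mm\n",
              paste(dim(x$data), collapse = "x"),
              paste(format(x$voxel_size), collapse = "x")))
  invisible(x)
}

#' Integer-labeled region atlas
#'
#' A 3-D integer parcellation (0 = background) paired with a region table
#' describing every label (see [region_table()] for the expected columns).
#'
#' @param labels Integer 3-D array of region ids; 0 is background.
#' @param regions Region table `data.frame`.
#' @param voxel_size Voxel edge lengths in mm.
#' @return An object of class `label_atlas`.
#' @export
label_atlas <- function(labels, regions, voxel_size = c(1, 1, 1)) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stopf("`labels` must be a 3-D array")
  if (any(labels != round(labels), na.rm = TRUE))
    stopf("`labels` must be integer-valued")
  storage.mode(labels) <- "integer"
  validate_region_table(regions)
  present <- setdiff(unique(as.vector(labels)), 0L)
  unknown <- setdiff(present, regions$region_id)
  if (length(unknown))
    stopf("atlas labels not in region table: %s",
          paste(sort(unknown), collapse = ", "))
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  structure(list(labels = labels, regions = regions,
                 voxel_size = as.numeric(voxel_size)), class = "label_atlas")
}

#' @export
print.label_atlas <- function(x, ...) {
  cat(sprintf("<label_atlas> %s voxels, %d regions (%d present)\n",
              paste(dim(x$labels), collapse = "x"), nrow(x$regions),
              length(setdiff(unique(as.vector(x$labels)), 0L))))
  invisible(x)
}

check_same_shape <- function(volume, atlas) {
  if (!identical(dim(volume$data), dim(atlas$labels)))
    stopf("volume (%s) and atlas (%s) shapes differ; no resampling is done",
          paste(dim(volume$data), collapse = "x"),
          paste(dim(atlas$labels), collapse = "x"))
  invisible(TRUE)
}
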