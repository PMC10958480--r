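#' Default phantom geometry
#'
#' Lays the 24 pathway regions out as non-overlapping axis-aligned
#' ellipsoids on a lattice of centers inside the grid, with the occipital
#' reference modeled as a posterior slab. Striatal regions are larger
#' (semi-axes 15 x 13.5 x 12 mm, ~370 voxels at 3 mm) than cortical/limbic
#' ones (10.5 mm spheres, ~180 voxels), so every region clears the
#' >100-voxel cluster rule.
#'
#' @param regions Region table; default [region_table()].
#' @param grid_dim Grid shape in voxels (length 3 or scalar).
#' @param voxel_size Voxel edge length in mm (scalar).
#' @return A `data.frame` with columns `region_id`, `shape`
#'   (`"ellipsoid"`/`"slab"`), `cx`, `cy`, `cz`, `rx`, `ry`, `rz` (mm;
#'   slabs use `cy`/`ry` as center/half-thickness along y and span x, z).
#' @export
default_phantom_geometry <- function(regions = region_table(),
                                     grid_dim = c(64, 64, 64),
                                     voxel_size = 3) {
  if (length(grid_dim) == 1L) grid_dim <- rep(grid_dim, 3)
  ext <- grid_dim * voxel_size
  ids <- regions$region_id[!regions$is_reference]
  if (length(ids) > 24)
    stopf("default geometry supports at most 24 non-reference regions")
  centers <- expand.grid(cx = ext[1] * c(0.16, 0.39, 0.62, 0.86),
                         cy = ext[2] * c(0.16, 0.37, 0.58),
                         cz = ext[3] * c(0.31, 0.68))
  geo <- data.frame(region_id = ids, shape = "ellipsoid",
                    centers[seq_along(ids), ],
                    rx = 10.5, ry = 10.5, rz = 10.5,
                    stringsAsFactors = FALSE)
  striatal <- regions$region_id[regions$is_striatal]
  geo$rx[geo$region_id %in% striatal] <- 15
  geo$ry[geo$region_id %in% striatal] <- 13.5
  geo$rz[geo$region_id %in% striatal] <- 12
  ref_id <- regions$region_id[regions$is_reference][1]
  geo <- rbind(geo, data.frame(
    region_id = ref_id, shape = "slab", cx = ext[1] / 2,
    cy = ext[2] * 0.93, cz = ext[3] / 2,
    rx = Inf, ry = ext[2] * 0.035, rz = Inf, stringsAsFactors = FALSE))
  rownames(geo) <- NULL
  geo
}

#' Phantom generator configuration
#'
#' @param grid_dim Grid shape in voxels; default `c(64, 64, 64)`.
#' @param voxel_size Voxel edge length in mm; default 3.
#' @param geometry Region geometry table; default
#'   [default_phantom_geometry()].
#' @param regions Region table matching the geometry.
#' @param reference_level Uptake level (arbitrary units) of the reference
#'   region and background; default 100.
#' @param smooth_fwhm Gaussian smoothing FWHM in mm applied to the noise-free
#'   signal; default 6.
#' @param noise_sd Additive Gaussian noise SD as a fraction of
#'   `reference_level`; default 0.05.
#' @param seed Integer master seed for the noise stream.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(grid_dim = c(64, 64, 64), voxel_size = 3,
                           geometry = NULL, regions = region_table(),
                           reference_level = 100, smooth_fwhm = 6,
                           noise_sd = 0.05, seed = 1L) {
  if (length(grid_dim) == 1L) grid_dim <- rep(grid_dim, 3)
  if (!is_scalar_number(reference_level) || reference_level <= 0)
    stopf("`reference_level` must be positive")
  if (!is_scalar_number(smooth_fwhm) || smooth_fwhm < 0)
    stopf("`smooth_fwhm` must be >= 0")
  if (!is_scalar_number(noise_sd) || noise_sd < 0)
    stopf("`noise_sd` must be >= 0")
  validate_region_table(regions)
  if (is.null(geometry))
    geometry <- default_phantom_geometry(regions, grid_dim, voxel_size)
  structure(list(grid_dim = as.integer(grid_dim), voxel_size = voxel_size,
                 geometry = geometry, regions = regions,
                 reference_level = reference_level,
                 smooth_fwhm = smooth_fwhm, noise_sd = noise_sd,
                 seed = as.integer(seed)), class = "phantom_config")
}

# Build the (unsmoothed, exact) label atlas implied by a phantom config.
# Errors on overlapping regions or regions extending outside the grid.
build_phantom_atlas <- function(config) {
  gd <- config$grid_dim
  vs <- config$voxel_size
  cx <- (seq_len(gd[1]) - 0.5) * vs
  cy <- (seq_len(gd[2]) - 0.5) * vs
  cz <- (seq_len(gd[3]) - 0.5) * vs
  labels <- array(0L, gd)
  ext <- gd * vs
  for (i in seq_len(nrow(config$geometry))) {
    g <- config$geometry[i, ]
    if (g$shape == "ellipsoid") {
      if (g$cx - g$rx < 0 || g$cx + g$rx > ext[1] ||
          g$cy - g$ry < 0 || g$cy + g$ry > ext[2] ||
          g$cz - g$rz < 0 || g$cz + g$rz > ext[3])
        stopf("region %d extends outside the grid", g$region_id)
      dx2 <- ((cx - g$cx) / g$rx)^2
      dy2 <- ((cy - g$cy) / g$ry)^2
      dz2 <- ((cz - g$cz) / g$rz)^2
      inside <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
    } else if (g$shape == "slab") {
      iny <- abs(cy - g$cy) <= g$ry
      inside <- outer(outer(rep(TRUE, gd[1]), iny, `&`),
                      rep(TRUE, gd[3]), `&`)
    } else stopf("unknown shape '%s'", g$shape)
    if (any(labels[inside] != 0L))
      stopf("region %d overlaps region %d", g$region_id,
            labels[inside][labels[inside] != 0L][1])
    labels[inside] <- as.integer(g$region_id)
  }
  label_atlas(labels, config$regions, voxel_size = rep(vs, 3))
}

# Separable Gaussian smoothing with edge renormalization.
gaussian_smooth <- function(arr, fwhm_mm, voxel_size) {
  if (fwhm_mm <= 0) return(arr)
  if (length(voxel_size) == 1L) voxel_size <- rep(voxel_size, 3)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  d <- dim(arr)
  for (ax in 1:3) {
    s_vox <- sigma / voxel_size[ax]
    half <- max(1L, ceiling(4 * s_vox))
    n <- d[ax]
    idx <- seq_len(n)
    K <- exp(-(outer(idx, idx, `-`))^2 / (2 * s_vox^2))
    K[abs(outer(idx, idx, `-`)) > half] <- 0
    K <- K / rowSums(K)
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(arr, perm), n)
    sm <- K %*% m
    arr <- aperm(array(sm, d[perm]), order(perm))
  }
  arr
}

#' Generate 3-D phantom volumes for a cohort panel
#'
#' For every subject-timepoint row of `cohort`, builds an uptake volume in
#' which voxels of region *r* hold `(SBR_r + 1) * reference_level`, the
#' reference region and background hold `reference_level`, then applies
#' Gaussian smoothing followed by additive Gaussian noise. The shared label
#' atlas is exact and unsmoothed.
#'
#' @param config A [phantom_config()].
#' @param cohort An `sbr_panel`; every ROI column must have geometry (ROI
#'   names are matched to region-table names).
#' @return A list with elements `atlas` (a [label_atlas()]) and `volumes`
#'   (named list of [volume_image()], names `subject-id.timepoint`), plus
#'   `panel_index` (data.frame mapping volume names to panel rows).
#' @export
generate_phantom_images <- function(config, cohort) {
  if (!inherits(config, "phantom_config")) stopf("`config` must be a phantom_config")
  atlas <- build_phantom_atlas(config)
  rois <- roi_names(cohort)
  reg <- config$regions
  roi_ids <- reg$region_id[match(rois, reg$name)]
  if (anyNA(roi_ids))
    stopf("panel ROI(s) missing from region table: %s",
          paste(rois[is.na(roi_ids)], collapse = ", "))
  in_geom <- roi_ids %in% config$geometry$region_id
  if (!all(in_geom))
    stopf("no geometry for ROI(s): %s", paste(rois[!in_geom], collapse = ", "))
  masks <- lapply(roi_ids, function(id) which(atlas$labels == id))
  empty <- lengths(masks) == 0
  if (any(empty))
    stopf("region(s) rasterize to zero voxels: %s",
          paste(rois[empty], collapse = ", "))
  ref <- config$reference_level
  vols <- vector("list", nrow(cohort))
  names(vols) <- paste0(cohort$subject_id, ".", cohort$timepoint)
  for (i in seq_len(nrow(cohort))) {
    vol <- array(ref, config$grid_dim)
    for (j in seq_along(rois))
      vol[masks[[j]]] <- (cohort[[rois[j]]][i] + 1) * ref
    vol <- gaussian_smooth(vol, config$smooth_fwhm, config$voxel_size)
    if (config$noise_sd > 0) {
      set.seed(derive_seed(config$seed, paste0("noise:", names(vols)[i])))
      vol <- vol + stats::rnorm(length(vol), 0, config$noise_sd * ref)
    }
    vols[[i]] <- volume_image(vol, voxel_size = rep(config$voxel_size, 3))
  }
  list(atlas = atlas, volumes = vols,
       panel_index = data.frame(volume = names(vols),
                                subject_id = cohort$subject_id,
                                timepoint = cohort$timepoint,
                                group = cohort$group,
                                stringsAsFactors = FALSE))
}
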