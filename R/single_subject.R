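#' Single-case voxel-wise t-map against a control sample
#'
#' Tests one scan for relative dopaminergic depletion against a set of
#' control scans with the Crawford-Howell single-case t-test,
#' `t = (x - mean_HC) / (s_HC * sqrt(1 + 1/n_HC))`, `df = n_HC - 1` — the
#' two-sample pooled-variance t with one observation in group 1. Inputs
#' should be intensity-normalized parametric images ([parametric_sbr_image()]).
#'
#' An SPM-like implicit analysis mask restricts testing to voxels whose
#' control mean exceeds `mask_fraction` of the global control mean; outside
#' the mask (and where the control variance is zero) `t` and `p` are `NA`.
#'
#' @param subject A [volume_image()].
#' @param controls List of at least 3 control [volume_image()]s, all the
#'   same shape.
#' @param direction `"less"` (default: one-sided depletion, subject below
#'   controls) or `"two.sided"`.
#' @param mask_fraction Implicit-mask threshold as a fraction of the global
#'   control mean; `0` disables masking. Default 0.1.
#' @return A `stat_map`: list with 3-D arrays `t` and `p`, scalar `df`,
#'   `direction`, logical `mask`, and `voxel_size`.
#' @export
single_case_t_map <- function(subject, controls, direction = c("less", "two.sided"),
                              mask_fraction = 0.1) {
  direction <- match.arg(direction)
  if (length(controls) < 3) stopf("need at least 3 control volumes")
  d <- dim(subject$data)
  for (ctl in controls)
    if (!identical(dim(ctl$data), d)) stopf("control/subject shapes differ")
  n <- length(controls)
  C <- vapply(controls, function(v) as.vector(v$data), numeric(prod(d)))
  m <- rowMeans(C)
  s <- sqrt(rowSums((C - m)^2) / (n - 1))
  mask <- rep(TRUE, length(m))
  if (mask_fraction > 0) mask <- m > mask_fraction * mean(m)
  mask <- mask & s > 0
  tval <- rep(NA_real_, length(m))
  tval[mask] <- (as.vector(subject$data)[mask] - m[mask]) /
    (s[mask] * sqrt(1 + 1 / n))
  df <- n - 1
  p <- rep(NA_real_, length(m))
  p[mask] <- if (direction == "less") stats::pt(tval[mask], df)
             else 2 * stats::pt(-abs(tval[mask]), df)
  structure(list(t = array(tval, d), p = array(p, d), df = df,
                 direction = direction, mask = array(mask, d),
                 voxel_size = subject$voxel_size), class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("<stat_map> %s voxels, df = %.1f, direction = %s\n",
              paste(dim(x$t), collapse = "x"), x$df, x$direction))
  invisible(x)
}

neighbor_offsets <- function(connectivity) {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  ord <- abs(g$dx) + abs(g$dy) + abs(g$dz)
  switch(as.character(connectivity),
         "6" = g[ord == 1, ],
         "18" = g[ord <= 2, ],
         "26" = g,
         stopf("`connectivity` must be 6, 18 or 26"))
}

# Connected components of a logical 3-D array; returns an integer array of
# component labels (0 = background), labels ordered by decreasing size.
label_components <- function(supra, connectivity = 26) {
  d <- dim(supra)
  idx <- which(supra)
  labels <- array(0L, d)
  if (!length(idx)) return(labels)
  pos <- arrayInd(idx, d)
  off <- neighbor_offsets(connectivity)
  half <- off[off$dx > 0 | (off$dx == 0 & off$dy > 0) |
              (off$dx == 0 & off$dy == 0 & off$dz > 0), ]
  edges <- list()
  for (k in seq_len(nrow(half))) {
    nx <- pos[, 1] + half$dx[k]
    ny <- pos[, 2] + half$dy[k]
    nz <- pos[, 3] + half$dz[k]
    ok <- nx >= 1 & nx <= d[1] & ny >= 1 & ny <= d[2] & nz >= 1 & nz <= d[3]
    nidx <- (nz[ok] - 1L) * d[1] * d[2] + (ny[ok] - 1L) * d[1] + nx[ok]
    j <- match(nidx, idx)
    keep <- !is.na(j)
    if (any(keep))
      edges[[length(edges) + 1L]] <- cbind(which(ok)[keep], j[keep])
  }
  if (length(edges)) {
    el <- do.call(rbind, edges)
    gr <- igraph::graph_from_edgelist(el, directed = FALSE)
    gr <- igraph::add_vertices(gr, max(0L, length(idx) - igraph::vcount(gr)))
    comp <- igraph::components(gr)$membership
  } else comp <- seq_along(idx)
  sizes <- tabulate(comp)
  relabel <- integer(length(sizes))
  relabel[order(sizes, decreasing = TRUE)] <- seq_along(sizes)
  labels[idx] <- relabel[comp]
  labels
}

#' Cluster-extent thresholding of a statistical map
#'
#' Groups voxels with `p < p_threshold` into connected components and
#' retains components strictly larger than `min_extent` voxels.
#'
#' @param map A `stat_map`.
#' @param p_threshold Voxel-level p threshold; default 0.05.
#' @param min_extent Minimum cluster extent; clusters must exceed it
#'   strictly ("more than `min_extent` voxels"). Default 100.
#' @param connectivity Neighborhood: 6, 18 or 26 (default 26).
#' @return A `cluster_set`: list with `labels` (integer 3-D array, retained
#'   clusters numbered 1..K by decreasing size) and `table` (`cluster_id`,
#'   `size`, `peak_t`, `peak_x`, `peak_y`, `peak_z`; 1-based voxel indices).
#' @export
threshold_clusters <- function(map, p_threshold = 0.05, min_extent = 100,
                               connectivity = 26) {
  if (!is_scalar_number(p_threshold) || p_threshold <= 0 || p_threshold >= 1)
    stopf("`p_threshold` must lie in (0, 1)")
  if (min_extent < 1) stopf("`min_extent` must be >= 1")
  supra <- !is.na(map$p) & map$p < p_threshold
  comp <- label_components(supra, connectivity)
  sizes <- tabulate(comp[comp > 0L])
  keep <- which(sizes > min_extent)
  labels <- array(0L, dim(comp))
  tab <- data.frame(cluster_id = integer(), size = integer(),
                    peak_t = numeric(), peak_x = integer(),
                    peak_y = integer(), peak_z = integer())
  for (new_id in seq_along(keep)) {
    vox <- which(comp == keep[new_id])
    labels[vox] <- new_id
    tv <- map$t[vox]
    pk <- if (map$direction == "less") vox[which.min(tv)]
          else vox[which.max(abs(tv))]
    pk3 <- arrayInd(pk, dim(comp))
    tab <- rbind(tab, data.frame(
      cluster_id = new_id, size = length(vox),
      peak_t = map$t[pk], peak_x = pk3[1], peak_y = pk3[2], peak_z = pk3[3]))
  }
  structure(list(labels = labels, table = tab,
                 p_threshold = p_threshold, min_extent = min_extent,
                 connectivity = connectivity), class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> %d cluster(s) > %d voxels at p < %g\n",
              nrow(x$table), x$min_extent, x$p_threshold))
  if (nrow(x$table)) print(x$table)
  invisible(x)
}

#' Classify a screen as showing striatal dopaminergic depletion
#'
#' A scan is positive when at least one retained cluster overlaps a
#' striatal atlas region by at least one voxel.
#'
#' @param clusters A `cluster_set` from [threshold_clusters()].
#' @param atlas A [label_atlas()] with `is_striatal` flags.
#' @return A `depletion_screen`: list with logical `positive` and a
#'   per-cluster `report` (`cluster_id`, `size`, `peak_t`,
#'   `striatal_overlap_voxels`).
#' @export
classify_depletion <- function(clusters, atlas) {
  if (!any(atlas$regions$is_striatal))
    stopf("atlas flags no striatal regions")
  if (!identical(dim(clusters$labels), dim(atlas$labels)))
    stopf("cluster map and atlas shapes differ")
  striatal_ids <- atlas$regions$region_id[atlas$regions$is_striatal]
  striatal <- atlas$labels %in% striatal_ids
  tab <- clusters$table
  overlap <- vapply(tab$cluster_id, function(id)
    sum(striatal[clusters$labels == id]), integer(1))
  report <- cbind(tab[, c("cluster_id", "size", "peak_t")],
                  striatal_overlap_voxels = overlap)
  structure(list(positive = any(overlap >= 1), report = report),
            class = "depletion_screen")
}

#' @export
print.depletion_screen <- function(x, ...) {
  cat(sprintf("<depletion_screen> %s\n",
              if (x$positive) "POSITIVE: significant striatal depletion"
              else "negative: no significant striatal depletion"))
  if (nrow(x$report)) print(x$report)
  invisible(x)
}
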