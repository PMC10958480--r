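#' Regional patient-vs-control alteration z-scores
#'
#' For each ROI, `z = (mean_patient - mean_control) / sd_control` — the
#' control-SD standardized mean difference used by JuSpace-style spatial
#' correlation analyses. Regions with zero control SD are dropped with a
#' warning.
#'
#' @param panel An `sbr_panel`.
#' @param patient_group,control_group Group labels (each with n >= 3 at
#'   `timepoint`).
#' @param rois ROI columns to use; default: all panel ROIs.
#' @param timepoint Panel timepoint; default `"baseline"`.
#' @return Named numeric vector of z-scores.
#' @export
region_zscores <- function(panel, patient_group, control_group,
                           rois = NULL, timepoint = "baseline") {
  rois <- rois %||% roi_names(panel)
  df <- as.data.frame(panel)
  df <- df[df$timepoint == timepoint, ]
  pat <- df[df$group == patient_group, rois, drop = FALSE]
  ctl <- df[df$group == control_group, rois, drop = FALSE]
  if (nrow(pat) < 3 || nrow(ctl) < 3)
    stopf("both groups need n >= 3 (got %d and %d)", nrow(pat), nrow(ctl))
  m_p <- colMeans(pat)
  m_c <- colMeans(ctl)
  s_c <- apply(ctl, 2, stats::sd)
  if (any(s_c == 0)) {
    warnf("dropping region(s) with zero control SD: %s",
          paste(rois[s_c == 0], collapse = ", "))
    keep <- s_c > 0
    m_p <- m_p[keep]; m_c <- m_c[keep]; s_c <- s_c[keep]
  }
  (m_p - m_c) / s_c
}

#' Read a region-level neurotransmitter template map
#'
#' @param path TSV file with columns `region` and `value`.
#' @return Named numeric vector of template values.
#' @export
read_template <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("region", "value") %in% names(df)))
    stopf("%s: template TSV needs columns 'region' and 'value'", path)
  v <- suppressWarnings(as.numeric(df$value))
  if (anyNA(v)) stopf("%s: non-numeric template value at row %d", path,
                      which(is.na(v))[1])
  stats::setNames(v, df$region)
}

#' Spearman correlation between a z-score vector and a template map
#'
#' Rank correlation (average ranks for ties) over the regions shared by
#' both vectors; invariant to any strictly monotone transform of the
#' template.
#'
#' @param z Named numeric vector of regional z-scores.
#' @param template Named numeric vector of template values.
#' @return Spearman rho.
#' @export
spatial_spearman <- function(z, template) {
  shared <- intersect(names(z), names(template))
  if (length(shared) < 5)
    stopf("need at least 5 shared regions (got %d)", length(shared))
  tv <- template[shared]
  if (length(unique(tv)) < 2) stopf("template is constant over shared regions")
  stats::cor(z[shared], tv, method = "spearman")
}

#' Permutation test of template spatial correlations
#'
#' Computes the observed Spearman correlation between patient-vs-control
#' regional z-scores and each template, then builds a null by permuting the
#' group labels of the pooled subjects and recomputing the z-vector and
#' correlation. Two-sided on `|rho|`:
#' `p = (1 + #\{|rho*| >= |rho_obs|\}) / (n_perm + 1)`; Benjamini-Hochberg
#' adjustment across templates.
#'
#' @inheritParams region_zscores
#' @param templates Named list of template vectors (see [read_template()]).
#' @param n_perm Number of permutations (>= 100); if fewer distinct label
#'   assignments exist they are all used, with a warning.
#' @param seed Integer seed.
#' @return List of `spatial_corr_result` (one per template): `template`,
#'   `z` (observed z-vector), `rho`, `p_perm`, `p_adj`, `n_regions`,
#'   `n_perm`, `seed`.
#' @export
template_permutation_test <- function(panel, patient_group, control_group,
                                      templates, n_perm = 1000, seed = 1L,
                                      rois = NULL, timepoint = "baseline") {
  if (n_perm < 100) stopf("`n_perm` must be >= 100")
  if (is.null(names(templates)) || any(names(templates) == ""))
    stopf("`templates` must be a named list")
  rois <- rois %||% roi_names(panel)
  df <- as.data.frame(panel)
  df <- df[df$timepoint == timepoint & df$group %in%
             c(patient_group, control_group), ]
  n_pat <- sum(df$group == patient_group)
  n_tot <- nrow(df)
  z_obs <- region_zscores(panel, patient_group, control_group, rois,
                          timepoint)
  rho_obs <- vapply(templates, function(tm) spatial_spearman(z_obs, tm),
                    numeric(1))
  X <- as.matrix(df[rois])
  zscore_of <- function(pat_idx) {
    P <- X[pat_idx, , drop = FALSE]
    C <- X[-pat_idx, , drop = FALSE]
    s <- apply(C, 2, stats::sd)
    keep <- s > 0
    ((colMeans(P) - colMeans(C)) / s)[keep]
  }
  n_distinct <- choose(n_tot, n_pat)
  if (n_distinct <= n_perm) {
    combos <- utils::combn(n_tot, n_pat)
    warnf("only %d distinct group assignments exist; using all of them",
          ncol(combos))
    perm_idx <- lapply(seq_len(ncol(combos)), function(j) combos[, j])
  } else {
    set.seed(derive_seed(seed, "template_perm"))
    perm_idx <- lapply(seq_len(n_perm), function(b) sample.int(n_tot, n_pat))
  }
  rho_null <- matrix(NA_real_, length(perm_idx), length(templates))
  for (b in seq_along(perm_idx)) {
    zb <- zscore_of(perm_idx[[b]])
    rho_null[b, ] <- vapply(templates, function(tm)
      suppressWarnings(spatial_spearman(zb, tm)), numeric(1))
  }
  np <- length(perm_idx)
  p_perm <- vapply(seq_along(templates), function(j)
    (1 + sum(abs(rho_null[, j]) >= abs(rho_obs[j]))) / (np + 1), numeric(1))
  p_adj <- stats::p.adjust(p_perm, "BH")
  out <- lapply(seq_along(templates), function(j) {
    structure(list(template = names(templates)[j], z = z_obs,
                   rho = rho_obs[j], p_perm = p_perm[j], p_adj = p_adj[j],
                   n_regions = length(intersect(names(z_obs),
                                                names(templates[[j]]))),
                   n_perm = np, seed = seed),
              class = "spatial_corr_result")
  })
  names(out) <- names(templates)
  out
}

#' @export
print.spatial_corr_result <- function(x, ...) {
  cat(sprintf("<spatial_corr_result> %s: rho = %.3f, p_perm = %.4g, p_adj = %.4g (%d regions, %d perms)\n",
              x$template, x$rho, x$p_perm, x$p_adj, x$n_regions, x$n_perm))
  invisible(x)
}
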