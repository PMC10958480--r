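#' Convert a planted partial-correlation structure to a correlation matrix
#'
#' Builds the precision matrix with unit diagonal and off-diagonal entries
#' `-pc[i, j]`, inverts it, and rescales to a correlation matrix. If the
#' implied precision matrix is not positive definite it is repaired by
#' adding the smallest `eps * I` with `eps` in `1e-8 * 2^k` that pushes the
#' minimum eigenvalue above `1e-10`, with a warning.
#'
#' Because partial correlations are invariant to variable scaling, the
#' partial-correlation matrix implied by the returned correlation matrix is
#' exactly `pc` (up to the repair perturbation).
#'
#' @param pc Symmetric matrix of target partial correlations, entries in
#'   (-1, 1); the diagonal is ignored.
#' @return A positive-definite correlation matrix.
#' @examples
#' pc <- diag(3); pc[1, 2] <- pc[2, 1] <- 0.5
#' R <- pcor_to_cor(pc)
#' @export
pcor_to_cor <- function(pc) {
  pc <- as.matrix(pc)
  if (nrow(pc) != ncol(pc) || !isTRUE(all.equal(pc, t(pc), tolerance = 1e-8)))
    stopf("partial-correlation structure must be a symmetric matrix")
  off <- pc[row(pc) != col(pc)]
  if (any(abs(off) >= 1)) stopf("partial correlations must lie in (-1, 1)")
  P <- -pc
  diag(P) <- 1
  ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    eps <- 1e-8
    repeat {
      if (min(ev) + eps > 1e-10) break
      eps <- eps * 2
      if (eps > 1e8)
        stopf("partial-correlation structure is not repairable to positive definite")
    }
    warnf("precision matrix not positive definite; repaired with eps = %g", eps)
    diag(P) <- diag(P) + eps
  }
  stats::cov2cor(solve(P))
}

#' Cohort generator configuration
#'
#' Describes the groups, regional SBR distributions, planted
#' partial-correlation structure, two-timepoint trajectories and covariates
#' of a synthetic cohort. Each group is a list with elements `label`,
#' `n` (>= 4), `mean` and `sd` (named numeric vectors over the same ROIs),
#' optional `followup_mean`/`followup_sd` (defaults: baseline values),
#' optional `pcor` (symmetric matrix over the ROIs; default: independence),
#' and covariate parameters `age_mean`, `age_sd`, `female_prop`,
#' `updrs3_mean`, `updrs3_sd`.
#'
#' @param groups List of group specifications (see Details).
#' @param rho_t Within-subject baseline/follow-up correlation in \[0, 1).
#' @param seed Integer master seed; every draw derives from it.
#' @return An object of class `cohort_config`.
#' @seealso [default_cohort_config()] for the published-parameter defaults.
#' @export
cohort_config <- function(groups, rho_t = 0.7, seed = 1L) {
  if (!length(groups)) stopf("at least one group is required")
  if (!is_scalar_number(rho_t) || rho_t < 0 || rho_t >= 1)
    stopf("`rho_t` must lie in [0, 1)")
  rois <- names(groups[[1]]$mean)
  for (g in groups) {
    if (is.null(g$label) || is.null(g$n) || is.null(g$mean) || is.null(g$sd))
      stopf("each group needs `label`, `n`, `mean`, `sd`")
    if (g$n < 4) stopf("group '%s': n must be >= 4", g$label)
    if (!identical(names(g$mean), rois))
      stopf("group '%s': ROI names differ from first group", g$label)
    if (!identical(names(g$sd), rois))
      stopf("group '%s': `sd` names must match `mean`", g$label)
    if (any(g$sd <= 0)) stopf("group '%s': SDs must be positive", g$label)
    for (fld in c("followup_mean", "followup_sd"))
      if (!is.null(g[[fld]]) && !identical(names(g[[fld]]), rois))
        stopf("group '%s': `%s` names must match `mean`", g$label, fld)
    if (!is.null(g$pcor)) {
      pcm <- as.matrix(g$pcor)
      if (!all(dim(pcm) == length(rois)))
        stopf("group '%s': `pcor` must be %d x %d", g$label,
              length(rois), length(rois))
      offd <- pcm[row(pcm) != col(pcm)]
      if (any(abs(offd) >= 1))
        stopf("group '%s': partial correlations must lie in (-1, 1)", g$label)
    }
  }
  if (anyDuplicated(vapply(groups, `[[`, "", "label")))
    stopf("group labels must be unique")
  structure(list(groups = groups, rho_t = rho_t, rois = rois,
                 seed = as.integer(seed)), class = "cohort_config")
}

#' Default cohort configuration from published regional parameters
#'
#' Parameterizes the generator with the published PD and SWEDD regional SBR
#' means/SDs at baseline and two-year follow-up
#' ([sbr_reference_parameters()]). Healthy controls (HC), whose regional
#' values are not published, follow the package convention: SWEDD baseline
#' means +10\%, SWEDD SDs, flat trajectory. Covariates: age 63.4 (8.2)
#' years for all groups, 37\% female; UPDRS-III 18.5 (6.87) for PD,
#' 15.1 (9.11) for SWEDD, 1.0 (1.0) for HC (synthetic convention).
#'
#' @param n Named integer vector of group sizes; defaults to the study's
#'   analyzed sample sizes (PD 49, SWEDD 36, HC 49).
#' @param pcor Optional named list of per-group partial-correlation matrices
#'   over the 24 ROIs.
#' @param rho_t Within-subject baseline/follow-up correlation; default 0.7.
#' @param seed Integer master seed.
#' @return A [cohort_config()].
#' @examples
#' cfg <- default_cohort_config(n = c(PD = 10, SWEDD = 10, HC = 10))
#' panel <- generate_sbr_cohort(cfg)
#' @export
default_cohort_config <- function(n = c(PD = 49, SWEDD = 36, HC = 49),
                                  pcor = NULL, rho_t = 0.7, seed = 1L) {
  ref <- sbr_reference_parameters()
  rois <- ref$region
  nv <- function(x) stats::setNames(x, rois)
  grp <- function(label, bl_m, bl_s, fu_m, fu_s, updrs_m, updrs_s) {
    list(label = label, n = unname(n[[label]]),
         mean = nv(bl_m), sd = nv(bl_s),
         followup_mean = nv(fu_m), followup_sd = nv(fu_s),
         pcor = pcor[[label]],
         age_mean = 63.4, age_sd = 8.2, female_prop = 0.37,
         updrs3_mean = updrs_m, updrs3_sd = updrs_s)
  }
  groups <- list()
  if ("PD" %in% names(n))
    groups <- c(groups, list(grp("PD", ref$pd_bl_mean, ref$pd_bl_sd,
                                 ref$pd_fu_mean, ref$pd_fu_sd, 18.5, 6.87)))
  if ("SWEDD" %in% names(n))
    groups <- c(groups, list(grp("SWEDD", ref$swedd_bl_mean, ref$swedd_bl_sd,
                                 ref$swedd_fu_mean, ref$swedd_fu_sd,
                                 15.1, 9.11)))
  if ("HC" %in% names(n))
    groups <- c(groups, list(grp("HC", 1.1 * ref$swedd_bl_mean,
                                 ref$swedd_bl_sd, 1.1 * ref$swedd_bl_mean,
                                 ref$swedd_bl_sd, 1.0, 1.0)))
  if (!length(groups)) stopf("`n` must name at least one of PD, SWEDD, HC")
  cohort_config(groups, rho_t = rho_t, seed = seed)
}

#' Generate a synthetic subject-by-ROI SBR panel
#'
#' Draws, per group, baseline and follow-up regional SBR vectors from a
#' joint multivariate normal. Across ROIs the correlation matrix is the one
#' implied by the group's planted partial-correlation structure
#' ([pcor_to_cor()]; identity if none); across timepoints each ROI has
#' within-subject correlation `rho_t`. The joint covariance is
#' `D %*% (T \%x\% R) %*% D` with `T = [[1, rho_t], [rho_t, 1]]`, which is
#' positive definite by construction. Covariates (age, sex, UPDRS-III) are
#' attached per subject; age advances 2 years at follow-up.
#'
#' @param config A [cohort_config()].
#' @return An `sbr_panel`: a `data.frame` with one row per
#'   subject-timepoint, metadata columns `subject_id`, `group`, `timepoint`
#'   (`"baseline"`/`"followup"`), `age`, `sex`, `updrs3`, and one column
#'   per ROI holding SBR values.
#' @export
generate_sbr_cohort <- function(config) {
  if (!inherits(config, "cohort_config")) stopf("`config` must be a cohort_config")
  rois <- config$rois
  p <- length(rois)
  Tm <- matrix(c(1, config$rho_t, config$rho_t, 1), 2, 2)
  out <- lapply(config$groups, function(g) {
    R <- if (is.null(g$pcor)) diag(p) else pcor_to_cor(g$pcor)
    fu_m <- g$followup_mean %||% g$mean
    fu_s <- g$followup_sd %||% g$sd
    D <- diag(c(g$sd, fu_s))
    sigma <- D %*% (Tm %x% R) %*% D
    set.seed(derive_seed(config$seed, paste0("sbr:", g$label)))
    draws <- rmvn(g$n, c(g$mean, fu_m), sigma)
    age <- stats::rnorm(g$n, g$age_mean %||% 63.4, g$age_sd %||% 8.2)
    sex <- ifelse(stats::runif(g$n) < (g$female_prop %||% 0.37), "F", "M")
    updrs3 <- stats::rnorm(g$n, g$updrs3_mean %||% 0, g$updrs3_sd %||% 1)
    id <- sprintf("%s_%03d", g$label, seq_len(g$n))
    base <- data.frame(subject_id = id, group = g$label,
                       timepoint = "baseline", age = age, sex = sex,
                       updrs3 = updrs3, stringsAsFactors = FALSE)
    fu <- base
    fu$timepoint <- "followup"
    fu$age <- fu$age + 2
    bl_block <- as.data.frame(draws[, seq_len(p), drop = FALSE])
    fu_block <- as.data.frame(draws[, p + seq_len(p), drop = FALSE])
    names(bl_block) <- names(fu_block) <- rois
    rbind(cbind(base, bl_block), cbind(fu, fu_block))
  })
  panel <- do.call(rbind, out)
  rownames(panel) <- NULL
  as_sbr_panel(panel, rois)
}

as_sbr_panel <- function(df, rois) {
  meta <- c("subject_id", "group", "timepoint", "age", "sex", "updrs3")
  miss <- setdiff(c(meta, rois), names(df))
  if (length(miss)) stopf("panel missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(df[c("subject_id", "timepoint")]))
    stopf("duplicated (subject, timepoint) rows in panel")
  for (r in rois) {
    bad <- !is.finite(df[[r]])
    if (any(bad))
      stopf("non-finite SBR in column '%s' (first at row %d)", r,
            which(bad)[1])
  }
  structure(df, rois = rois, class = c("sbr_panel", "data.frame"))
}

#' @export
print.sbr_panel <- function(x, ...) {
  cat(sprintf("<sbr_panel> %d rows (%d subjects), %d ROIs, groups: %s\n",
              nrow(x), length(unique(x$subject_id)), length(attr(x, "rois")),
              paste(unique(x$group), collapse = ", ")))
  invisible(x)
}

#' ROI column names of an SBR panel
#' @param panel An `sbr_panel`.
#' @return Character vector of ROI column names.
#' @export
roi_names <- function(panel) {
  r <- attr(panel, "rois")
  if (is.null(r))
    r <- setdiff(names(panel), c("subject_id", "group", "timepoint",
                                 "age", "sex", "updrs3"))
  r
}

#' Write / read an SBR panel as TSV
#'
#' The round trip is lossless: numeric columns are serialized with 17
#' significant digits.
#'
#' @param panel An `sbr_panel`.
#' @param path TSV file path (one row per subject-timepoint).
#' @return `write_cohort`: `path` invisibly; `read_cohort`: an `sbr_panel`.
#' @export
write_cohort <- function(panel, path) {
  df <- as.data.frame(panel)
  for (nm in names(df))
    if (is.numeric(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  meta <- c("subject_id", "group", "timepoint", "age", "sex", "updrs3")
  miss <- setdiff(meta, names(df))
  if (length(miss))
    stopf("%s: missing required column(s): %s", path,
          paste(miss, collapse = ", "))
  rois <- setdiff(names(df), meta)
  if (!length(rois)) stopf("%s: no ROI columns found", path)
  for (nm in c("age", "updrs3", rois)) {
    v <- suppressWarnings(as.numeric(df[[nm]]))
    bad <- is.na(v) & !(df[[nm]] %in% c("NA", ""))
    if (any(bad))
      stopf("%s: non-numeric value '%s' at row %d, column '%s'",
            path, df[[nm]][which(bad)[1]], which(bad)[1], nm)
    df[[nm]] <- v
  }
  as_sbr_panel(df, rois)
}
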