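#' Build a voxel-wise GLM design
#'
#' Intercept, a group indicator (second factor level coded 1), and optional
#' nuisance covariates. The default contrast tests the group effect.
#'
#' @param group Factor or character vector of group labels (2 levels).
#' @param covariates Optional `data.frame` of numeric/factor nuisance
#'   covariates (e.g. age, sex, UPDRS-III), same length as `group`.
#' @return List with `X` (design matrix), `contrast` (vector picking the
#'   group column) and `nuisance` (column indices of intercept+covariates).
#' @export
design_matrix <- function(group, covariates = NULL) {
  group <- factor(group)
  if (nlevels(group) != 2) stopf("`group` must have exactly 2 levels")
  df <- data.frame(group = group)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(group))
      stopf("`covariates` rows must match `group` length")
    df <- cbind(df, covariates)
  }
  X <- stats::model.matrix(~ ., df)
  contrast <- as.numeric(colnames(X) == paste0("group", levels(group)[2]))
  list(X = X, contrast = contrast, nuisance = which(contrast == 0))
}

stack_volumes <- function(volumes) {
  d <- dim(volumes[[1]]$data)
  for (v in volumes)
    if (!identical(dim(v$data), d)) stopf("volume shapes differ")
  list(Y = t(vapply(volumes, function(v) as.vector(v$data),
                    numeric(prod(d)))), dim = d,
       voxel_size = volumes[[1]]$voxel_size)
}

# Core voxel-wise OLS: Y is n x V, X n x k; returns t for c'beta per voxel.
ols_t_map <- function(Y, X, contrast) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[-seq_len(qrX$rank)] %||% "unknown"
    stopf("design matrix is rank deficient (collinear: %s)",
          paste(dropped, collapse = ", "))
  }
  XtXi <- chol2inv(qr.R(qrX))
  B <- XtXi %*% crossprod(X, Y)            # k x V
  res <- Y - X %*% B
  df <- nrow(X) - qrX$rank
  sigma2 <- colSums(res^2) / df
  cvar <- drop(t(contrast) %*% XtXi %*% contrast)
  tval <- drop(crossprod(contrast, B)) / sqrt(sigma2 * cvar)
  list(t = tval, df = df)
}

#' Voxel-wise GLM contrast map
#'
#' Ordinary-least-squares fit per voxel with a t statistic for the given
#' contrast; with a two-group design and no covariates this is exactly the
#' pooled-variance two-sample t-test.
#'
#' @param volumes List of [volume_image()]s, one per subject, aligned with
#'   the design rows.
#' @param X Design matrix (`n x k`, full column rank).
#' @param contrast Numeric contrast vector of length `k`, not all zero.
#' @param alternative `"greater"` (default, SPM-style one-sided t
#'   contrast), `"less"`, or `"two.sided"`.
#' @return A `stat_map` (see [single_case_t_map()]).
#' @export
glm_contrast_map <- function(volumes, X, contrast,
                             alternative = c("greater", "less", "two.sided")) {
  alternative <- match.arg(alternative)
  X <- as.matrix(X)
  if (length(contrast) != ncol(X)) stopf("contrast length != design columns")
  if (all(contrast == 0)) stopf("contrast vector is all zeros")
  if (nrow(X) != length(volumes)) stopf("design rows != number of volumes")
  sv <- stack_volumes(volumes)
  fit <- ols_t_map(sv$Y, X, contrast)
  p <- switch(alternative,
              greater = stats::pt(fit$t, fit$df, lower.tail = FALSE),
              less = stats::pt(fit$t, fit$df),
              two.sided = 2 * stats::pt(-abs(fit$t), fit$df))
  structure(list(t = array(fit$t, sv$dim), p = array(p, sv$dim),
                 df = fit$df, direction = alternative,
                 mask = array(TRUE, sv$dim), voxel_size = sv$voxel_size),
            class = "stat_map")
}

all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Permutation-based cluster-level FWE correction
#'
#' Forms clusters in the observed contrast map at voxel `p <
#' cluster_forming_p`, then builds the null distribution of the maximum
#' cluster extent by Freedman-Lane permutation: residuals of the reduced
#' (nuisance-only) model are permuted, reduced-model fitted values are added
#' back, and the full model is refit. The cluster-level FWE-corrected
#' p-value is `(1 + #\{max_extent* >= extent\}) / (n_perm + 1)`.
#'
#' @inheritParams glm_contrast_map
#' @param n_perm Number of permutations (>= 100). If fewer distinct
#'   permutations exist, all of them are used, with a warning.
#' @param cluster_forming_p Voxel-level cluster-forming threshold;
#'   default 0.005.
#' @param connectivity Cluster connectivity (6/18/26); default 26.
#' @param seed Integer seed for the permutation stream.
#' @return A `cluster_fwe_result`: list with `stat_map`, `clusters`
#'   (`cluster_id`, `size`, `peak_t`, `fwe_p`), `labels` array,
#'   `max_null_extent` vector, `n_perm`, `seed`.
#' @export
cluster_fwe <- function(volumes, X, contrast, n_perm = 1000,
                        cluster_forming_p = 0.005,
                        alternative = c("greater", "less", "two.sided"),
                        connectivity = 26, seed = 1L) {
  alternative <- match.arg(alternative)
  if (n_perm < 100) stopf("`n_perm` must be >= 100")
  X <- as.matrix(X)
  n <- nrow(X)
  sv <- stack_volumes(volumes)
  obs <- glm_contrast_map(volumes, X, contrast, alternative)
  supra_p <- function(map) !is.na(map$p) & map$p < cluster_forming_p
  comp <- label_components(array(supra_p(obs), sv$dim), connectivity)
  sizes <- tabulate(comp[comp > 0L], nbins = max(comp))

  # Freedman-Lane: permute reduced-model residuals
  nuis <- which(contrast == 0)
  Z <- X[, nuis, drop = FALSE]
  if (!ncol(Z)) Z <- matrix(1, n, 1)
  Hz <- Z %*% solve(crossprod(Z), t(Z))
  Yred <- Hz %*% sv$Y
  Rz <- sv$Y - Yred

  if (lfactorial(n) <= log(n_perm)) {
    perms <- all_permutations(n)
    warnf("only %d distinct permutations exist; using all of them",
          nrow(perms))
  } else {
    set.seed(derive_seed(seed, "cluster_fwe"))
    perms <- t(replicate(n_perm, sample.int(n)))
  }
  df <- n - qr(X)$rank
  crit_t <- switch(alternative,
                   greater = stats::qt(cluster_forming_p, df, lower.tail = FALSE),
                   less = stats::qt(cluster_forming_p, df),
                   two.sided = stats::qt(cluster_forming_p / 2, df,
                                         lower.tail = FALSE))
  max_null <- numeric(nrow(perms))
  for (b in seq_len(nrow(perms))) {
    Ystar <- Yred + Rz[perms[b, ], , drop = FALSE]
    tstar <- ols_t_map(Ystar, X, contrast)$t
    supra <- switch(alternative,
                    greater = tstar > crit_t,
                    less = tstar < crit_t,
                    two.sided = abs(tstar) > crit_t)
    if (!any(supra)) { max_null[b] <- 0; next }
    cstar <- label_components(array(supra, sv$dim), connectivity)
    max_null[b] <- max(tabulate(cstar[cstar > 0L]))
  }
  ord <- order(sizes, decreasing = TRUE)
  clusters <- data.frame(cluster_id = seq_along(ord),
                         size = sizes[ord],
                         peak_t = vapply(ord, function(k) {
                           tv <- obs$t[comp == k]
                           if (alternative == "less") min(tv)
                           else if (alternative == "greater") max(tv)
                           else tv[which.max(abs(tv))]
                         }, numeric(1)),
                         fwe_p = vapply(sizes[ord], function(sz)
                           (1 + sum(max_null >= sz)) / (nrow(perms) + 1),
                           numeric(1)))
  labels <- array(0L, sv$dim)
  for (j in seq_along(ord)) labels[comp == ord[j]] <- j
  structure(list(stat_map = obs, clusters = clusters, labels = labels,
                 max_null_extent = max_null,
                 cluster_forming_p = cluster_forming_p,
                 n_perm = nrow(perms), seed = seed),
            class = "cluster_fwe_result")
}

#' @export
print.cluster_fwe_result <- function(x, ...) {
  cat(sprintf("<cluster_fwe_result> %d cluster(s) at voxel p < %g, %d permutations\n",
              nrow(x$clusters), x$cluster_forming_p, x$n_perm))
  if (nrow(x$clusters)) print(x$clusters)
  invisible(x)
}

#' Voxel-wise paired t-map of follow-up minus baseline
#'
#' One-sample t-test on per-subject difference images, `df = n - 1`.
#' Voxels with zero difference variance but nonzero mean yield infinite t
#' and are counted in attribute `n_degenerate`.
#'
#' @param volumes_baseline,volumes_followup Lists of [volume_image()]s in
#'   matched subject order (same names if named).
#' @param alternative Sidedness; default `"two.sided"`.
#' @return A `stat_map`.
#' @export
paired_t_map <- function(volumes_baseline, volumes_followup,
                         alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  n <- length(volumes_baseline)
  if (length(volumes_followup) != n)
    stopf("baseline and follow-up lists differ in length")
  if (!is.null(names(volumes_baseline)) && !is.null(names(volumes_followup)) &&
      !identical(names(volumes_baseline), names(volumes_followup)))
    stopf("baseline and follow-up subjects are not matched")
  if (n < 3) stopf("need at least 3 matched subjects")
  sv_b <- stack_volumes(volumes_baseline)
  sv_f <- stack_volumes(volumes_followup)
  if (!identical(sv_b$dim, sv_f$dim)) stopf("volume shapes differ")
  D <- sv_f$Y - sv_b$Y
  m <- colMeans(D)
  s <- sqrt(colSums((D - rep(m, each = n))^2) / (n - 1))
  tval <- ifelse(s > 0, m / (s / sqrt(n)),
                 ifelse(m == 0, 0, sign(m) * Inf))
  df <- n - 1
  p <- switch(alternative,
              greater = stats::pt(tval, df, lower.tail = FALSE),
              less = stats::pt(tval, df),
              two.sided = 2 * stats::pt(-abs(tval), df))
  out <- structure(list(t = array(tval, sv_b$dim), p = array(p, sv_b$dim),
                        df = df, direction = alternative,
                        mask = array(TRUE, sv_b$dim),
                        voxel_size = sv_b$voxel_size), class = "stat_map")
  attr(out, "n_degenerate") <- sum(s == 0 & m != 0)
  out
}

#' ROI-level ANCOVA of SBR between groups
#'
#' Per-ROI analysis of covariance: OLS of SBR on group plus nuisance
#' covariates; the group effect is the partial F from dropping the group
#' term. Adjusted group means are predictions at the grand covariate means.
#' Constant covariates are dropped with a warning.
#'
#' @param panel An `sbr_panel`.
#' @param roi ROI column name.
#' @param covariates Character vector of covariate columns; default
#'   `c("age", "sex", "updrs3")`.
#' @param groups Optional character vector restricting (and ordering) the
#'   groups compared; default: all groups in the panel.
#' @param timepoint Panel timepoint to analyze; default `"baseline"`.
#' @return List with `F`, `df`, `p`, `t` (signed, only for 2 groups:
#'   second group minus first), `adjusted_means`, `n`.
#' @export
roi_ancova <- function(panel, roi, covariates = c("age", "sex", "updrs3"),
                       groups = NULL, timepoint = "baseline") {
  df <- as.data.frame(panel)
  df <- df[df$timepoint == timepoint, ]
  if (!is.null(groups)) df <- df[df$group %in% groups, ]
  df$group <- factor(df$group, levels = groups %||% unique(df$group))
  if (nlevels(df$group) < 2) stopf("need at least 2 groups")
  if (!roi %in% names(df)) stopf("ROI '%s' not in panel", roi)
  keep <- character()
  for (cv in covariates) {
    if (!cv %in% names(df)) stopf("covariate '%s' not in panel", cv)
    if (length(unique(df[[cv]])) < 2) {
      warnf("covariate '%s' is constant; dropped", cv)
    } else keep <- c(keep, cv)
  }
  if (nrow(df) <= length(keep) + nlevels(df$group))
    stopf("too few subjects for %d covariates", length(keep))
  fml <- stats::reformulate(c("group", keep), response = "y")
  dat <- cbind(y = df[[roi]], df[c("group", keep)])
  fit <- stats::lm(fml, data = dat)
  a <- stats::anova(stats::update(fit, . ~ . - group), fit)
  Fval <- a$F[2]
  pval <- a$`Pr(>F)`[2]
  newdata <- do.call(rbind, lapply(levels(df$group), function(g) {
    nd <- data.frame(group = factor(g, levels = levels(df$group)))
    for (cv in keep)
      nd[[cv]] <- if (is.numeric(dat[[cv]])) mean(dat[[cv]])
                  else names(which.max(table(dat[[cv]])))
    nd
  }))
  adj <- stats::setNames(stats::predict(fit, newdata), levels(df$group))
  tval <- if (nlevels(df$group) == 2) {
    cf <- summary(fit)$coefficients
    cf[paste0("group", levels(df$group)[2]), "t value"]
  } else NA_real_
  list(F = Fval, df = c(a$Df[2], a$Res.Df[2]), p = pval, t = tval,
       adjusted_means = adj, n = nrow(df))
}

#' Multivariate (Wilks' lambda) ANCOVA across an ROI set
#'
#' @inheritParams roi_ancova
#' @param rois Character vector of ROI columns (>= 2).
#' @return List with `wilks`, `F`, `df`, `p`, `n`.
#' @export
roi_mancova <- function(panel, rois, covariates = c("age", "sex", "updrs3"),
                        groups = NULL, timepoint = "baseline") {
  df <- as.data.frame(panel)
  df <- df[df$timepoint == timepoint, ]
  if (!is.null(groups)) df <- df[df$group %in% groups, ]
  df$group <- factor(df$group, levels = groups %||% unique(df$group))
  if (nlevels(df$group) < 2) stopf("need at least 2 groups")
  if (length(rois) < 2) stopf("need at least 2 ROIs for MANCOVA")
  keep <- covariates[vapply(covariates, function(cv)
    length(unique(df[[cv]])) > 1, logical(1))]
  if (length(keep) < length(covariates))
    warnf("constant covariate(s) dropped: %s",
          paste(setdiff(covariates, keep), collapse = ", "))
  Y <- as.matrix(df[rois])
  fml <- stats::reformulate(c("group", keep), response = "Y")
  dat <- cbind(as.data.frame(df[c("group", keep)]))
  dat$Y <- Y
  fit <- stats::manova(fml, data = dat)
  s <- summary(fit, test = "Wilks")$stats
  list(wilks = s["group", "Wilks"], F = s["group", "approx F"],
       df = s["group", c("num Df", "den Df")], p = s["group", "Pr(>F)"],
       n = nrow(df))
}

#' Two-timepoint longitudinal group contrast on an ROI
#'
#' Tests whether the change score (follow-up minus baseline) of an ROI's
#' SBR differs between two groups with a pooled-variance two-sample t-test.
#' At exactly two timepoints this equals the group-by-time interaction test
#' of a random-intercept linear mixed model fitted by generalized least
#' squares (the change-score contrast is the interaction contrast, and the
#' random intercept cancels in the within-subject difference).
#'
#' @param panel An `sbr_panel` with both timepoints.
#' @param roi ROI column name.
#' @param groups Length-2 character vector; the estimate is mean change in
#'   `groups[1]` minus mean change in `groups[2]`.
#' @return List with `estimate`, `t`, `df`, `p`, `n` (per group),
#'   `n_dropped` (subjects missing a timepoint).
#' @export
longitudinal_group_contrast <- function(panel, roi, groups) {
  if (length(groups) != 2) stopf("`groups` must name exactly 2 groups")
  df <- as.data.frame(panel)
  df <- df[df$group %in% groups, ]
  if (!roi %in% names(df)) stopf("ROI '%s' not in panel", roi)
  bl <- df[df$timepoint == "baseline", c("subject_id", "group", roi)]
  fu <- df[df$timepoint == "followup", c("subject_id", roi)]
  merged <- merge(bl, fu, by = "subject_id", suffixes = c("_bl", "_fu"))
  n_dropped <- length(unique(df$subject_id)) - nrow(merged)
  if (n_dropped > 0)
    message(sprintf("%d subject(s) missing a timepoint; dropped", n_dropped))
  merged$change <- merged[[paste0(roi, "_fu")]] - merged[[paste0(roi, "_bl")]]
  g1 <- merged$change[merged$group == groups[1]]
  g2 <- merged$change[merged$group == groups[2]]
  if (length(g1) < 2 || length(g2) < 2)
    stopf("need at least 2 complete subjects per group")
  est <- mean(g1) - mean(g2)
  n1 <- length(g1); n2 <- length(g2)
  sp2 <- ((n1 - 1) * stats::var(g1) + (n2 - 1) * stats::var(g2)) / (n1 + n2 - 2)
  tval <- if (sp2 > 0) est / sqrt(sp2 * (1 / n1 + 1 / n2)) else
    ifelse(est == 0, 0, sign(est) * Inf)
  df_t <- n1 + n2 - 2
  list(estimate = est, t = tval, df = df_t,
       p = 2 * stats::pt(-abs(tval), df_t),
       n = stats::setNames(c(n1, n2), groups), n_dropped = n_dropped)
}
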