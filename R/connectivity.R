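#' Per-group partial-correlation network
#'
#' Estimates the full partial correlation between every pair of network
#' ROIs, controlling for all remaining `k = p - 2` nodes, from the inverse
#' of the sample correlation matrix:
#' `pc_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj)`. Per-edge p-values come
#' from `t = r * sqrt((n - 2 - k) / (1 - r^2))` with `df = n - 2 - k`,
#' two-tailed. A residualization estimator (correlate the residuals of each
#' node regressed on all others) is available as an independent route and
#' agrees with the precision route to numerical precision.
#'
#' @param panel An `sbr_panel`.
#' @param network A [network_definition()].
#' @param group Group label to estimate the network in.
#' @param timepoint Panel timepoint; default `"baseline"`.
#' @param method `"precision"` (default), `"residual"`, or
#'   `"pseudoinverse"` (Moore-Penrose fallback for singular correlation
#'   matrices).
#' @return A `pcor_network`: list with `nodes`, matrices `r`, `z`
#'   (Fisher-transformed), `p`, and scalars `n`, `k`, `group`.
#' @export
partial_corr_network <- function(panel, network, group,
                                 timepoint = "baseline",
                                 method = c("precision", "residual",
                                            "pseudoinverse")) {
  method <- match.arg(method)
  # a bare character vector is accepted; p = 2 then reduces to the plain
  # Pearson correlation (k = 0)
  rois <- if (inherits(network, "network_definition")) network$rois
          else as.character(network)
  if (length(rois) < 2) stopf("need at least 2 ROIs")
  miss <- setdiff(rois, names(panel))
  if (length(miss)) stopf("network ROI(s) not in panel: %s",
                          paste(miss, collapse = ", "))
  df <- as.data.frame(panel)
  df <- df[df$group == group & df$timepoint == timepoint, rois]
  n <- nrow(df)
  p <- length(rois)
  if (n < p + 3)
    stopf("group '%s' has n = %d subjects; need at least p + 3 = %d",
          group, n, p + 3)
  X <- as.matrix(df)
  r <- matrix(NA_real_, p, p, dimnames = list(rois, rois))
  diag(r) <- 1
  if (method == "residual") {
    for (i in seq_len(p - 1)) for (j in (i + 1):p) {
      others <- X[, -c(i, j), drop = FALSE]
      ri <- stats::lm.fit(cbind(1, others), X[, i])$residuals
      rj <- stats::lm.fit(cbind(1, others), X[, j])$residuals
      r[i, j] <- r[j, i] <- stats::cor(ri, rj)
    }
  } else {
    Rhat <- stats::cor(X)
    omega <- if (method == "pseudoinverse") MASS::ginv(Rhat) else
      tryCatch(solve(Rhat), error = function(e)
        stopf(paste("sample correlation matrix is singular;",
                    "retry with method = 'pseudoinverse'")))
    d <- sqrt(diag(omega))
    r <- -omega / tcrossprod(d)
    diag(r) <- 1
    dimnames(r) <- list(rois, rois)
  }
  k <- p - 2
  df_t <- n - 2 - k
  if (df_t < 1) stopf("n too small for %d controlled variables", k)
  tstat <- r * sqrt(df_t / pmax(1 - r^2, .Machine$double.eps))
  pmat <- 2 * stats::pt(-abs(tstat), df_t)
  diag(pmat) <- NA_real_
  z <- r
  z[abs(z) < 1] <- atanh(z[abs(z) < 1])
  z[abs(r) >= 1 & row(r) != col(r)] <- sign(r[abs(r) >= 1 & row(r) != col(r)]) * Inf
  diag(z) <- NA_real_
  structure(list(nodes = rois, r = r, z = z, p = pmat, n = n, k = k,
                 group = group), class = "pcor_network")
}

#' @export
print.pcor_network <- function(x, ...) {
  cat(sprintf("<pcor_network> group %s: %d nodes, n = %d, k = %d\n",
              x$group, length(x$nodes), x$n, x$k))
  invisible(x)
}

#' Fisher z transformation and its variance for partial correlations
#'
#' `fisher_z(r) = atanh(r)`; `fisher_z_variance(n, k) = 1 / (n - k - 3)`,
#' the standard variance of a Fisher-transformed partial correlation
#' controlling `k` variables (`k = 0` recovers the plain correlation case).
#'
#' @param r Correlation(s) with `|r| < 1`.
#' @param n Sample size.
#' @param k Number of controlled variables; default 0.
#' @return Transformed value(s) / variance (scalar).
#' @examples
#' fisher_z(0.5)            # 0.549306...
#' fisher_z_variance(40, 6) # 1/31
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1, na.rm = TRUE))
    stopf("|r| must be < 1 for the Fisher transform")
  atanh(r)
}

#' @rdname fisher_z
#' @export
fisher_z_variance <- function(n, k = 0) {
  if (n - k - 3 <= 0) stopf("need n - k - 3 > 0 (got n = %d, k = %d)", n, k)
  1 / (n - k - 3)
}

#' Edge-wise comparison of two partial-correlation networks
#'
#' For every edge, tests the difference of Fisher-transformed partial
#' correlations between a patient and a reference network with the normal
#' statistic `Z = (z_pat - z_ref) / sqrt(var_pat + var_ref)`, where each
#' variance is `1/(n - k - 3)` (k-corrected default) or `1/(n - 3)`
#' (`variance = "classic"`). An edge is altered when its two-tailed p falls
#' below `alpha`; its direction is `"increase"` when the patient z exceeds
#' the reference z.
#'
#' @param net_patient,net_reference `pcor_network`s over identical node
#'   sets and ordering.
#' @param alpha Alteration threshold on the two-tailed p; default 0.01,
#'   uncorrected. A Benjamini-Hochberg column is also emitted.
#' @param variance `"k-corrected"` (default) or `"classic"`.
#' @param restrict_to_significant If `TRUE`, only edges significant
#'   (p < `within_alpha`) within either group are eligible as altered.
#' @param within_alpha Within-group significance level; default 0.01.
#' @return An `edge_comparison`: list with `edges` (data.frame: `node_i`,
#'   `node_j`, `r_patient`, `r_reference`, `z_patient`, `z_reference`, `Z`,
#'   `p`, `p_bh`, `altered`, `direction`) and `summary` (list: `n_edges`,
#'   `n_altered`, `pct_altered`, `pct_increases`, group sizes).
#' @export
compare_networks <- function(net_patient, net_reference, alpha = 0.01,
                             variance = c("k-corrected", "classic"),
                             restrict_to_significant = FALSE,
                             within_alpha = 0.01) {
  variance <- match.arg(variance)
  if (!identical(net_patient$nodes, net_reference$nodes))
    stopf("networks are defined over different node sets")
  p <- length(net_patient$nodes)
  k <- if (variance == "k-corrected") net_patient$k else 0
  v_a <- fisher_z_variance(net_patient$n, k)
  v_b <- fisher_z_variance(net_reference$n, k)
  ut <- which(upper.tri(net_patient$r), arr.ind = TRUE)
  z_a <- net_patient$z[ut]
  z_b <- net_reference$z[ut]
  Z <- (z_a - z_b) / sqrt(v_a + v_b)
  pval <- 2 * stats::pnorm(-abs(Z))
  eligible <- rep(TRUE, nrow(ut))
  if (restrict_to_significant)
    eligible <- net_patient$p[ut] < within_alpha |
      net_reference$p[ut] < within_alpha
  altered <- eligible & pval < alpha
  edges <- data.frame(
    node_i = net_patient$nodes[ut[, 1]],
    node_j = net_patient$nodes[ut[, 2]],
    r_patient = net_patient$r[ut], r_reference = net_reference$r[ut],
    z_patient = z_a, z_reference = z_b,
    Z = Z, p = pval, p_bh = stats::p.adjust(pval, "BH"),
    altered = altered,
    direction = ifelse(altered, ifelse(z_a > z_b, "increase", "decrease"),
                       NA_character_),
    stringsAsFactors = FALSE)
  n_edges <- nrow(edges)
  n_alt <- sum(altered)
  structure(list(
    edges = edges,
    summary = list(n_edges = n_edges, n_altered = n_alt,
                   pct_altered = 100 * n_alt / n_edges,
                   pct_increases = if (n_alt) 100 *
                     sum(edges$direction == "increase", na.rm = TRUE) / n_alt
                   else NA_real_,
                   n_patient = net_patient$n, n_reference = net_reference$n,
                   alpha = alpha)), class = "edge_comparison")
}

#' @export
print.edge_comparison <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<edge_comparison> %d/%d edges altered (%.1f%%) at p < %g\n",
              s$n_altered, s$n_edges, s$pct_altered, s$alpha))
  invisible(x)
}

#' Chi-squared comparison of alteration percentages
#'
#' Pearson chi-squared test (1 df, no continuity correction) on the 2x2
#' table of altered vs unaltered edge counts in two groups.
#'
#' @param altered_a,altered_b Altered edge counts in groups A and B.
#' @param n_edges Total number of edges per network (same for both).
#' @return List with `chi2`, `df`, `p` and the 2x2 `table`.
#' @examples
#' chi2_alteration_compare(10, 4, 66)
#' @export
chi2_alteration_compare <- function(altered_a, altered_b, n_edges) {
  if (n_edges <= 0) stopf("`n_edges` must be positive")
  if (altered_a < 0 || altered_a > n_edges ||
      altered_b < 0 || altered_b > n_edges)
    stopf("altered counts must lie in [0, n_edges]")
  obs <- rbind(A = c(altered = altered_a, unaltered = n_edges - altered_a),
               B = c(altered = altered_b, unaltered = n_edges - altered_b))
  expct <- outer(rowSums(obs), colSums(obs)) / sum(obs)
  if (any(expct > 0 & expct < 1))
    warnf("expected cell count < 1; consider an exact test")
  terms <- (obs - expct)^2 / expct
  terms[expct == 0] <- 0  # a margin of zero contributes nothing
  chi2 <- sum(terms)
  list(chi2 = chi2, df = 1,
       p = stats::pchisq(chi2, 1, lower.tail = FALSE), table = obs)
}
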