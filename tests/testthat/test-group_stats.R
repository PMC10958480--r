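test_that("GLM contrast map equals the pooled two-sample t oracle", {
  vols <- random_volumes(15, seed = 20)
  grp <- rep(c("A", "B"), c(8, 7))
  dsn <- design_matrix(grp)
  smap <- glm_contrast_map(vols, dsn$X, dsn$contrast,
                           alternative = "two.sided")
  Y <- t(vapply(vols, function(v) as.vector(v$data), numeric(60)))
  for (v in c(1, 17, 60)) {
    tt <- t.test(Y[grp == "B", v], Y[grp == "A", v], var.equal = TRUE)
    expect_equal(smap$t[v], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(smap$p[v], tt$p.value, tolerance = 1e-10)
  }
  expect_equal(smap$df, 13)
  expect_error(glm_contrast_map(vols, dsn$X, c(0, 0)), "all zeros")
  # rank deficiency is named
  X2 <- cbind(dsn$X, dup = dsn$X[, 2])
  expect_error(glm_contrast_map(vols, X2, c(0, 1, 0)), "rank deficient")
})

test_that("GLM with permuted labels is calibrated at the voxel level", {
  set.seed(33)
  rates <- replicate(20, {
    vols <- lapply(1:16, function(i) volume_image(array(rnorm(125), c(5, 5, 5))))
    dsn <- design_matrix(sample(rep(c("A", "B"), 8)))
    smap <- glm_contrast_map(vols, dsn$X, dsn$contrast,
                             alternative = "two.sided")
    mean(smap$p < 0.05)
  })
  expect_gt(mean(rates), 0.03)
  expect_lt(mean(rates), 0.07)
})

test_that("paired t-map equals the paired t oracle and flags degeneracy", {
  bl <- random_volumes(6, seed = 31)
  fu <- random_volumes(6, seed = 32, shift = 0.3)
  smap <- paired_t_map(bl, fu)
  B <- t(vapply(bl, function(v) as.vector(v$data), numeric(60)))
  F_ <- t(vapply(fu, function(v) as.vector(v$data), numeric(60)))
  for (v in c(2, 30)) {
    tt <- t.test(F_[, v], B[, v], paired = TRUE)
    expect_equal(smap$t[v], unname(tt$statistic), tolerance = 1e-10)
    expect_equal(smap$p[v], tt$p.value, tolerance = 1e-10)
  }
  # identical inputs: t = 0 everywhere
  smap0 <- paired_t_map(bl, bl)
  expect_true(all(smap0$t == 0))
  # constant shift: infinite t, flagged (integer data so the shift is
  # floating-point exact)
  bl_int <- lapply(bl, function(v)
    volume_image(array(round(v$data * 4), dim(v$data)), v$voxel_size))
  shifted <- lapply(bl_int, function(v)
    volume_image(v$data + 1, v$voxel_size))
  sms <- paired_t_map(bl_int, shifted)
  expect_true(all(is.infinite(sms$t)))
  expect_equal(attr(sms, "n_degenerate"), 60)
  expect_error(paired_t_map(bl, fu[1:5]), "differ in length")
})

test_that("cluster FWE detects a planted difference and orders p by size", {
  set.seed(40)
  d <- c(12, 12, 12)
  grp <- rep(c("A", "B"), each = 20)
  effect <- array(0, d)
  effect[3:7, 3:10, 3:7] <- 1.2          # 5*8*5 = 200-voxel planted region
  vols <- lapply(seq_along(grp), function(i) {
    base <- array(rnorm(prod(d)), d)
    if (grp[i] == "B") base <- base + effect
    volume_image(base)
  })
  dsn <- design_matrix(grp)
  res <- cluster_fwe(vols, dsn$X, dsn$contrast, n_perm = 200,
                     cluster_forming_p = 0.005, seed = 5)
  expect_gte(nrow(res$clusters), 1)
  expect_lte(res$clusters$fwe_p[1], 0.05)
  expect_gte(res$clusters$size[1], 100)
  # monotone: larger clusters never have larger FWE p
  expect_false(is.unsorted(res$clusters$fwe_p))
  expect_true(all(res$clusters$fwe_p >= 1 / (res$n_perm + 1)))
  # deterministic given seed
  res2 <- cluster_fwe(vols, dsn$X, dsn$contrast, n_perm = 200,
                      cluster_forming_p = 0.005, seed = 5)
  expect_identical(res$clusters, res2$clusters)
})

test_that("cluster FWE handles empty results and small permutation spaces", {
  set.seed(41)
  vols <- lapply(1:10, function(i) volume_image(array(rnorm(64), c(4, 4, 4))))
  dsn <- design_matrix(rep(c("A", "B"), each = 5))
  res <- cluster_fwe(vols, dsn$X, dsn$contrast, n_perm = 200,
                     cluster_forming_p = 1e-6, seed = 2)
  expect_equal(nrow(res$clusters), 0)
  # n = 5 subjects: only 120 distinct permutations exist
  vols5 <- vols[1:5]
  dsn5 <- design_matrix(c("A", "A", "A", "B", "B"))
  expect_warning(
    res5 <- cluster_fwe(vols5, dsn5$X, dsn5$contrast, n_perm = 150,
                        cluster_forming_p = 0.05, seed = 3),
    "distinct permutations")
  expect_equal(res5$n_perm, 120)
})

test_that("roi_ancova matches the two-sample t when covariates are absent or orthogonal", {
  set.seed(50)
  n <- 40
  grp <- rep(c("HC", "PD"), each = n / 2)
  X <- matrix(rnorm(n * 2, mean = rep(c(2, 1.4), each = n / 2)), n, 2)
  colnames(X) <- c("left_dorsal_putamen", "right_dorsal_putamen")
  # constant covariates are dropped with a warning -> plain two-group test
  panel <- make_panel(grp, X)
  expect_warning(res <- roi_ancova(panel, "left_dorsal_putamen",
                                   covariates = "sex",
                                   groups = c("HC", "PD")),
                 "constant")
  tt <- t.test(X[grp == "PD", 1], X[grp == "HC", 1], var.equal = TRUE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p, tt$p.value, tolerance = 1e-10)
  expect_equal(unname(res$F), unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(unname(diff(res$adjusted_means)),
               unname(diff(tt$estimate)) * -1, tolerance = 1e-10)
  expect_error(roi_ancova(panel, "left_dorsal_putamen", groups = "PD"),
               "2 groups")

  # with informative covariates the adjusted test differs from the raw t
  panel2 <- make_panel(grp, X, age = rnorm(n, 60, 8),
                       sex = sample(c("F", "M"), n, TRUE),
                       updrs3 = rnorm(n, 15, 5))
  res2 <- roi_ancova(panel2, "left_dorsal_putamen",
                     covariates = c("age", "sex", "updrs3"),
                     groups = c("HC", "PD"))
  fit <- lm(X[, 1] ~ factor(grp, c("HC", "PD")) + panel2$age[1:n] +
              factor(panel2$sex[1:n]) + panel2$updrs3[1:n])
  expect_equal(res2$t, summary(fit)$coefficients[2, "t value"],
               tolerance = 1e-10)
})

test_that("roi_ancova p-values are uniform under the null", {
  set.seed(51)
  pvals <- replicate(200, {
    grp <- rep(c("A", "B"), each = 12)
    X <- matrix(rnorm(24), 24, 1, dimnames = list(NULL, "roi1"))
    suppressWarnings(roi_ancova(make_panel(grp, X), "roi1",
                                covariates = "age")$p)
  })
  ks <- ks.test(pvals, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("Wilks MANCOVA runs and rejects single-group input", {
  set.seed(52)
  grp <- rep(c("A", "B"), each = 20)
  X <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("r1", "r2")))
  panel <- make_panel(grp, X, age = rnorm(40, 60, 5))
  res <- roi_mancova(panel, c("r1", "r2"), covariates = "age")
  expect_true(res$wilks > 0 && res$wilks <= 1)
  expect_true(res$p > 0 && res$p <= 1)
  expect_error(roi_mancova(make_panel(rep("A", 10),
    matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("r1", "r2")))),
    c("r1", "r2"), covariates = NULL), "2 groups")
})

test_that("change-score contrast equals the mixed-model interaction at 2 timepoints", {
  skip_if_not_installed("lme4")
  cfg <- default_cohort_config(n = c(PD = 15, SWEDD = 12), seed = 60)
  panel <- generate_sbr_cohort(cfg)
  res <- longitudinal_group_contrast(panel, "left_dorsal_putamen",
                                     c("PD", "SWEDD"))
  df <- as.data.frame(panel)
  df$time <- as.integer(df$timepoint == "followup")
  df$grp <- factor(df$group, c("SWEDD", "PD"))
  fit <- lme4::lmer(left_dorsal_putamen ~ grp * time + (1 | subject_id),
                    data = df, REML = TRUE)
  cf <- summary(fit)$coefficients
  expect_equal(unname(cf["grpPD:time", "Estimate"]), res$estimate,
               tolerance = 1e-6)
  expect_equal(unname(cf["grpPD:time", "t value"]), res$t, tolerance = 1e-4)
})

test_that("longitudinal contrast: null calibration, power oracle, degenerate input", {
  # zero change everywhere -> estimate 0, t 0
  X <- matrix(1.5, 8, 1, dimnames = list(NULL, "roi1"))
  panel0 <- rbind(make_panel(rep(c("A", "B"), 4), X),
                  make_panel(rep(c("A", "B"), 4), X,
                             timepoint = "followup"))
  panel0 <- datspect:::as_sbr_panel(panel0, "roi1")
  res0 <- longitudinal_group_contrast(panel0, "roi1", c("A", "B"))
  expect_equal(res0$estimate, 0)
  expect_equal(res0$t, 0)

  # power at the published parameterization (PD decline vs SWEDD flat,
  # n = 39/26, rho_t = 0.7), checked against an independent oracle that
  # simulates change scores directly from their implied normal
  # distributions (pooled t under unequal variances is not exactly
  # noncentral t, so a closed form would be approximate)
  sd_ch <- function(s1, s2, rho) sqrt(s1^2 + s2^2 - 2 * rho * s1 * s2)
  s_pd <- sd_ch(0.48, 0.37, 0.7)
  s_sw <- sd_ch(0.73, 0.55, 0.7)
  n_sim <- 500
  set.seed(601)
  power_oracle <- mean(replicate(n_sim, {
    t.test(rnorm(39, 0.98 - 1.34, s_pd), rnorm(26, 2.29 - 2.33, s_sw),
           var.equal = TRUE)$p.value < 0.05
  }))
  hits <- vapply(seq_len(n_sim), function(i) {
    cfg <- default_cohort_config(n = c(PD = 39, SWEDD = 26),
                                 seed = 6100 + i)
    pan <- generate_sbr_cohort(cfg)
    longitudinal_group_contrast(pan, "left_dorsal_putamen",
                                c("PD", "SWEDD"))$p < 0.05
  }, logical(1))
  mc_se <- sqrt(2 * power_oracle * (1 - power_oracle) / n_sim)
  expect_lt(abs(mean(hits) - power_oracle), 3 * mc_se)
  expect_gt(mean(hits), 0.75)

  # identical change distributions -> uniform p
  set.seed(62)
  pvals <- replicate(200, {
    Xb <- matrix(rnorm(30), 30, 1, dimnames = list(NULL, "roi1"))
    Xf <- Xb + rnorm(30, 0, 0.3)
    colnames(Xf) <- "roi1"
    g <- rep(c("A", "B"), 15)
    pan <- rbind(make_panel(g, Xb), make_panel(g, Xf, timepoint = "followup"))
    pan <- datspect:::as_sbr_panel(pan, "roi1")
    longitudinal_group_contrast(pan, "roi1", c("A", "B"))$p
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
})
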