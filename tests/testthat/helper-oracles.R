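# Shared fixtures and independent oracles used across the suite.

# --- tiny region tables / atlases ------------------------------------------

toy_regions <- function() {
  data.frame(
    region_id = 1:3,
    name = c("left_dorsal_putamen", "left_insula", "occipital_reference"),
    hemisphere = c("left", "left", "bilateral"),
    pathway = c("nigrostriatal", "mesocorticolimbic", "none"),
    is_reference = c(FALSE, FALSE, TRUE),
    is_striatal = c(TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

# 6x6x6 atlas: region 1 = front slab, region 2 = middle slab,
# reference = back slab
toy_atlas <- function() {
  lab <- array(0L, c(6, 6, 6))
  lab[, 1:2, ] <- 1L
  lab[, 3:4, ] <- 2L
  lab[, 5:6, ] <- 3L
  label_atlas(lab, toy_regions(), voxel_size = c(2, 2, 2))
}

toy_volume <- function(v1 = 2, v2 = 1.5, ref = 1) {
  lab <- toy_atlas()$labels
  arr <- array(0, dim(lab))
  arr[lab == 1L] <- v1
  arr[lab == 2L] <- v2
  arr[lab == 3L] <- ref
  volume_image(arr, voxel_size = c(2, 2, 2))
}

# minimal sbr_panel built directly from a matrix of ROI values
make_panel <- function(groups, X, timepoint = "baseline",
                       age = NULL, sex = NULL, updrs3 = NULL) {
  n <- nrow(X)
  df <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)), group = groups,
    timepoint = timepoint,
    age = age %||% rep(60, n),
    sex = sex %||% rep("F", n),
    updrs3 = updrs3 %||% rep(10, n), stringsAsFactors = FALSE)
  df <- cbind(df, as.data.frame(X))
  datspect:::as_sbr_panel(df, colnames(X))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# --- independent oracles ----------------------------------------------------

# partial correlation of columns i, j controlling all others, by explicit
# residualization through lm()
pcor_residual_oracle <- function(X, i, j) {
  others <- X[, -c(i, j), drop = FALSE]
  ri <- stats::residuals(stats::lm(X[, i] ~ others))
  rj <- stats::residuals(stats::lm(X[, j] ~ others))
  stats::cor(ri, rj)
}

# brute-force flood fill labeling of a logical 3-D array
floodfill_oracle <- function(supra, connectivity = 26) {
  d <- dim(supra)
  off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  off <- off[rowSums(abs(off)) > 0, ]
  off <- switch(as.character(connectivity),
                "6" = off[rowSums(abs(off)) == 1, , drop = FALSE],
                "18" = off[rowSums(abs(off)) <= 2, , drop = FALSE],
                "26" = off)
  labels <- array(0L, d)
  nxt <- 0L
  for (v in which(supra)) {
    if (labels[v] != 0L) next
    nxt <- nxt + 1L
    queue <- list(arrayInd(v, d)[1, ])
    labels[v] <- nxt
    while (length(queue)) {
      cur <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(off))) {
        nb <- cur + off[k, ]
        if (any(nb < 1) || any(nb > d)) next
        if (supra[nb[1], nb[2], nb[3]] &&
            labels[nb[1], nb[2], nb[3]] == 0L) {
          labels[nb[1], nb[2], nb[3]] <- nxt
          queue[[length(queue) + 1]] <- nb
        }
      }
    }
  }
  labels
}

# random volume list for GLM tests
random_volumes <- function(n, dim = c(5, 4, 3), seed = 1, shift = 0) {
  set.seed(seed)
  lapply(seq_len(n), function(i)
    volume_image(array(rnorm(prod(dim), mean = shift), dim)))
}
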