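#' Default region table for the DAT-SPECT pipeline
#'
#' Twenty-four bilateral regions of interest spanning the nigrostriatal and
#' mesocorticolimbic dopaminergic pathways (dorsal caudate, dorsal putamen,
#' ventral striatum, amygdala, hippocampus, parahippocampus, insula,
#' olfactory cortex, anterior/middle cingulate, pre-/postcentral gyri, each
#' left and right) plus the lateral superior occipital reference region used
#' for intensity normalization.
#'
#' @return A `data.frame` with one row per region and columns `region_id`
#'   (positive integer label), `name`, `hemisphere` (`"left"`, `"right"` or
#'   `"bilateral"`), `pathway` (`"nigrostriatal"`, `"mesocorticolimbic"` or
#'   `"none"`), `is_reference` and `is_striatal`.
#' @examples
#' head(region_table())
#' @export
region_table <- function() {
  base <- data.frame(
    stem = c("dorsal_caudate", "dorsal_putamen", "ventral_striatum",
             "amygdala", "hippocampus", "parahippocampus", "insula",
             "olfactory", "anterior_cingulate", "middle_cingulate",
             "postcentral", "precentral"),
    pathway = c("nigrostriatal", "nigrostriatal", "nigrostriatal",
                rep("mesocorticolimbic", 7),
                "nigrostriatal", "nigrostriatal"),
    is_striatal = c(TRUE, TRUE, TRUE, rep(FALSE, 9)),
    stringsAsFactors = FALSE
  )
  rows <- do.call(rbind, lapply(c("left", "right"), function(h) {
    data.frame(name = paste0(h, "_", base$stem), hemisphere = h,
               pathway = base$pathway, is_striatal = base$is_striatal,
               stringsAsFactors = FALSE)
  }))
  rows <- rbind(rows, data.frame(
    name = "occipital_reference", hemisphere = "bilateral",
    pathway = "none", is_striatal = FALSE, stringsAsFactors = FALSE))
  data.frame(region_id = seq_len(nrow(rows)),
             name = rows$name,
             hemisphere = rows$hemisphere,
             pathway = rows$pathway,
             is_reference = rows$name == "occipital_reference",
             is_striatal = rows$is_striatal,
             stringsAsFactors = FALSE)
}

validate_region_table <- function(regions) {
  need <- c("region_id", "name", "hemisphere", "pathway",
            "is_reference", "is_striatal")
  miss <- setdiff(need, names(regions))
  if (length(miss)) stopf("region table missing column(s): %s",
                          paste(miss, collapse = ", "))
  if (anyDuplicated(regions$region_id))
    stopf("region_id values must be unique")
  if (any(regions$region_id <= 0)) stopf("region_id values must be positive")
  if (!any(regions$is_reference))
    stopf("region table must flag at least one reference region")
  invisible(regions)
}

#' Published regional SBR reference parameters
#'
#' Mean and standard deviation of the specific binding ratio in each of the
#' 24 pathway regions for de-novo Parkinson's disease (PD) and SWEDD (scan
#' without evidence of dopaminergic deficit) patients, at baseline and
#' two-year follow-up. These are the default parameterization of the
#' synthetic cohort generator. Healthy-control (HC) values are not published
#' at regional level; the generator's HC convention is SWEDD baseline means
#' inflated by 10\% with SWEDD SDs (see [default_cohort_config()]).
#'
#' @return A `data.frame` with columns `region`, `pd_bl_mean`, `pd_bl_sd`,
#'   `pd_fu_mean`, `pd_fu_sd`, `swedd_bl_mean`, `swedd_bl_sd`,
#'   `swedd_fu_mean`, `swedd_fu_sd`. SBR is unitless.
#' @export
sbr_reference_parameters <- function() {
  # region, PD BL m, sd, PD FU m, sd, SWEDD BL m, sd, SWEDD FU m, sd
  tab <- rbind(
    c("left_dorsal_caudate",      1.34, 0.43, 1.01, 0.44, 1.59, 0.55, 1.69, 0.58),
    c("right_dorsal_caudate",     1.44, 0.45, 1.15, 0.47, 1.77, 0.70, 1.72, 0.61),
    c("left_dorsal_putamen",      1.34, 0.48, 0.98, 0.37, 2.33, 0.73, 2.29, 0.55),
    c("right_dorsal_putamen",     1.33, 0.49, 1.03, 0.44, 2.25, 0.74, 2.34, 0.50),
    c("left_ventral_striatum",    1.16, 0.44, 0.85, 0.36, 1.52, 0.54, 1.60, 0.59),
    c("right_ventral_striatum",   1.22, 0.47, 0.87, 0.37, 1.50, 0.59, 1.63, 0.60),
    c("left_amygdala",            0.31, 0.16, 0.33, 0.17, 0.56, 0.48, 0.48, 0.19),
    c("right_amygdala",           0.36, 0.20, 0.29, 0.16, 0.53, 0.50, 0.49, 0.19),
    c("left_hippocampus",         0.29, 0.11, 0.29, 0.10, 0.47, 0.35, 0.41, 0.12),
    c("right_hippocampus",        0.30, 0.12, 0.29, 0.12, 0.46, 0.33, 0.41, 0.14),
    c("left_parahippocampus",     0.16, 0.10, 0.17, 0.11, 0.34, 0.45, 0.25, 0.10),
    c("right_parahippocampus",    0.17, 0.12, 0.15, 0.12, 0.31, 0.50, 0.24, 0.11),
    c("left_insula",              0.36, 0.14, 0.29, 0.13, 0.47, 0.21, 0.50, 0.21),
    c("right_insula",             0.34, 0.11, 0.29, 0.10, 0.45, 0.16, 0.48, 0.19),
    c("left_olfactory",           0.38, 0.22, 0.31, 0.24, 0.48, 0.24, 0.47, 0.30),
    c("right_olfactory",          0.39, 0.24, 0.30, 0.23, 0.48, 0.28, 0.44, 0.27),
    c("left_anterior_cingulate",  0.21, 0.10, 0.17, 0.11, 0.18, 0.15, 0.18, 0.12),
    c("right_anterior_cingulate", 0.22, 0.10, 0.18, 0.11, 0.17, 0.14, 0.20, 0.13),
    c("left_middle_cingulate",    0.25, 0.12, 0.21, 0.12, 0.28, 0.11, 0.29, 0.13),
    c("right_middle_cingulate",   0.25, 0.12, 0.23, 0.12, 0.29, 0.12, 0.30, 0.15),
    c("left_postcentral",         0.07, 0.07, 0.04, 0.06, 0.05, 0.06, 0.05, 0.06),
    c("right_postcentral",        0.06, 0.05, 0.05, 0.07, 0.06, 0.07, 0.06, 0.07),
    c("right_precentral",         0.16, 0.12, 0.15, 0.12, 0.17, 0.12, 0.16, 0.11),
    c("left_precentral",          0.15, 0.11, 0.14, 0.11, 0.16, 0.10, 0.16, 0.11)
  )
  out <- data.frame(region = tab[, 1], stringsAsFactors = FALSE)
  num <- apply(tab[, -1], 2, as.numeric)
  colnames(num) <- c("pd_bl_mean", "pd_bl_sd", "pd_fu_mean", "pd_fu_sd",
                     "swedd_bl_mean", "swedd_bl_sd", "swedd_fu_mean",
                     "swedd_fu_sd")
  cbind(out, as.data.frame(num))
}

#' Dopaminergic pathway network definitions
#'
#' Node sets for the two molecular-connectivity networks. Each bilateral
#' region appears left then right. The nigrostriatal network covers the
#' striatal subdivisions plus the pre- and postcentral gyri (10 nodes); the
#' mesocorticolimbic network covers the ventral striatum and limbic/cortical
#' targets (16 nodes). Node membership is configuration, not a constraint:
#' pass `rois` to override.
#'
#' @param name `"nigrostriatal"` or `"mesocorticolimbic"` (ignored if `rois`
#'   is given together with a custom `name`).
#' @param rois Optional character vector of ROI (panel column) names, at
#'   least 3, overriding the default node set.
#' @return An object of class `network_definition`: list with `name` and
#'   `rois`.
#' @examples
#' network_definition("nigrostriatal")$rois
#' @export
network_definition <- function(name = c("nigrostriatal", "mesocorticolimbic"),
                               rois = NULL) {
  if (is.null(rois)) {
    name <- match.arg(name)
    stems <- switch(name,
      nigrostriatal = c("dorsal_caudate", "dorsal_putamen",
                        "ventral_striatum", "precentral", "postcentral"),
      mesocorticolimbic = c("ventral_striatum", "anterior_cingulate",
                            "middle_cingulate", "olfactory", "insula",
                            "amygdala", "hippocampus", "parahippocampus"))
    rois <- as.vector(t(outer(stems, c("left", "right"),
                              function(s, h) paste0(h, "_", s))))
  } else {
    name <- if (length(name) == 1L) name else "custom"
  }
  if (length(rois) < 3) stopf("a network needs at least 3 ROIs")
  if (anyDuplicated(rois)) stopf("duplicated ROI in network definition")
  structure(list(name = name, rois = rois), class = "network_definition")
}
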