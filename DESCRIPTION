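Package: datspect
Title: Semi-Quantitative Analysis of Dopamine Transporter SPECT Imaging
Version: 0.1.0
Authors@R:
    person("datspect", "developers", email = "datspect@example.org",
           role = c("aut", "cre"))
Description: Tools for semi-quantitative analysis of 123I-FP-CIT (DAT) SPECT
    brain imaging: regional specific binding ratio (SBR) quantification
    against an occipital reference region, single-subject voxel-wise
    depletion screening with cluster-extent thresholding, group-level
    voxel-wise general linear models with permutation-based cluster
    family-wise-error correction, ROI-level (M)ANCOVA and two-timepoint
    longitudinal contrasts, partial-correlation molecular connectivity with
    Fisher-z group comparison, and spatial correlation of regional
    alteration z-scores with neurotransmitter template maps. Includes a
    synthetic cohort and 3-D phantom generator so every stage can be
    exercised and calibrated without access-controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    MASS,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    lme4
Config/testthat/edition: 3
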