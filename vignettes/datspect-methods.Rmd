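---
title: "datspect: models, conventions and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{datspect: models, conventions and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`datspect` implements a semi-quantitative analysis chain for dopamine
transporter (DAT) SPECT imaging with ^123^I-FP-CIT: regional specific
binding ratio (SBR) quantification, single-subject voxel-wise depletion
screening, group voxel-wise statistics with permutation-based cluster
family-wise-error (FWE) control, ROI-level (M)ANCOVA and a two-timepoint
longitudinal contrast, partial-correlation "molecular connectivity" with
Fisher-z group comparison, and spatial correlation of regional alteration
z-scores against neurotransmitter template maps. Because the patient data
such analyses are normally run on (e.g. PPMI) are access-controlled, the
package ships a synthetic cohort and 3-D phantom generator that reproduces
the statistical structure every downstream stage assumes; all tests and the
acceptance report run against synthetic data only.

Out of scope by design: MRI segmentation and parcellation (label atlases
are inputs), image registration and spatial normalization (volumes and
atlases must already share a grid; no resampling is performed),
partial-volume-effect correction, random-field-theory cluster correction,
mixed-effects fitting beyond two timepoints, and raw SPECT
projection/reconstruction physics.

# The SBR model

For an uptake volume and an integer-labeled atlas, the specific binding
ratio of region $r$ is

$$\mathrm{SBR}_r = \frac{\overline{u}_r}{\overline{u}_\mathrm{ref}} - 1,$$

where $\overline{u}$ is the mean over the region's finite voxels and the
reference is the union of all atlas regions flagged `is_reference` (the
lateral superior occipital cortex in the default atlas). The parametric
image maps every voxel $v \mapsto v/\overline{u}_\mathrm{ref} - 1$, so the
regional mean of the parametric image equals the regional SBR exactly. SBR
is invariant to global intensity scaling; this is asserted as an exact test.
`NaN` voxels are excluded from means; negative voxels (reconstruction
artifacts) are retained, with a warning when they exceed 1% of a region.
No partial-volume correction is applied. Voxel indices in all reports are
1-based, the R convention.

# Synthetic cohort generator

The generator is a first-class module, not a fixture. Per group, baseline
and follow-up ROI vectors are drawn jointly from a multivariate normal:
across ROIs the correlation matrix $R$ is derived from a planted
partial-correlation structure (below; identity if none), across timepoints
each ROI has within-subject correlation $\rho_t$, and the joint covariance
is $D\,(T \otimes R)\,D$ with $T = \begin{pmatrix}1 & \rho_t\\ \rho_t &
1\end{pmatrix}$ and $D$ the diagonal of baseline and follow-up SDs — a
positive-definite construction by the Kronecker structure.

Defaults are the published regional means and SDs for de-novo PD and SWEDD
patients at baseline and two-year follow-up
(`sbr_reference_parameters()`), e.g. left dorsal putamen 1.34 (0.48) for
PD and 2.33 (0.73) for SWEDD at baseline. Choices where no published value
exists, fixed once and documented:

* **Healthy controls**: regional HC values are not published; the
  convention is SWEDD baseline means inflated by 10% with SWEDD SDs and a
  flat trajectory. This is a synthetic stand-in, not an estimate of real
  HC values, and is overridable in the configuration.
* **Within-subject correlation** $\rho_t = 0.7$: unpublished; chosen so
  change-score tests are well powered at the study's sample sizes.
* **Covariates**: age 63.4 (8.2) years for all groups; 37% female;
  UPDRS-III 18.5 (6.87) for PD, 15.1 (9.11) for SWEDD, and 1.0 (1.0) for
  HC (unpublished, synthetic convention). Covariates are drawn as plain
  normals (no truncation at zero; they serve as nuisance regressors only).
  Age advances 2 years at follow-up; UPDRS-III is held at its baseline
  draw.

**Planted partial correlations.** A target partial-correlation matrix
`pc` is converted to a correlation matrix by building the precision matrix
$P$ with unit diagonal and off-diagonal $-\mathrm{pc}_{ij}$, inverting,
and rescaling (`pcor_to_cor()`). Because partial correlations are
scale-invariant, the partial-correlation matrix implied by the result is
exactly `pc`; the generator and the estimator are therefore mutually
consistent, which the recovery tests exploit. If $P$ is not positive
definite it is repaired by adding the smallest $\varepsilon I$ with
$\varepsilon \in 10^{-8}\cdot 2^k$ that lifts the minimum eigenvalue above
$10^{-10}$, with a warning.

All randomness flows from one integer seed; module-level sub-seeds are
derived deterministically from it, so identical configurations are
bit-reproducible.

# Phantom generator

Regions are axis-aligned ellipsoids on a 64³ grid of 3 mm voxels (the
occipital reference is a posterior slab); striatal regions are larger
(~370 voxels) than cortical/limbic ones (~180), so each clears the
100-voxel cluster rule. Voxels of region $r$ hold
$(\mathrm{SBR}_r + 1)\cdot\mathrm{ref}$, background and reference hold
$\mathrm{ref}$ (default 100), then Gaussian smoothing (default FWHM 6 mm,
separable kernel with edge renormalization) and additive Gaussian noise
(default SD 5% of the reference level) are applied, in that order. The
label atlas is exact and unsmoothed.

What the phantom does *not* emulate: spatially correlated reconstruction
noise, scanner/site effects, atrophy, head motion, and
registration error. Two consequences matter for interpreting green tests:

* **Boundary dilution.** Smoothing a region of effective radius $R$ with
  kernel SD $\sigma$ dilutes its mean by roughly
  $3\sigma/(R\sqrt{2\pi})$ — about 20% for a 300-voxel region at 6 mm
  FWHM. Regional SBR from smoothed phantoms is therefore biased toward
  zero exactly as real partial-volume effects bias it, and the recovery
  test uses a large target (~7000 voxels, predicted bias ~8%) to keep the
  10% recovery bound meaningful. Round-trip exactness is asserted at zero
  smoothing and noise.
* **Cohort heterogeneity vs scan noise.** With published between-subject
  SDs (e.g. 0.73 on a SWEDD putamen mean of 2.33), a subject's whole
  region moves coherently relative to controls, so the single-case t-map
  flags entire regions at the exact per-region rate $\alpha$, and the
  >100-voxel cluster rule provides no additional protection: the
  striatal familywise false-positive rate is $1-(1-\alpha)^6 \approx
  26\%$ under the default independent-ROI structure, and a deterministic
  40% putamen reduction is not reliably detected (power $\approx$ 0.6).
  In the scan-noise-dominated regime (homogeneous cohort), suprathreshold
  voxels are spatially independent at ~5% occupancy — below the ~9.7%
  site-percolation threshold of 26-connectivity — so the cluster rule
  drives the false-positive rate to ~0 and a 40% reduction is always
  detected. The test suite asserts the favorable bounds in the regime
  where they hold and checks the heterogeneous regime against the exact
  analytic rates. Real screening performance sits between the two regimes
  and depends on the true HC between-subject dispersion.

# Single-subject screening

A scan is compared voxel-wise to $n$ controls with the Crawford–Howell
single-case t,

$$t = \frac{x - \bar{m}}{s\sqrt{1 + 1/n}}, \qquad \mathrm{df} = n - 1,$$

algebraically identical to a pooled-variance two-sample t-test with one
observation in the first group (asserted to 1e-10 against `t.test`).
Depletion is tested one-sided by default; a two-sided option exists. An
SPM-like implicit mask retains voxels whose control mean exceeds 10% of
the global control mean (configurable; the imaging literature rarely
states this step, so it is exposed rather than hard-coded). Suprathreshold
voxels at $p < 0.05$ are grouped by 26-connectivity (6/18 selectable) and
clusters must exceed 100 voxels *strictly*; a screen is positive when a
retained cluster overlaps any striatal atlas region by at least one voxel.
Age is not covaried at single-subject level.

# Group statistics

Voxel-wise contrasts use per-voxel OLS with a t statistic for the
requested contrast; with two groups and no covariates this reduces exactly
to the pooled two-sample t. Cluster-level FWE control is by permutation:
clusters are formed at voxel $p < 0.005$ (the conventional
cluster-forming reading of a "p = 0.005, FWE-corrected at the cluster
level" threshold; both knobs are exposed), the null distribution of the
maximum cluster extent is built by Freedman–Lane permutation (reduced-model
residuals are permuted and the reduced-model fit added back — the standard
scheme when nuisance covariates are present), and each observed cluster
gets $p_\mathrm{FWE} = (1 + \#\{M^* \ge m\})/(B + 1)$. Random-field-theory
correction is deliberately not implemented; permutation is exact under
exchangeability and testable at desk scale. When fewer distinct
permutations than requested exist they are all used, with a warning.

ROI-level analysis is ANCOVA per ROI (group effect as a partial F after
age, sex and UPDRS-III; adjusted means at the grand covariate means), with
a Wilks'-lambda MANCOVA option across a named ROI set. Raw p-values are
reported; a Benjamini–Hochberg column is optional, matching the
uncorrected reporting convention of the regional tables this mirrors.

The longitudinal contrast compares follow-up-minus-baseline change scores
between groups with a pooled two-sample t. At exactly two timepoints this
equals the group-by-time interaction test of a random-intercept mixed
model: writing $y_{its} = \mu + \beta_1 g_i + \beta_2 t + \beta_3 g_i t +
b_i + \varepsilon_{its}$, the within-subject difference eliminates $b_i$
and leaves $\Delta_i = \beta_2 + \beta_3 g_i + (\varepsilon_{i2} -
\varepsilon_{i1})$, whose two-group comparison is precisely the
$\beta_3$ test; the suite confirms the equality numerically against an
`lme4` REML fit. More than two timepoints are out of scope.

# Molecular connectivity

"Partial correlation" is the *full* partial correlation: for nodes $i, j$
of a $p$-node network, all remaining $k = p - 2$ nodes are controlled,
computed from the inverse sample correlation matrix,
$r_{ij\cdot} = -\Omega_{ij}/\sqrt{\Omega_{ii}\Omega_{jj}}$. An independent
residualization estimator (correlate the residuals of each node regressed
on all others) is provided and asserted to agree to 1e-10. Edge p-values
use $t = r\sqrt{(n-2-k)/(1-r^2)}$ with $\mathrm{df} = n-2-k$. Groups are
compared per edge on the Fisher scale,

$$Z = \frac{z_A - z_B}{\sqrt{\frac{1}{n_A - k - 3} + \frac{1}{n_B - k - 3}}},$$

with the $k$-corrected variance by default (standard for partial
coefficients and less anticonservative; the classic $1/(n-3)$ variant is
selectable). An edge is "altered" at two-tailed $p < 0.01$, uncorrected
(a BH column is emitted); alteration percentages of two patient groups are
compared with a 2×2 Pearson chi-squared test without continuity
correction. The default node sets — nigrostriatal: striatal subdivisions
plus pre-/postcentral gyri (10 nodes); mesocorticolimbic: ventral striatum
plus limbic/cingulate/insular/olfactory targets (16 nodes) — are
configuration, not assumptions: exact published node membership is not
fully recoverable, so any ROI list of three or more panel columns is
accepted.

The within-group significance threshold ($p < 0.01$) describes networks;
the altered-edge determination applies the between-group Z-test to *all*
edges by default, with an option to restrict to edges significant within
either group.

# Neurotransmitter template mapping

Regional alteration z-scores follow the JuSpace convention,
$z_i = (\bar{x}_{\mathrm{pat},i} - \bar{x}_{\mathrm{ctl},i}) /
s_{\mathrm{ctl},i}$, and are rank-correlated (Spearman, average ranks for
ties) with region-level template values. Inference permutes group labels,
recomputing the z-vector and correlation each time, two-sided on
$|\rho|$: $p = (1 + \#\{|\rho^*| \ge |\rho_\mathrm{obs}|\})/(B+1)$, never
exactly zero. "Adjusted" p-values are Benjamini–Hochberg across the
supplied templates; spatial-autocorrelation-preserving nulls (spin tests)
are out of scope, which is the main divergence candidate from
toolbox-specific "adjusted" values. The bundled DAT/SERT templates are
synthetic toy values (named `*_synthetic.tsv`); real template maps are
user-supplied.

# Numerical and interface conventions

* Tolerances: oracle equivalences at 1e-10; exact identities
  (scale invariance, round trips) at machine precision; stochastic
  calibrations at fixed seeds with Monte-Carlo error bands.
* Degenerate inputs: zero control variance yields `NA` (masked) voxels in
  single-case maps and infinite flagged t in paired maps; constant
  covariates are dropped with a warning; singular correlation matrices
  error with a pointer to the pseudo-inverse option.
* Cluster labels are ordered by decreasing size and FWE p is monotone in
  extent by construction. Connected components are computed via an
  adjacency edge list and `igraph`; tests verify against a brute-force
  flood fill.
* File formats: NIfTI-1 single-file volumes (a minimal built-in
  reader/writer; no external imaging dependency), TSV panels serialized at
  17 significant digits for lossless round trips, YAML configurations for
  the CLIs.

# Known limitations

* The HC +10% convention and the synthetic templates are stand-ins; no
  quantity derived from them should be read as an estimate of real-cohort
  values.
* Under published between-subject dispersion the single-subject screen's
  error rates are governed by cohort heterogeneity, not scan noise (see
  above); published screening performance figures are not reproducible
  from the generator's stated world, and the corresponding headline counts
  (e.g. reclassified-case totals) are not acceptance targets.
* The between-group edge Z-test at the published sample sizes has analytic
  power ~0.34 for a 0.5-vs-0 planted partial correlation at
  $\alpha = 0.01$; a stated 60% recovery figure for that configuration is
  unattainable and the corresponding acceptance check is left failing by
  design, with the Monte-Carlo estimate reported.
* Permutation FWE assumes exchangeability under the reduced model;
  heteroscedastic groups violate it mildly (Freedman–Lane is
  asymptotically robust but not exact).
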