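---
title: "Local radiomics for radioresistant sub-volume detection: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local radiomics for radioresistant sub-volume detection: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(localradiomics)
```

## The problem

Local recurrences after radiochemotherapy of head-and-neck squamous cell
carcinoma tend to originate in sub-volumes of the primary tumor that harbor
radioresistant clones. If those sub-volumes could be identified on the
*pretreatment* planning CT, they could be targeted with a higher focal dose
(dose painting). `localradiomics` implements a complete analysis chain for
this question: it quantifies the density texture of tumor sub-volumes with a
fixed vocabulary of radiomic features, labels sub-volumes by their overlap
with a recurrence region transferred from follow-up imaging, and trains
logistic classification models that differentiate (bi-regional design) or
detect (local designs) recurrent sub-volumes.

Three study designs are supported:

1. **Bi-regional**: two regions per patient — the overlap of the recurrence
   with the gross tumor volume (GTVrec) and the remainder (GTVcontrol) —
   and a classifier that differentiates them.
2. **Local, fixed count**: the GTV is split into 8 octants around its
   center of mass; the task is detection without knowledge of the
   recurrence location.
3. **Local, fixed size**: a 5×5×5-voxel grid with optimized placement
   tiles the GTV; cells with at least 25 ROI voxels are analyzed in
   patient-level leave-one-out cross-validation.

## Preprocessing

Volumes are resampled to cubic 3.3 mm voxels (trilinear for images,
nearest-neighbor for masks; corner-aligned output grid covering the input
extent), and analysis is restricted to the soft-tissue window of
**-20 to 180 HU**, both bounds inclusive. Out-of-ROI and out-of-window
voxels carry a missing marker and are invisible to every feature
calculation. Regions with fewer than **27** analyzable voxels (a 3×3×3
neighborhood) are excluded. Slices affected by metal artifacts can be
cleared from a mask by index; artifact detection itself is out of scope.

The recurrence region may be delineated externally or derived from a
PET-like volume with `segment_relative_threshold()` (voxels at or above
40% of the maximum), applied to whatever scalar volume is supplied.

## The feature vocabulary

The extractor computes exactly **161 features**: 18 statistics of the raw
HU values plus 7 features of the discretized gray-level histogram
(25 intensity features), and 136 texture features — 25 co-occurrence (GLCM)
features in two aggregations (per-direction *averaged* and *merged*
matrices over the 13 unique 3D directions at Chebyshev distance 1), 16
run-length (GLRLM) features in the same two aggregations, 16 size-zone
(GLSZM), 16 distance-zone (GLDZM), 5 neighbourhood gray-tone difference
(NGTDM) and 17 neighbouring gray-level dependence (NGLDM) features, the
latter four families computed with 26-connectivity. Shape features are
deliberately absent: sub-volume shape is an artifact of the partitioning,
not of tumor biology.

Numerical conventions (fixed, and needed for constant or degenerate
regions to yield finite vectors):

* Discretization uses a fixed bin width of **5 HU** anchored at the window
  lower edge, giving Ng = 41 levels for every region of every patient.
  A window-anchored scheme — rather than region-wise min/max — is what
  makes features comparable across sub-regions, which local analysis
  requires.
* Population (divide-by-*n*) moments; skewness and excess kurtosis of a
  zero-variance region are 0; correlation-type GLCM features of a
  single-level region are 1; 0/0 ratios from empty counts are 0.
* Percentiles use linear interpolation between order statistics
  (`quantile(type = 7)`) everywhere, including the classification cut-off.
* Zone distance is the Chebyshev distance to the ROI border (missing
  voxels and the volume edge count as border, minimum 1). The NGLDM
  dependence axis is the same-level neighbour count plus one, keeping
  low-dependence weights finite; the coarseness parameter is α = 0.
* A run is broken by a missing voxel; merged run matrices normalize run
  percentage by 13 × the voxel count.

## Sub-volume partitioning

`partition_fixed_count()` cuts three axis-aligned planes through the
rounded center of mass; a voxel whose index equals the center coordinate
goes to the upper half. All 8 octants stay in the partition (empty ones
flagged), and octants below the 27-voxel minimum are dropped from feature
tables with a logged reason. `partition_fixed_size()` searches all 5³ grid
offsets exhaustively and keeps the placement covering the most ROI volume
in retained (≥ 25 ROI voxels) cells; ties prefer fewer, larger cells, then
the lexicographically smallest offset. Sub-regions never overlap.

A sub-region is labeled **recurrent** when *strictly more than 50%* of its
ROI voxels lie in GTVrec (the denominator is the sub-region's ROI voxels,
not the full grid cell, since only ROI voxels are analyzed — a switchable
reading, as the alternative is defensible too).

## The selection and classification cascade

1. **Voxel-count filter**: features with |Pearson r| > 0.5 against the
   region voxel count are excluded (size-confounded), as are constant
   features.
2. **Component retention**: features are z-scored and the eigenvalues of
   their correlation matrix compared against 1000 column-permutation null
   tables (parallel analysis, 95th percentile criterion, seeded).
3. **Grouping**: every feature joins the retained component with the
   largest |Spearman ρ| to the component scores.
4. **Representatives**: per group, univariate logistic fits score each
   feature; the largest-AUC feature among those with likelihood-ratio
   p < 0.05 represents the group. A likelihood-ratio rather than Wald test
   is used because the Wald statistic degenerates under perfect separation
   (Hauck–Donner), which small radiomic cohorts regularly produce.
5. **Backward AIC**: multivariable logistic regression starting from all
   representatives, iteratively removing the variable whose removal most
   decreases AIC. Fits are ridge-stabilized (penalty 10⁻⁶ on slopes) so
   separation cannot derail the elimination; reported likelihoods and AIC
   are unpenalized quantities at the fitted coefficients.
6. **Cut-off**: the 75th percentile of training predictions; a region at
   or above it is classified recurrent (the top training quartile).

Confidence intervals for AUCs use **2000 stratified bootstrap replicates**
(resampling within each class, percentile interval). The AUC itself is the
rank/Mann–Whitney statistic with ties counted ½; constant predictions give
AUC 0.5. In `loocv_patient()` the *entire* cascade is rerun inside each
training fold — no leakage — and only patients contributing both sub-region
classes enter, with exclusions logged. Sub-regions of one patient are
treated as independent rows — the convention this package reproduces; an
acknowledged limitation, not corrected here.

## The synthetic phantom and what it does (not) show

Patient imaging for this problem is not publicly available, so the package
ships a generator whose defaults mirror the emulated clinical scenario: cohorts of
28 training and 12 validation patients; ellipsoidal GTVs with per-axis
semi-axes drawn from 10–28 mm (the order-of-magnitude volume spread of
clinical primaries — essential, because with near-constant tumor size the
region voxel count would be a trivial label surrogate); a recurrent
fraction of the GTV drawn log-uniformly from 2%–71% (seed-reproducible,
mean ≈ 20%); tumor texture as spatially correlated Gaussian noise (SD 15 HU,
4 mm correlation length, mean 90 HU) in a distinct background, with ≥ 95%
of GTV voxels inside the HU window.

The recurrence is an **ellipsoid cap** — the part of the GTV on one side of
a plane — so recurrent and control regions are geometrically comparable
pieces of one body. Heterogeneity is **additive**: inside the cap an
independent 2 mm-correlation field is added with amplitude
`control_sd * sqrt(effect_size² − 1)`, making the voxel SD ratio equal to
the effect size and the construction continuous at effect size 1. At
effect size 1 the phantom is an exactly null tumor: one stationary texture
with an arbitrarily labeled cap, no seam.

What passing tests on these phantoms shows: the chain recovers a planted
second-order (variance/correlation-length) heterogeneity difference through
resampling, windowing, discretization, partitioning, and the full selection
cascade, and does not invent one under the exact null *in the local
designs*. What it does not show: robustness to scanner effects, contrast
timing, delineation error, registration error, or non-Gaussian tissue
texture — none of which the phantom emulates.

**A deliberate finding kept visible.** Under the exact null the
*bi-regional* design still reaches validation AUCs far above chance. This
is structural, not a bug: with recurrent fractions below 50%, GTVcontrol is
almost always the larger complement of the same tumor, and features with
monotone finite-sample size bias (minimum, joint maximum, cluster
prominence) or surface sensitivity survive a linear |r| ≤ 0.5 voxel-count
filter, carrying reproducible label signal without any texture difference.
The local designs are immune because sub-region geometry there does not
depend on the label. This is a caveat worth remembering when interpreting
bi-regional radiomics AUCs as pure texture signal.

## Problem sizes used in the shipped checks

Cohort-level checks run at the default 28/12 cohort size with 3 seeds per
condition (effect sizes 1, 1.5, 2, 3), LOOCV demonstrations on 14-patient
cohorts, parallel analysis at its 1000-permutation default in pipelines and
200–300 permutations in unit tests, and bootstrap coverage at 400 inner ×
200 outer replicates; these sizes are the package's choice of a
demonstration scale. The oracle suite re-derives every texture matrix from
naive coordinate loops on 200 random volumes with missing voxels.

## Known limitations

* Texture features are estimated on as few as 25–27 voxels; estimates at
  that size are noisy by construction (the very motivation for the
  minimum-volume rules).
* DICOM/DICOM-RT ingestion, rigid registration, SUV computation, and
  artifact detection are out of scope; inputs are NIfTI volumes on a
  shared grid.
* The fixed-count scheme's octant geometry and several unstated details of
  the original method (discretization, percentile rule, aggregation of the
  reported "GLRLM gray level non-uniformity") are pinned to documented
  defaults and exposed as configuration.
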