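---
title: "Methods: stratifying preclinical vascular dementia in SVD MRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stratifying preclinical vascular dementia in SVD MRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svdstrat)
```

## The scientific problem

In symptomatic cerebral small vessel disease (SVD) — lacunar stroke with
confluent white-matter hyperintensities (WMH) — a minority of patients
convert to clinically diagnosed dementia within a few years. `svdstrat`
implements the analysis chain used to characterize that preclinical phase
from baseline and longitudinal structural MRI: whole-brain volumetrics and
a composite vascular-burden marker, lesion mapping, voxel-wise group
statistics, supervised prediction of conversion, unsupervised anatomical
subtyping of the convertors, and survival analysis stratified by prediction
and burden.

All imaging enters in a single shared template space as 3-D scalar lattices
(`volume()` objects) with isotropic voxels: tissue probability maps
(GM/WM/CSF/WMH), binary lacune masks, Jacobian determinant maps of the
template deformation, and per-time-point divergence maps describing local
expansion/contraction relative to each subject's mid-point average anatomy.
Registration itself is out of scope: the package consumes its outputs.

## Volumetrics and SVDp

Tissue volume is the count of voxels at or above a probability threshold
times the voxel volume. Thresholds: 0.2 for GM, WM and CSF; the WMH map is
binarised at a per-subject threshold (default 0.5), standing in for the
manually chosen per-subject cutoffs used when segmenting confluent lesions.
Total cerebral volume is `TCV = GM + WM + WMH` and `TIV = TCV + CSF`. The
package builds TCV from the same binarised WMH volume it reports, so the
row identity `tcv = gm + wm + wmh` holds exactly in every output table.

`SVDp = 100 · WMH / TCV` expresses lesion load relative to the (shrinking)
brain, so a static lesion inside an atrophying brain does not masquerade as
lesion regression. Note that a ratio-of-means differs from a mean-of-ratios:
per-subject SVDp values are averaged, and group-mean WMH divided by
group-mean TCV will not reproduce that average exactly.

Annualized rates of change are ordinary-least-squares slopes on time in
years over all available visits — with two time points this reduces to the
difference quotient.

## Voxel-wise statistics

Baseline maps are Jacobian-modulated (multiplying density by the local
volume-change factor makes the quantity volume-preserving), smoothed with a
separable 6 mm FWHM Gaussian (`sigma = fwhm / (2 * sqrt(2 * log 2))` per
axis, kernel truncated at 4 sigma, renormalized to unit sum, zero padding),
and restricted to an analysis mask of voxels whose cohort-mean value
exceeds 0.1 — the masking rule of the original toolchain is undocumented,
so this explicit rule is the package's own documented stand-in.

At every in-mask voxel an OLS model of value on a group indicator,
covariates (age, sex, lacune volume, TIV, NART) and an intercept gives
`t = c'beta / sqrt(sigma2 * c'(X'X)^-1 c)`. Voxels with zero residual
variance get `t = 0` and are flagged and excluded from the maximum
statistic. One-sided contrasts are run in both directions, since deficits
and excesses are reported separately.

Family-wise error is controlled by max-statistic permutation with
Freedman–Lane residualization rather than random-field theory: RFT needs
smoothness-estimation machinery tangential to the claims being tested,
whereas the permutation scheme has an exactly testable contract. Data are
residualized against the nuisance design, residual rows are permuted and
added back to the nuisance fit, the full model is refit, and the maximum t
over admissible voxels forms the null distribution:
`p_FWE(v) = (1 + #{max-t* >= t(v)}) / (1 + B)`, so `p_FWE >= 1 / (1 + B)`
always. With an intercept-only nuisance this reduces to the exact
label-permutation test. Results are displayed at both uncorrected
p < 0.001 and FWE p < 0.05, with 26-connected cluster tables.

## Longitudinal rate maps

The divergence maps of one subject are fit voxel-wise against scan time;
the slope map is the rate map (fractional volume change per year, treating
divergence as log-volume change). Whether the original fit included an
intercept is not stated; because the mid-point convention makes the
intercept near zero, one is fitted and reported. Rate maps can be
tissue-weighted (voxel-wise product) and smoothed by the warped weighted
average `WWA(f; w) = smooth(f·w) / smooth(w)`, masking out voxels whose
smoothed weight falls below `eps = 1e-5`. The WWA construction is cited in
the literature without a formula; weight-normalized Gaussian smoothing is
the standard reading and is recorded here as an interpretation.

## Prediction

Conversion is decoded from baseline maps by a soft-margin linear SVM
(`e1071::svm`, cost 1 — "default hyperparameters") under leave-one-out
cross-validation. In each fold, per-feature confound-regression
coefficients (age, sex, TIV, NART, with intercept) and feature means are
estimated on the training rows only and applied to all rows; appending
confounds as extra features was rejected because it would let the
confounds drive the kernel. Labels are predicted at decision threshold 0;
class imbalance is addressed only through reporting balanced accuracy.
Undefined ratios (zero denominators) are reported as missing, never as 0.
The AUC is the rank-based estimator with half credit for ties.
Permutation significance reruns the entire pipeline (confound regression,
centering, SVM) per label permutation — conservative relative to permuting
inside a fixed residualization. Pooled sensitivity/specificity define the
reported balanced accuracy; per-fold averaging, which some toolboxes use,
can differ in the second decimal.

## Subtyping

Convertors are clustered on their in-brain Jacobian vectors: subjects ×
subjects Pearson correlation, then Euclidean distance between the rows of
that correlation matrix (the literal construction, self-correlation
entries included; a `1 - r` dissimilarity is available behind a flag), then
Ward linkage. "Ward" is convention-ambiguous; the Ward.D2 variant (squared
Lance–Williams update on Euclidean inputs) is used and tagged in the
output, guaranteeing monotone merge heights. The tree is cut at k = 4 by
default — the number of subgroups chosen visually in the motivating
analysis — and the dendrogram is exported so the choice can be inspected.
Cluster labels are renumbered by dendrogram left-to-right order; tied
heights resolve to the earlier merge with a warning.

## Cognition

Domain indices are arithmetic means of available component z-scores
(executive function, processing speed, working memory, long-term memory,
and a global score over all administered tests); missing components are
excluded with a logged count. Longitudinal slopes come from a two-level
linear mixed model (random intercept and slope, unstructured 2×2
covariance, maximum likelihood — the original software's exact
specification is unstated, so ML with unstructured covariance is
implemented and tagged); per-subject OLS slopes are always emitted
alongside, and are the fallback on non-convergence. BLUP shrinkage makes
the LME slope variance at most the OLS slope variance. Baseline group
comparisons use a two-sample t-test for continuous variables and
Kruskal–Wallis for ordinal/bounded ones (MMSE, Rankin by default — the
original per-variable assignment is not itemized, so it is configurable),
Bonferroni-corrected over the tested family (0.05 / 17 ≈ 0.003 for a
17-variable family).

## Survival

Kaplan–Meier product-limit curves with administrative censoring; the
median is the first event time with survival ≤ 0.5, reported as undefined
when never reached. Group differences use the standard log-rank statistic.
The SVDp threshold separating high from low vascular burden is selected by
maximizing Youden's J over the sensitivity/specificity curves (the original
selection criterion beyond "plotting the curves" is unstated; Youden's J
reproduces an operating point of the quoted kind and the choice is logged).
The stratified analysis crosses SVM prediction with burden into four
strata, reporting per-stratum curves and 5-year conversion probabilities
`1 - S(5)`; empty strata are reported as missing rather than errors.

## The synthetic cohort generator

`simulate_cohort()` generates the study conditions the pipeline assumes:

- **Grid**: 32³ voxels at 2 mm isotropic (configurable). Volumes are
  phantom-scale (brain ≈ 68,000 mm³); ratios and contrasts, not absolute
  volumes, are the meaningful quantities.
- **Groups**: 97 non-convertors and 22 planted convertors, the source
  cohort's split.
- **Tissue anatomy**: a deterministic template (CSF rim, GM shell, WM
  core, subcortical GM nuclei, deep-WM ROIs, WMH lesion cores graded
  radially 0.7 → 0.1 and carved out of WM so tissue probabilities sum to
  at most 1), plus voxel-wise Gaussian noise (`noise_sd = 0.05`) clipped
  to [0, 1] and renormalized where the tissue sum exceeds 1.
- **Planted convertor effects**: GM in the left striatum and left
  hippocampus scaled by 1 − 0.15 before noise; +0.2 WMH probability in
  frontal WM (scaled per subtype); left-lateralized lacune excess.
  Lacunes are 2-voxel (16 mm³) in-region clusters with per-region Poisson
  counts, so ROI presence follows `1 - exp(-lambda)` exactly.
- **Subtypes**: four profiles in 5/2/5/10 proportions along two axes —
  vascular burden (WMH multiplier 2.0 → 0.5, lacune multiplier
  2.5 → 0.6) and atrophy (extra hippocampal GM loss 0 → 0.12,
  hippocampal contraction rate 0.005 → 0.040 /y) — with distinct Jacobian
  contraction patterns per subtype. Cognitive intercepts/slopes follow the
  direction, not the magnitude, of the corresponding subgroup gradient.
- **Longitudinal data**: four annual visits with 10 % per-visit dropout;
  divergence maps are `rate × (t - mean(t)) + noise`, honouring the
  mid-point registration convention (the series averages ~0 at the mean
  scan time).
- **Conversion**: exponential event times per subtype hazard
  (0.15 / 0.35 / 0.40 / 0.35 per year), truncated at the 5-year horizon
  for planted convertors so the planted group and the derived `converted`
  flag coincide; the non-convertor hazard defaults to 0. The source data
  report only a mean time to conversion, no per-subtype hazards, so these
  values are illustrative and reproduce only the ordering of onset times;
  a 5-year-truncated exponential cannot reach a conditional mean of
  3.0 y (its conditional mean is below 2.5 y for any hazard), a known
  limitation of the exponential choice.

What the generator does **not** emulate: MR contrast, bias fields, scanner
and session noise, registration error, spatially correlated inter-subject
anatomy, comorbidity structure. Its planted effects are spatially exact and
its noise is voxel-wise independent, which makes the decoding and subtype
recovery tasks much cleaner than on real data: the leave-one-out balanced
accuracy and the adjusted Rand index saturate at the default effect sizes.
Passing those tests demonstrates that the machinery is correct and
calibrated — null calibration of the FWE procedure, the decoder and the
log-rank test are all verified at chance level — not that real cohorts are
this separable.

## Numerical choices and test scale

- All randomness flows from explicit integer seeds; per-subject seeds are
  drawn from the master stream so cohorts with different master seeds share
  no noise fields.
- Smoothing kernels are truncated at 4 sigma and renormalized; lattice
  boundaries use zero padding, so mass is conserved only for interior
  support (the WWA form renormalizes this at the boundary).
- Zero-variance voxels: `t = 0`, flagged, excluded from max-t.
- Permutation p-values use `(1 + count) / (1 + B)`; permutations on which
  a statistic is undefined are dropped with a warning and the denominator
  adjusted.
- Ties: Youden threshold ties resolve to the smallest threshold; AUC ties
  get half credit; tied merge heights resolve to the earlier merge.
- The test suite exercises calibration at sizes chosen for a desk run:
  500 null cohorts (n = 30, 16³ grid, 200 permutations) for FWE
  calibration; 200 permuted-label cohorts and 50 planted-effect replicates
  for the decoder; 50 replicates for subtype recovery; 1,000 exponential
  simulations for log-rank calibration and n = 2,000 for the Kaplan–Meier
  median; 1,000 null runs (119 permutations) for the rate-map contrast.

## Known limitations

- Segmentation, registration, cortical-thickness estimation and lesion
  delineation are upstream of this package and not modelled.
- The exponential conversion-time model cannot match the reported
  conditional mean time to conversion under a 5-year horizon (above).
- ICC terminology in the source is ambiguous ("Pearson's intra-class
  correlation"); both a Pearson consistency coefficient and ICC(2,1)
  absolute agreement are reported, and the "standard error of mean" for
  rater agreement is implemented as the standard error of measurement
  `SD(a - b) / sqrt(2)` — one of two near-identical readings.
- Phantom-scale volumes mean published absolute cohort means cannot be
  reproduced; the pipeline instead verifies the arithmetic identities the
  published tables must satisfy and all engine-level contracts.
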