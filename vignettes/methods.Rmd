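---
title: "Longitudinal prostate mpMRI radiomics: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Longitudinal prostate mpMRI radiomics: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`deltarad` implements a complete longitudinal multiparametric-MRI (mpMRI)
radiomics workflow for prostate cancer radiotherapy follow-up: region
construction from prostate/zone/tumor masks, first-order diffusion (ADC)
statistics, Extended Tofts pharmacokinetics on dynamic contrast-enhanced
(DCE) curves, longitudinal change statistics, and an endpoint-biopsy
prediction procedure with leave-one-out (LOO) evaluation. Because patient
imaging of this kind cannot be redistributed, the package ships a synthetic
digital-phantom cohort generator with the same statistical structure, so the
entire pipeline is exercised and tested end to end without any external
data. This vignette documents the models, the tunable parameters and their
defaults, the numerical choices, and what the synthetic cohort does and does
not establish about real data.

## Regions of interest

Five regions are analyzed per scan, derived from three input masks on a
common grid:

* **GTV** — the gross tumor volume (multifocal lesions are merged by voxel
  union before any geometry, so overlapping per-lesion rings are never
  double-counted);
* **PT-PZ**, **PT-TZ** — the intersection of a peritumoral ring with the
  peripheral zone (PZ) and transition zone (TZ);
* **NAT-PZ**, **NAT-TZ** — normally-appearing tissue: each zone minus tumor
  and ring.

The TZ is the prostate minus the PZ. The peritumoral ring contains every
non-tumor voxel whose centre lies within 5 mm (Euclidean, in physical
millimetres under anisotropic spacing) of a tumor voxel centre. Two open
geometry questions were settled as follows:

* the ring is built in **3-D**, not per slice: "5 mm" is a physical
  distance, and at 3 mm slice thickness a 2-D ring would silently exclude
  the out-of-plane habitat;
* ring voxels **outside the prostate are discarded** — features are only
  ever computed inside prostate tissue, and retaining extra-prostatic voxels
  would contaminate the NAT accounting.

Up to 1% of PZ voxels may fall outside the prostate after resampling
(interpolation slivers); they are clipped, and more than 1% is treated as a
data error. Voxels claimed by both zones resolve to the PZ, where the large
majority of tumors sit. Every derived region set is checked against the
invariants (ring disjoint from tumor, PT-PZ disjoint from PT-TZ, NAT
disjoint from tumor and ring, everything inside the prostate) at
construction time.

## Preprocessing

All volumes are resampled to the analysis grid before geometry: trilinear
interpolation for images (value-preserving for constants and free of
overshoot — quantitative maps should not acquire values outside their input
range, so no higher-order spline by default), nearest-neighbour for masks
(binarity preserved). Volumes are cropped to the prostate bounding box with
10 pixels of in-plane padding; the z range is the prostate extent with no
padding, since the slice direction has no analysis outside the gland. The
crop returns its offset so coordinates map back to the original grid.
DCE frames are resampled like any other image and ROI curves averaged on the
analysis grid.

## First-order ADC features

Eleven statistics per region: the 10/25/50/75/90th percentiles, mean,
standard deviation, skewness, excess kurtosis, minimum and maximum. The
percentile definition is linear interpolation between closest ranks;
kurtosis is reported as excess (normal = 0). The canonical feature list of
this analysis names nine statistics while stating that eleven were used;
minimum and maximum are the two most common remaining first-order members
and fill the gap here, each individually switchable, and the discrepancy is
deliberately surfaced in this paragraph rather than silently resolved.
Skewness and kurtosis of a constant sample are undefined and emitted as
missing (not zero). Regions with fewer than `min_voxels = 10` voxels yield a
missing feature fragment rather than an error — small PT-TZ intersections
are expected and must not abort a cohort run. Feature names follow the
`ROI_Sequence_Feature` convention (`GTV_ADC_90`, `NAT-TZ_ADC_SD`, ...).

## DCE pharmacokinetics

The tissue concentration model is the Extended Tofts model

$$C_t(t) = v_p\,C_p(t') + K^{trans}\!\int_0^{t'} C_p(u)\,
  e^{-k_{ep}(t'-u)}\,du, \qquad t' = t - t_{onset},$$

with $C_p$ the Parker population arterial input function (two Gaussians plus
a sigmoid-gated exponential washout, the published population constants as
defaults, all ten exposed in the configuration). Fitting is performed on the
**ROI-averaged** contrast-time curve, not voxelwise: at the low temporal
resolution typical of prostate DCE (5 s frames here), averaging first is
what keeps compartmental modeling valid, and it is the procedure this
analysis prescribes.

Numerical choices:

* the convolution is evaluated on an internal uniform grid (0.5 s) by an
  exponentially weighted recursion that is *exact* for a piecewise-linear
  AIF; halving the step changes the curve by well under 0.25%;
* the fit is bounded Levenberg–Marquardt over $(K^{trans}, k_{ep}, v_p,
  t_{onset})$, multi-started from a coarse grid of physiologically plausible
  values ($K^{trans} \in \{0.05, 0.2, 0.5\}$ min⁻¹, $k_{ep} \in \{0.25,
  0.8, 2.0\}$ min⁻¹) with the onset start taken from the data; the search
  stops early once residuals reach the noise floor estimated from the
  pre-bolus frames. The fit is deterministic given identical inputs;
* $k_{ep}$ is fitted directly and $v_e = K^{trans}/k_{ep}$ derived, so the
  identity holds by construction; a penalty residual enforces $v_e \le 1$.
  $v_p$ is free with bounds $[0, 0.3]$ — the "extended" term is part of the
  model even though the analysis reports only $K^{trans}$, $k_{ep}$, $v_e$;
* curves are treated as proportional to gadolinium concentration; no
  T1/signal-equation conversion is applied because none is specified for
  this analysis. Absolute $K^{trans}$ units therefore follow the input
  scaling; all recovery tests use self-consistent synthetic curves in mM.

Semi-quantitative features: $t_{onset}$ is the first time the curve exceeds
baseline mean + 3 baseline SDs for 2 consecutive frames (both constants
configurable — no rule is canonical); AUC90 and AUC120 integrate the
baseline-subtracted curve by trapezoid over the 90/120 s following onset.
If no onset is detected the AUCs fall back to $t = 0$ and the curve is
flagged.

## Longitudinal statistics

Percent change is $100\,(v_{new} - v_{ref})/v_{ref}$ with the sign
retained. Scan-point comparisons default to the unpaired pooled-variance
two-tailed t-test — the per-scan cohorts differ in size, so an unpaired
default is the faithful reading — with Welch and paired variants selectable.
No multiple-testing correction is applied in the descriptive report (raw
p-values are the convention this analysis follows); a Benjamini–Hochberg
option exists but is off by default.

## Outcome modeling

Ten comparisons are built: the feature matrices at the four scan points and
the six pairwise differences (Δ radiomics, each restricted to patients
present at both scans, features suffixed `_S2-S1` etc.). Per comparison:

1. **Screen** — univariate logistic regression per feature, likelihood-ratio
   p-value against the intercept-only model; features with p < 0.05 pass.
   Complete separation is detected and flagged, the capped-iteration LRT
   p-value still reported.
2. **Rank and decorrelate** — survivors are ranked by ascending Welch t-test
   p-value between the outcome groups; the greedy loop takes the best
   remaining feature and drops every remaining feature with |Pearson r| >
   0.85 against it, until empty or `max_k = 4` features are selected (4
   matches the model sizes this analysis reports; 0 removes the cap). Ties
   break lexicographically, so selection is deterministic.
3. **Model and evaluate** — unpenalized multivariate logistic regression,
   evaluated by leave-one-out. In the default **flat** mode the selection is
   done once on the full cohort and only the coefficients are refit per
   fold. This mirrors the procedure as described (selection precedes the
   LOO evaluation) and is *optimistically biased*; a fully nested mode
   (selection redone inside every fold) is available for honest error
   estimation. The classification threshold for the confusion matrix is 0.5.

A fold whose training set loses a class falls back to the prior rate with a
warning; an empty selection skips the model with an explicit report, never
silently. F1 is $2\,TP/(2\,TP + FP + FN)$, undefined (missing) when there
are no actual positives.

Two quirks of the prescribed procedure are implemented exactly as stated
rather than "fixed": a logistic screen followed by a *Welch* ranking uses
two different statistics for two roles, and flat LOO leaks selection
information. Both are documented here so nobody mistakes them for accidents.

## The synthetic cohort

The generator is the package's data source and is itself first-class,
tested code. One phantom is a schematic prostate: an ellipsoid (default
semi-axes 24 × 20 × 18 mm) on a 48 × 48 × 16 grid at 1.5 × 1.5 × 3 mm
spacing; the posterior 35% of prostate voxels form the PZ; 1–3 spherical
lesions (default one, 7 mm radius) are placed inside the gland, 85% of
secondary lesions in the PZ. Geometry is schematic on purpose — every
downstream computation depends only on mask topology and intensity
statistics, not anatomy.

Tissue values are anchored to a published reference cohort: baseline ADC
1177.84 ± 217.12 (GTV), 1616.37 ± 304.02 (NAT-PZ), 1381.76 ± 170.34
(NAT-TZ) ×1e-6 mm²/s; $K^{trans}$ 0.12/0.08/0.12 min⁻¹ and $v_e$
0.255/0.228/0.336 with their reported SDs. Per patient, class-level means
are drawn from those between-patient distributions; voxels add Gaussian
noise (SD 150 ×1e-6 mm²/s for ADC, 0.05 mM for DCE — ordinary magnitudes
for 3 T prostate imaging). The DCE series is synthesized **directly in
concentration units** by the same Extended Tofts forward model with the
Parker AIF (onset 20 s, 5 s frames, 300 s duration); no scanner signal
equation is simulated, consistent with the fitting-side choice above.
Longitudinal change is modeled as per-scan multipliers equal to the ratios
of the reference cohort means to baseline, so tumor ADC rises ~16% at three
months while normal-tissue ADC falls, tumor $v_e$ rises and $k_{ep}$
falls — the directions and magnitudes of the reference data. One global
seed expands deterministically into per-patient geometry streams and
per-patient-per-scan noise streams, so any patient-scan can be
rematerialized bit-identically in isolation.

**Endpoint-biopsy labels.** Labels are Bernoulli draws from a logistic rule
on the standardized *true* baseline features, by default $-20 \cdot
z(\text{GTV ADC mean}) - 8 \cdot z(\text{GTV } v_e)$ with the intercept
calibrated so the expected prevalence is 20% (five positives in 25, the
design of the reference study). Three deliberate choices:

* the weights are steep, making class membership a nearly deterministic
  function of the generating features: the generator's role is to provide
  *recoverable* signal for validating the modeling stage, and with only ~5
  positives a shallow rule would drown the coupling in Bernoulli noise;
* ADC and $v_e$ are drawn with within-class correlation 0.5 — both reflect
  tissue cellularity (densely cellular tumors restrict diffusion *and*
  shrink the extravascular-extracellular fraction), and the shared axis is
  also what makes each feature marginally detectable at this sample size.
  With independent draws, two features splitting one unit of standardized
  separation can never both clear a marginal screen in 90% of 25-patient
  cohorts — a power bound, not an implementation limit;
* low ADC carries the risk (negative weight), consistent with the
  literature on post-radiotherapy biopsy prediction, and $v_e$'s weight is
  negative for the same cellularity reasoning.

**Problem sizes.** The default study — 25 patients × 4 scans on the grid
above, and the 50-replicate recovery studies at baseline only — was chosen
so a full cohort pass takes on the order of a minute and the replicate
studies minutes, which is what a routine development cycle tolerates; all
sizes scale up freely through the configuration.

## What the synthetic tests do and do not show

Passing tests establish that the implementation is faithful: geometry
matches brute-force oracles, the forward/fit round trip recovers parameters
to 1% noise-free (median 0.5% at 1% curve noise), zero-noise cohorts return
the generating values through the entire pipeline, label signal planted in
baseline features is found by the selection procedure, and permuted labels
collapse the models to chance. They do **not** show that the procedure
generalizes to real prostate mpMRI: the phantom has no registration error,
no contouring variability, no T2 shine-through or perfusion heterogeneity
within a region, homogeneous tissue classes, and labels truly generated by
a logistic rule on two features. Real-data performance claims require real
cohorts; on small replicate cohorts the permuted-label AUC also sits
slightly *below* 0.5 — the well-known pessimism of leave-one-out on null
data — which is why the negative control is tested as a band around chance
rather than an exact 0.5.

## Known limitations

* No texture or shape radiomics, no T2-weighted intensity features — first
  order only, by scope.
* No voxelwise PK maps and no measured/individual AIFs.
* No inter-sequence or inter-timepoint registration: inputs are assumed
  co-registered, as they are after the upstream manual workflow this
  pipeline mirrors.
* Flat-LOO AUCs are optimistic by construction; use the nested mode for
  unbiased estimates.
* With ~5 positives per cohort, every outcome-model statistic has wide
  sampling variability; single-cohort AUCs should be read alongside the
  replicate-study medians.
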