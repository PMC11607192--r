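---
title: "Whole-body SSTR-PET heterogeneity: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Whole-body SSTR-PET heterogeneity: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(ssthet)
```

## The problem

Patients with metastatic, well-differentiated neuroendocrine tumors
typically carry tens of somatostatin-receptor (SSTR) expressing lesions
across liver, bone, nodes and soft tissue. Peptide receptor radionuclide
therapy (PRRT) targets that receptor, so the *amount* and the *uniformity*
of receptor expression across the whole body are natural candidates for
predicting treatment benefit — and analyses restricted to one or two index
lesions can misjudge both. `ssthet` implements a whole-body analysis: every
lesion in a [68Ga]-DOTA-TATE-like SUV volume is segmented and described by
first-order intensity-histogram features, lesion features are reduced to
patient-level predictors (including explicit inter-lesional heterogeneity
indices), and the predictors are related to 24-month time-to-progression
(TTP) and overall survival (OS) with a penalized Cox workflow whose
discrimination is honestly estimated by optimism correction.

Because no patient data ship with the package, a synthetic cohort module
generates PET phantoms and survival outcomes with *known* ground truth;
every stage of the pipeline is tested against that truth or against
independent oracles.

## Lesion features (intra-lesional indices)

For each lesion the voxel SUV histogram yields 14 indices: volume (ml),
SUVmean, SUVmax, SD of SUV, skewness, kurtosis, CV = SD/mean,
SUVmax/SUVmean, (SUVmax−SUVmean)/SUVmean, receptor expression
(volume × SUVmean), and four liver-normalized quantities —
volume × (SUVmean/liver SUVmean), SUVmean/liver SUVmean,
SUVmax/liver SUVmax and SUVmax/liver SUVmean. Conventions that the source
software of such workflows rarely documents had to be fixed here:

* **SD divisor.** Population SD (divisor *n*) at the voxel level, the
  intensity-histogram convention of the IBSI radiomics standard; the
  divisor is configurable (`sd_divisor`).
* **Kurtosis.** Excess kurtosis (Gaussian = 0), again following IBSI; the
  −3 offset is configurable (`kurtosis_excess`) since vendor software
  varies.
* **Degenerate histograms.** A flat lesion (zero variance) or one with
  fewer than 3 voxels has *missing* skewness and kurtosis rather than 0:
  0/0 is undefined, and silent zeros would bias the across-lesion SD
  summaries toward artificial homogeneity.
* **No intensity discretization.** All indices are continuous-histogram
  statistics; no SUV binning is applied anywhere.

Lesions below **0.524 cc** (the volume of a 1 cm sphere, the scale of
scanner resolution) suffer partial-volume dilution, so they are excluded
from every index *except* total tumor volume and the lesion count, which
deliberately keep all lesions. The boundary is closed: exactly 0.524 cc is
eligible. This split — totals over all lesions, everything else over
eligible lesions — is enforced by `apply_volume_filter()` and tested with
constructed fixtures.

## Patient-level reduction: the 53 predictors

Each of the 14 indices is summarized across a patient's eligible lesions by
mean, max and sample SD (divisor *n*−1; these are statistics *across*
lesions, not voxel histograms) — 42 features. Four totals (volume, lesion
count, receptor expression, liver-corrected expression), three spread
indices (max SUVmax/min SUVmax, max SUVmax − min SUVmean, max of the
per-lesion SUVmax − SUVmean), two cosine heterogeneity indices, and the
liver reference SUVmean/SUVmax complete the set of 53 quantitative
features (`patient_feature_names()`), plus the liver-dominance flag.

Decisions made where the design was genuinely open:

* **Cosine heterogeneity.** Each eligible lesion becomes a vector of the 14
  indices, min–max scaled to [0, 1] **across the cohort's eligible
  lesions** (so components are nonnegative and every pairwise cosine
  dissimilarity lands in [0, 1]); *average tumoral heterogeneity* and
  *maximal tumor divergence* are the mean and max of the n(n−1)/2 pairwise
  dissimilarities within a patient. The feature list and the scaling
  (minmax / zscore / none) are configurable and recorded in the output
  metadata. Features constant across the cohort are dropped with a warning;
  if *all* features are constant the lesions are identical and the indices
  are 0 by construction. Patients with fewer than 2 eligible lesions get
  missing heterogeneity (and missing SD summaries) — never imputed.
* **Liver dominance.** Implemented as liver lesion volume > 50% of total
  lesion volume (threshold configurable). A literal "liver volume greater
  than total volume" condition would be satisfiable only for purely hepatic
  disease; the majority-volume reading is the clinically standard one.
* **Spread indices** use eligible lesions only, and the min in
  "max SUVmax − min SUVmean" is taken over all eligible lesions
  independently of where the max occurs.

## Segmentation

The delineation principle is gradient-based (edges are placed where the SUV
falls fastest, not at a fixed threshold). The package defines a
reproducible star-convex variant:

1. Smooth the volume with an isotropic Gaussian (default σ = 2 mm) and
   hill-climb the seed to the local maximum.
2. Cast 92 quasi-uniform rays (icosphere subdivision, frequency 3,
   configurable) up to 40 mm; on each ray place the boundary at the most
   negative directional derivative of the smoothed profile (1 mm steps,
   trilinear interpolation).
3. Median-filter the boundary radii over the 6 neighboring directions.
4. Correct each radius for blur-induced shrinkage: for a blurred sphere the
   gradient peak sits about σ²/R *inside* the true boundary (verified
   numerically against the closed-form blurred-ball profile). The total
   edge blur σ is estimated per lesion from the peak gradient magnitude via
   the erf-edge relation σ = A/(√(2π)·|f′|), which captures the scanner PSF
   without knowing it; the correction inverts r = R − σ²/R. It can be
   disabled (`curvature_correction = FALSE`), and the uncorrected boundary
   retains the expected monotone degradation with PSF width.
5. Keep voxels whose centers fall inside the star-convex region
   (nearest-ray radius; 0-based indices, world = origin + index × spacing)
   and return the 26-connected component containing the seed.

On the bundled blurred-sphere experiments (radii 8–15 mm, FWHM 6 mm,
automatically detected seeds) this recovers lesions at Dice ≈ 0.95 with
volume errors within a few percent — the acceptance suite requires
Dice ≥ 0.80 and |volume error| ≤ 20%, and the unblurred sphere volume
within one voxel shell of the analytic value. A region with no negative
gradient extremum on at least half the rays is rejected as "not a lesion".
Segmentation is optional: the pipeline's primary path consumes label maps
(ground truth or externally curated), and `detect_candidate_seeds()` /
`segment_lesion()` are validated as a standalone property suite.

Seed detection thresholds at a multiple (default 1.5) of the liver
reference SUVmean — physiologic liver uptake is the classic yardstick for
"definitely lesional" uptake on SSTR PET — or at an absolute SUV fallback
(default 2.0) without a liver reference.

The liver reference itself is a 3 cm spherical VOI centered at the
lesion-free liver voxel deepest inside the organ (maximal erosion depth),
excluding every lesion voxel; if no such sphere fits, all lesion-free liver
voxels are used with a warning.

## Survival analysis

* **Kaplan–Meier** (via `survival::survfit`): product-limit estimates,
  Greenwood variance, pointwise 95% CIs on the log(−log) scale.
* **Univariable screening** (via `survival::coxph`, Efron ties): per
  feature, the hazard ratio per unit with Wald CI, a direction flag
  ("+" when increasing values shorten survival), and Uno's C with a
  two-sided test against 0.50. Each feature uses its own complete cases.
* **Uno's C** is authored in compiled code: pairs (i, j) with an event in i,
  T_i < T_j and T_i < τ, weighted by Ĝ(T_i−)⁻² where Ĝ is the Kaplan–Meier
  estimate of the censoring distribution; score ties count ½. Its SE is a
  leave-one-subject-out jackknife over the weighted pair sums (censoring
  weights held fixed). τ defaults to 24 months for TTP24 and the largest
  observed time for OS. The implementation is verified against a
  brute-force double loop (10⁻¹² agreement) and equals Harrell's C without
  censoring.
* **LASSO-penalized Cox** is likewise authored here: Efron-tie-corrected
  partial likelihood, internal standardization (population SD), and
  IRLS with diagonal curvature plus coordinate-descent soft thresholding,
  warm-started down a log-spaced 100-point grid from λ_max to 10⁻³ λ_max.
  Unpenalized solutions agree with `coxph` to 10⁻⁶ and penalized solutions
  with `glmnet` (Breslow, tie-free data) to 10⁻⁵ — both serve as
  independent cross-checks, not as the implementation. With more
  predictors than events the unpenalized end of the path can diverge
  (monotone likelihood); the path fitter detects this and flags the entry
  rather than looping, and resampling contexts accept flagged entries while
  direct fits error.
* **λ selection**: repeated event-stratified threefold cross-validation
  (default 1000 iterations); each held-out fold is scored by Uno's C of the
  linear predictor and λ* maximizes the average C, ties broken toward the
  larger (sparser) λ. Splits yielding an event-free fold are redrawn and
  counted. Inner CV fits use a relaxed tolerance (10⁻⁴) — the selected λ
  is insensitive to it while fitting is ~3× faster.
* **Optimism correction**: Harrell's bootstrap (default B = 1000) at fixed
  λ* (re-selecting λ inside every resample is available but costly);
  corrected C = apparent C − mean(C_boot − C_orig). The 95% CI is the
  percentile interval of the optimism-shifted distribution
  {apparent − optimism_b}; a normal-approximation CI is also available, and
  the "CI excludes 0.50" chance rule is reported. Resamples with fewer than
  2 events are redrawn. On null cohorts (n = 80, 20 noise features) the
  corrected C centers within 0.05 of 0.50 while the apparent C exceeds it —
  the calibration the acceptance suite checks.

All randomness flows from one master seed through derived per-stage
streams (`derive_seed`), so a `(config, seed)` pair reproduces every output
byte (gzip timestamps aside).

## The synthetic cohort: what it does and does not emulate

`generate_phantom()` builds SUV volumes as Gaussian background
(0.5 ± 0.1 SUV) + an ellipsoidal liver (6.0 ± 0.5 SUV, physiologic
DOTA-TATE scale) + ellipsoidal lesions with configurable core SUV, voxel
noise and a linear core-to-rim gradient, convolved with an isotropic
Gaussian PSF (default FWHM 6 mm, typical clinical PET) and clipped at 0.
The PSF is what makes the 0.524 cc filter meaningful in tests: small
lesions genuinely lose signal. Lesions may not overlap (per-lesion truth
stays unambiguous) and must fit inside the grid. `generate_cohort()` draws
2–8 lesions per patient (organ mix ≈ 39% liver / 35% bone / 13% node /
13% soft tissue), radii 4–16 mm spanning the eligibility threshold, core
SUVs 4–25, and simulates both endpoints from proportional-hazards models on
standardized patient features (so coefficients are log-HR per SD): the
TTP24 generator loads total receptor expression and mean liver-corrected
SUVmean with baseline hazard log(2)/19 per month, uniform censoring to 36
months and administrative truncation at 24; the OS generator loads total
receptor expression and mean skewness at 0.02/month with censoring to 61
months. Event times are exponential (constant baseline hazard — the
simplest PH-consistent choice; a Weibull shape is configurable).

Deliberately *not* emulated: DICOM/scanner reconstruction, anatomically
realistic organ shapes, SUV harmonization across scanners, correlated
lesion phenotypes within a patient, and any attempt to match the event
rates or feature distributions of a real clinical cohort. Passing tests
therefore demonstrate the *correctness of the computations and the
calibration of the statistical machinery* under known truth — not clinical
performance on real DOTA-TATE images.

## Numerical choices and problem sizes

Cox coordinate descent converges at 10⁻⁸ (final fits) with outer-iteration
caps and a divergence guard at ‖β‖∞ > 100; λ grids are log-spaced;
voxel membership uses voxel centers (half-open, 0-based); seed
deduplication uses the smoothing-kernel truncation radius (4σ); boundary
radii for failed rays are filled by the neighborhood median. The test and
acceptance suites run at desk scale chosen to finish in minutes on one
core: phantoms on 48³ grids at 2–4 mm spacing, cohorts of 20 patients,
LASSO recovery over 50 replicates × 50 CV iterations, optimism calibration
over 20 replicates × 200 bootstraps. The full-scale settings (1000 CV
iterations, 1000 bootstraps) remain the function defaults.

## Known limitations

* The segmenter assumes star-convex lesions around a single uptake peak;
  confluent or ring-like lesions will be split or truncated.
* The edge-blur estimate behind the boundary correction assumes an
  erf-like edge; for lesions smaller than ~2 PSF widths both the gradient
  location and the amplitude estimate degrade together, which is exactly
  why sub-0.524 cc lesions are filtered from the indices.
* Uno's C jackknife SE treats the censoring distribution as fixed; for
  small n with heavy censoring the test against 0.50 is approximate.
* The optimism CI construction (like every bootstrap CI at fixed λ*) does
  not account for the variability of λ selection itself unless
  `refit_lambda = TRUE` is used.
* Patient-level complete-case modeling drops patients with undefined SD /
  heterogeneity summaries (fewer than 2 eligible lesions); with very small
  synthetic cohorts this can remove a meaningful fraction of patients —
  exactly as it would in a real analysis.
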