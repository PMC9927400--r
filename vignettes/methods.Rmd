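---
title: "Models, synthetic world and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models, synthetic world and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, what the synthetic data generator does
and does not emulate, and the numerical and design choices made where the
problem left them open. It states no empirical result that the test suite
does not itself compute.

## The prediction problem

A lung metastasis treated by radiofrequency ablation is either completely
ablated (CR) or leaves viable tumour (non-CR); the truth is only observable
months later on follow-up CT. The pipeline predicts non-CR immediately
after the procedure from two modalities: (a) radiomics features of the
pre-ablation nodule and the immediately post-ablation ablation zone on CT,
and (b) routine clinical covariates (serum markers, lesion location and
size, proximity to vessels and pleura, intra-procedural complications).
Confidences of the two single-modality random-forest models are combined by
decision-level (late) fusion,

$$\mathrm{confidence} = \omega_1\,\mathrm{confidence_{image}} +
  \omega_2\,\mathrm{confidence_{clinical}}, \qquad \omega_1+\omega_2=1 .$$

## The synthetic world

No public imaging cohort accompanies this problem, so the generator *is*
the test substrate, and its defaults are the stated world of the study the
pipeline re-implements:

* **Cohort structure.** 479 lesions; marginals of all ten covariates match
  the published cohort characteristics (e.g. CA19-9 10.8 ± 6.2 U/ml,
  227/479 lesions under 10 mm, 119/479 in the left lower lobe).
  Continuous markers are truncated normal at zero. Naive truncation
  would inflate the mean (CEA 4.6 ± 4.1 truncated at 0 averages ≈ 5.6),
  so the *underlying* mean is calibrated by root-finding such that the
  truncated mean equals the printed value — without this the generator
  could not satisfy its own calibration contract.
* **Outcome model.** `P(nonCR) = logistic(b0 + Σ β·x)` using only the
  multivariate-significant variables as true effects: β(CA19-9) =
  ln 1.007 per U/ml, β(RLL) = ln 2.997, β(LLL) = ln 2.498 against the
  right-upper-lobe reference; every other covariate is noise by design
  (the multivariate column is the causal claim being emulated). The
  intercept is calibrated by bisection over a fixed deterministic
  Monte-Carlo draw of covariates so the marginal non-CR prevalence is
  100/479 ≈ 0.209 at any `effect_scale`; with `effect_scale = 0` it is
  exactly `qlogis(100/479)`.
* **Phantoms.** An ellipsoidal soft-tissue nodule (diameter drawn within
  its size category) over an aerated-lung background near −800 HU, and a
  concentric ablation zone (nodule + 5–7 mm margin) whose periphery ramps
  to a darker ground-glass-like rim. Texture is white Gaussian noise
  smoothed by a separable Gaussian kernel and rescaled to a fixed marginal
  SD — a Gaussian random field with squared-exponential covariance. The
  original design sketch called for exponential covariance; the
  squared-exponential field was chosen instead because it is exactly
  separable (O(N) per axis) and its correlation length plays the identical
  role of the class-signal knob. The anisotropic default spacing
  (0.7 × 0.7 × 1.25 mm) deliberately forces the resampling stage to work.
* **The planted class signal.** With `texture_signal = "none"` the image
  model never reads the label, so image statistics are identical in
  distribution across classes. With `"weak"`/`"strong"`, non-CR ablation
  zones get a longer correlation length (1.7 / 3.0 mm vs ≈ 1 mm) and an
  off-centre hyperdense remnant (+40 / +120 HU). Preset values were frozen
  after a one-off calibration simulation so that the strong preset gives a
  single-feature AUC ≥ 0.75 on the post-ablation run entropy; the weak
  preset was set to roughly 0.8 single-feature AUC. They were not revisited
  after the acceptance tests were written.
* **What a green test does not establish.** The phantoms have no airways,
  vessels, respiratory motion, scanner noise model or segmentation error;
  lesions are independent even within a synthetic patient. Passing tests
  demonstrate the *pipeline machinery* (features, selection, split,
  models, fusion, statistics) — they say nothing about clinical
  performance on real CT.

## Pipeline stages and their knobs

* **Preprocessing order** is frozen as resample → window/scale → crop →
  per-cube min–max. Resampling uses an interpolating cubic B-spline
  (tridiagonal prefilter with mirror boundary, edge replication at the
  borders); masks use nearest neighbour, since interpolation for masks was
  left unspecified. Normalization is per cube, because each sample cube is
  normalized independently. Cube edge 40 mm; window [−1200, 600] HU. The
  crop anchor is the mask's unweighted voxel centroid — robust to
  irregular ablation zones, and with disjoint components the centroid of
  the union (documented, tested).
* **Discretization**: 32 equal-width bins over the in-mask range; a
  constant region collapses to a single level with documented degenerate
  feature values. Texture matrices aggregate counts over the 13 unique 3D
  directions before normalization (the merged strategy); entropies are
  log base 2. Degenerate conventions: `Imc1 = Imc2 = 0` when both marginal
  entropies vanish; `Correlation = 1` at zero variance; `Elongation = 1`
  for a single voxel; an F statistic with zero within-class variance is
  capped at 1e8 with a warning.
* **mRMR**: plug-in mutual information on 8 quantile bins (simple and
  exactly testable; kNN estimators are out of scope), |Pearson| redundancy
  for the F/forest criteria, quotient denominators guarded at 1e-12, ties
  broken by feature name so column order is irrelevant. Consensus counts
  membership over 5 criteria × 3 cutoffs = 15 lists; the set size m is the
  argmax of inner 5-fold CV forest AUC, ties to the smaller m. In
  simulation the *ordering* reliably puts planted informative features
  first, but the argmax lands on the exact planted set size only rarely —
  the CV-AUC curve plateaus and its estimation noise exceeds the true
  differences. This is a property of the rule, not a bug; tests assert the
  ordering and the contract, not a specific m.
* **Data division**: the features are z-scored and (in the pipeline)
  reduced to the leading principal components before the GMM — a full
  covariance on hundreds of features with a few hundred lesions is
  unidentifiable, and using the *selected* features would leak the
  selection into the split. EM uses k-means++ initialization, 10 restarts,
  BIC over K ∈ [2, 8] (truncated so n ≥ 10K), covariance ridge 1e-3 on
  standardized data, at most 50 iterations, and stops as soon as the raw
  log-likelihood stops improving — the recorded trace is therefore
  monotone even though the ridge makes each M-step a penalized update.
  The distance-metric-learning component of the original splitting scheme
  is not reproducible from the available description; plain GMM is used,
  with the feature subset a user hook.
* **Screening and models**: univariate logistic retention at P < 0.1
  (likelihood-ratio p for the 5-level location factor), multivariate
  retention at P < 0.05; complete separation falls back to a
  ridge-penalized Newton fit flagged `penalized`. CA19-9 and CEA enter as
  continuous (the odds ratios are per unit). SMOTE (k = 5, reduced with a
  warning when the minority class is small) balances the training fold
  only; forests are 500 trees, √p candidate features, grown to purity,
  seeded. Model confidences are probabilities of CR, so the two class
  confidences sum to one.
* **Fusion and evaluation**: the fusion weight is chosen on a
  training-fold grid scan (ω1 ∈ {0.1, …, 0.9}, ties toward the larger
  radiomics weight) and then frozen; scanning on the test fold — as the
  original report table appears to do — inflates the fused AUC of a null
  model far above 0.5 at small test-fold sizes, which would break the
  pipeline's own null-safety property. The test-fold grid is still
  reported for inspection. Classification thresholds are Youden's J on the
  training scores, frozen before test scoring; sensitivity counts CR as
  positive (documented and switchable via label orientation). DeLong
  variance uses midrank structural components; identical score vectors
  give p = 1 by convention, and fewer than two members in a class yields
  p = NA with a warning rather than a crash.

## Determinism

One master seed drives everything; each stage derives its own 32-bit seed
from (seed, stage tag, index), so stages are reproducible independently
and two runs of the same configuration agree bit-for-bit (tested). The
forest and all C++ code use a private mt19937, leaving R's RNG state to
the orchestration layer.

## Scaling of the test suite

Property simulations keep every stated count and tolerance (100 seeds,
2000 replicates, 50 cohorts, ±20 % recovery, 0.5 ± 0.08 null band) but
choose the sizes the properties leave open for a single-CPU run: null
screening replicates use n = 300; null-safety cohorts use 60 lesions on
48 mm isotropic grids with K = 2; the planted log-odds 0.7 of the recovery
test rides on CA19-9 per SD, a continuous carrier, because a binary
covariate at n = 2000 cannot support ±20 % recovery at the required seed
rate (Wald SE ≈ 0.11 vs the ±0.14 band).

## Known limitations

* The phantom world is geometric; no claim of anatomical realism.
* The full filter-bank feature catalogue (Gabor, LoG, LBP, wavelets) is
  out of scope; only the families containing the core selected features
  plus their GLSZM/NGTDM companions are implemented.
* GLSZM/NGTDM values follow IBSI formulas but are not cross-checked
  against an external reference implementation (none is available in this
  environment); GLCM/GLRLM/GLDM are oracle-verified by exhaustive
  enumeration.
* The clinical model's planted effects are weak by construction (odds
  ratio 1.007 per U/ml), so at desk-scale n its AUC is modest — matching
  the modelled world, not a defect of the screening code.
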