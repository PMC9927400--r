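# rfaradiomics

Multimodal prediction of the **immediate response of CT-guided
radiofrequency ablation (RFA)** of lung metastases, combining radiomics of
paired pre-/post-ablation CT volumes with clinical covariates.

## The problem

After percutaneous RFA of a lung metastasis, the operator only sees a
ground-glass halo around the ablation zone on the intra-procedural CT;
whether the ablation is actually *complete* (CR) is normally known only
months later, on follow-up imaging under modified RECIST. An immediate,
objective predictor of non-complete response (non-CR) would let the
operator extend the ablation while the needle is still placed.

This package implements that predictor as a fully reproducible pipeline
for researchers in quantitative imaging / interventional radiology:

1. **Synthetic study generator** (`generator_config()`, `generate_cohort()`)
   — ellipsoidal nodule and ablation-zone CT phantoms over a −800 HU lung
   background, plus a clinical table whose marginals match a 479-lesion
   cohort (CA19-9 10.8 ± 6.2 U/ml, CEA 4.6 ± 4.1 ng/ml, five lobar
   locations, …). Outcome labels follow a logistic model with non-CR as the
   event: odds ratios 1.007 per U/ml CA19-9, 2.997 for right-lower-lobe and
   2.498 for left-lower-lobe lesions, intercept calibrated to a marginal
   non-CR prevalence of 100/479. Non-CR lesions (under an active texture
   preset) carry a longer texture correlation length and a hyperdense
   remnant inside the ablation zone.
2. **Preprocessing** (`preprocess_pair()`) — B-spline resampling to 1 mm
   isotropic, window [−1200, 600] HU → [0, 255], a 40 mm cube around the
   mask centroid, per-cube min–max normalization to [0, 1].
3. **Radiomics features** (`extract_feature_table()`) — native first-order,
   shape, GLCM, GLRLM, GLDM, GLSZM and NGTDM families (IBSI-style
   definitions, 32 equal-width bins, 13-direction merged aggregation,
   log2 entropies), verified against brute-force enumeration oracles.
4. **Feature selection** (`select_features()`) — five minimum-redundancy
   maximum-relevance (mRMR) criteria
   (MID, MIQ, FCD, FCQ, RFCQ: e.g. `f_MID(Xi) = I(Y; Xi) − mean_{Xs ∈ S} I(Xs; Xi)`)
   with a top-5/10/15 frequency consensus and an inner-CV choice of the set
   size *m* ∈ [5, 15].
5. **Data division** (`fit_gmm()`, `stratified_group_split()`) — EM-fitted
   Gaussian mixture (BIC-selected K) and a per-(cluster × class)
   round-robin deal into 5 groups, one held out as the test set.
6. **Models** (`train_rf()`, `univariate_screen()`, `multivariate_screen()`,
   `smote_balance()`) — univariate (P < 0.1) → multivariate (P < 0.05)
   logistic screening for the clinical model; SMOTE-balanced random forests
   (500 trees, √p splits; forest implemented natively in C++).
7. **Fusion and evaluation** (`evaluate_models()`, `weight_scan()`,
   `delong_test()`) — decision-level fusion
   `confidence = ω1·confidence_image + ω2·confidence_clinical` with the
   weight frozen on a training-fold grid scan, rank AUC, DeLong tests for
   correlated ROC curves, and accuracy / sensitivity / specificity at a
   Youden threshold frozen on the training fold.

## Worked example

```r
library(rfaradiomics)
cfg <- pipeline_config(n_lesions = 150, seed = 11, texture_signal = "strong",
                       image_shape = 48, spacing_mm = c(1, 1, 1))
res <- run_pipeline(cfg)
res$report
#> <evaluation_report>
#>   best fusion weight w1 = 0.9 (radiomics), w2 = 0.1 (clinical)
#>      model   auc accuracy sensitivity specificity
#>   clinical 0.461    0.448       0.364       0.714
#>  radiomics 1.000    1.000       1.000       1.000
#>      fused 1.000    1.000       1.000       1.000
res$selection$consensus$chosen_set
#> [1] "post_GLDM_DependenceVariance" "post_GLCM_JointEnergy"
#> [3] "post_GLRLM_RunEntropy"        "post_GLRLM_LongRunEmphasis"
#> [5] "post_GLRLM_RunPercentage"
```

Reading this: on a 150-lesion synthetic cohort with the `strong` texture
preset, the consensus selection lands on post-ablation run-length/texture
features (the preset plants its class signal in the ablation-zone texture,
and the planted separation is deliberately large, hence the saturated
radiomics AUC on the 29-lesion test fold). The clinical covariates carry
only the weak planted odds ratios, so the clinical model hovers near
chance at this sample size, and the training-fold scan puts almost all
fusion weight on the radiomics model. With `texture_signal = "none"` and
`effect_scale = 0` all three models sit at AUC ≈ 0.5 (the null-safety
property tested in `tests/testthat/test-acceptance.R`).

## CLI

```sh
Rscript inst/cli/rfa-radiomics.R simulate --out cohort/ --seed 17 --n-lesions 50
Rscript inst/cli/rfa-radiomics.R run-all --config cfg.json --out run1/ --seed 17
```

`simulate` writes NIfTI volumes/masks plus `clinical.csv` and
`manifest.json`; `run-all` writes the feature table, split, screening
table, weight grid and JSON report.
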