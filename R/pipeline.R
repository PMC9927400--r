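# End-to-end orchestration: simulate -> preprocess+extract -> split (GMM on
# unsupervised PCA scores of the standardized feature table) -> consensus
# selection on the training folds -> clinical screening -> SMOTE random
# forests -> fused evaluation. A single seed drives every stage through
# derived per-stage seeds.

#' Pipeline configuration
#'
#' @param n_lesions cohort size.
#' @param seed master seed for all stages.
#' @param texture_signal generator texture preset.
#' @param effect_scale generator outcome effect multiplier.
#' @param image_shape,spacing_mm phantom grid geometry.
#' @param size_mm preprocessing cube edge (mm).
#' @param n_bins discretization levels.
#' @param depth mRMR ranking depth.
#' @param m_range consensus set sizes.
#' @param k_range GMM component counts.
#' @param gmm_features `"pca"` (default: GMM on the leading principal
#'   components of the standardized feature table, unsupervised), `"all"`
#'   (full table), or a character vector of feature names.
#' @param n_pca number of principal components when `gmm_features = "pca"`.
#' @param n_groups data-division groups; `fold` selects the test group.
#' @param fold test group index (1..n_groups).
#' @param n_trees forest size for the final models.
#' @param grid fusion weight grid.
#' @param threshold_policy confusion threshold policy.
#' @return a `run_config` list with a config hash attached.
#' @export
pipeline_config <- function(n_lesions = 479, seed = 17,
                            texture_signal = "strong", effect_scale = 1,
                            image_shape = c(64, 64, 64),
                            spacing_mm = c(0.7, 0.7, 1.25),
                            size_mm = 40, n_bins = 32, depth = 15,
                            m_range = 5:15, k_range = 2:8,
                            gmm_features = "pca", n_pca = 6,
                            n_groups = 5, fold = 1, n_trees = 500,
                            grid = seq(0.1, 0.9, by = 0.1),
                            threshold_policy = "youden-on-train") {
  cfg <- list(n_lesions = n_lesions, seed = seed,
              texture_signal = texture_signal, effect_scale = effect_scale,
              image_shape = image_shape, spacing_mm = spacing_mm,
              size_mm = size_mm, n_bins = n_bins, depth = depth,
              m_range = m_range, k_range = k_range,
              gmm_features = gmm_features, n_pca = n_pca,
              n_groups = n_groups, fold = fold, n_trees = n_trees,
              grid = grid, threshold_policy = threshold_policy)
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' Run the full pipeline on a synthetic cohort
#'
#' @param config a [pipeline_config()].
#' @param cohort optionally, a pre-generated `rfa_cohort` (skips simulation).
#' @param features optionally, a pre-extracted feature table (skips imaging).
#' @param out_dir optional directory for artifacts (cohort CSV, feature
#'   table, rankings, split, screening, report).
#' @param verbose print stage progress.
#' @return list with `report` ([evaluate_models()] output), `split`,
#'   `selection`, `screening`, `features`, `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), cohort = NULL,
                         features = NULL, out_dir = NULL, verbose = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf(...))
  gen_cfg <- generator_config(
    n_lesions = config$n_lesions, seed = config$seed,
    image_shape = config$image_shape, spacing_mm = config$spacing_mm,
    texture_signal = config$texture_signal, effect_scale = config$effect_scale)

  say("stage simulate: %d lesions", config$n_lesions)
  if (is.null(cohort)) cohort <- generate_cohort(gen_cfg, images = is.null(features))
  clinical <- cohort$clinical
  labels <- clinical$label

  say("stage extract: preprocessing and feature extraction")
  if (is.null(features))
    features <- extract_feature_table(cohort, size_mm = config$size_mm,
                                      n_bins = config$n_bins)
  fmat <- as.matrix(features[, setdiff(names(features), "lesion_id")])

  say("stage split: GMM cluster-stratified division")
  gmm_input <- if (identical(config$gmm_features, "pca")) {
    sds <- apply(fmat, 2, sd)
    pc <- prcomp(fmat[, sds > 0, drop = FALSE], center = TRUE, scale. = TRUE)
    pc$x[, seq_len(min(config$n_pca, ncol(pc$x))), drop = FALSE]
  } else if (identical(config$gmm_features, "all")) {
    fmat
  } else {
    fmat[, config$gmm_features, drop = FALSE]
  }
  gmm <- fit_gmm(gmm_input, k_range = config$k_range,
                 seed = derive_seed(config$seed, "split"))
  split <- stratified_group_split(gmm, labels, n_groups = config$n_groups,
                                  seed = derive_seed(config$seed, "split"),
                                  fold = config$fold,
                                  ids = clinical$lesion_id)
  tr <- split$role == "train"
  te <- split$role == "test"

  say("stage select: mRMR consensus on %d training lesions", sum(tr))
  selection <- select_features(as.data.frame(fmat)[tr, , drop = FALSE],
                               labels[tr], depth = config$depth,
                               m_range = config$m_range,
                               seed = derive_seed(config$seed, "select"))
  sel_feats <- selection$consensus$chosen_set

  say("stage train: clinical screening + random forests")
  uni <- univariate_screen(clinical[tr, ], labels[tr])
  retained1 <- attr(uni, "retained")
  screening <- list(univariate = uni, multivariate = NULL)
  clin_vars <- retained1
  if (length(retained1) > 0) {
    multi <- multivariate_screen(clinical[tr, ], labels[tr], retained1)
    screening$multivariate <- multi
    if (length(attr(multi, "retained")) > 0)
      clin_vars <- attr(multi, "retained")
  }
  if (length(clin_vars) == 0L) {
    warnf("no clinical variable retained: falling back to all screened")
    clin_vars <- intersect(clinical_variables, names(clinical))
  }
  Xc <- clinical_design(clinical, clin_vars)
  Xr <- fmat[, sel_feats, drop = FALSE]
  m_clin <- train_rf(Xc[tr, , drop = FALSE], labels[tr], "clinical",
                     n_trees = config$n_trees,
                     seed = derive_seed(config$seed, "clinical_rf"))
  m_rad <- train_rf(Xr[tr, , drop = FALSE], labels[tr], "radiomics",
                    n_trees = config$n_trees,
                    seed = derive_seed(config$seed, "radiomics_rf"))

  say("stage evaluate: %d test lesions", sum(te))
  # scores are CR confidences, so CR is the positive (second) level
  labels_eval <- factor(labels, levels = c("nonCR", "CR"))
  test_scores <- list(
    clinical = setNames(predict_scores(m_clin, Xc[te, , drop = FALSE]),
                        clinical$lesion_id[te]),
    radiomics = setNames(predict_scores(m_rad, Xr[te, , drop = FALSE]),
                         clinical$lesion_id[te]))
  train_scores <- list(
    clinical = predict_scores(m_clin, Xc[tr, , drop = FALSE]),
    radiomics = predict_scores(m_rad, Xr[tr, , drop = FALSE]),
    labels = labels_eval[tr])
  report <- evaluate_models(test_scores, labels_eval[te], train_scores,
                            grid = config$grid,
                            threshold_policy = config$threshold_policy)

  out <- list(report = report, split = split, selection = selection,
              screening = screening, features = features,
              models = list(clinical = m_clin, radiomics = m_rad),
              clinical_variables = clin_vars, config = config,
              wall_time = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  if (!is.null(out_dir)) write_artifacts(out, cohort, out_dir)
  out
}

write_artifacts <- function(result, cohort, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$clinical, file.path(out_dir, "clinical.csv"), row.names = FALSE)
  write.csv(result$features, file.path(out_dir, "features.csv"), row.names = FALSE)
  write.csv(as.data.frame(result$split), file.path(out_dir, "split.csv"),
            row.names = FALSE)
  write.csv(result$report$metrics, file.path(out_dir, "metrics.csv"),
            row.names = FALSE)
  write.csv(result$report$weight_table, file.path(out_dir, "weight_table.csv"),
            row.names = FALSE)
  write_report(result$report, file.path(out_dir, "report.json"),
               config = result$config)
  invisible(out_dir)
}

#' Write an evaluation report as JSON
#'
#' @param report an `evaluation_report`.
#' @param path output JSON path.
#' @param config optional `run_config` to embed (with its hash).
#' @export
write_report <- function(report, path, config = NULL) {
  payload <- list(metrics = report$metrics, weight_table = report$weight_table,
                  best_w1 = report$best_w1, delong = report$delong)
  if (!is.null(config)) payload$config <- unclass(config)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write a cohort to disk (NIfTI volumes + clinical CSV + manifest JSON)
#'
#' @param cohort an `rfa_cohort` with images.
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "rfa_cohort"))
  if (is.null(cohort$cases)) stopf("cohort has no image cases")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(cohort$clinical, file.path(dir, "clinical.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(seed = cohort$config$seed,
         n_lesions = cohort$config$n_lesions,
         config_hash = config_hash(unclass(cohort$config)),
         lesion_ids = cohort$clinical$lesion_id),
    file.path(dir, "manifest.json"), auto_unbox = TRUE)
  for (case in cohort$cases) {
    base <- file.path(dir, case$lesion_id)
    sp <- case$pre_volume$spacing
    write_nifti(case$pre_volume$data, paste0(base, "_pre.nii.gz"), sp)
    write_nifti(case$pre_mask$data, paste0(base, "_pre_mask.nii.gz"), sp, "uint8")
    write_nifti(case$post_volume$data, paste0(base, "_post.nii.gz"), sp)
    write_nifti(case$post_mask$data, paste0(base, "_post_mask.nii.gz"), sp, "uint8")
  }
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir cohort directory.
#' @return an `rfa_cohort` (config slot carries only the manifest info).
#' @export
read_cohort <- function(dir) {
  clin_path <- file.path(dir, "clinical.csv")
  if (!file.exists(clin_path)) stopf("no clinical.csv in '%s'", dir)
  clinical <- read.csv(clin_path, stringsAsFactors = TRUE)
  clinical$lesion_id <- as.character(clinical$lesion_id)
  clinical$patient_id <- as.character(clinical$patient_id)
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  cases <- lapply(seq_len(nrow(clinical)), function(i) {
    base <- file.path(dir, clinical$lesion_id[i])
    structure(list(
      lesion_id = clinical$lesion_id[i],
      patient_id = clinical$patient_id[i],
      clinical = clinical[i, ],
      label = clinical$label[i],
      pre_volume = read_nifti(paste0(base, "_pre.nii.gz")),
      pre_mask = read_nifti(paste0(base, "_pre_mask.nii.gz")),
      post_volume = read_nifti(paste0(base, "_post.nii.gz")),
      post_mask = read_nifti(paste0(base, "_post_mask.nii.gz"))),
      class = "lesion_case")
  })
  structure(list(clinical = clinical, cases = cases, config = manifest,
                 manifest = manifest),
            class = "rfa_cohort")
}
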