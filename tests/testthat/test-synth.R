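# Generator calibration, outcome-model arithmetic, phantom contracts.

cfg_small <- generator_config(n_lesions = 20, seed = 7, image_shape = 48,
                              spacing_mm = c(1, 1, 1))

test_that("covariate marginals are calibrated to the cohort table", {
  draws <- withr::with_seed(42, sample_clinical(cfg_small, 1e4))
  expect_lt(abs(mean(draws$ca19_9) - 10.8), 0.2)
  expect_lt(abs(mean(draws$cea) - 4.6), 0.2)
  expect_lt(abs(mean(draws$location == "LLL") - 119 / 479), 0.02)
  expect_lt(abs(mean(draws$gender == "male") - 269 / 479), 0.02)
  expect_true(all(draws$cea >= 0) && all(draws$ca19_9 >= 0))

  # degenerate marginal: sd 0 collapses to the mean
  m <- default_marginals()
  m$ca19_9["sd"] <- 0
  cfg0 <- generator_config(covariate_marginals = m)
  d0 <- withr::with_seed(1, sample_clinical(cfg0, 50))
  expect_true(all(d0$ca19_9 == 10.8))
})

test_that("outcome prevalence and odds ratios match the planted model", {
  cl <- clinical_cohort(cfg_small, 1e5, seed = 9)
  expect_lt(abs(mean(cl$label == "nonCR") - 100 / 479), 0.01)

  # conditional odds ratio for RLL vs reference RUL, all else fixed
  rec <- cl[rep(1, 1e5), ]
  rec$ca19_9 <- 10.8
  rec$location <- factor("RUL", levels = levels(cl$location))
  p0 <- mean(withr::with_seed(11, sample_outcome(rec, cfg_small)) == "nonCR")
  rec$location <- factor("RLL", levels = levels(cl$location))
  p1 <- mean(withr::with_seed(12, sample_outcome(rec, cfg_small)) == "nonCR")
  or <- (p1 / (1 - p1)) / (p0 / (1 - p0))
  expect_lt(abs(or - 2.997), 0.4)
})

test_that("effect_scale = 0 reduces to the intercept-only model", {
  cfg0 <- generator_config(n_lesions = 20, seed = 1, effect_scale = 0)
  expect_equal(cfg0$intercept, qlogis(100 / 479), tolerance = 1e-9)
  cl <- clinical_cohort(cfg0, 2e4, seed = 3)
  expect_lt(abs(mean(cl$label == "nonCR") - plogis(cfg0$intercept)), 0.01)
})

test_that("cohort generation is deterministic and seed-sensitive", {
  c1 <- generate_cohort(generator_config(n_lesions = 10, seed = 5,
                                         image_shape = 48,
                                         spacing_mm = c(1, 1, 1)))
  c2 <- generate_cohort(generator_config(n_lesions = 10, seed = 5,
                                         image_shape = 48,
                                         spacing_mm = c(1, 1, 1)))
  expect_identical(c1$clinical, c2$clinical)
  expect_identical(c1$cases[[3]]$post_volume$data, c2$cases[[3]]$post_volume$data)

  c3 <- generate_cohort(generator_config(n_lesions = 10, seed = 6,
                                         image_shape = 48,
                                         spacing_mm = c(1, 1, 1)))
  expect_false(identical(c1$cases[[3]]$post_volume$data,
                         c3$cases[[3]]$post_volume$data))
  expect_identical(names(c1$clinical), names(c3$clinical))
})

test_that("phantom masks are valid and oversized nodules error", {
  coh <- generate_cohort(generator_config(n_lesions = 10, seed = 2,
                                          image_shape = 48,
                                          spacing_mm = c(1, 1, 1)))
  for (case in coh$cases) {
    expect_gt(sum(case$pre_mask$data), 0)
    expect_gt(sum(case$post_mask$data), sum(case$pre_mask$data))
    expect_true(all(case$pre_mask$data %in% c(0, 1)))
    expect_identical(dim(case$pre_volume$data), dim(case$pre_mask$data))
  }

  cfg32 <- generator_config(n_lesions = 10, seed = 2, image_shape = 32,
                            spacing_mm = c(1, 1, 1))
  rec <- withr::with_seed(1, sample_clinical(cfg32, 1))
  rec$nodule_size_cat <- factor("20-30", levels = levels(rec$nodule_size_cat))
  expect_error(withr::with_seed(1, generate_phantom_pair(rec, "CR", cfg32)),
               "larger than grid")
})

test_that("config validation rejects invalid worlds", {
  expect_error(generator_config(n_lesions = 5), "n_lesions")
  expect_error(generator_config(spacing_mm = c(1, 0, 1)), "positive")
  expect_error(generator_config(image_shape = 16), "image_shape")
  m <- default_marginals()
  m$age["sd"] <- -1
  expect_error(generator_config(covariate_marginals = m), "invalid marginal")
  expect_error(generator_config(log_odds = c(bogus_var = 1)),
               "matches no covariate")
})

test_that("null preset plants no class signal in the images", {
  coh <- small_cohort(60, seed = 31, preset = "none")
  ft <- extract_feature_table(coh)
  lab <- coh$clinical$label
  skipcols <- c("post_GLRLM_RunEntropy", "post_GLCM_Imc2", "post_GLCM_Idmn")
  for (col in skipcols) {
    ks <- suppressWarnings(stats::ks.test(ft[[col]][lab == "CR"],
                                          ft[[col]][lab == "nonCR"]))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("strong preset separates classes on the planted run feature", {
  coh <- small_cohort(150, seed = 13, preset = "strong")
  ft <- extract_feature_table(coh)
  auc <- roc_auc(ft$post_GLRLM_RunEntropy, coh$clinical$label == "nonCR")
  expect_gte(auc, 0.75)
})
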