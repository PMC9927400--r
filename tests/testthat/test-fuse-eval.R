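# Decision-level fusion, AUC, DeLong and threshold metrics.

test_that("fusion is the stated convex combination", {
  expect_equal(fuse(0.9, 0.5, 0.7), 0.78)
  s <- withr::with_seed(1, runif(10))
  expect_identical(fuse(s, runif(10), 1), s)
  expect_equal(fuse(s, s, 0.5), s)
  expect_error(fuse(setNames(s, letters[1:10]), setNames(s, LETTERS[1:10]), 0.5),
               "different lesions")
  expect_error(fuse(1:3 / 4, 1:2 / 4, 0.5), "length")
  expect_error(fuse(0.5, 0.5, 1.2), "w1")
  # bounded whenever inputs are
  a <- withr::with_seed(2, runif(50)); b <- withr::with_seed(3, runif(50))
  for (w in seq(0, 1, 0.25)) {
    f <- fuse(a, b, w)
    expect_true(all(f >= 0 & f <= 1))
  }
})

test_that("rank AUC handles perfect, reversed, tied and null scores", {
  lab <- c(rep(FALSE, 5), rep(TRUE, 5))
  expect_equal(roc_auc(1:10, lab), 1)
  expect_equal(roc_auc(10:1, lab), 0)
  expect_equal(roc_auc(rep(1, 10), lab), 0.5) # midranks
  expect_error(roc_auc(1:5, rep(TRUE, 5)), "both classes")

  null_mean <- mean(vapply(1:100, function(s) withr::with_seed(s, {
    roc_auc(runif(200), rep(c(TRUE, FALSE), 100))
  }), 0))
  expect_lt(abs(null_mean - 0.5), 0.02)

  # invariance under strictly monotone transforms
  sc <- withr::with_seed(4, rnorm(100))
  lb <- withr::with_seed(5, runif(100) < 0.4)
  expect_equal(roc_auc(sc, lb), roc_auc(plogis(3 * sc + 1), lb))
})

test_that("the weight scan brackets components and breaks ties upward", {
  s <- latent_scores(1)
  ws <- weight_scan(s$radiomics, s$clinical, s$labels)
  expect_equal(nrow(ws$table), 9)
  expect_true(ws$best_w1 %in% seq(0.1, 0.9, 0.1))
  expect_equal(max(ws$table$auc), ws$best_auc)
  # identical scores: constant AUC across the grid, tie goes to larger w1
  wsc <- weight_scan(s$radiomics, s$radiomics, s$labels)
  expect_equal(diff(range(wsc$table$auc)), 0)
  expect_equal(wsc$best_w1, 0.9)
})

test_that("informative radiomics with noise clinical drives w1 to the edge", {
  edge <- 0
  for (s in 1:40) {
    sim <- withr::with_seed(s, {
      n <- 300
      z <- rnorm(n)
      list(lab = rbinom(n, 1, plogis(2 * z)) == 1,
           sr = plogis(z + 0.5 * rnorm(n)), sc = runif(n))
    })
    if (weight_scan(sim$sr, sim$sc, sim$lab)$best_w1 == 0.9) edge <- edge + 1
  }
  expect_gte(edge, 32) # >= 80%
})

test_that("DeLong is symmetric, antisymmetric in the difference, exact on ties", {
  s <- latent_scores(7, n = 150)
  ab <- delong_test(s$radiomics, s$clinical, s$labels)
  ba <- delong_test(s$clinical, s$radiomics, s$labels)
  expect_equal(ab$p, ba$p, tolerance = 1e-12)
  expect_equal(ab$diff, -ba$diff, tolerance = 1e-12)
  ident <- delong_test(s$radiomics, s$radiomics, s$labels)
  expect_equal(ident$p, 1)
  expect_equal(ident$diff, 0)

  # power: strongly different models
  pw <- 0
  for (s2 in 1:30) {
    sim <- withr::with_seed(s2, {
      n <- 500; z <- rnorm(n)
      list(lab = rbinom(n, 1, plogis(2 * z)) == 1,
           a = z + 0.4 * rnorm(n), b = rnorm(n))
    })
    if (delong_test(sim$a, sim$b, sim$lab)$p < 0.001) pw <- pw + 1
  }
  expect_gte(pw, 29)
})

test_that("confusion metrics follow the printed formulas", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.4, 0.3, 0.2, 0.45, 0.55, 0.35)
  labels <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  cm <- confusion_metrics(scores, labels, threshold = 0.5)
  expect_equal(cm$TP, 3); expect_equal(cm$FN, 2)
  expect_equal(cm$FP, 2); expect_equal(cm$TN, 3)
  expect_equal(cm$accuracy, 0.6)
  expect_equal(cm$sensitivity, 0.6)
  expect_equal(cm$specificity, 0.6)

  all_good <- confusion_metrics(labels * 1, labels, 0.5)
  expect_equal(all_good$accuracy, 1)
  expect_equal(all_good$sensitivity, 1)
  expect_equal(all_good$specificity, 1)

  everything_pos <- confusion_metrics(scores, labels, threshold = 0)
  expect_equal(everything_pos$sensitivity, 1)
  expect_equal(everything_pos$specificity, 0)

  expect_warning(cm0 <- confusion_metrics(scores, rep(FALSE, 10), 0.5),
                 "sensitivity undefined")
  expect_true(is.na(cm0$sensitivity))
})

test_that("the evaluation report is complete and internally consistent", {
  s <- latent_scores(11, n = 200)
  tr <- latent_scores(12, n = 200)
  tr$labels <- factor(ifelse(tr$labels, "CR", "nonCR"), levels = c("nonCR", "CR"))
  rep_ <- evaluate_models(list(radiomics = s$radiomics, clinical = s$clinical),
                          s$labels, train_scores = tr)
  expect_identical(rep_$metrics$model, c("clinical", "radiomics", "fused"))
  expect_true(all(rep_$metrics$auc >= 0 & rep_$metrics$auc <= 1))
  expect_equal(nrow(rep_$weight_table), 9)
  expect_equal(nrow(rep_$delong), 3)
  # the fusion weight is frozen on the training scan; the fused test AUC then
  # equals the test grid row at that weight
  expect_equal(rep_$metrics$auc[rep_$metrics$model == "fused"],
               rep_$weight_table$auc[rep_$weight_table$w1 == rep_$best_w1],
               tolerance = 1e-12)
  cm <- rep_$metrics[1, ]
  expect_equal(cm$TP + cm$FP + cm$TN + cm$FN, 200)
})
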