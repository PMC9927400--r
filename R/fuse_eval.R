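# Decision-level fusion of the radiomics and clinical confidences, the
# weight-grid scan, and all performance metrics: rank AUC, the DeLong test
# for correlated ROC curves, and thresholded accuracy / sensitivity /
# specificity.

#' Fuse two confidence score sets
#'
#' `fused = w1 * radiomics + w2 * clinical` with `w1 + w2 = 1`, elementwise
#' over lesions matched by name (when both vectors are named).
#'
#' @param scores_radiomics,scores_clinical numeric confidence vectors in
#'   `[0, 1]`.
#' @param w1 radiomics weight in `[0, 1]`; the clinical weight is `1 - w1`.
#' @return fused confidence vector.
#' @export
fuse <- function(scores_radiomics, scores_clinical, w1) {
  if (w1 < 0 || w1 > 1) stopf("w1 must be in [0, 1]")
  a <- scores_radiomics; b <- scores_clinical
  if (!is.null(names(a)) && !is.null(names(b))) {
    if (!setequal(names(a), names(b))) stopf("score sets cover different lesions")
    b <- b[names(a)]
  } else if (length(a) != length(b)) {
    stopf("score sets differ in length")
  }
  w1 * a + (1 - w1) * b
}

#' Mann-Whitney rank AUC
#'
#' Probability that a random positive outranks a random negative, with
#' midranks for ties.
#'
#' @param scores numeric scores.
#' @param labels logical/0-1/two-level factor; `TRUE` (second level) is the
#'   positive class.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  pos <- as_positive(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) stopf("roc_auc needs both classes present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_positive <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.factor(labels)) return(labels == levels(labels)[2])
  if (is.numeric(labels)) return(labels == max(labels))
  f <- factor(labels)
  f == levels(f)[2]
}

#' Scan the fusion weight grid
#'
#' Computes the fused AUC for each radiomics weight on the grid and returns
#' the table plus the best weight (ties resolved toward the larger radiomics
#' weight).
#'
#' @param scores_radiomics,scores_clinical confidence vectors.
#' @param labels outcome labels (positive = second level / `TRUE`).
#' @param grid radiomics weights to scan (default `seq(0.1, 0.9, 0.1)`).
#' @return list with `table` (data.frame `w1`, `w2`, `auc`), `best_w1`,
#'   `best_auc`.
#' @export
weight_scan <- function(scores_radiomics, scores_clinical, labels,
                        grid = seq(0.1, 0.9, by = 0.1)) {
  if (length(grid) == 0L) stopf("empty weight grid")
  auc <- vapply(grid, function(w)
    roc_auc(fuse(scores_radiomics, scores_clinical, w), labels), 0)
  best <- order(-auc, -grid)[1]
  list(table = data.frame(w1 = grid, w2 = 1 - grid, auc = auc),
       best_w1 = grid[best], best_auc = auc[best])
}

#' DeLong test for two correlated AUCs
#'
#' Structural-component variance estimate of the paired AUC difference with a
#' two-sided normal approximation. Identical score vectors (zero variance)
#' return `p = 1`.
#'
#' @param scores_a,scores_b paired scores on the same lesions.
#' @param labels outcome labels.
#' @return list with `auc_a`, `auc_b`, `diff`, `se`, `p`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  pos <- as_positive(labels)
  if (length(scores_a) != length(scores_b) || length(scores_a) != length(pos))
    stopf("scores and labels must be paired")
  m <- sum(pos); n <- sum(!pos)
  if (m == 0 || n == 0) stopf("delong_test needs both classes present")
  if (m < 2 || n < 2) {
    warnf("delong_test needs >= 2 members per class for a variance; p is NA")
    auc <- roc_auc(scores_a, pos)
    return(list(auc_a = auc, auc_b = roc_auc(scores_b, pos),
                diff = auc - roc_auc(scores_b, pos), se = NA_real_,
                p = NA_real_))
  }
  comp <- function(s) {
    x <- s[pos]; y <- s[!pos]
    # midrank structural components
    v10 <- vapply(x, function(xi) (sum(xi > y) + 0.5 * sum(xi == y)) / n, 0)
    v01 <- vapply(y, function(yi) (sum(x > yi) + 0.5 * sum(x == yi)) / m, 0)
    list(auc = mean(v10), v10 = v10, v01 = v01)
  }
  A <- comp(scores_a); B <- comp(scores_b)
  s10 <- cov(cbind(A$v10, B$v10))
  s01 <- cov(cbind(A$v01, B$v01))
  S <- s10 / m + s01 / n
  d <- A$auc - B$auc
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  if (!is.finite(v)) v <- 0
  if (v <= 0) {
    p <- if (d == 0) 1 else 0
    return(list(auc_a = A$auc, auc_b = B$auc, diff = d, se = 0, p = p))
  }
  z <- d / sqrt(v)
  list(auc_a = A$auc, auc_b = B$auc, diff = d, se = sqrt(v),
       p = 2 * pnorm(-abs(z)))
}

#' Confusion counts and threshold metrics
#'
#' `ACC = (TP + TN) / n`, `Sensitivity = TP / (TP + FN)`,
#' `Specificity = TN / (TN + FP)`; scores at or above the threshold are
#' called positive. With no positives present, sensitivity is `NA` with a
#' warning (and symmetrically for specificity).
#'
#' @param scores confidence of the positive class.
#' @param labels outcome labels.
#' @param threshold decision threshold (default 0.5; see [youden_threshold()]
#'   for the train-fold policy).
#' @return list with `TP`, `FP`, `TN`, `FN`, `accuracy`, `sensitivity`,
#'   `specificity`, `threshold`.
#' @export
confusion_metrics <- function(scores, labels, threshold = 0.5) {
  pos <- as_positive(labels)
  call_pos <- scores >= threshold
  TP <- sum(call_pos & pos); FP <- sum(call_pos & !pos)
  TN <- sum(!call_pos & !pos); FN <- sum(!call_pos & pos)
  sens <- if (TP + FN == 0) {
    warnf("no positives: sensitivity undefined")
    NA_real_
  } else TP / (TP + FN)
  spec <- if (TN + FP == 0) {
    warnf("no negatives: specificity undefined")
    NA_real_
  } else TN / (TN + FP)
  list(TP = TP, FP = FP, TN = TN, FN = FN,
       accuracy = (TP + TN) / length(scores),
       sensitivity = sens, specificity = spec, threshold = threshold)
}

#' Youden-optimal threshold on a (training) score set
#'
#' Maximizes `sensitivity + specificity - 1` over the observed scores;
#' intended to be frozen on the training fold before test scoring.
#'
#' @param scores training confidences.
#' @param labels training labels.
#' @return threshold value.
#' @export
youden_threshold <- function(scores, labels) {
  pos <- as_positive(labels)
  cand <- sort(unique(scores))
  cand <- c(cand, max(cand) + 1e-9)
  j <- vapply(cand, function(th) {
    tp <- sum(scores >= th & pos); fn <- sum(scores < th & pos)
    tn <- sum(scores < th & !pos); fp <- sum(scores >= th & !pos)
    sens <- if (tp + fn == 0) 0 else tp / (tp + fn)
    spec <- if (tn + fp == 0) 0 else tn / (tn + fp)
    sens + spec - 1
  }, 0)
  cand[which.max(j)]
}

#' Evaluate the clinical, radiomics and fused models on a test set
#'
#' Computes AUC / accuracy / sensitivity / specificity per model (decision
#' thresholds frozen on the training scores by Youden's J, or fixed at 0.5)
#' and the pairwise DeLong comparisons. The fusion weight is frozen on the
#' training-fold scan when training scores are supplied (anything else leaks
#' the test labels into the model choice); the reported `weight_table` is
#' still the test-set grid for inspection.
#'
#' @param scores list with `radiomics` and `clinical` test confidences.
#' @param labels test labels.
#' @param train_scores optional list of training confidences (same names) and
#'   `labels`, used to freeze the fusion weight and Youden thresholds.
#' @param grid fusion weight grid.
#' @param threshold_policy `"youden-on-train"` or `"fixed"`.
#' @return an `evaluation_report`: `metrics` data.frame, `weight_table`,
#'   `best_w1`, `delong` data.frame.
#' @export
evaluate_models <- function(scores, labels, train_scores = NULL,
                            grid = seq(0.1, 0.9, by = 0.1),
                            threshold_policy = c("youden-on-train", "fixed")) {
  threshold_policy <- match.arg(threshold_policy)
  scan <- weight_scan(scores$radiomics, scores$clinical, labels, grid)
  w1 <- if (!is.null(train_scores)) {
    weight_scan(train_scores$radiomics, train_scores$clinical,
                train_scores$labels, grid)$best_w1
  } else {
    scan$best_w1
  }
  fused <- fuse(scores$radiomics, scores$clinical, w1)
  all_scores <- list(clinical = scores$clinical, radiomics = scores$radiomics,
                     fused = fused)
  thresholds <- lapply(names(all_scores), function(mod) {
    if (threshold_policy == "youden-on-train" && !is.null(train_scores)) {
      tr <- if (mod == "fused")
        fuse(train_scores$radiomics, train_scores$clinical, w1)
      else train_scores[[mod]]
      youden_threshold(tr, train_scores$labels)
    } else 0.5
  })
  names(thresholds) <- names(all_scores)
  metrics <- do.call(rbind, lapply(names(all_scores), function(mod) {
    cm <- confusion_metrics(all_scores[[mod]], labels, thresholds[[mod]])
    data.frame(model = mod, auc = roc_auc(all_scores[[mod]], labels),
               accuracy = cm$accuracy, sensitivity = cm$sensitivity,
               specificity = cm$specificity, threshold = cm$threshold,
               TP = cm$TP, FP = cm$FP, TN = cm$TN, FN = cm$FN,
               stringsAsFactors = FALSE)
  }))
  pairs <- utils::combn(names(all_scores), 2)
  delong <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    dt <- delong_test(all_scores[[a]], all_scores[[b]], labels)
    data.frame(model_a = a, model_b = b, auc_a = dt$auc_a, auc_b = dt$auc_b,
               diff = dt$diff, p = dt$p, stringsAsFactors = FALSE)
  }))
  structure(list(metrics = metrics, weight_table = scan$table,
                 best_w1 = w1, delong = delong, scores = all_scores),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  cat(sprintf("  best fusion weight w1 = %.1f (radiomics), w2 = %.1f (clinical)\n",
              x$best_w1, 1 - x$best_w1))
  print(x$metrics[, c("model", "auc", "accuracy", "sensitivity", "specificity")],
        row.names = FALSE, digits = 3)
  invisible(x)
}
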