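# Five-criterion minimum-redundancy maximum-relevance (mRMR) feature
# ranking and the top-5/10/15 frequency-consensus selection.
#
# Criteria: MID/MIQ pair mutual-information relevance with raw
# mutual-information redundancy (difference / quotient form); FCD/FCQ pair
# the one-way ANOVA F relevance with |Pearson| redundancy; RFCQ pairs random
# forest impurity importance with |Pearson| redundancy (quotient form).

F_CAP <- 1e8 # finite stand-in for an infinite F statistic

#' Plug-in mutual information between a feature and class labels
#'
#' Continuous features are quantile-binned (`n_bins`), labels are treated as
#' categorical; MI is the plug-in estimate on the joint histogram in nats.
#'
#' @param x numeric feature column.
#' @param y class labels (factor or vector).
#' @param n_bins quantile bins for continuous `x`.
#' @return MI in nats (0 for a constant `x`).
#' @export
mutual_information <- function(x, y, n_bins = 8) {
  if (length(x) < 4L) stopf("need at least 4 observations")
  if (length(unique(x)) <= 1L) return(0)
  xb <- bin_quantile(x, n_bins)
  joint <- table(xb, y)
  p <- joint / sum(joint)
  px <- rowSums(p); py <- colSums(p)
  e <- outer(px, py)
  nz <- p > 0
  sum(p[nz] * log(p[nz] / e[nz]))
}

bin_quantile <- function(x, n_bins) {
  if (length(unique(x)) <= n_bins) return(factor(x))
  br <- unique(quantile(x, probs = seq(0, 1, length.out = n_bins + 1)))
  cut(x, breaks = br, include.lowest = TRUE)
}

# integer codes of the quantile binning (same partition as bin_quantile)
bin_codes <- function(x, n_bins) {
  f <- bin_quantile(x, n_bins)
  list(codes = as.integer(f), n = nlevels(f))
}

# plug-in MI between two integer-coded discrete vectors, in nats
mi_disc <- function(a, na, b, nb) {
  n <- length(a)
  p <- tabulate((a - 1L) * nb + b, na * nb) / n
  pa <- tabulate(a, na) / n
  pb <- tabulate(b, nb) / n
  e <- as.vector(t(outer(pa, pb)))
  nz <- p > 0
  sum(p[nz] * log(p[nz] / e[nz]))
}

#' One-way ANOVA F statistic of a feature across classes
#'
#' @param x numeric feature.
#' @param y grouping with >= 2 classes of >= 2 members each.
#' @return F value; zero within-group variance with distinct means returns a
#'   large finite cap with a warning.
#' @export
f_statistic <- function(x, y) {
  y <- factor(y)
  n <- length(x)
  if (nlevels(y) < 2L) stopf("need at least 2 classes")
  cnt <- table(y)
  if (any(cnt < 2L)) stopf("every class needs at least 2 members")
  gm <- tapply(x, y, mean)
  ssb <- sum(cnt * (gm - mean(x))^2)
  ssw <- sum((x - gm[y])^2)
  dfb <- nlevels(y) - 1L
  dfw <- n - nlevels(y)
  if (ssw == 0) {
    if (ssb == 0) return(0)
    warnf("zero within-class variance: F capped at %g", F_CAP)
    return(F_CAP)
  }
  (ssb / dfb) / (ssw / dfw)
}

#' Absolute Pearson correlation (redundancy measure)
#'
#' @param x1,x2 numeric vectors.
#' @return `|r|`; 0 with a warning if either input is constant.
#' @export
pearson_redundancy <- function(x1, x2) {
  if (sd(x1) == 0 || sd(x2) == 0) {
    warnf("constant input: redundancy set to 0")
    return(0)
  }
  abs(cor(x1, x2))
}

#' Random-forest relevance scores
#'
#' Impurity-decrease importances of a seeded forest fit on all features.
#'
#' @param X feature matrix/data.frame (n >= 20).
#' @param y class labels.
#' @param n_trees forest size.
#' @param seed integer seed.
#' @return named non-negative scores summing to <= 1.
#' @export
rf_relevance <- function(X, y, n_trees = 500, seed = 1) {
  if (nrow(as.matrix(X)) < 20L) stopf("rf_relevance needs n >= 20")
  rf_importance(rf_fit(X, y, n_trees = n_trees, seed = seed))
}

mrmr_criteria <- c("MID", "MIQ", "FCD", "FCQ", "RFCQ")

#' Greedy mRMR feature ranking under one of five criteria
#'
#' The first feature maximizes the criterion's relevance (mutual information
#' for MID/MIQ, the F statistic for FCD/FCQ, forest importance for RFCQ);
#' each subsequent feature maximizes relevance minus (difference forms) or
#' divided by (quotient forms) the mean redundancy against the already
#' selected set. Quotient denominators are guarded at `1e-12`. Ties break by
#' feature name, so permuting input columns changes nothing.
#'
#' @param X feature data.frame/matrix with named columns.
#' @param y class labels.
#' @param criterion one of `"MID"`, `"MIQ"`, `"FCD"`, `"FCQ"`, `"RFCQ"`.
#' @param depth number of features to rank.
#' @param n_bins MI binning.
#' @param seed seed for the RFCQ forest.
#' @return a `ranking_result`: list with `criterion`, `features` (ordered
#'   names) and `scores` (criterion value at each pick).
#' @export
mrmr_rank <- function(X, y, criterion = "MID", depth = ncol(X),
                      n_bins = 8, seed = 1) {
  criterion <- match.arg(criterion, mrmr_criteria)
  X <- as.data.frame(X)
  if (depth < 1) stopf("depth must be >= 1")
  depth <- min(depth, ncol(X))
  feats <- colnames(X)
  mi_based <- criterion %in% c("MID", "MIQ")
  bins <- if (mi_based) setNames(lapply(X, bin_codes, n_bins = n_bins), feats)
  yf <- factor(y)
  yi <- as.integer(yf)
  relevance <- switch(criterion,
    MID = , MIQ = vapply(feats, function(f) {
      if (bins[[f]]$n <= 1L) return(0)
      mi_disc(bins[[f]]$codes, bins[[f]]$n, yi, nlevels(yf))
    }, 0),
    FCD = , FCQ = vapply(X, f_statistic, 0, y = y),
    RFCQ = rf_relevance(X, y, seed = seed)[feats]
  )
  red_fun <- if (mi_based) {
    function(a, b) {
      if (bins[[a]]$n <= 1L || bins[[b]]$n <= 1L) return(0)
      mi_disc(bins[[a]]$codes, bins[[a]]$n, bins[[b]]$codes, bins[[b]]$n)
    }
  } else {
    function(a, b) suppressWarnings(pearson_redundancy(X[[a]], X[[b]]))
  }
  quotient <- criterion %in% c("MIQ", "FCQ", "RFCQ")
  selected <- character(0)
  scores <- numeric(0)
  remaining <- feats
  red_sum <- setNames(numeric(length(feats)), feats)
  for (step in seq_len(depth)) {
    if (step == 1L) {
      val <- relevance[remaining]
    } else {
      mean_red <- red_sum[remaining] / length(selected)
      val <- if (quotient) {
        relevance[remaining] / pmax(mean_red, 1e-12)
      } else {
        relevance[remaining] - mean_red
      }
    }
    ord <- order(-val, remaining)
    pick <- remaining[ord[1]]
    selected <- c(selected, pick)
    scores <- c(scores, val[[pick]])
    remaining <- setdiff(remaining, pick)
    for (f in remaining) red_sum[f] <- red_sum[f] + red_fun(f, pick)
  }
  structure(list(criterion = criterion, features = selected, scores = scores),
            class = "ranking_result")
}

#' Frequency-consensus selection over the five mRMR rankings
#'
#' Counts, for every candidate feature, its appearances in the top-5, top-10
#' and top-15 lists of each criterion (15 lists total). Candidates are ordered
#' by frequency (ties by mean rank, then by name); for each size `m` in
#' `m_range` the top-`m` set is scored by seeded stratified inner
#' cross-validated forest AUC, and the best `m` (ties to the smaller) is
#' chosen.
#'
#' @param rankings list of `ranking_result`s over identical candidates.
#' @param X,y training features and labels for the inner CV.
#' @param m_range integer range of set sizes (default 5:15).
#' @param cutoffs top-k cutoffs counted (default `c(5, 10, 15)`).
#' @param n_folds inner CV folds.
#' @param n_trees forest size for the inner CV.
#' @param seed integer seed.
#' @return a `consensus_selection`: `frequency` table, ordered `candidates`,
#'   `chosen_set`, `chosen_m`, and `cv_auc` per `m`.
#' @export
consensus_select <- function(rankings, X, y, m_range = 5:15,
                             cutoffs = c(5, 10, 15), n_folds = 5,
                             n_trees = 200, seed = 1) {
  cand_sets <- lapply(rankings, function(r) sort(r$features))
  all_feats <- sort(unique(unlist(cand_sets)))
  depth <- max(vapply(rankings, function(r) length(r$features), 0L))
  if (length(all_feats) < max(m_range)) {
    warnf("only %d candidates: m_range truncated", length(all_feats))
    m_range <- m_range[m_range <= length(all_feats)]
  }
  freq <- setNames(numeric(length(all_feats)), all_feats)
  rank_sum <- setNames(numeric(length(all_feats)), all_feats)
  rank_n <- setNames(numeric(length(all_feats)), all_feats)
  for (r in rankings) {
    pos <- seq_along(r$features)
    rank_sum[r$features] <- rank_sum[r$features] + pos
    rank_n[r$features] <- rank_n[r$features] + 1
    for (k in cutoffs) {
      topk <- head(r$features, k)
      freq[topk] <- freq[topk] + 1
    }
  }
  mean_rank <- ifelse(rank_n > 0, rank_sum / pmax(rank_n, 1), depth + 1)
  ordered <- all_feats[order(-freq, mean_rank, all_feats)]
  X <- as.data.frame(X)
  y <- factor(y)
  folds <- stratified_folds(y, n_folds, seed = derive_seed(seed, "consensus_cv"))
  cv_auc <- vapply(m_range, function(m) {
    sel <- head(ordered, m)
    aucs <- vapply(seq_len(n_folds), function(f) {
      tr <- folds != f; te <- folds == f
      if (length(unique(y[te])) < 2L || length(unique(y[tr])) < 2L) return(NA_real_)
      fit <- rf_fit(X[tr, sel, drop = FALSE], y[tr], n_trees = n_trees,
                    seed = derive_seed(seed, "consensus_rf", m * 100 + f))
      roc_auc(predict(fit, X[te, sel, drop = FALSE]),
              y[te] == levels(y)[2])
    }, 0)
    mean(aucs, na.rm = TRUE)
  }, 0)
  best <- m_range[order(-cv_auc, m_range)][1]
  structure(list(frequency = freq, candidates = ordered,
                 chosen_set = head(ordered, best), chosen_m = best,
                 cv_auc = setNames(cv_auc, m_range)),
            class = "consensus_selection")
}

# deterministic stratified fold assignment
stratified_folds <- function(y, n_folds, seed = 1) {
  folds <- integer(length(y))
  withr::with_seed(seed, {
    for (lev in levels(factor(y))) {
      ids <- sample(which(y == lev))
      folds[ids] <- rep_len(seq_len(n_folds), length(ids))
    }
  })
  folds
}

#' Run all five mRMR criteria and the consensus selection
#'
#' @param X training feature table (without id columns).
#' @param y training labels.
#' @param depth ranking depth (default 15).
#' @param m_range consensus sizes.
#' @param seed integer seed.
#' @param n_bins MI binning.
#' @return list with `rankings` (per criterion) and `consensus`.
#' @export
select_features <- function(X, y, depth = 15, m_range = 5:15, seed = 1,
                            n_bins = 8) {
  rankings <- lapply(mrmr_criteria, function(cr)
    mrmr_rank(X, y, cr, depth = depth, n_bins = n_bins,
              seed = derive_seed(seed, "mrmr", match(cr, mrmr_criteria))))
  names(rankings) <- mrmr_criteria
  consensus <- consensus_select(rankings, X, y, m_range = m_range, seed = seed)
  list(rankings = rankings, consensus = consensus)
}
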