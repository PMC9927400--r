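# Gaussian-mixture cluster-stratified data division: EM with k-means++
# initialization and BIC model selection, then a per-(cluster x class)
# round-robin deal into five groups with one group held out as the test set.

log_dmvnorm <- function(x, mean, chol_sigma) {
  d <- length(mean)
  z <- backsolve(chol_sigma, t(x) - mean, transpose = TRUE)
  -0.5 * d * log(2 * pi) - sum(log(diag(chol_sigma))) - 0.5 * colSums(z^2)
}

kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    probs <- if (sum(d2) == 0) rep(1 / n, n) else d2 / sum(d2)
    centers[j + 1, ] <- x[sample.int(n, 1, prob = probs), ]
    d2 <- pmin(d2, rowSums((x - matrix(centers[j + 1, ], n, ncol(x), byrow = TRUE))^2))
  }
  centers
}

em_gmm <- function(x, k, max_iter = 50, tol = 1e-6, ridge = 1e-3) {
  n <- nrow(x); d <- ncol(x)
  centers <- kmeanspp_centers(x, k)
  km <- suppressWarnings(kmeans(x, centers = centers, iter.max = 20))
  weights <- pmax(km$size, 1) / sum(pmax(km$size, 1))
  means <- km$centers
  sig_global <- cov(x) * (n - 1) / n + diag(ridge, d)
  sigmas <- lapply(seq_len(k), function(j) {
    xi <- x[km$cluster == j, , drop = FALSE]
    if (nrow(xi) > d + 1) {
      s <- cov(xi) * (nrow(xi) - 1) / nrow(xi) + diag(ridge, d)
      if (inherits(try(chol(s), silent = TRUE), "try-error")) sig_global else s
    } else sig_global
  })
  ll_trace <- numeric(0)
  resp <- matrix(0, n, k)
  for (iter in seq_len(max_iter)) {
    logdens <- vapply(seq_len(k), function(j) {
      ch <- tryCatch(chol(sigmas[[j]]),
                     error = function(e) chol(sigmas[[j]] + diag(1e-4, d)))
      log(weights[j]) + log_dmvnorm(x, means[j, ], ch)
    }, numeric(n))
    mx <- apply(logdens, 1, max)
    lse <- mx + log(rowSums(exp(logdens - mx)))
    ll <- sum(lse)
    # ridge-regularized M-steps maximize a penalized objective; stop as soon
    # as the raw log-likelihood stops improving so the trace is monotone
    if (iter > 1 && (!is.finite(ll) || ll < ll_trace[iter - 1])) break
    ll_trace <- c(ll_trace, ll)
    resp <- exp(logdens - lse)
    if (iter > 1 && abs(ll - ll_trace[iter - 1]) < tol * abs(ll)) break
    nk <- colSums(resp)
    weights <- nk / n
    means <- t(resp) %*% x / nk
    sigmas <- lapply(seq_len(k), function(j) {
      xc <- x - matrix(means[j, ], n, d, byrow = TRUE)
      s <- t(xc * resp[, j]) %*% xc / nk[j] + diag(ridge, d)
      s
    })
  }
  list(k = k, weights = as.numeric(weights), means = means, sigmas = sigmas,
       loglik = ll_trace, resp = resp,
       n_params = (k - 1) + k * d + k * d * (d + 1) / 2)
}

#' Fit a Gaussian mixture model with BIC-selected component count
#'
#' Features are z-scored internally; for each K in `k_range` EM is run from
#' `n_restarts` k-means++ initializations (10 by default) and the best
#' log-likelihood fit is kept; the K minimizing BIC wins. Singular
#' covariances are ridge-regularized. The per-iteration log-likelihood trace
#' of the winning fit is retained.
#'
#' @param features numeric matrix/data.frame (rows = lesions).
#' @param k_range candidate component counts (default 2:8; truncated so that
#'   `n >= 10 K`).
#' @param seed integer seed.
#' @param n_restarts restarts per K.
#' @param standardize z-score the features first (recommended).
#' @return a `gmm_model` with weights, means, covariances, `loglik` trace,
#'   `cluster` hard assignments, `bic` per K.
#' @export
fit_gmm <- function(features, k_range = 2:8, seed = 1, n_restarts = 10,
                    standardize = TRUE) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (standardize) {
    sds <- apply(x, 2, sd)
    x <- scale(x[, sds > 0, drop = FALSE])
  }
  k_range <- k_range[k_range >= 1 & n >= 10 * k_range]
  if (length(k_range) == 0L) stopf("n = %d too small for requested k_range", n)
  fits <- withr::with_seed(derive_seed(seed, "gmm"), {
    lapply(k_range, function(k) {
      best <- NULL
      for (r in seq_len(n_restarts)) {
        fit <- em_gmm(x, k)
        if (is.null(best) || max(fit$loglik) > max(best$loglik)) best <- fit
      }
      best
    })
  })
  bic <- vapply(seq_along(k_range), function(i) {
    -2 * max(fits[[i]]$loglik) + fits[[i]]$n_params * log(n)
  }, 0)
  best <- which.min(bic)
  fit <- fits[[best]]
  structure(list(k = fit$k, weights = fit$weights, means = fit$means,
                 sigmas = fit$sigmas, loglik = fit$loglik,
                 cluster = max.col(fit$resp),
                 bic = setNames(bic, k_range), seed = seed),
            class = "gmm_model")
}

#' Cluster-and-class stratified division into groups
#'
#' Within every (cluster x class) cell, members are shuffled (seeded) and
#' dealt round-robin into `n_groups` groups (the starting group rotates per
#' cell so no group is systematically favoured). One group — `fold` if given,
#' otherwise derived from the seed — becomes the test set.
#'
#' @param gmm a fitted [fit_gmm()] model (its `cluster` assignment is used).
#' @param labels class labels, one per row used to fit the GMM.
#' @param n_groups number of groups (default 5).
#' @param seed integer seed.
#' @param fold which group is the test set (1-based; default seed-derived).
#' @param ids optional lesion ids.
#' @return a `split_assignment` data.frame: `id`, `cluster`, `group`, `role`.
#' @export
stratified_group_split <- function(gmm, labels, n_groups = 5, seed = 1,
                                   fold = NULL, ids = NULL) {
  cluster <- if (inherits(gmm, "gmm_model")) gmm$cluster else as.integer(gmm)
  n <- length(cluster)
  stopifnot(length(labels) == n)
  ids <- ids %||% seq_len(n)
  group <- integer(n)
  cells <- split(seq_len(n), list(cluster, labels), drop = TRUE)
  withr::with_seed(derive_seed(seed, "group_split"), {
    for (ci in seq_along(cells)) {
      members <- cells[[ci]]
      members <- members[sample.int(length(members))]
      start <- (ci - 1L) %% n_groups
      group[members] <- ((seq_along(members) - 1L + start) %% n_groups) + 1L
    }
  })
  test_group <- fold %||% (derive_seed(seed, "test_group") %% n_groups + 1L)
  out <- data.frame(id = ids, cluster = cluster, group = group,
                    role = ifelse(group == test_group, "test", "train"),
                    stringsAsFactors = FALSE)
  attr(out, "test_group") <- test_group
  class(out) <- c("split_assignment", "data.frame")
  out
}
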