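# Clinical screening (univariate P < 0.1 -> multivariate P < 0.05 logistic
# regression, non-CR as the event), SMOTE balancing of the training data,
# and the seeded random-forest clinical / radiomics models.

clinical_variables <- c("gender", "age", "cea", "ca19_9", "nodule_size_cat",
                        "location", "distance1", "distance2", "pneumothorax",
                        "iah")

# logistic fit with a ridge fallback when glm fails to converge or separates
safe_logistic <- function(formula, data) {
  fit <- suppressWarnings(glm(formula, data = data, family = binomial()))
  penalized <- FALSE
  if (!fit$converged || any(abs(coef(fit)[-1]) > 15, na.rm = TRUE)) {
    # ridge-penalized Newton refit (Firth-style stabilization stand-in)
    X <- model.matrix(formula, data)
    yy <- model.response(model.frame(formula, data))
    if (is.factor(yy)) yy <- as.integer(yy) - 1L
    b <- rep(0, ncol(X))
    lambda <- 1
    for (it in 1:50) {
      eta <- drop(X %*% b)
      mu <- plogis(eta)
      W <- mu * (1 - mu)
      H <- crossprod(X, X * W) + diag(lambda, ncol(X))
      g <- crossprod(X, yy - mu) - lambda * b
      step <- solve(H, g)
      b <- b + step
      if (max(abs(step)) < 1e-8) break
    }
    vc <- solve(crossprod(X, X * plogis(drop(X %*% b)) *
                            (1 - plogis(drop(X %*% b)))) + diag(lambda, ncol(X)))
    fit <- list(coefficients = setNames(drop(b), colnames(X)), vcov = vc,
                penalized = TRUE)
    penalized <- TRUE
  }
  list(fit = fit, penalized = penalized)
}

coef_table <- function(fit) {
  if (is.list(fit) && !is.null(fit$penalized) && isTRUE(fit$penalized)) {
    b <- fit$coefficients
    se <- sqrt(diag(fit$vcov))
  } else {
    b <- coef(fit)
    se <- sqrt(diag(vcov(fit)))
  }
  z <- b / se
  data.frame(term = names(b), estimate = unname(b), se = unname(se),
             or = exp(unname(b)),
             ci_lo = exp(unname(b - 1.96 * se)),
             ci_hi = exp(unname(b + 1.96 * se)),
             p = 2 * pnorm(-abs(unname(z))),
             stringsAsFactors = FALSE)
}

# variable-level p: Wald for single-df terms, LR test for multi-level factors
variable_p <- function(var, data, labels) {
  d <- data.frame(y = labels, x = data[[var]])
  if (length(unique(na.omit(d$x))) < 2L) return(NA_real_)
  f1 <- suppressWarnings(glm(y ~ x, data = d, family = binomial()))
  f0 <- suppressWarnings(glm(y ~ 1, data = d, family = binomial()))
  pchisq(f0$deviance - f1$deviance, df = f1$df.null - f1$df.residual,
         lower.tail = FALSE)
}

#' Univariate logistic screening of clinical variables
#'
#' One logistic fit per variable with non-CR as the event; multi-level
#' location is dummy-coded against the right-upper-lobe reference and
#' retained on its likelihood-ratio p. Constant variables are skipped with a
#' warning.
#'
#' @param clinical clinical data.frame (see [sample_clinical()]).
#' @param labels factor with levels `CR`, `nonCR`.
#' @param alpha retention threshold (default 0.1).
#' @param variables variables to screen.
#' @return a `screening_result` data.frame with per-term OR/CI/p plus a
#'   `retained` attribute listing variables with p < `alpha`.
#' @export
univariate_screen <- function(clinical, labels, alpha = 0.1,
                              variables = intersect(clinical_variables,
                                                    names(clinical))) {
  if (length(labels) < 50L) warnf("univariate screening on n < 50 is fragile")
  y <- as.integer(factor(labels, levels = c("CR", "nonCR"))) - 1L
  rows <- list()
  retained <- character(0)
  pvals <- setNames(numeric(0), character(0))
  for (v in variables) {
    if (length(unique(na.omit(clinical[[v]]))) < 2L) {
      warnf("variable '%s' is constant: skipped", v)
      next
    }
    d <- data.frame(y = y, clinical[v])
    sf <- safe_logistic(as.formula(paste("y ~", v)), d)
    tab <- coef_table(sf$fit)
    tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
    tab$variable <- v
    tab$penalized <- sf$penalized
    p_var <- variable_p(v, clinical, y)
    tab$p_variable <- p_var
    rows[[v]] <- tab
    pvals[v] <- p_var
    if (!is.na(p_var) && p_var < alpha) retained <- c(retained, v)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "retained") <- retained
  attr(out, "alpha") <- alpha
  attr(out, "p_values") <- pvals
  class(out) <- c("screening_result", "data.frame")
  out
}

#' Multivariate logistic screening of univariate-retained variables
#'
#' Joint logistic fit of the candidates; rank-deficient (collinear) columns
#' are dropped with a message. Variables with p < `alpha` (per-term Wald, or
#' LR for multi-level factors) are the independent factors used by the
#' clinical model.
#'
#' @param clinical clinical data.frame.
#' @param labels factor with levels `CR`, `nonCR`.
#' @param candidates variable names from the univariate stage.
#' @param alpha retention threshold (default 0.05).
#' @return a `screening_result` data.frame with a `retained` attribute.
#' @export
multivariate_screen <- function(clinical, labels, candidates, alpha = 0.05) {
  if (length(candidates) == 0L) stopf("no candidate variables")
  y <- as.integer(factor(labels, levels = c("CR", "nonCR"))) - 1L
  d <- data.frame(y = y, clinical[candidates])
  f <- as.formula(paste("y ~", paste(candidates, collapse = " + ")))
  sf <- safe_logistic(f, d)
  tab <- coef_table(sf$fit)
  tab <- tab[tab$term != "(Intercept)", , drop = FALSE]
  tab <- tab[is.finite(tab$estimate), , drop = FALSE]
  retained <- character(0)
  pvals <- setNames(numeric(0), character(0))
  full <- suppressWarnings(glm(f, data = d, family = binomial()))
  for (v in candidates) {
    if (is.factor(d[[v]]) && nlevels(droplevels(d[[v]])) > 2L) {
      red <- suppressWarnings(glm(
        as.formula(paste("y ~", paste(setdiff(candidates, v), collapse = " + "),
                         if (length(candidates) == 1L) "1" else "")),
        data = d, family = binomial()))
      p_var <- pchisq(red$deviance - full$deviance,
                      df = red$df.residual - full$df.residual,
                      lower.tail = FALSE)
    } else {
      term_rows <- grep(paste0("^", v), tab$term)
      p_var <- if (length(term_rows)) min(tab$p[term_rows]) else NA_real_
    }
    pvals[v] <- p_var
    if (!is.na(p_var) && p_var < alpha) retained <- c(retained, v)
  }
  tab$variable <- vapply(tab$term, function(tm) {
    hit <- candidates[startsWith(tm, candidates)]
    if (length(hit)) hit[which.max(nchar(hit))] else tm
  }, "")
  rownames(tab) <- NULL
  attr(tab, "retained") <- retained
  attr(tab, "alpha") <- alpha
  attr(tab, "p_values") <- pvals
  class(tab) <- c("screening_result", "data.frame")
  tab
}

#' SMOTE oversampling of the minority class
#'
#' Each synthetic observation is a convex combination of a minority point and
#' one of its `k` minority-class nearest neighbours (Euclidean); the minority
#' class is raised to the majority count. Training data only — never apply to
#' a test fold.
#'
#' @param X numeric matrix/data.frame.
#' @param y two-level factor.
#' @param k neighbours (reduced with a warning if the minority class has
#'   fewer than `k + 1` members).
#' @param seed integer seed.
#' @return list with balanced `X` (matrix), `y`, and logical `synthetic`
#'   flags.
#' @export
smote_balance <- function(X, y, k = 5, seed = 1) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  y <- factor(y)
  tab <- table(y)
  if (length(tab) != 2L) stopf("smote_balance requires exactly 2 classes")
  minor <- names(tab)[which.min(tab)]
  n_needed <- max(tab) - min(tab)
  if (n_needed == 0L)
    return(list(X = X, y = y, synthetic = rep(FALSE, nrow(X))))
  Xm <- X[y == minor, , drop = FALSE]
  nm <- nrow(Xm)
  if (nm < 2L) stopf("minority class too small for SMOTE (n = %d)", nm)
  if (nm < k + 1L) {
    k <- nm - 1L
    warnf("minority class smaller than k + 1: k reduced to %d", k)
  }
  D <- as.matrix(dist(Xm))
  diag(D) <- Inf
  nn <- t(apply(D, 1, function(r) order(r)[seq_len(k)]))
  synth <- withr::with_seed(derive_seed(seed, "smote"), {
    base_idx <- rep_len(seq_len(nm), n_needed)
    nb_idx <- nn[cbind(base_idx, sample.int(k, n_needed, replace = TRUE))]
    gap <- runif(n_needed)
    Xm[base_idx, , drop = FALSE] +
      gap * (Xm[nb_idx, , drop = FALSE] - Xm[base_idx, , drop = FALSE])
  })
  list(X = rbind(X, synth),
       y = factor(c(as.character(y), rep(minor, n_needed)), levels = levels(y)),
       synthetic = c(rep(FALSE, nrow(X)), rep(TRUE, n_needed)))
}

#' Train a clinical or radiomics random-forest model
#'
#' The training rows are SMOTE-balanced, then a seeded forest (500 trees,
#' `sqrt(p)` features per split) is fit. Confidences returned by
#' [predict_scores()] are probabilities of complete response (CR), so the two
#' class confidences sum to one per lesion.
#'
#' @param X training predictors: the multivariate-retained clinical design
#'   (`kind = "clinical"`) or the consensus radiomics features
#'   (`kind = "radiomics"`).
#' @param y labels with levels `CR`, `nonCR`.
#' @param kind model tag.
#' @param n_trees forest size.
#' @param seed integer seed.
#' @param smote apply SMOTE balancing (default TRUE).
#' @return an `ablation_model`.
#' @export
train_rf <- function(X, y, kind = c("clinical", "radiomics"), n_trees = 500,
                     seed = 1, smote = TRUE) {
  kind <- match.arg(kind)
  y <- factor(y, levels = c("nonCR", "CR")) # CR = positive (second) class
  if (any(is.na(y))) stopf("labels must be CR/nonCR")
  X <- as.matrix(X)
  if (length(unique(y)) < 2L) stopf("single-class training data")
  if (smote) {
    bal <- smote_balance(X, y, seed = derive_seed(seed, paste0(kind, "_smote")))
    X <- bal$X
    y <- bal$y
  }
  fit <- rf_fit(X, y, n_trees = n_trees, seed = derive_seed(seed, kind))
  structure(list(fit = fit, kind = kind, features = colnames(X)),
            class = "ablation_model")
}

#' Predict CR confidences
#'
#' @param model an `ablation_model` from [train_rf()].
#' @param X predictor matrix with the training columns.
#' @return numeric vector in `[0, 1]`: confidence of complete response.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "ablation_model"))
  predict(model$fit, as.matrix(X))
}

#' Build the clinical design matrix
#'
#' Continuous variables enter as-is; factors are dummy-coded against their
#' first level (right upper lobe for location).
#'
#' @param clinical clinical data.frame.
#' @param variables retained variable names.
#' @return numeric model matrix without intercept.
#' @export
clinical_design <- function(clinical, variables) {
  f <- as.formula(paste("~", paste(variables, collapse = " + ")))
  mm <- model.matrix(f, clinical)
  mm[, colnames(mm) != "(Intercept)", drop = FALSE]
}
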