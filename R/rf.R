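#' Fit a random forest classifier
#'
#' Bagged CART trees with Gini splits and `mtry` features considered per
#' split. Binary classification only; `y` must be a two-level factor whose
#' second level is the positive class. Fits are reproducible from `seed` and
#' independent of R's RNG state.
#'
#' @param X numeric matrix or data.frame of predictors.
#' @param y two-level factor (or 0/1 vector).
#' @param n_trees number of trees (default 500).
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param min_node minimum node size.
#' @param seed integer seed.
#' @return an `rf_model` with the fitted forest, levels and importance.
#' @export
rf_fit <- function(X, y, n_trees = 500, mtry = NULL, min_node = 1, seed = 1) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (!is.factor(y)) y <- factor(y)
  if (nlevels(y) != 2L) stopf("rf_fit requires exactly 2 classes, got %d", nlevels(y))
  yi <- as.integer(y) - 1L
  if (length(unique(yi)) < 2L) stopf("single-class training data")
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(X))))
  ptr <- .rf_fit_cpp(X, yi, as.integer(n_trees), as.integer(mtry),
                     as.integer(min_node), as.integer(seed))
  structure(list(forest = ptr, levels = levels(y), p = ncol(X),
                 colnames = colnames(X), n_trees = n_trees, mtry = mtry,
                 seed = seed),
            class = "rf_model")
}

#' Predict class-probabilities from a random forest
#'
#' @param object an `rf_model`.
#' @param newdata matrix/data.frame with the training columns.
#' @param ... unused.
#' @return numeric vector of probabilities of the positive (second) class.
#' @export
predict.rf_model <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  storage.mode(X) <- "double"
  if (ncol(X) != object$p) stopf("newdata has %d columns, model expects %d",
                                 ncol(X), object$p)
  if (!is.null(object$colnames) && !is.null(colnames(X)))
    X <- X[, object$colnames, drop = FALSE]
  as.numeric(.rf_predict_cpp(object$forest, X))
}

#' Impurity-decrease importance of a fitted forest
#'
#' @param model an `rf_model`.
#' @return non-negative named scores normalized to sum to 1.
#' @export
rf_importance <- function(model) {
  stopifnot(inherits(model, "rf_model"))
  setNames(as.numeric(.rf_importance_cpp(model$forest)),
           model$colnames %||% paste0("V", seq_len(model$p)))
}
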