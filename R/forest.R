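#' Fit a single regression tree
#'
#' Grows one CART-style regression tree with mean-squared-error impurity.
#' At every node the chosen (feature, threshold) pair minimizes the weighted
#' child impurity \eqn{G(x_i, v_{ij}) = (n_{left} H(X_{left}) + n_{right}
#' H(X_{right})) / N_s} over all candidate splits, where the candidate
#' thresholds are midpoints between consecutive distinct sorted feature
#' values; ties are broken by lowest feature index then lowest threshold.
#' Leaves predict the mean response of their training samples.
#'
#' @param x Numeric matrix or data frame of features (samples x features).
#' @param y Numeric response vector.
#' @param min_split Minimum samples in a node to attempt a split (default 2).
#' @param min_leaf Minimum samples per child (default 1).
#' @param mtry Features considered per split; defaults to all features for a
#'   single tree.
#' @param seed Optional integer seed (only relevant when `mtry < ncol(x)`).
#' @return An object of class `wq_tree`: a data frame of nodes (`feature`,
#'   `threshold`, `left`, `right`, `n_node`, `impurity`, `value`; ids are
#'   1-based, `feature` is `NA` at leaves) with the feature names attached.
#' @export
fit_tree <- function(x, y, min_split = 2L, min_leaf = 1L, mtry = NULL,
                     seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 1L) stop("need at least one sample")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (any(!is.finite(y)) || any(!is.finite(x)))
    stop("features and response must be finite")
  if (is.null(mtry)) mtry <- ncol(x)
  if (!is.null(seed)) set.seed(seed)
  fit <- cpp_fit_forest(x, as.numeric(y), 1L, as.integer(mtry),
                        as.integer(min_split), as.integer(min_leaf), FALSE)
  structure(tree_frame(fit$trees[[1L]]),
            features = colnames(x), class = c("wq_tree", "data.frame"))
}

tree_frame <- function(tr) {
  data.frame(feature = ifelse(tr$feature < 0, NA_integer_,
                              tr$feature + 1L),
             threshold = tr$threshold,
             left = ifelse(tr$left < 0, NA_integer_, tr$left + 1L),
             right = ifelse(tr$right < 0, NA_integer_, tr$right + 1L),
             n_node = tr$n_node, impurity = tr$impurity, value = tr$value)
}

#' @export
predict.wq_tree <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  tr <- list(feature = ifelse(is.na(object$feature), -1L,
                              object$feature - 1L),
             threshold = object$threshold,
             left = ifelse(is.na(object$left), -1L, object$left - 1L),
             right = ifelse(is.na(object$right), -1L, object$right - 1L),
             value = object$value)
  cpp_predict_forest(list(tr), x)
}

#' Fit a regression forest
#'
#' An ensemble of regression trees, each grown on an independent bootstrap
#' resample of the training data with a fresh random feature subset drawn at
#' every node; the forest prediction is the mean over trees. Defaults follow
#' the usual regression-forest conventions: 500 trees, `mtry = max(1,
#' floor(m/3))`, unlimited depth, minimum two samples to split and one per
#' leaf.
#'
#' @param x Numeric matrix or data frame of features (samples x features).
#' @param y Numeric response vector.
#' @param n_trees Number of trees (>= 1, default 500).
#' @param mtry Features tried per split (default `max(1, floor(m/3))`).
#' @param min_split,min_leaf Growth limits, as in [fit_tree()].
#' @param bootstrap Draw a bootstrap resample per tree (default TRUE).
#' @param seed Optional integer seed; fixed seed gives bit-identical forests.
#' @return An object of class `wq_forest` with elements `trees` (internal
#'   node arrays), `importance_matrix` (per-tree normalized importances),
#'   `features`, and the fit settings.
#' @export
fit_forest <- function(x, y, n_trees = 500L, mtry = NULL, min_split = 2L,
                       min_leaf = 1L, bootstrap = TRUE, seed = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (n_trees < 1L) stop("n_trees must be >= 1")
  if (length(y) != nrow(x)) stop("length(y) must equal nrow(x)")
  if (any(!is.finite(y)) || any(!is.finite(x)))
    stop("features and response must be finite")
  if (is.null(mtry)) mtry <- max(1L, floor(ncol(x) / 3))
  mtry <- min(as.integer(mtry), ncol(x))
  if (!is.null(seed)) set.seed(seed)
  fit <- cpp_fit_forest(x, as.numeric(y), as.integer(n_trees), mtry,
                        as.integer(min_split), as.integer(min_leaf),
                        isTRUE(bootstrap))
  imp <- fit$importance
  colnames(imp) <- colnames(x)
  structure(list(trees = fit$trees, importance_matrix = imp,
                 features = colnames(x), n_features = ncol(x),
                 n_trees = as.integer(n_trees),
                 mtry = mtry, min_split = min_split, min_leaf = min_leaf,
                 bootstrap = isTRUE(bootstrap), seed = seed),
            class = "wq_forest")
}

#' @export
predict.wq_forest <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (!is.null(colnames(x)) && !is.null(object$features) &&
      all(object$features %in% colnames(x)))
    x <- x[, object$features, drop = FALSE]
  if (ncol(x) != object$n_features)
    stop("newdata must supply the ", object$n_features,
         " training features")
  cpp_predict_forest(object$trees, x)
}

#' @export
print.wq_forest <- function(x, ...) {
  cat(sprintf("Regression forest: %d trees, %d features, mtry %d\n",
              x$n_trees, length(x$features), x$mtry))
  invisible(x)
}

#' Mean-decrease-impurity feature importance of a forest
#'
#' Within each tree, the importance of internal node k is
#' \eqn{n_k = w_k H_k - w_{left} H_{left} - w_{right} H_{right}}, with
#' weights equal to the node's share of the tree's training samples and H
#' the node MSE impurity. A feature's raw importance is the sum of \eqn{n_k}
#' over the nodes splitting on it divided by the sum over all internal
#' nodes, then normalized so the per-tree importances sum to one. The
#' forest-level importance is the mean of the per-tree normalized vectors
#' (trees without any split are excluded).
#'
#' @param forest A `wq_forest`.
#' @return A named numeric vector of class `wq_importance` summing to one.
#'   If no tree in the forest made any split the importance is undefined:
#'   all entries are `NA` and the attribute `undefined` is `TRUE`.
#' @export
feature_importance <- function(forest) {
  stopifnot(inherits(forest, "wq_forest"))
  imp <- forest$importance_matrix
  ok <- !is.na(imp[, 1L])
  if (!any(ok)) {
    out <- setNames(rep(NA_real_, ncol(imp)), colnames(imp))
    attr(out, "undefined") <- TRUE
    class(out) <- "wq_importance"
    return(out)
  }
  out <- colMeans(imp[ok, , drop = FALSE])
  attr(out, "undefined") <- FALSE
  class(out) <- "wq_importance"
  out
}

#' @export
print.wq_importance <- function(x, ...) {
  v <- sort(unclass(x), decreasing = TRUE)
  cat("Normalized feature importances (sum = 1):\n")
  print(round(v, 4))
  invisible(x)
}

#' Regression evaluation metrics
#'
#' Standard definitions: \eqn{R^2 = 1 - \sum(y - \hat y)^2 / \sum(y - \bar
#' y)^2}, MSE, MAE, and MAPE = mean(|y - \eqn{\hat y}| / |y|) reported in
#' percent. When any observed value is zero, MAPE is undefined and returned
#' as `NA` (the other metrics are still computed).
#'
#' @param y_true Observed values (length >= 2).
#' @param y_pred Predicted values, same length.
#' @return A list of class `wq_metrics` with `r2`, `mse`, `mae`,
#'   `mape_pct`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2L) stop("need at least two observations")
  resid <- y_true - y_pred
  mse <- mean(resid^2)
  mae <- mean(abs(resid))
  ss_tot <- sum((y_true - mean(y_true))^2)
  r2 <- if (ss_tot == 0) NA_real_ else 1 - sum(resid^2) / ss_tot
  mape <- if (any(y_true == 0)) NA_real_ else
    100 * mean(abs(resid) / abs(y_true))
  structure(list(r2 = r2, mse = mse, mae = mae, mape_pct = mape),
            class = "wq_metrics")
}

#' @export
print.wq_metrics <- function(x, ...) {
  cat(sprintf("R2 %.4f  MSE %.4g  MAE %.4g  MAPE %.3f%%\n",
              x$r2, x$mse, x$mae, x$mape_pct))
  invisible(x)
}

#' Random train/test partition
#'
#' Uniform random assignment of samples to a training and a held-out test
#' split (default ratio 9:1), without stratification.
#'
#' @param n Number of samples.
#' @param train_fraction Fraction assigned to training (in (0, 1)).
#' @param seed Optional integer seed.
#' @return List with integer index vectors `train` and `test`.
#' @export
train_test_split <- function(n, train_fraction = 0.9, seed = NULL) {
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n_test <- max(1L, round(n * (1 - train_fraction)))
  test <- sort(sample.int(n, n_test))
  list(train = setdiff(seq_len(n), test), test = test)
}
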