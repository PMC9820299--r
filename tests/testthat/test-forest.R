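test_that("degenerate trees and separable splits behave as specified", {
  x <- matrix(c(1, 2, 10, 11), ncol = 1)
  # constant response: root is a leaf predicting that value
  tr0 <- fit_tree(x, rep(3.5, 4))
  expect_equal(nrow(tr0), 1L)
  expect_true(is.na(tr0$feature[1]))
  expect_equal(tr0$value[1], 3.5)

  # separated response: first split strictly between 2 and 10
  tr <- fit_tree(x, c(0, 0, 1, 1))
  expect_gt(tr$threshold[1], 2)
  expect_lt(tr$threshold[1], 10)
  expect_equal(tr$threshold[1], 6) # midpoint of the optimal gap

  # every leaf predicts the mean of its training responses
  set.seed(4)
  xm <- matrix(runif(60), 20, 3)
  y <- runif(20)
  tr2 <- fit_tree(xm, y)
  pred <- predict(tr2, xm)
  leafs <- split(y, pred)
  for (v in names(leafs))
    expect_equal(mean(leafs[[v]]), as.numeric(v))
})

test_that("chosen splits match the exhaustive-enumeration oracle", {
  set.seed(7)
  for (rep in 1:40) {
    n <- sample(2:8, 1)
    m <- sample(1:3, 1)
    x <- matrix(round(runif(n * m, 0, 4), 2), n, m)
    y <- round(runif(n, 0, 10), 2)
    tr <- fit_tree(x, y)
    best <- oracle_best_split(x, y)
    if (is.null(best) || var(y) == 0) {
      next
    }
    expect_equal(tr$feature[1], best$feature)
    expect_equal(tr$threshold[1], best$threshold)
  }
})

test_that("whole-tree structure and importance match the reference grower", {
  set.seed(8)
  for (rep in 1:25) {
    n <- sample(4:8, 1)
    m <- sample(2:3, 1)
    x <- matrix(round(runif(n * m, 0, 4), 2), n, m)
    y <- round(runif(n, 0, 10), 2)
    tr <- fit_tree(x, y)
    ref <- oracle_grow_tree(x, y)
    fn_ref <- oracle_tree_importance(ref, m)
    fn_imp <- walk_tree_importance(tr, m)
    if (all(is.na(fn_ref))) {
      expect_true(all(is.na(fn_imp)))
    } else {
      expect_equal(fn_imp, fn_ref, tolerance = 1e-10)
    }
    # prediction equivalence on the training grid
    pred_ref <- apply(x, 1, function(row) {
      nd <- ref
      while (!is.null(nd$feature))
        nd <- if (row[nd$feature] <= nd$threshold) nd$left else nd$right
      nd$value
    })
    expect_equal(predict(tr, x), as.numeric(pred_ref), tolerance = 1e-12)
  }
})

test_that("per-tree node importances telescope and normalize to one", {
  set.seed(9)
  x <- matrix(runif(120), 40, 3)
  y <- x[, 1] * 2 + runif(40, 0, 0.5)
  fr <- fit_forest(x, y, n_trees = 15, seed = 10)
  expect_equal(rowSums(fr$importance_matrix), rep(1, 15), tolerance = 1e-12)

  imp <- feature_importance(fr)
  expect_equal(sum(imp), 1, tolerance = 1e-12)
  expect_true(all(imp >= 0))

  # telescoping: sum of raw node importances = root term - leaf terms
  tr <- fit_tree(x, y)
  internal <- which(!is.na(tr$feature))
  leaves <- which(is.na(tr$feature))
  n_root <- tr$n_node[1]
  nk_sum <- 0
  for (k in internal) {
    l <- tr$left[k]; r <- tr$right[k]
    nk_sum <- nk_sum + (tr$n_node[k] * tr$impurity[k] -
                          tr$n_node[l] * tr$impurity[l] -
                          tr$n_node[r] * tr$impurity[r]) / n_root
  }
  leaf_sum <- sum(tr$n_node[leaves] * tr$impurity[leaves]) / n_root
  expect_equal(nk_sum, tr$impurity[1] - leaf_sum, tolerance = 1e-10)

  # single-split tree puts all importance on the split feature
  x1 <- matrix(c(0, 0, 1, 1, 5, 6, 7, 8), 4, 2)
  tr1 <- fit_tree(x1, c(0, 0, 10, 10), min_split = 4L, min_leaf = 2L)
  expect_equal(walk_tree_importance(tr1, 2), c(1, 0))
})

test_that("forests are deterministic, reduce to trees, and learn signal", {
  set.seed(11)
  x <- matrix(runif(1000), 500, 2)
  y <- 3 * x[, 1] + rnorm(500, 0, 0.1)

  f1 <- fit_forest(x, y, n_trees = 30, seed = 5)
  f2 <- fit_forest(x, y, n_trees = 30, seed = 5)
  expect_identical(predict(f1, x), predict(f2, x))

  # degenerate ensemble equals a single fully-grown tree
  fd <- fit_forest(x, y, n_trees = 1, mtry = 2, bootstrap = FALSE, seed = 6)
  tt <- fit_tree(x, y)
  expect_equal(predict(fd, x), predict(tt, x))

  sp <- train_test_split(500, 0.9, seed = 7)
  fr <- fit_forest(x[sp$train, ], y[sp$train], n_trees = 60, seed = 8)
  mets <- regression_metrics(y[sp$test], predict(fr, x[sp$test, ]))
  expect_gt(mets$r2, 0) # beats the mean-only predictor

  expect_error(fit_forest(x, y, n_trees = 0), ">= 1")
})

test_that("evaluation metrics follow their standard definitions", {
  y <- c(3, 1, 4, 1, 5)
  perfect <- regression_metrics(y, y)
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$mae, 0)
  expect_equal(perfect$mape_pct, 0)

  mean_only <- regression_metrics(y, rep(mean(y), 5))
  expect_equal(mean_only$r2, 0)

  hand <- regression_metrics(c(100, 50), c(90, 55))
  expect_equal(hand$mae, 7.5)
  expect_equal(hand$mape_pct, 10)
  expect_equal(hand$mse, (100 + 25) / 2)

  withzero <- regression_metrics(c(0, 2), c(1, 2))
  expect_true(is.na(withzero$mape_pct))
  expect_equal(withzero$mae, 0.5)
})

test_that("importance ranking agrees with a reference forest on clear signal", {
  skip_if_not_installed("randomForest")
  set.seed(12)
  n <- 400
  x <- matrix(runif(5 * n), n, 5,
              dimnames = list(NULL, paste0("x", 1:5)))
  y <- 6 * x[, 1] + 3 * x[, 2] + rnorm(n, 0, 0.2)
  fr <- fit_forest(x, y, n_trees = 200, seed = 13)
  imp <- feature_importance(fr)
  rf <- randomForest::randomForest(x, y, ntree = 200, importance = FALSE)
  ref_rank <- order(rf$importance[, 1], decreasing = TRUE)
  expect_equal(order(imp, decreasing = TRUE)[1:2], c(1L, 2L))
  expect_equal(ref_rank[1:2], c(1L, 2L))
})
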