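test_that("parameter ranking is importance-descending with alphabetic ties", {
  imp <- structure(c(Mn = 0.35, Fe = 0.23, F_coli = 0.18, DO = 0.08,
                     TN = 0.04, TP = 0.12), class = "wq_importance")
  expect_equal(rank_parameters(imp)[1:3], c("Mn", "Fe", "F_coli"))

  tied <- structure(setNames(rep(0.25, 4), c("b", "d", "a", "c")),
                    class = "wq_importance")
  expect_equal(rank_parameters(tied), c("a", "b", "c", "d"))

  single <- structure(c(TN = 1), class = "wq_importance")
  expect_equal(rank_parameters(single), "TN")
})

test_that("incremental models are nested, comparable, and k = m matches the reference", {
  ds <- small_dataset(seed = 50, n_stations = 3L, n_months = 40L)
  specs <- default_parameter_specs()
  wqi <- wqi_table(ds, specs)
  x <- ds$values
  sp <- train_test_split(nrow(x), 0.9, seed = 51)
  fr <- fit_forest(x[sp$train, ], wqi$WQI[sp$train], n_trees = 80,
                   seed = 52)
  imp <- feature_importance(fr)
  rk <- rank_parameters(imp)

  rep <- build_wqimin_models(x, wqi$WQI, rk, importance = imp,
                             k_values = c(2, 3, 14), split = sp,
                             n_trees = 80, seed = 52)
  expect_equal(nrow(rep), 4L) # three k rows plus the all-parameter reference

  # cumulative importance is non-decreasing and subsets are ranking prefixes
  expect_true(all(diff(rep$cum_importance[1:3]) >= -1e-12))
  expect_equal(rep$parameters[1], paste(rk[1:2], collapse = " + "))
  expect_equal(rep$parameters[2], paste(rk[1:3], collapse = " + "))

  # the k = m row reproduces the all-parameter reference metrics exactly
  expect_equal(rep[3, c("r2", "mse", "mae", "mape_pct")],
               rep[4, c("r2", "mse", "mae", "mape_pct")],
               ignore_attr = TRUE)
  expect_equal(rep$cum_importance[3], 1, tolerance = 1e-12)

  expect_error(build_wqimin_models(x, wqi$WQI, rk, k_values = 20),
               "exceeds")
})

test_that("a planted predictive pair beats every other two-subset", {
  set.seed(60)
  n <- 300
  x <- matrix(runif(4 * n), n, 4,
              dimnames = list(NULL, c("a", "b", "c", "d")))
  y <- 10 * x[, "a"] + 8 * x[, "c"] + rnorm(n, 0, 0.2)
  sp <- train_test_split(n, 0.9, seed = 61)
  pairs <- combn(colnames(x), 2, simplify = FALSE)
  r2 <- vapply(pairs, function(pp) {
    fr <- fit_forest(x[sp$train, pp], y[sp$train], n_trees = 60, seed = 62)
    regression_metrics(y[sp$test], predict(fr, x[sp$test, pp]))$r2
  }, numeric(1))
  planted <- which(vapply(pairs, setequal, logical(1), c("a", "c")))
  expect_equal(which.max(r2), planted)
})

test_that("best-subset choice follows the within-slack rule", {
  mk <- function(k, r2, mse, mae, mape) {
    structure(data.frame(k = k, parameters = paste0("set", k),
                         cum_importance = NA, r2 = r2, mse = mse, mae = mae,
                         mape_pct = mape),
              class = c("wq_selection", "data.frame"))
  }
  one <- mk(2, 0.9, 1, 0.5, 2)
  expect_equal(select_best(one)$k, 2)

  improving <- structure(rbind(mk(2, 0.8, 3, 1.5, 4), mk(3, 0.9, 2, 1.0, 3),
                               mk(4, 0.95, 1, 0.7, 2)),
                         class = c("wq_selection", "data.frame"))
  expect_equal(select_best(improving, tolerance = 0)$k, 4)
  expect_equal(select_best(improving, tolerance = 1.5)$k, 3)
  expect_equal(select_best(improving, tolerance = 2)$k, 2)

  # the worked comparison: k = 5 dominates k = 4 on every metric
  ladder <- structure(rbind(mk(4, 0.93, 2.99, 1.41, 1.98),
                            mk(5, 0.96, 1.77, 1.06, 1.47)),
                      class = c("wq_selection", "data.frame"))
  expect_equal(select_best(ladder, tolerance = 0)$k, 5)
  expect_error(select_best(ladder[0, ]), "empty")
})
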