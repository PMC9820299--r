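#' Rank parameters by forest feature importance
#'
#' @param importance A `wq_importance` vector (see [feature_importance()]).
#' @return Character vector of parameter names in descending importance;
#'   ties are broken alphabetically for determinism.
#' @export
rank_parameters <- function(importance) {
  if (isTRUE(attr(importance, "undefined")))
    stop("importance is undefined (forest made no splits)")
  v <- unclass(importance)
  names(v)[order(-v, names(v))]
}

#' Build incremental minimal-parameter WQI surrogate models
#'
#' For each subset size k, fits a fresh regression forest on the top-k
#' parameters of the ranking to predict the WQI, evaluates R2, MSE, MAE and
#' MAPE on the held-out split, and records the subset's cumulative share of
#' the full-model feature importance. The same train/test partition is used
#' for every row so the rows are directly comparable, and an all-parameter
#' reference model is always included as the last row.
#'
#' @param x Sample-by-parameter feature matrix (or data frame).
#' @param wqi_values Numeric WQI response, one per sample (computed by the
#'   index engine on the same records).
#' @param ranking Parameter names in descending importance (a prefix
#'   ordering; see [rank_parameters()]).
#' @param importance Optional `wq_importance` vector used for the cumulative
#'   importance column; when `NULL` it is computed from a fresh
#'   all-parameter forest.
#' @param k_values Subset sizes to evaluate (default `2:5`).
#' @param split Optional list with `train`/`test` index vectors; by default
#'   a 9:1 [train_test_split()] drawn under `seed`.
#' @param n_trees Trees per forest (default 500).
#' @param seed Integer seed controlling the split and every forest fit.
#' @return An object of class `wq_selection`: a data frame with columns
#'   `k`, `parameters`, `cum_importance`, `r2`, `mse`, `mae`, `mape_pct`,
#'   with the ranking and split stored as attributes.
#' @export
build_wqimin_models <- function(x, wqi_values, ranking, importance = NULL,
                                k_values = 2:5, split = NULL, n_trees = 500L,
                                seed = 1L) {
  x <- as.matrix(x)
  m <- ncol(x)
  if (any(k_values > m)) stop("subset size k exceeds the parameter count")
  if (!all(ranking %in% colnames(x)))
    stop("ranking names parameters absent from the feature matrix")
  if (length(wqi_values) != nrow(x)) stop("length mismatch: wqi_values")
  if (is.null(split)) split <- train_test_split(nrow(x), 0.9, seed = seed)

  fit_row <- function(params, label) {
    fr <- fit_forest(x[split$train, params, drop = FALSE],
                     wqi_values[split$train], n_trees = n_trees,
                     seed = seed)
    mets <- regression_metrics(wqi_values[split$test],
                               predict(fr, x[split$test, params,
                                             drop = FALSE]))
    list(forest = fr,
         row = data.frame(k = length(params), parameters = label,
                          cum_importance = NA_real_, r2 = mets$r2,
                          mse = mets$mse, mae = mets$mae,
                          mape_pct = mets$mape_pct,
                          stringsAsFactors = FALSE))
  }

  full <- fit_row(colnames(x), "all parameters")
  if (is.null(importance)) importance <- feature_importance(full$forest)
  cum <- cumsum(unclass(importance)[ranking])

  rows <- lapply(sort(unique(as.integer(k_values))), function(k) {
    subset_k <- ranking[seq_len(k)]
    # fit in canonical column order so k = m reproduces the reference row
    params <- colnames(x)[colnames(x) %in% subset_k]
    r <- fit_row(params, paste(subset_k, collapse = " + "))$row
    r$cum_importance <- unname(cum[k])
    r
  })
  full$row$cum_importance <- sum(unclass(importance))
  report <- do.call(rbind, c(rows, list(full$row)))
  rownames(report) <- NULL
  structure(report, ranking = ranking, split = split,
            importance = importance,
            metadata = list(
              metrics_on = "held-out test split",
              cumulative_importance = "subset sum of full-model importances"),
            class = c("wq_selection", "data.frame"))
}

#' Choose the best parameter subset from a selection report
#'
#' Operationalizes a comprehensive evaluation over R2, MSE, MAE and MAPE:
#' the chosen row is the smallest subset whose metrics are all within
#' `tolerance` of the best value attained for that metric across rows
#' (higher-is-better for R2, lower-is-better otherwise). With zero
#' tolerance this returns the metric-optimal row; if no row is
#' simultaneously within tolerance on every metric, the row with the best
#' mean rank across metrics (smallest k on ties) is returned.
#'
#' @param report A `wq_selection` data frame.
#' @param tolerance Non-negative absolute slack per metric (default 0).
#' @return The chosen row of the report (single-row data frame).
#' @export
select_best <- function(report, tolerance = 0) {
  if (nrow(report) == 0L) stop("empty selection report")
  df <- as.data.frame(report)
  vals <- data.frame(r2 = -df$r2, mse = df$mse, mae = df$mae,
                     mape = df$mape_pct) # all lower-is-better
  vals[is.na(vals)] <- Inf
  best <- vapply(vals, min, numeric(1))
  ok <- rowSums(sweep(as.matrix(vals), 2, best) > tolerance) == 0L
  idx <- if (any(ok)) which(ok)[which.min(df$k[ok])] else {
    mean_rank <- rowMeans(apply(as.matrix(vals), 2, rank,
                                ties.method = "min"))
    order(mean_rank, df$k)[1L]
  }
  df[idx, , drop = FALSE]
}

#' @export
print.wq_selection <- function(x, ...) {
  cat("WQI_RFmin parameter-selection report (test-split metrics):\n")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Write a selection report as CSV
#'
#' Columns mirror the conventional selection-table layout: Parameters,
#' Feature Importance (cumulative), R2, MSE, MAE, MAPE (%).
#'
#' @param report A `wq_selection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_selection_csv <- function(report, path) {
  out <- data.frame(Parameters = report$parameters,
                    Feature.Importance = report$cum_importance,
                    R2 = report$r2, MSE = report$mse, MAE = report$mae,
                    MAPE.pct = report$mape_pct)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
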