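#' Normalize a concentration onto the 0-100 sub-index scale
#'
#' Maps measured values through the parameter's breakpoint curve. Linear
#' curves interpolate between breakpoints; step curves return the sub-index
#' tabulated for the breakpoint at or below the value. Values beyond the
#' outermost breakpoints clamp to the outermost tabulated sub-index, so a
#' value at or better than the ideal breakpoint scores 100 and a value at or
#' beyond the worst scores 0.
#'
#' @param value Numeric vector of concentrations.
#' @param spec A [parameter_spec()] object.
#' @return Numeric vector of sub-indices in \[0, 100\].
#' @export
normalize_parameter <- function(value, spec) {
  stopifnot(inherits(spec, "wq_parameter"))
  out <- rep(NA_real_, length(value))
  ok <- !is.na(value)
  if (any(!is.finite(value[ok])))
    stop("non-finite value passed to normalize_parameter for ", spec$name)
  if (!any(ok)) return(out)
  cv <- spec$curve
  if (length(cv$conc) == 1L) {
    out[ok] <- cv$ci
  } else if (cv$interpolation == "step") {
    out[ok] <- approx(cv$conc, cv$ci, xout = value[ok], method = "constant",
                      f = 0, rule = 2)$y
  } else {
    out[ok] <- approx(cv$conc, cv$ci, xout = value[ok], method = "linear",
                      rule = 2)$y
  }
  pmin(pmax(out, 0), 100)
}

#' Grade a WQI value into the five quality classes
#'
#' Band boundaries follow the integer bands 91-100 Excellent, 71-90 Good,
#' 51-70 Moderate, 26-50 Poor and 0-25 Very poor. Real-valued scores are
#' graded by the thresholds Excellent >= 91, Good >= 71, Moderate >= 51,
#' Poor >= 26, else Very poor, applied to the unrounded value, which
#' preserves the printed integer bands while totally ordering all reals.
#'
#' @param value Numeric vector of WQI values in \[0, 100\].
#' @return Character vector of grades.
#' @export
classify_wqi <- function(value) {
  if (any(!is.na(value) & (value < 0 | value > 100)))
    stop("WQI values must lie in [0, 100]")
  cut_pts <- c(-Inf, 26, 51, 71, 91, Inf)
  grades <- c("Very poor", "Poor", "Moderate", "Good", "Excellent")
  grades[findInterval(value, cut_pts, left.open = FALSE)]
}

#' Compute the additive water quality index for one record
#'
#' The index is the weighted mean of the parameter sub-indices,
#' \deqn{WQI = \sum_i C_i P_i / \sum_i P_i,}
#' where \eqn{C_i} is the normalized 0-100 sub-index of parameter i and
#' \eqn{P_i} its weight. Parameters missing from the record (or `NA`) are
#' excluded from both sums, so the index stays a proper weighted mean of the
#' parameters actually measured.
#'
#' @param record Named numeric vector of concentrations.
#' @param specs A `wq_spec_set`; every non-`NA` entry of `record` must have a
#'   matching spec.
#' @return A list of class `wq_wqi` with `value`, `grade` and the
#'   per-parameter `sub_indices`.
#' @export
compute_wqi <- function(record, specs) {
  if (length(record) == 0L || all(is.na(record)))
    stop("record has no measured parameters")
  present <- names(record)[!is.na(record)]
  missing_spec <- setdiff(present, names(specs))
  if (length(missing_spec))
    stop("no spec for parameter(s): ", paste(missing_spec, collapse = ", "))
  ci <- setNames(rep(NA_real_, length(record)), names(record))
  for (nm in present)
    ci[nm] <- normalize_parameter(record[[nm]], specs[[nm]])
  w <- vapply(names(record), function(nm)
    if (nm %in% present) specs[[nm]]$weight else NA_real_, numeric(1))
  ok <- !is.na(ci)
  value <- sum(ci[ok] * w[ok]) / sum(w[ok])
  structure(list(value = value, grade = classify_wqi(value),
                 sub_indices = ci),
            class = "wq_wqi")
}

#' @export
print.wq_wqi <- function(x, ...) {
  cat(sprintf("WQI %.2f (%s)\n", x$value, x$grade))
  invisible(x)
}

#' Compute WQI for every sample of a monitoring dataset
#'
#' @param dataset A `wq_dataset` (see [simulate_monitoring()] or
#'   [read_monitoring_csv()]).
#' @param specs A `wq_spec_set`.
#' @return A data frame with station, date, `WQI`, `grade`, and one `Ci_*`
#'   column per parameter.
#' @export
wqi_table <- function(dataset, specs) {
  stopifnot(inherits(dataset, "wq_dataset"))
  X <- dataset$values
  params <- colnames(X)
  ci <- matrix(NA_real_, nrow(X), ncol(X), dimnames = dimnames(X))
  for (nm in intersect(params, names(specs)))
    ci[, nm] <- normalize_parameter(X[, nm], specs[[nm]])
  w <- vapply(params, function(nm)
    if (nm %in% names(specs)) specs[[nm]]$weight else NA_real_, numeric(1))
  wm <- matrix(w, nrow(X), ncol(X), byrow = TRUE)
  wm[is.na(ci)] <- NA
  value <- rowSums(ci * wm, na.rm = TRUE) / rowSums(wm, na.rm = TRUE)
  out <- data.frame(station = dataset$station, date = dataset$date,
                    WQI = value, grade = classify_wqi(value),
                    stringsAsFactors = FALSE)
  colnames(ci) <- paste0("Ci_", colnames(ci))
  cbind(out, as.data.frame(ci))
}

#' Descriptive screening statistics per parameter and station
#'
#' For each parameter, per station and pooled over all stations: mean,
#' standard deviation, coefficient of variation (CV = sd/mean, percent; `NA`
#' when the mean is zero), and the exceedance rate against each defined
#' class standard in the parameter's harmful direction (above the threshold
#' for pollutants, below for dissolved oxygen, outside the band for pH).
#'
#' @param dataset A `wq_dataset`.
#' @param specs A `wq_spec_set`.
#' @return A data frame with one row per (parameter, station) pair; the
#'   pooled rows carry station `"ALL"`. Exceedance columns are `exceed_I`
#'   ... `exceed_V` (fractions), `NA` for classes without a standard.
#' @export
descriptive_stats <- function(dataset, specs) {
  stopifnot(inherits(dataset, "wq_dataset"))
  if (nrow(dataset$values) == 0L) stop("dataset is empty")
  stations <- c("ALL", unique(as.character(dataset$station)))
  params <- colnames(dataset$values)
  rows <- list()
  for (nm in params) {
    sp <- if (nm %in% names(specs)) specs[[nm]] else NULL
    for (st in stations) {
      x <- if (st == "ALL") dataset$values[, nm] else
        dataset$values[dataset$station == st, nm]
      x <- x[!is.na(x)]
      mu <- mean(x)
      s <- if (length(x) > 1L) sd(x) else 0
      cv <- if (length(x) == 0L || mu == 0) NA_real_ else 100 * s / mu
      ex <- setNames(rep(NA_real_, 5L), c("I", "II", "III", "IV", "V"))
      if (!is.null(sp) && !is.null(sp$class_standards) && length(x)) {
        if (sp$direction == "range") {
          frac <- mean(x < sp$class_standards[["low"]] |
                         x > sp$class_standards[["high"]])
          ex[] <- frac
        } else {
          for (cl in names(sp$class_standards)) {
            thr <- sp$class_standards[[cl]]
            ex[cl] <- if (sp$direction == "below") mean(x < thr)
                      else mean(x > thr)
          }
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        parameter = nm, station = st, n = length(x), mean = mu, sd = s,
        cv_pct = cv, exceed_I = ex[["I"]], exceed_II = ex[["II"]],
        exceed_III = ex[["III"]], exceed_IV = ex[["IV"]],
        exceed_V = ex[["V"]], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
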