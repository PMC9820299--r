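#' Write a monitoring dataset as wide CSV
#'
#' One row per station-month: `station`, `date` (ISO year-month), then one
#' column per parameter in canonical order.
#'
#' @param dataset A `wq_dataset`.
#' @param path Output file path.
#' @param truth_path Optional path prefix for the ground-truth sidecar
#'   files; when the dataset carries planted truth, writes
#'   `<truth_path>_profiles.csv` (F) and `<truth_path>_contributions.csv`
#'   (G).
#' @return `path`, invisibly.
#' @export
write_monitoring_csv <- function(dataset, path, truth_path = NULL) {
  stopifnot(inherits(dataset, "wq_dataset"))
  df <- data.frame(station = as.character(dataset$station),
                   date = format(dataset$date, "%Y-%m"),
                   stringsAsFactors = FALSE)
  vals <- as.data.frame(dataset$values)
  # full-precision text so write-then-read round-trips exactly
  vals[] <- lapply(vals, function(x)
    ifelse(is.na(x), NA_character_, sprintf("%.17g", x)))
  df <- cbind(df, vals)
  write.csv(df, path, row.names = FALSE)
  if (!is.null(truth_path) && !is.null(dataset$truth)) {
    write.csv(as.data.frame(dataset$truth$F),
              paste0(truth_path, "_profiles.csv"), row.names = FALSE)
    write.csv(as.data.frame(dataset$truth$G),
              paste0(truth_path, "_contributions.csv"), row.names = FALSE)
  }
  invisible(path)
}

#' Read a monitoring dataset from wide CSV
#'
#' Expects `station` and `date` columns plus at least one known parameter
#' column. Unknown columns are dropped with a warning; blank cells become
#' missing values; dates are parsed as ISO year-month (a day component is
#' tolerated and ignored).
#'
#' @param path Input CSV path.
#' @param specs Optional `wq_spec_set` supplying the known parameter set
#'   and unit metadata (default [default_parameter_specs()]).
#' @return A `wq_dataset` (without planted truth).
#' @export
read_monitoring_csv <- function(path, specs = default_parameter_specs()) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("station", "date") %in% names(df)))
    stop("input file must have 'station' and 'date' columns")
  known <- names(specs)
  params <- intersect(names(df), known)
  if (length(params) == 0L)
    stop("no known parameter columns found in ", path)
  unknown <- setdiff(names(df), c("station", "date", known))
  if (length(unknown))
    warning("ignoring unknown column(s): ", paste(unknown, collapse = ", "))
  dates <- parse_year_month(df$date)
  bad <- which(is.na(dates))
  if (length(bad))
    stop("unparseable date(s) in rows: ",
         paste(utils::head(bad, 10L), collapse = ", "))
  vals <- as.matrix(df[, params, drop = FALSE])
  storage.mode(vals) <- "double"
  structure(list(
    station = factor(df$station, levels = unique(df$station)),
    date = dates,
    values = vals,
    censored = matrix(FALSE, nrow(vals), ncol(vals),
                      dimnames = list(NULL, params)),
    units = vapply(specs[params], `[[`, character(1), "unit"),
    truth = NULL), class = "wq_dataset")
}

parse_year_month <- function(x) {
  x <- trimws(as.character(x))
  ym <- grepl("^\\d{4}-\\d{2}$", x)
  out <- rep(as.Date(NA), length(x))
  if (any(ym)) out[ym] <- as.Date(paste0(x[ym], "-01"))
  other <- which(!ym)
  for (i in other)
    out[i] <- tryCatch(as.Date(x[i]), error = function(e) as.Date(NA))
  out
}

#' Extract the sample-by-parameter matrix from a dataset
#'
#' @param dataset A `wq_dataset`.
#' @param parameters Optional subset/order of parameter columns.
#' @return Numeric matrix.
#' @export
dataset_matrix <- function(dataset, parameters = NULL) {
  stopifnot(inherits(dataset, "wq_dataset"))
  if (is.null(parameters)) return(dataset$values)
  missing_p <- setdiff(parameters, colnames(dataset$values))
  if (length(missing_p))
    stop("parameters not in dataset: ", paste(missing_p, collapse = ", "))
  dataset$values[, parameters, drop = FALSE]
}
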