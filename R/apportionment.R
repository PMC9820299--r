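#' Attribute WQI variation to pollution sources
#'
#' Combines the forest's normalized feature importances with the PMF
#' species-contribution matrix: source j's contribution to the variation in
#' WQI values is
#' \deqn{p_j = (1 - MAPE) \sum_i fn_i \, c_{ji},}
#' where \eqn{fn_i} is the importance of parameter i in the WQI regression
#' forest, \eqn{c_{ji}} the share of parameter i's modeled mass attributed
#' to source j, and MAPE the surrogate model's mean absolute percentage
#' error (consumed as a fraction, reported in percent). Because the
#' importances sum to one and each c column sums to one, the source
#' contributions plus the model-error term add up to exactly 100%.
#'
#' Parameters carrying importance but absent from the PMF species set are
#' not silently renormalized: their importance mass is reported as an
#' explicit "uncovered importance" row.
#'
#' @param importance `wq_importance` vector (must sum to 1).
#' @param c_matrix `wq_contribution` matrix (columns sum to 1).
#' @param mape Model error as a fraction in \[0, 1) (e.g. 0.0135 for 1.35%).
#' @param labels Optional character vector of source labels (default the
#'   factor names of `c_matrix`).
#' @return An object of class `wq_apportionment`: data frame with columns
#'   `source` and `contribution_pct`, sources in descending contribution,
#'   any uncovered-importance row next, and the model-error row last.
#' @export
apportion_wqi <- function(importance, c_matrix, mape, labels = NULL) {
  if (!is.numeric(mape) || length(mape) != 1L || is.na(mape) ||
      mape < 0 || mape >= 1)
    stop("mape must be a single fraction in [0, 1)")
  fn <- unclass(importance)
  if (isTRUE(attr(importance, "undefined")) || any(is.na(fn)))
    stop("importance is undefined")
  cm <- unclass(c_matrix)
  covered <- intersect(names(fn), colnames(cm))
  if (length(covered) == 0L)
    stop("importance and contribution matrix share no parameters")
  extra <- setdiff(colnames(cm), names(fn))
  if (length(extra))
    cm <- cm[, colnames(cm) %in% names(fn), drop = FALSE]
  uncovered <- setdiff(names(fn), colnames(cm))

  p <- nrow(cm)
  if (is.null(labels)) labels <- rownames(cm)
  if (is.null(labels)) labels <- paste0("F", seq_len(p))
  if (length(labels) != p) stop("need one label per source")

  pj <- (1 - mape) * as.vector(cm[, covered, drop = FALSE] %*%
                                 fn[covered]) * 100
  out <- data.frame(source = labels, contribution_pct = pj,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$contribution_pct), , drop = FALSE]
  if (length(uncovered))
    out <- rbind(out, data.frame(
      source = "uncovered importance",
      contribution_pct = (1 - mape) * sum(fn[uncovered]) * 100))
  out <- rbind(out, data.frame(source = "model error",
                               contribution_pct = mape * 100))
  rownames(out) <- NULL
  structure(out, mape_pct = mape * 100,
            uncovered_parameters = uncovered,
            class = c("wq_apportionment", "data.frame"))
}

#' @export
print.wq_apportionment <- function(x, ...) {
  cat("Source contributions to WQI variation (%):\n")
  print.data.frame(
    data.frame(source = x$source,
               contribution_pct = round(x$contribution_pct, 2)),
    row.names = FALSE)
  cat(sprintf("total: %.4f%%\n", sum(x$contribution_pct)))
  invisible(x)
}

#' Default dominance rules for source labelling
#'
#' Conventional signatures for surface-water pollution sources: microbial
#' contamination (faecal coliform), non-point agricultural pollution
#' (nitrogen species and major ions), nutrient pollution (total
#' phosphorus), and heavy-metal pollution (Fe, Mn). A factor matching no
#' rule is labelled "unexplained variability".
#'
#' @param min_share Minimum mean species share for a rule to fire
#'   (default 0.6).
#' @return Named list of rules, each `list(species =, min_share =)`.
#' @export
default_label_rules <- function(min_share = 0.6) {
  list(
    "microbial contamination" =
      list(species = "F_coli", min_share = min_share),
    "heavy metal pollution" =
      list(species = c("Fe", "Mn"), min_share = min_share),
    "non-point agricultural pollution" =
      list(species = c("TN", "NO3_N", "SO4", "Cl", "F_ion"),
           min_share = min_share),
    "nutrient pollution" = list(species = "TP", min_share = min_share)
  )
}

#' Label PMF factors by dominance rules
#'
#' Each factor receives the first label whose rule it satisfies: the mean
#' of the factor's contribution shares over the rule's species set must
#' reach the rule's minimum share. Factors matching no rule are labelled
#' "unexplained variability".
#'
#' @param c_matrix A `wq_contribution` matrix (factors x species).
#' @param rules Named list of rules (see [default_label_rules()]).
#' @return Character vector of labels, one per factor.
#' @export
label_sources <- function(c_matrix, rules = default_label_rules()) {
  cm <- unclass(c_matrix)
  labels <- rep("unexplained variability", nrow(cm))
  for (j in seq_len(nrow(cm))) {
    for (lab in names(rules)) {
      sp <- intersect(rules[[lab]]$species, colnames(cm))
      if (length(sp) == 0L) next
      if (mean(cm[j, sp]) >= rules[[lab]]$min_share) {
        labels[j] <- lab
        break
      }
    }
  }
  labels
}
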