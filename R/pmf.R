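#' Build the measurement-uncertainty matrix for PMF
#'
#' Follows the receptor-modelling convention for concentration
#' uncertainties: for an uncensored entry
#' \eqn{u = \sqrt{(ef \cdot x)^2 + (MDL/2)^2}} with `ef` the per-parameter
#' error fraction, and for a censored (below-detection) entry, whose stored
#' value is MDL/2, \eqn{u = (5/6) \cdot MDL}.
#'
#' @param X Sample-by-species concentration matrix (nonnegative).
#' @param mdl Named (or length-m) numeric vector of detection limits.
#' @param error_fraction Per-species error fractions (scalar recycled;
#'   default 0.1).
#' @param censored Optional logical matrix marking below-detection entries.
#' @return Positive numeric matrix of the same shape as `X`.
#' @export
build_uncertainty <- function(X, mdl = 0, error_fraction = 0.1,
                              censored = NULL) {
  X <- as.matrix(X)
  m <- ncol(X)
  mdl <- expand_by_species(mdl, X, "mdl")
  ef <- expand_by_species(error_fraction, X, "error_fraction")
  if (any(ef <= 0 & mdl <= 0))
    stop("every species needs error_fraction > 0 or mdl > 0")
  U <- sqrt(sweep(X, 2, ef, "*")^2 +
              matrix((mdl / 2)^2, nrow(X), m, byrow = TRUE))
  if (!is.null(censored) && any(censored)) {
    Ucens <- matrix((5 / 6) * mdl, nrow(X), m, byrow = TRUE)
    U[censored] <- Ucens[censored]
  }
  U[U <= 0] <- min(U[U > 0]) # numerical floor; reachable only when x = 0
  dimnames(U) <- dimnames(X)
  U
}

expand_by_species <- function(v, X, what) {
  m <- ncol(X)
  if (length(v) == 1L) return(rep(v, m))
  if (!is.null(names(v)) && !is.null(colnames(X))) {
    out <- rep(0, m)
    names(out) <- colnames(X)
    common <- intersect(names(v), colnames(X))
    out[common] <- v[common]
    return(out)
  }
  if (length(v) != m) stop(what, " must have one value per species")
  v
}

#' Weighted objective of a PMF solution
#'
#' \eqn{Q = \sum_{ij} ((X - G F)_{ij} / U_{ij})^2}, the uncertainty-scaled
#' squared residual sum the factorization minimizes.
#'
#' @param X,U Data and uncertainty matrices (n x m).
#' @param G Contribution matrix (n x p).
#' @param F Profile matrix (p x m).
#' @return The scalar Q value.
#' @export
q_statistic <- function(X, U, G, F) {
  stopifnot(nrow(X) == nrow(G), ncol(X) == ncol(F), ncol(G) == nrow(F),
            all(dim(X) == dim(U)))
  sum(((X - G %*% F) / U)^2)
}

#' Fit a positive matrix factorization by alternating weighted NNLS
#'
#' Decomposes the sample-by-species matrix as \eqn{X = G F + E} with
#' elementwise-nonnegative contributions G (n x p) and profiles F (p x m),
#' minimizing the uncertainty-weighted objective [q_statistic()]. Each
#' iteration solves every row of G and every column of F to optimality
#' under nonnegativity (exact block-coordinate descent), so Q is
#' non-increasing across iterations. The best of `n_starts` random
#' nonnegative initializations is retained. The returned solution is put in
#' canonical form: each profile row is scaled to sum to one (G columns
#' carry the mass) and factors are ordered by total modeled mass,
#' descending.
#'
#' @param X Nonnegative data matrix (after censoring substitution).
#' @param U Positive uncertainty matrix, same shape (see
#'   [build_uncertainty()]).
#' @param p Number of factors, `1 <= p < min(n, m)`.
#' @param n_starts Random restarts (default 20).
#' @param seed Integer seed.
#' @param tol Relative Q-change convergence tolerance (default 1e-8).
#' @param max_iter Iteration cap per start (default 5000).
#' @return An object of class `wq_pmf`: list with `G`, `F`, `E`, `Q`,
#'   `q_history`, `p`, `starts` (per-start final Q), `converged`, and
#'   `q_dof` (Q divided by the degrees of freedom `nm - p(n + m)`).
#' @export
fit_pmf <- function(X, U, p, n_starts = 20L, seed = 1L, tol = 1e-8,
                    max_iter = 5000L) {
  X <- as.matrix(X)
  U <- as.matrix(U)
  n <- nrow(X); m <- ncol(X)
  if (any(X < 0)) stop("X must be nonnegative (substitute censored values)")
  if (any(U <= 0)) stop("U must be strictly positive")
  if (p < 1 || p >= min(n, m))
    stop("factor count p must satisfy 1 <= p < min(n, m)")
  W <- 1 / U^2
  set.seed(seed)
  best <- NULL
  start_q <- numeric(n_starts)
  scale0 <- sqrt(mean(X) / p)
  for (s in seq_len(n_starts)) {
    G0 <- matrix(runif(n * p, 0.1, 1) * scale0, n, p)
    F0 <- matrix(runif(p * m, 0.1, 1) * scale0, p, m)
    fit <- cpp_pmf_fit(X, W, G0, F0, as.integer(max_iter), tol)
    start_q[s] <- fit$Q
    if (is.null(best) || fit$Q < best$Q) best <- fit
  }
  G <- best$G; F <- best$F
  # canonical form: profile rows sum to one, mass carried by G
  rs <- rowSums(F)
  live <- rs > 0
  F[live, ] <- F[live, , drop = FALSE] / rs[live]
  G[, live] <- sweep(G[, live, drop = FALSE], 2, rs[live], "*")
  ord <- order(colSums(G), decreasing = TRUE)
  G <- G[, ord, drop = FALSE]
  F <- F[ord, , drop = FALSE]
  colnames(F) <- colnames(X)
  rownames(F) <- colnames(G) <- paste0("F", seq_len(p))
  E <- X - G %*% F
  dof <- n * m - p * (n + m)
  structure(list(G = G, F = F, E = E, Q = best$Q,
                 q_history = best$q_history, p = as.integer(p),
                 starts = start_q, converged = isTRUE(best$converged),
                 n_starts = as.integer(n_starts), seed = seed,
                 q_dof = if (dof > 0) best$Q / dof else NA_real_),
            class = "wq_pmf")
}

#' @export
print.wq_pmf <- function(x, ...) {
  cat(sprintf(
    "PMF solution: %d factors, Q = %.6g (Q/dof = %.3g), %s, %d starts\n",
    x$p, x$Q, x$q_dof, if (x$converged) "converged" else "NOT converged",
    x$n_starts))
  invisible(x)
}

#' Species-contribution matrix of a PMF solution
#'
#' \eqn{c_{ji} = \sum_n G_{nj} F_{ji} / \sum_{j'} \sum_n G_{nj'} F_{j'i}}:
#' the share of species i's modeled mass attributed to factor j. Columns
#' sum to one; a species with zero modeled mass yields an `NA` column,
#' flagged via the `undefined_species` attribute.
#'
#' @param result A `wq_pmf` object, or a list with `G` and `F` matrices.
#' @return A p x m matrix of class `wq_contribution`.
#' @export
contribution_matrix <- function(result) {
  G <- result$G; F <- result$F
  mass <- colSums(G) * F # (p x m): factor j's total modeled mass of species i
  tot <- colSums(mass)
  c_mat <- sweep(mass, 2, tot, "/")
  undef <- tot == 0
  if (any(undef)) c_mat[, undef] <- NA_real_
  structure(c_mat, undefined_species = colnames(F)[undef],
            class = c("wq_contribution", "matrix", "array"))
}

#' Match recovered factors to reference factors by best permutation
#'
#' Finds the factor permutation maximizing the Pearson correlation between
#' the vectorized recovered and reference species-contribution matrices
#' (enumerating all permutations; intended for small p), resolving the
#' permutation indeterminacy of matrix factorizations before scoring
#' recovery.
#'
#' @param c_est Recovered contribution matrix (p x m).
#' @param c_true Reference contribution matrix (p x m).
#' @return List with `perm` (indices into rows of `c_est`), `correlation`
#'   (Pearson r after matching), and `c_matched`.
#' @export
match_factors <- function(c_est, c_true) {
  p <- nrow(c_true)
  stopifnot(nrow(c_est) == p, ncol(c_est) == ncol(c_true))
  perms <- all_permutations(p)
  best <- list(correlation = -Inf)
  for (i in seq_len(nrow(perms))) {
    pm <- perms[i, ]
    r <- cor(as.vector(c_est[pm, , drop = FALSE]), as.vector(c_true))
    if (!is.na(r) && r > best$correlation)
      best <- list(perm = pm, correlation = r,
                   c_matched = c_est[pm, , drop = FALSE])
  }
  best
}

all_permutations <- function(p) {
  if (p == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(p - 1L)
  out <- matrix(0L, 0, p)
  for (k in seq_len(p)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

#' Sweep the PMF factor count and report fit diagnostics
#'
#' Helper for choosing p: fits the factorization for each candidate count
#' and reports Q and Q per degree of freedom.
#'
#' @param X,U Data and uncertainty matrices.
#' @param p_values Candidate factor counts.
#' @param ... Passed to [fit_pmf()] (e.g. `n_starts`, `seed`).
#' @return Data frame with columns `p`, `Q`, `q_dof`, `converged`.
#' @export
pmf_p_sweep <- function(X, U, p_values, ...) {
  rows <- lapply(p_values, function(p) {
    fit <- fit_pmf(X, U, p, ...)
    data.frame(p = p, Q = fit$Q, q_dof = fit$q_dof,
               converged = fit$converged)
  })
  do.call(rbind, rows)
}
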