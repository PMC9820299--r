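# Independent brute-force oracles used to check the compiled tree/forest and
# the matrix-algebra shortcuts. Everything here is written as plain,
# unoptimized R so it shares no code path with the implementation.

# All candidate splits of a node, scored by the weighted child impurity
# G = (n_l * H_l + n_r * H_r) / n with H the child MSE.
oracle_all_splits <- function(x, y, min_leaf = 1L) {
  x <- as.matrix(x)
  out <- list()
  for (f in seq_len(ncol(x))) {
    v <- sort(unique(x[, f]))
    if (length(v) < 2L) next
    for (k in seq_len(length(v) - 1L)) {
      thr <- (v[k] + v[k + 1L]) / 2
      li <- x[, f] <= thr
      nl <- sum(li); nr <- sum(!li)
      if (nl < min_leaf || nr < min_leaf) next
      sse <- function(z) sum((z - mean(z))^2)
      score <- (sse(y[li]) + sse(y[!li])) / length(y)
      out[[length(out) + 1L]] <-
        data.frame(feature = f, threshold = thr, score = score)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

# Best split under the tie rule: minimal score, then lowest feature index,
# then lowest threshold. Scores within `eps` of the minimum count as tied.
oracle_best_split <- function(x, y, min_leaf = 1L, eps = NULL) {
  cand <- oracle_all_splits(x, y, min_leaf)
  if (is.null(cand)) return(NULL)
  if (is.null(eps)) eps <- 1e-12 * (1 + abs(min(cand$score)))
  tied <- cand[cand$score <= min(cand$score) + eps, , drop = FALSE]
  tied[order(tied$feature, tied$threshold)[1L], , drop = FALSE]
}

# Full reference tree grown by the same contract, as nested lists.
oracle_grow_tree <- function(x, y, min_split = 2L, min_leaf = 1L) {
  x <- as.matrix(x)
  n <- length(y)
  node <- list(n = n, value = mean(y), impurity = mean((y - mean(y))^2))
  if (n < min_split || node$impurity <= 0) return(node)
  sp <- oracle_best_split(x, y, min_leaf)
  if (is.null(sp)) return(node)
  li <- x[, sp$feature] <= sp$threshold
  node$feature <- sp$feature
  node$threshold <- sp$threshold
  node$left <- oracle_grow_tree(x[li, , drop = FALSE], y[li],
                                min_split, min_leaf)
  node$right <- oracle_grow_tree(x[!li, , drop = FALSE], y[!li],
                                 min_split, min_leaf)
  node
}

# Normalized per-feature importance of a reference tree: node importance
# n_k = w_k H_k - w_l H_l - w_r H_r with weights relative to the root count,
# summed per split feature and normalized over all internal nodes.
oracle_tree_importance <- function(node, m, n_root = node$n) {
  acc <- numeric(m)
  total <- 0
  walk <- function(nd) {
    if (is.null(nd$feature)) return(invisible())
    nk <- (nd$n / n_root) * nd$impurity -
      (nd$left$n / n_root) * nd$left$impurity -
      (nd$right$n / n_root) * nd$right$impurity
    acc[nd$feature] <<- acc[nd$feature] + nk
    total <<- total + nk
    walk(nd$left)
    walk(nd$right)
  }
  walk(node)
  if (total <= 0) return(rep(NA_real_, m))
  acc / total
}

# Importance of a fitted wq_tree (node-table form), computed by an
# independent walk over the exported arrays.
walk_tree_importance <- function(tree, m) {
  internal <- which(!is.na(tree$feature))
  if (!length(internal)) return(rep(NA_real_, m))
  n_root <- tree$n_node[1L]
  acc <- numeric(m)
  for (k in internal) {
    l <- tree$left[k]; r <- tree$right[k]
    nk <- (tree$n_node[k] / n_root) * tree$impurity[k] -
      (tree$n_node[l] / n_root) * tree$impurity[l] -
      (tree$n_node[r] / n_root) * tree$impurity[r]
    acc[tree$feature[k]] <- acc[tree$feature[k]] + nk
  }
  acc / sum(acc)
}

# Species-contribution matrix by explicit double loop.
oracle_contribution <- function(G, F) {
  p <- ncol(G); m <- ncol(F)
  cm <- matrix(0, p, m)
  for (i in seq_len(m)) {
    denom <- 0
    for (j in seq_len(p)) {
      mass <- sum(G[, j] * F[j, i])
      cm[j, i] <- mass
      denom <- denom + mass
    }
    cm[, i] <- cm[, i] / denom
  }
  cm
}

# Per-source WQI-variation contribution by explicit double sum.
oracle_apportion <- function(fn, cm, mape) {
  p <- nrow(cm)
  out <- numeric(p)
  for (j in seq_len(p)) {
    s <- 0
    for (i in colnames(cm)) s <- s + fn[[i]] * cm[j, i]
    out[j] <- (1 - mape) * s * 100
  }
  out
}

# True species-contribution matrix of a synthetic dataset's planted truth.
truth_contribution <- function(dataset) {
  G <- dataset$truth$G
  F <- dataset$truth$F
  mass <- colSums(G) * F
  sweep(mass, 2, colSums(mass), "/")
}

# Small reference scenario used across tests.
small_dataset <- function(seed = 42, n_stations = 2L, n_months = 24L,
                          config = list()) {
  model <- generate_source_model(5, wq_mass_species(), config = config,
                                 seed = seed)
  simulate_monitoring(model, n_stations, n_months, seed = seed + 1L)
}

random_column_stochastic <- function(p, m, names_m) {
  cm <- matrix(runif(p * m), p, m, dimnames = list(NULL, names_m))
  sweep(cm, 2, colSums(cm), "/")
}

random_importance <- function(names_m) {
  v <- runif(length(names_m))
  structure(setNames(v / sum(v), names_m), class = "wq_importance")
}
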