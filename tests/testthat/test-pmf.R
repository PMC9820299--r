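test_that("uncertainty matrix follows the censoring-aware convention", {
  X <- matrix(c(1, 0.4, 2, 0.005), 2, 2,
              dimnames = list(NULL, c("A", "B")))
  U <- build_uncertainty(X, mdl = c(A = 0.02, B = 0.01),
                         error_fraction = 0.1)
  expect_equal(unname(U[1, "A"]), sqrt((0.1 * 1)^2 + (0.02 / 2)^2))
  expect_equal(unname(U[1, "A"]), 0.1004988, tolerance = 1e-6)

  cens <- matrix(c(FALSE, FALSE, FALSE, TRUE), 2, 2)
  U2 <- build_uncertainty(X, mdl = c(A = 0.02, B = 0.01),
                          error_fraction = 0.1, censored = cens)
  expect_equal(unname(U2[2, "B"]), (5 / 6) * 0.01)

  U3 <- build_uncertainty(X, mdl = 0, error_fraction = 0.1)
  expect_equal(U3, 0.1 * X)

  expect_error(build_uncertainty(X, mdl = 0, error_fraction = 0),
               "error_fraction > 0 or mdl > 0")
})

test_that("the Q statistic is the uncertainty-scaled residual sum", {
  G <- matrix(c(1, 2, 3, 4), 2, 2)
  F <- matrix(c(1, 0, 0.5, 1), 2, 2)
  X <- G %*% F
  U <- matrix(1, 2, 2)
  expect_equal(q_statistic(X, U, G, F), 0)

  E <- matrix(c(0.1, -0.2, 0.3, 0), 2, 2)
  expect_equal(q_statistic(X + E, U, G, F), sum(E^2))

  # 2x2 hand computation with non-unit uncertainties
  U2 <- matrix(c(0.5, 1, 2, 0.1), 2, 2)
  hand <- (0.1 / 0.5)^2 + (-0.2 / 1)^2 + (0.3 / 2)^2 + 0
  expect_equal(q_statistic(X + E, U2, G, F), hand)
})

test_that("noiseless exact-rank data are recovered to machine precision", {
  set.seed(70)
  n <- 40; m <- 6; p <- 2
  G0 <- matrix(runif(n * p, 0.2, 2), n, p)
  # anchor samples where one source is silent pin down the factorization
  G0[1:4, 1] <- 0
  G0[5:8, 2] <- 0
  F0 <- matrix(0, p, m, dimnames = list(NULL, paste0("s", 1:m)))
  F0[1, 1:3] <- c(5, 1, 0.2)
  F0[2, 4:6] <- c(0.5, 2, 4)
  X <- G0 %*% F0
  U <- build_uncertainty(X, mdl = 0, error_fraction = 0.1)
  fit <- fit_pmf(X, U, p, n_starts = 8, seed = 71)
  expect_lte(fit$Q, 1e-6)
  expect_true(fit$converged)
  expect_true(all(fit$G >= 0))
  expect_true(all(fit$F >= 0))

  # Q history is non-increasing within the winning run
  expect_true(all(diff(fit$q_history) <=
                    1e-9 * pmax(1, head(fit$q_history, -1))))

  # species-contribution recovery up to factor permutation
  c_true <- oracle_contribution(G0, F0)
  mt <- match_factors(unclass(contribution_matrix(fit)), c_true)
  expect_lt(max(abs(mt$c_matched - c_true)), 1e-3)

  expect_error(fit_pmf(X, U, 6), "p must satisfy")
  expect_error(fit_pmf(-X, U, 2), "nonnegative")
})

test_that("solutions come in canonical form", {
  ds <- small_dataset(seed = 80, n_stations = 2L, n_months = 30L)
  X <- ds$values[, wq_mass_species()]
  U <- build_uncertainty(X, mdl = 0, error_fraction = 0.1)
  fit <- fit_pmf(X, U, 3, n_starts = 3, seed = 81, max_iter = 800)
  expect_equal(unname(rowSums(fit$F)), rep(1, 3), tolerance = 1e-9)
  expect_true(all(diff(colSums(fit$G)) <= 1e-9))
  expect_equal(fit$E, X - fit$G %*% fit$F, ignore_attr = TRUE)
  expect_equal(fit$Q, q_statistic(X, U, fit$G, fit$F),
               tolerance = 1e-6)
  expect_length(fit$starts, 3L)
  expect_equal(fit$Q, min(fit$starts))
})

test_that("the contribution matrix is column-stochastic and oracle-exact", {
  # single factor owns every species
  fit1 <- list(G = matrix(runif(10, 1, 2), 10, 1),
               F = matrix(runif(4), 1, 4,
                          dimnames = list(NULL, letters[1:4])))
  c1 <- contribution_matrix(fit1)
  expect_equal(as.numeric(c1), rep(1, 4))

  # zero profile entry gives a zero share
  set.seed(82)
  G <- matrix(runif(15, 0.5, 2), 5, 3)
  F <- matrix(runif(12), 3, 4, dimnames = list(NULL, letters[1:4]))
  F[2, 1] <- 0
  cm <- contribution_matrix(list(G = G, F = F))
  expect_equal(unname(cm[2, 1]), 0)
  expect_equal(colSums(cm), setNames(rep(1, 4), letters[1:4]),
               tolerance = 1e-9)
  expect_equal(unclass(cm), oracle_contribution(G, F),
               ignore_attr = TRUE, tolerance = 1e-12)

  # scale indeterminacy of the factorization does not change c
  s <- c(2, 0.5, 3)
  cm2 <- contribution_matrix(list(G = sweep(G, 2, s, "/"),
                                  F = F * s))
  expect_equal(unclass(cm2), unclass(cm), tolerance = 1e-12)
})

test_that("factor matching resolves permutations", {
  set.seed(83)
  ct <- random_column_stochastic(4, 6, paste0("s", 1:6))
  perm <- c(3, 1, 4, 2)
  mt <- match_factors(ct[perm, ], ct)
  expect_equal(mt$correlation, 1, tolerance = 1e-12)
  expect_equal(mt$c_matched, ct, ignore_attr = TRUE)
  expect_equal(nrow(all_permutations(4)), 24L)
})
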