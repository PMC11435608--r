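test_that("uncertainties follow both branches of the MDL/EF rule", {
  cfg <- analyte_config(c("A", "B"), mdl = c(0.06, 1),
                        error_fraction = c(0.1, 0.1))
  X <- rbind(c(0.03, 10), c(0.06, 0.5))
  colnames(X) <- c("A", "B")
  tab <- conc_table(X, cfg)
  u <- build_uncertainty(tab)
  expect_equal(u[1, "A"], 0.05, tolerance = 1e-12)            # (5/6)*0.06
  expect_equal(u[1, "B"], sqrt(1^2 + 0.5^2), tolerance = 1e-12)
  expect_equal(u[2, "A"], 0.05, tolerance = 1e-12)  # x == MDL: below branch
  expect_equal(u[2, "B"], (5 / 6) * 1, tolerance = 1e-12)
  expect_true(all(u > 0))
})

test_that("noiseless low-rank data is factorized to Q near zero", {
  set.seed(3)
  G0 <- matrix(runif(10 * 2, 0.2, 2), 10, 2)
  F0 <- matrix(runif(2 * 6, 0.2, 2), 2, 6)
  X <- G0 %*% F0
  U <- matrix(1, 10, 6)
  fit <- pmf(X, p = 2, u = U, n_starts = 20, seed = 1)
  expect_lt(fit$Q, 1e-6)
  expect_true(all(fit$G >= 0))
  expect_true(all(fit$F >= 0))
})

test_that("solution structure holds: residual identity, Q recomputation,
          normalizations", {
  syn <- generate_synthetic(synth_spec(n_surface = 15, n_ground = 0,
                                       n_mine = 0, m = 7, p = 2),
                            seed = 5)
  fit <- pmf(syn$table, p = 2, n_starts = 5, seed = 2)
  expect_equal(fit$E, fit$X - fit$G %*% fit$F, tolerance = 1e-12)
  expect_equal(fit$Q, sum((fit$E / fit$u)^2), tolerance = 1e-8)
  expect_equal(fit$q_expected, 15 * 7 - 2 * (15 + 7))
  expect_equal(unname(colMeans(fit$G)), rep(1, 2), tolerance = 1e-12)
  expect_equal(sum(fit$factor_percent), 100, tolerance = 1e-6)
  expect_equal(unname(colSums(fit$profile_percent)), rep(100, 7),
               tolerance = 1e-6)
})

test_that("repeated fits with the same seed are bit-identical", {
  syn <- generate_synthetic(synth_spec(n_surface = 12, n_ground = 0,
                                       n_mine = 0, m = 6, p = 2),
                            seed = 8)
  f1 <- pmf(syn$table, p = 2, n_starts = 4, seed = 33)
  f2 <- pmf(syn$table, p = 2, n_starts = 4, seed = 33)
  expect_identical(f1$Q, f2$Q)
  expect_identical(f1$G, f2$G)
  expect_identical(f1$F, f2$F)
})

test_that("Q trajectory is monotone non-increasing within the run", {
  syn <- generate_synthetic(synth_spec(n_surface = 20, n_ground = 0,
                                       n_mine = 0, m = 8, p = 3),
                            seed = 4)
  fit <- pmf(syn$table, p = 3, n_starts = 3, seed = 9)
  expect_true(all(diff(fit$q_trajectory) <= 1e-8 * fit$q_trajectory[1]))
})

test_that("Q is invariant under factor permutation and positive
          rescaling of the G/F pair", {
  syn <- generate_synthetic(synth_spec(n_surface = 10, n_ground = 0,
                                       n_mine = 0, m = 6, p = 2),
                            seed = 6)
  fit <- pmf(syn$table, p = 2, n_starts = 3, seed = 3)
  q_of <- function(G, F_) sum(((fit$X - G %*% F_) / fit$u)^2)
  perm <- c(2, 1)
  expect_equal(q_of(fit$G[, perm], fit$F[perm, ]), fit$Q,
               tolerance = 1e-10)
  D <- diag(c(0.37, 5.1))
  expect_equal(q_of(fit$G %*% D, solve(D) %*% fit$F), fit$Q,
               tolerance = 1e-8)
})

test_that("parameter bounds and degenerate inputs are rejected", {
  X <- matrix(runif(12, 1, 2), 4, 3)
  U <- matrix(1, 4, 3)
  expect_error(pmf(X, p = 3, u = U), "p must satisfy")
  expect_error(pmf(X, p = 0, u = U), "p must satisfy")
  Xbad <- X; Xbad[1, 1] <- NA
  expect_error(pmf(Xbad, p = 1, u = U), "non-finite")
  expect_error(pmf(X, p = 1, u = -U), "positive")
  expect_error(pmf(-X, p = 1, u = U), "non-negative")
})

test_that("factor summaries match direct arithmetic", {
  # p = 1: everything is one factor
  X <- matrix(runif(12, 1, 2), 4, 3)
  fit1 <- pmf(X, p = 1, u = matrix(1, 4, 3), n_starts = 3, seed = 1)
  expect_equal(unname(fit1$factor_percent), 100)
  expect_true(all(abs(fit1$profile_percent - 100) < 1e-9))

  # hand-built 2-factor case
  G <- rbind(c(1, 2), c(3, 4))
  F_ <- rbind(c(1, 0), c(0.5, 2))
  fs <- ptesr:::factor_summaries_impl(G, F_)
  mass1 <- sum(G[, 1] %o% F_[1, ]); mass2 <- sum(G[, 2] %o% F_[2, ])
  expect_equal(unname(fs$factor_percent),
               100 * c(mass1, mass2) / (mass1 + mass2))
  expect_equal(unname(fs$profile_percent[, 1]),
               100 * c(1, 0.5) / 1.5)

  # identical factors split the mass evenly
  fs2 <- ptesr:::factor_summaries_impl(cbind(G[, 1], G[, 1]),
                                       rbind(F_[1, ], F_[1, ]))
  expect_equal(unname(fs2$factor_percent), c(50, 50))
})

test_that("factor matching recovers permutations and is
          scale-invariant", {
  set.seed(21)
  F_true <- matrix(runif(4 * 6), 4, 6)
  perm <- c(3, 1, 4, 2)
  m1 <- match_factors(F_true[perm, ], F_true)
  expect_equal(m1$mean_cosine, 1, tolerance = 1e-12)
  # row k of F_true must be matched to its position in the shuffle
  expect_identical(m1$permutation, order(perm))

  m2 <- match_factors(3 * F_true, F_true)
  expect_identical(m2$permutation, 1:4)
  expect_equal(m2$mean_cosine, 1, tolerance = 1e-12)

  # orthogonal rows: only the correct matching reaches cosine 1
  Fo <- diag(4)
  sh <- c(2, 4, 1, 3)
  mo <- match_factors(Fo[sh, ], Fo)
  expect_equal(mo$mean_cosine, 1)
  wrong <- vapply(ptesr:::all_perms(4), function(pr) {
    C <- Fo %*% t(Fo[sh, ])
    mean(C[cbind(1:4, pr)])
  }, numeric(1))
  expect_equal(sum(wrong == 1), 1)  # unique optimum

  expect_error(match_factors(matrix(1, 9, 3), matrix(1, 9, 3)),
               "p <= 8")
})

test_that("predict reproduces training contributions from held-fixed
          profiles", {
  syn <- generate_synthetic(synth_spec(n_surface = 15, n_ground = 0,
                                       n_mine = 0, m = 7, p = 2,
                                       noise_cv = 0.05),
                            seed = 12)
  tab <- substitute_censored(syn$table)
  fit <- pmf(tab, p = 2, n_starts = 5, seed = 7)
  G_pred <- predict(fit, newdata = tab)
  expect_equal(unname(G_pred), unname(fit$G), tolerance = 1e-4)
})
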