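unit2 <- parameter_space(c("x1", "x2"), c(-1, -1), c(1, 1), c(0, 0))

test_that("multi-index sets have the binomial count and graded-lex order", {
  for (d in c(1, 2, 4, 5)) for (K in 0:6)
    expect_equal(build_basis(d, K)$J, choose(d + K, K))
  b <- build_basis(2, 2)
  # rows in graded-lex order: (0,0),(1,0),(0,1),(2,0),(1,1),(0,2)
  expect_equal(b$indices,
               matrix(as.integer(c(0, 1, 0, 2, 1, 0, 0, 0, 1, 0, 1, 2)),
                      6, 2))
  expect_equal(build_basis(3, 0)$J, 1)
  expect_equal(anyDuplicated(build_basis(3, 4)$indices), 0L)
})

test_that("basis values are orthonormal Legendre products", {
  b <- build_basis(2, 3)
  # constant term is 1 everywhere; degree-1 factors vanish at 0
  v <- eval_basis(c(0.37, -0.81), b)
  expect_equal(v[1], 1)
  expect_equal(eval_basis(c(0, 0.5), b)[2], 0)  # L1(0) = 0
  # Monte-Carlo orthonormality within 3 standard errors
  set.seed(21)
  n <- 2e5
  X <- matrix(runif(2 * n, -1, 1), n, 2)
  Psi <- eval_basis(X, b)
  G <- crossprod(Psi) / n
  # largest entrywise MC standard error is ~sqrt(Var(Psi_i Psi_j)/n) < 0.01
  # for this basis; 3 standard errors is well inside 0.03
  expect_lt(max(abs(G - diag(b$J))), 0.03)
  expect_error(eval_basis(c(1.1, 0), b), "outside")
})

test_that("OLS recovers planted polynomials exactly when n >= J", {
  b <- build_basis(2, 2)
  U <- sobol_points(2, 3 * b$J)
  Th <- 2 * U - 1
  # constant target: coefficient on the constant term only
  mc <- fit_pce(Th, rep(4.2, nrow(Th)), b, unit2)
  expect_equal(drop(mc$Z), c(4.2, rep(0, b$J - 1)), tolerance = 1e-10)
  # known degree-2 polynomial: exact coefficient recovery
  f <- 1 + 2 * Th[, 1] + 0.5 * Th[, 2]^2 - Th[, 1] * Th[, 2]
  m2 <- fit_pce(Th, f, b, unit2)
  # symbolic expansion oracle: direct evaluation at fresh points
  xs <- rbind(c(0.3, -0.6), c(-0.9, 0.2))
  truth <- 1 + 2 * xs[, 1] + 0.5 * xs[, 2]^2 - xs[, 1] * xs[, 2]
  expect_equal(drop(predict_pce(m2, xs)), truth, tolerance = 1e-8)
  # refit reproduces the fitted surface at training points to ~0 residual
  expect_equal(drop(predict_pce(m2, Th)), f, tolerance = 1e-8)
})

test_that("rank-deficient fits warn, interpolate, and generalize poorly", {
  d <- 4; K <- 6
  b <- build_basis(d, K)           # J = 210
  n <- 100
  U <- sobol_points(d, n + 50)
  sp <- parameter_space(paste0("x", 1:d), rep(-1, d), rep(1, d), rep(0, d))
  Th <- 2 * U[1:n, ] - 1
  f <- function(X) sin(2 * X[, 1]) + X[, 2] * X[, 3] + exp(X[, 4] / 2)
  expect_warning(mod <- fit_pce(Th, f(Th), b, sp), "minimum-norm")
  expect_lt(max(abs(drop(predict_pce(mod, Th)) - f(Th))), 1e-6)
  held <- 2 * U[(n + 1):(n + 50), ] - 1
  err_hi <- mean((drop(predict_pce(mod, held)) - f(held))^2)
  mod_lo <- fit_pce(Th, f(Th), build_basis(d, 2), sp)
  err_lo <- mean((drop(predict_pce(mod_lo, held)) - f(held))^2)
  expect_gt(err_hi, 10 * err_lo)
  expect_error(fit_pce(Th, c(NA, f(Th)[-1]), b, sp), "NaN|NA")
})

test_that("Sobol indices from coefficients match analytic ANOVA values", {
  U <- sobol_points(2, 60)
  Th <- 2 * U - 1
  # additive: S1 = a^2/(a^2+b^2), no interaction
  a <- 2; b <- 1
  s <- sobol_from_pce(fit_pce(Th, a * Th[, 1] + b * Th[, 2],
                              build_basis(2, 1), unit2))
  expect_equal(unname(s$first_order[1]), a^2 / (a^2 + b^2),
               tolerance = 1e-6)
  expect_equal(unname(s$total_order[1]), a^2 / (a^2 + b^2),
               tolerance = 1e-6)
  # single active parameter
  s1 <- sobol_from_pce(fit_pce(Th, 3 * Th[, 1]^2, build_basis(2, 3), unit2))
  expect_equal(unname(s1$first_order), c(1, 0), tolerance = 1e-8)
  expect_equal(unname(s1$total_order), c(1, 0), tolerance = 1e-8)
  # pure interaction: first-order zero, total-order one
  s2 <- sobol_from_pce(fit_pce(Th, Th[, 1] * Th[, 2], build_basis(2, 2),
                               unit2))
  expect_equal(unname(s2$first_order), c(0, 0), tolerance = 1e-8)
  expect_equal(unname(s2$total_order), c(1, 1), tolerance = 1e-8)
  # degenerate constant output
  expect_warning(sz <- sobol_from_pce(
    fit_pce(Th, rep(1, 60), build_basis(2, 1), unit2)), "zero total")
  expect_true(all(is.na(sz$first_order)))
  # screening keeps influential parameters only
  expect_equal(screen_parameters(s1), "x1")
})

test_that("index bounds and sums hold for a generic fitted model", {
  set.seed(33)
  U <- sobol_points(3, 150)
  sp <- parameter_space(c("x1", "x2", "x3"), rep(-1, 3), rep(1, 3),
                        rep(0, 3))
  Th <- 2 * U - 1
  f <- cbind(sin(Th[, 1]) + Th[, 2]^2 * Th[, 3],
             exp(Th[, 2]) + 0.5 * Th[, 1] * Th[, 3])
  s <- sobol_from_pce(fit_pce(Th, f, build_basis(3, 4), sp))
  expect_true(all(s$first_order >= -1e-10))
  expect_true(all(s$total_order <= 1 + 1e-10))
  expect_true(all(s$total_order - s$first_order >= -1e-10))
  expect_lte(sum(s$first_order), 1 + 1e-10)
  # per output: sum of all variance contributions equals total variance
  # (first-order + interactions = 1 by the orthonormal decomposition)
  idx <- build_basis(3, 4)$indices
  Z2 <- fit_pce(Th, f, build_basis(3, 4), sp)$Z^2
  V <- colSums(Z2[rowSums(idx) > 0, ])
  groups <- apply(idx[rowSums(idx) > 0, ] > 0, 1, paste, collapse = "")
  Vsum <- rowsum(Z2[rowSums(idx) > 0, ], groups)
  expect_equal(colSums(Vsum), V, tolerance = 1e-10)
})
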