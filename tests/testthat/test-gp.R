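spec_with <- function(family, hyp, ard = FALSE, period = 1,
                      jitter = 1e-6) {
  kernel_spec(family, ard = ard, jitter = jitter, period = period, hyp = hyp)
}

test_that("kernel evaluations match their closed forms", {
  se <- spec_with("SE", list(sf2 = 1.7, ell = 0.4))
  expect_equal(kernel_eval(c(1, 2), c(1, 2), se), 1.7)
  expect_equal(kernel_eval(0, 1, se), 1.7 * exp(-0.5 / 0.4^2))
  m32 <- spec_with("Matern32", list(sf2 = 2, ell = 0.3))
  expect_equal(kernel_eval(0, 0.3, m32), 2 * (1 + sqrt(3)) * exp(-sqrt(3)))
  m52 <- spec_with("Matern52", list(sf2 = 1, ell = 1))
  expect_equal(kernel_eval(0, 1, m52),
               (1 + sqrt(5) + 5 / 3) * exp(-sqrt(5)))
  pk <- spec_with("Periodic", list(sf2 = 1.3, ell = 0.5), period = 0.11)
  expect_equal(kernel_eval(0, 0.11, pk), 1.3)     # one full period
  expect_equal(kernel_eval(0, 0.22, pk), 1.3)
  nn <- spec_with("NN", list(sf2 = 1, s0 = 1, sw = 2))
  x <- 0.4
  arg <- 2 * (1 + 2 * x^2) / (1 + 2 * (1 + 2 * x^2))
  expect_equal(kernel_eval(x, x, nn), (2 / pi) * asin(arg))
  expect_error(kernel_eval(c(1, 2), 1, se), "dimension")
  expect_error(kernel_eval(0, 1, spec_with("SE", list(sf2 = -1, ell = 1))),
               "nonpositive")
  # symmetry and PSD of a Gram matrix
  X <- matrix(runif(20), 10, 2)
  for (fam in c("SE", "Matern32", "Matern52", "NN")) {
    hyp <- if (fam == "NN") list(sf2 = 1, s0 = 0.5, sw = 1)
           else list(sf2 = 1, ell = 0.5)
    K <- pwemu:::kernel_matrix(X, X, kernel_spec(fam), hyp)
    expect_equal(K, t(K), tolerance = 1e-12)
    expect_gt(min(eigen(K, symmetric = TRUE)$values), -1e-10)
  }
})

test_that("GP predictive mean matches the conditional-mean formula", {
  # one training point: mean at x* is k(x*, x) y / (sf2 + jitter)
  spec <- spec_with("SE", list(sf2 = 1.5, ell = 0.3), jitter = 1e-4)
  k <- kernel_eval(0.2, 0.5, spec)
  expect_equal(k * 2.0 / (1.5 + 1e-4),
               drop(pwemu:::kernel_matrix(matrix(0.2), matrix(0.5), spec) %*%
                      solve(1.5 + 1e-4, 2.0)))
  # several points: fitted model vs dense hand computation at fixed hypers
  set.seed(8)
  sp <- parameter_space("x", 0, 1, 0.5)
  X <- matrix(seq(0.1, 0.9, length.out = 6))
  y <- sin(3 * X[, 1])
  fit <- fit_gp_scores(X, rbind(y), kernel_spec("SE", jitter = 1e-6), sp,
                       n_restarts = 2)
  cj <- fit$components[[1]]
  xs <- matrix(c(0.33, 0.66))
  km <- pwemu:::kernel_matrix
  K <- km(fit$X, fit$X, fit$spec, cj$hyp)
  diag(K) <- diag(K) + 1e-6
  ys <- (y - cj$mu) / cj$sd
  manual <- drop(km(xs, fit$X, fit$spec, cj$hyp) %*% solve(K, ys)) *
    cj$sd + cj$mu
  expect_equal(drop(predict_gp(fit, xs)), manual, tolerance = 1e-8)
  # training points are reproduced to jitter-scale accuracy
  expect_equal(drop(predict_gp(fit, X)), y, tolerance = 1e-3)
})

test_that("all-zero scores give identically zero predictions", {
  sp <- parameter_space(c("a", "b"), c(0, 0), c(1, 1), c(0.5, 0.5))
  X <- matrix(runif(16), 8, 2)
  fit <- fit_gp_scores(X, rbind(rep(0, 8)), kernel_spec("SE"), sp)
  expect_equal(drop(predict_gp(fit, matrix(runif(10), 5, 2))), rep(0, 5))
})

test_that("Kronecker time-input GP equals a dense GP on the full grid", {
  set.seed(9)
  n <- 4; m <- 6
  sp <- parameter_space(c("a", "b"), c(0, 0), c(1, 1), c(0.5, 0.5))
  X <- matrix(runif(n * 2), n, 2)
  tg <- (0:(m - 1)) * 0.11 / m
  F <- matrix(0, m, n)
  for (j in 1:n)
    F[, j] <- sin(2 * pi * tg / 0.11 + X[j, 1]) * (1 + X[j, 2])
  emt <- fit_gp_time(X, F, kernel_spec("SE", jitter = 1e-6),
                     kernel_spec("Matern52", jitter = 1e-6), sp,
                     tgrid = tg, cycle_T = 0.11, n_restarts = 2)
  km <- pwemu:::kernel_matrix
  Kth <- km(emt$X, emt$X, emt$spec_theta, emt$hyp_theta)
  diag(Kth) <- diag(Kth) + 1e-6
  Kt <- km(emt$Tm, emt$Tm, emt$spec_time, emt$hyp_time)
  diag(Kt) <- diag(Kt) + 1e-6
  Kbig <- kronecker(Kt, Kth)
  Ys <- t((F - emt$mu) / emt$sd)
  y <- as.vector(Ys)
  L <- chol(Kbig)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  nll_dense <- 0.5 * sum(y * alpha) + sum(log(diag(L))) +
    0.5 * length(y) * log(2 * pi)
  lh <- log(unlist(c(emt$hyp_theta, emt$hyp_time), use.names = FALSE))
  nll_kron <- pwemu:::kron_nll(lh, emt$spec_theta, emt$spec_time, emt$X,
                               emt$Tm, Ys)
  expect_equal(nll_kron, nll_dense, tolerance = 1e-8)
  # predictions at a new input
  xs <- matrix(c(0.3, 0.7), 1)
  kbig <- kronecker(km(emt$Tm, emt$Tm, emt$spec_time, emt$hyp_time),
                    km(xs, emt$X, emt$spec_theta, emt$hyp_theta))
  pred_dense <- drop(kbig %*% alpha) * emt$sd + emt$mu
  expect_equal(drop(predict_gp(emt, xs)), pred_dense, tolerance = 1e-8)
  # interpolation of the training grid within jitter tolerance
  expect_equal(predict_gp(emt, X), F, tolerance = 1e-3)
})

test_that("training reproduction error grows with the jitter", {
  set.seed(10)
  X <- matrix(runif(12))
  y <- sin(4 * X[, 1])
  hyp <- list(sf2 = 1, ell = 0.3)
  km <- pwemu:::kernel_matrix
  errs <- vapply(10^-(9:4), function(j) {
    K0 <- km(X, X, kernel_spec("SE"), hyp)
    K <- K0
    diag(K) <- diag(K) + j
    max(abs(K0 %*% solve(K, y) - y))
  }, numeric(1))
  expect_true(all(diff(errs) > 0))
})

test_that("the predictive mean is linear in the training targets", {
  set.seed(12)
  sp <- parameter_space("x", 0, 1, 0.5)
  X <- matrix(seq(0, 1, length.out = 7))
  spec <- kernel_spec("Matern52", jitter = 1e-6,
                      hyp = list(sf2 = 1, ell = 0.4))
  km <- pwemu:::kernel_matrix
  K <- km(X, X, spec); diag(K) <- diag(K) + spec$jitter
  xs <- matrix(runif(4))
  predict_at <- function(y) drop(km(xs, X, spec) %*% solve(K, y))
  y1 <- rnorm(7); y2 <- rnorm(7)
  expect_equal(predict_at(2 * y1 - 3 * y2),
               2 * predict_at(y1) - 3 * predict_at(y2), tolerance = 1e-10)
})

test_that("maximum likelihood recovers a known length scale within 2x", {
  set.seed(13)
  n <- 200
  X <- matrix(runif(n))
  ell_true <- 0.25
  K <- pwemu:::kernel_matrix(X, X, kernel_spec("SE"),
                             list(sf2 = 1, ell = ell_true))
  y <- drop(crossprod(chol(K + 1e-8 * diag(n)), rnorm(n)))
  sp <- parameter_space("x", 0, 1, 0.5)
  fit <- fit_gp_scores(X, rbind(y), kernel_spec("SE", jitter = 1e-6), sp,
                       n_restarts = 3)
  ell_hat <- fit$components[[1]]$hyp$ell
  expect_gt(ell_hat, ell_true / 2)
  expect_lt(ell_hat, ell_true * 2)
})
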