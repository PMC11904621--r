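#' Gaussian-process kernel specification
#'
#' Families: squared exponential (`"SE"`), Matern 3/2 (`"Matern32"`), Matern
#' 5/2 (`"Matern52"`), arcsine neural-network (`"NN"`) and exp-sin^2 periodic
#' (`"Periodic"`, time input only; the period is fixed to the cardiac cycle
#' rather than learned). `ard = TRUE` gives each input its own length scale
#' (or weight variance for NN). `jitter` is the fixed diagonal variance added
#' for numerical stability, one of 1e-4 ... 1e-9.
#'
#' @param family kernel family name.
#' @param ard logical, automatic relevance determination.
#' @param jitter nugget variance (targets are standardized, so this is
#'   relative to unit signal variance).
#' @param period period of the periodic kernel in input units.
#' @param hyp optional named list of hyperparameters (`sf2` plus `ell` or,
#'   for NN, `s0` and `sw`); filled by fitting if omitted.
#' @return An object of class `pw_kernel`.
#' @export
kernel_spec <- function(family = c("SE", "Matern32", "Matern52", "NN",
                                   "Periodic"),
                        ard = FALSE, jitter = 1e-6, period = 1,
                        hyp = NULL) {
  family <- match.arg(family)
  if (!jitter %in% 10^-(4:9))
    stop("kernel_spec: jitter must be one of 1e-4 ... 1e-9")
  structure(list(family = family, ard = ard, jitter = jitter,
                 period = period, hyp = hyp),
            class = "pw_kernel")
}

n_hyp <- function(spec, d) {
  nl <- if (spec$ard) d else 1L
  switch(spec$family,
         SE = , Matern32 = , Matern52 = , Periodic = 1L + nl,
         NN = 2L + nl)
}

hyp_pack <- function(hyp) log(unlist(hyp, use.names = FALSE))

hyp_unpack <- function(lh, spec, d) {
  nl <- if (spec$ard) d else 1L
  if (spec$family == "NN")
    list(sf2 = exp(lh[1]), s0 = exp(lh[2]), sw = exp(lh[3:(2 + nl)]))
  else
    list(sf2 = exp(lh[1]), ell = exp(lh[2:(1 + nl)]))
}

# Cross-covariance matrix between rows of X (n1 x d) and Y (n2 x d).
kernel_matrix <- function(X, Y, spec, hyp = spec$hyp) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  d <- ncol(X)
  fam <- spec$family
  if (fam == "NN") {
    sw <- if (length(hyp$sw) == 1) rep(hyp$sw, d) else hyp$sw
    SX <- sweep(X, 2, sw, `*`)
    dXY <- 2 * (hyp$s0 + tcrossprod(SX, Y))
    dXX <- 1 + 2 * (hyp$s0 + rowSums(SX * X))
    dYY <- 1 + 2 * (hyp$s0 + rowSums(sweep(Y, 2, sw, `*`) * Y))
    arg <- dXY / sqrt(outer(dXX, dYY))
    arg <- pmin(pmax(arg, -1), 1)
    return(hyp$sf2 * (2 / pi) * asin(arg))
  }
  ell <- if (length(hyp$ell) == 1) rep(hyp$ell, d) else hyp$ell
  if (fam == "Periodic") {
    # univariate time input
    dt <- outer(drop(X[, 1]), drop(Y[, 1]), `-`)
    return(hyp$sf2 * exp(-2 * sin(pi * dt / spec$period)^2 / ell[1]^2))
  }
  Xs <- sweep(X, 2, ell, `/`); Ys <- sweep(Y, 2, ell, `/`)
  r2 <- outer(rowSums(Xs^2), rowSums(Ys^2), `+`) - 2 * tcrossprod(Xs, Ys)
  r2[r2 < 0] <- 0
  switch(fam,
    SE = hyp$sf2 * exp(-0.5 * r2),
    Matern32 = { r <- sqrt(3 * r2); hyp$sf2 * (1 + r) * exp(-r) },
    Matern52 = { r <- sqrt(5 * r2)
                 hyp$sf2 * (1 + r + r^2 / 3) * exp(-r) })
}

#' Evaluate a kernel between two points
#'
#' @param x,xp input vectors of equal length.
#' @param spec a [kernel_spec()] carrying hyperparameters in `spec$hyp`.
#' @return Scalar covariance.
#' @export
kernel_eval <- function(x, xp, spec) {
  if (length(x) != length(xp)) stop("kernel_eval: dimension mismatch")
  if (is.null(spec$hyp)) stop("kernel_eval: spec carries no hyperparameters")
  hv <- unlist(spec$hyp)
  if (any(hv <= 0)) stop("kernel_eval: nonpositive hyperparameters")
  drop(kernel_matrix(matrix(x, 1), matrix(xp, 1), spec))
}

# deterministic multistart draws in log-hyperparameter space
start_points <- function(nh, n_restarts, lo, hi) {
  U <- sobol_points(nh, n_restarts, skip = 7)
  sweep(sweep(U, 2, hi - lo, `*`), 2, lo, `+`)
}

default_start_box <- function(spec, d) {
  nl <- if (spec$ard) d else 1L
  if (spec$family == "NN")
    list(lo = c(log(0.5), log(0.5), rep(log(0.5), nl)),
         hi = c(log(2.0), log(10), rep(log(10), nl)))
  else
    list(lo = c(log(0.5), rep(log(0.1), nl)),
         hi = c(log(2.0), rep(log(2.0), nl)))
}

gp_nll <- function(lh, spec, X, y) {
  hyp <- hyp_unpack(lh, spec, ncol(X))
  K <- kernel_matrix(X, X, spec, hyp)
  diag(K) <- diag(K) + spec$jitter
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(1e10)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * length(y) * log(2 * pi)
}

optimize_hyp <- function(nll_fun, spec, d, n_restarts = 5, extra = NULL) {
  box <- default_start_box(spec, d)
  if (!is.null(extra)) {
    box$lo <- c(box$lo, extra$lo)
    box$hi <- c(box$hi, extra$hi)
  }
  starts <- start_points(length(box$lo), n_restarts, box$lo, box$hi)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- tryCatch(
      stats::optim(starts[r, ], nll_fun, method = "L-BFGS-B",
                   lower = rep(log(1e-4), length(box$lo)),
                   upper = rep(log(1e4), length(box$lo)),
                   control = list(maxit = 200, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value))
      best <- fit
  }
  if (is.null(best)) stop("GP fit: all hyperparameter restarts failed ",
                          "(try a larger jitter)")
  best
}

#' Fit independent GPs to principal-component scores
#'
#' One zero-mean GP per score component. Inputs are standardized to the unit
#' cube via the parameter-space bounds; each score is standardized to zero
#' mean and unit variance (recorded and inverted at prediction). The fixed
#' jitter from the kernel spec is added to the covariance diagonal, and
#' hyperparameters maximize the log marginal likelihood by multistart
#' L-BFGS from deterministic low-discrepancy starting points.
#'
#' @param Theta n x d training inputs in physical units.
#' @param scores q x n matrix of training scores (e.g. `fit_pca(...)$scores`).
#' @param spec a [kernel_spec()] for the parameter inputs.
#' @param space the `pw_space` defining the input bounds.
#' @param n_restarts multistart count.
#' @return An object of class `pw_gp_scores`.
#' @export
fit_gp_scores <- function(Theta, scores, spec, space, n_restarts = 5) {
  X <- to_unit_cube(as.matrix(Theta), space)
  scores <- if (is.null(dim(scores))) matrix(scores, 1) else as.matrix(scores)
  n <- nrow(X); d <- ncol(X)
  if (n < d + 2) stop("fit_gp_scores: need n >= d + 2 training points")
  comps <- vector("list", nrow(scores))
  for (j in seq_len(nrow(scores))) {
    y <- scores[j, ]
    mu <- mean(y); sdv <- stats::sd(y)
    if (!is.finite(sdv) || sdv < 1e-300) {
      comps[[j]] <- list(constant = TRUE, mu = mu, sd = 0)
      next
    }
    ys <- (y - mu) / sdv
    fit <- optimize_hyp(function(lh) gp_nll(lh, spec, X, ys), spec, d,
                        n_restarts)
    hyp <- hyp_unpack(fit$par, spec, d)
    K <- kernel_matrix(X, X, spec, hyp)
    diag(K) <- diag(K) + spec$jitter
    L <- chol(K)
    alpha <- backsolve(L, forwardsolve(t(L), ys))
    comps[[j]] <- list(constant = FALSE, mu = mu, sd = sdv, hyp = hyp,
                       alpha = alpha, nll = fit$value)
  }
  structure(list(components = comps, spec = spec, space = space, X = X),
            class = "pw_gp_scores")
}

kron_nll <- function(lh, spec_theta, spec_time, X, Tm, Y) {
  d <- ncol(X)
  nh_th <- n_hyp(spec_theta, d)
  hyp_th <- hyp_unpack(lh[seq_len(nh_th)], spec_theta, d)
  hyp_t <- hyp_unpack(lh[-seq_len(nh_th)], spec_time, 1L)
  Kth <- kernel_matrix(X, X, spec_theta, hyp_th)
  diag(Kth) <- diag(Kth) + spec_theta$jitter
  Kt <- kernel_matrix(Tm, Tm, spec_time, hyp_t)
  diag(Kt) <- diag(Kt) + spec_time$jitter
  eth <- tryCatch(eigen(Kth, symmetric = TRUE), error = function(e) NULL)
  et <- tryCatch(eigen(Kt, symmetric = TRUE), error = function(e) NULL)
  if (is.null(eth) || is.null(et) || min(eth$values) <= 0 ||
      min(et$values) <= 0) return(1e10)
  B <- crossprod(eth$vectors, Y) %*% et$vectors      # n x m rotated data
  lam <- outer(eth$values, et$values)
  0.5 * sum(B^2 / lam) + 0.5 * sum(log(lam)) +
    0.5 * length(Y) * log(2 * pi)
}

#' Fit a time-input GP with Kronecker-separable covariance
#'
#' Models the scalar output f(theta, t) with a product kernel
#' `k((theta,t),(theta',t')) = k_theta(theta,theta') * k_t(t,t')` on the grid
#' of all n design points x m time samples. The same jitter is added to the
#' diagonal of both covariance factors, and all likelihood evaluations and
#' solves use the two small eigendecompositions - the nm x nm covariance is
#' never materialized.
#'
#' @param Theta n x d training inputs (physical units).
#' @param F m x n waveform matrix (columns = design points), or `pw_waveset`.
#' @param spec_theta kernel for the parameter inputs.
#' @param spec_time kernel for the time input (`Periodic`, `Matern32` or
#'   `Matern52`); its `period` should equal the cardiac cycle for the
#'   periodic family. Time is rescaled to `[0, 1)` internally.
#' @param space the `pw_space` of the inputs.
#' @param tgrid the m sample times, s (defaults to uniform on one cycle).
#' @param cycle_T cycle length used to rescale time.
#' @param n_restarts multistart count.
#' @return An object of class `pw_gp_time`.
#' @export
fit_gp_time <- function(Theta, F, spec_theta, spec_time, space,
                        tgrid = NULL, cycle_T = 0.11, n_restarts = 5) {
  if (inherits(F, "pw_waveset")) { tgrid <- F$t; F <- F$F }
  F <- as.matrix(F)
  X <- to_unit_cube(as.matrix(Theta), space)
  m <- nrow(F); n <- ncol(F)
  if (n != nrow(X)) stop("fit_gp_time: design/waveform count mismatch ",
                         "(this model requires the full n x m grid)")
  if (is.null(tgrid)) tgrid <- (0:(m - 1)) * cycle_T / m
  Tm <- matrix(tgrid / cycle_T, ncol = 1)
  if (spec_time$family == "Periodic") spec_time$period <- 1
  mu <- mean(F); sdv <- stats::sd(as.vector(F))
  if (sdv < 1e-300) sdv <- 1
  Y <- t((F - mu) / sdv)                               # n x m
  d <- ncol(X)
  nh_th <- n_hyp(spec_theta, d)
  box_t <- default_start_box(spec_time, 1L)
  fit <- optimize_hyp(
    function(lh) kron_nll(lh, spec_theta, spec_time, X, Tm, Y),
    spec_theta, d, n_restarts,
    extra = list(lo = box_t$lo, hi = box_t$hi))
  hyp_th <- hyp_unpack(fit$par[seq_len(nh_th)], spec_theta, d)
  hyp_t <- hyp_unpack(fit$par[-seq_len(nh_th)], spec_time, 1L)
  Kth <- kernel_matrix(X, X, spec_theta, hyp_th)
  diag(Kth) <- diag(Kth) + spec_theta$jitter
  Kt <- kernel_matrix(Tm, Tm, spec_time, hyp_t)
  diag(Kt) <- diag(Kt) + spec_time$jitter
  eth <- eigen(Kth, symmetric = TRUE)
  et <- eigen(Kt, symmetric = TRUE)
  B <- crossprod(eth$vectors, Y) %*% et$vectors
  Alpha <- eth$vectors %*% (B / outer(eth$values, et$values)) %*%
    t(et$vectors)                                      # n x m
  structure(list(spec_theta = spec_theta, spec_time = spec_time,
                 hyp_theta = hyp_th, hyp_time = hyp_t, X = X, Tm = Tm,
                 Alpha = Alpha, mu = mu, sd = sdv, space = space,
                 cycle_T = cycle_T, tgrid = tgrid, nll = fit$value),
            class = "pw_gp_time")
}

#' GP predictive-mean waveforms
#'
#' For a `pw_gp_scores` model, predicts all score components at the new
#' parameter vectors and reconstructs waveforms through the PCA basis (or
#' returns the score matrix if `basis` is `NULL`). For a `pw_gp_time` model,
#' returns the predictive mean over the training time grid via Kronecker
#' algebra. All standardizations are inverted.
#'
#' @param model a `pw_gp_scores` or `pw_gp_time`.
#' @param theta_new vector (one point) or matrix of rows, physical units.
#' @param basis a `pw_pca` (required to get waveforms from a score model).
#' @return m x n_new matrix of waveforms (or q x n_new scores).
#' @export
predict_gp <- function(model, theta_new, basis = NULL) {
  if (is.null(dim(theta_new))) theta_new <- matrix(theta_new, nrow = 1)
  Xs <- to_unit_cube(as.matrix(theta_new), model$space)
  if (inherits(model, "pw_gp_time")) {
    Kcross <- kernel_matrix(Xs, model$X, model$spec_theta, model$hyp_theta)
    Ktcross <- kernel_matrix(model$Tm, model$Tm, model$spec_time,
                             model$hyp_time)
    pred <- Kcross %*% model$Alpha %*% Ktcross         # n_new x m
    return(t(pred) * model$sd + model$mu)
  }
  q <- length(model$components)
  scores <- matrix(NA_real_, q, nrow(Xs))
  for (j in seq_len(q)) {
    cj <- model$components[[j]]
    if (cj$constant) {
      scores[j, ] <- cj$mu
    } else {
      Kc <- kernel_matrix(Xs, model$X, model$spec, cj$hyp)
      scores[j, ] <- drop(Kc %*% cj$alpha) * cj$sd + cj$mu
    }
  }
  if (is.null(basis)) return(scores)
  out <- pca_reconstruct(scores, basis)
  if (is.null(dim(out))) matrix(out, ncol = 1) else out
}
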