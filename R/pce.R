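#' Total-degree multi-index set
#'
#' All d-tuples of nonnegative exponents with total degree at most K, in
#' graded lexicographic order; their count is `J = choose(d + K, K)`.
#'
#' @param d number of parameters (>= 1).
#' @param K polynomial order (>= 0).
#' @return An object of class `pw_mindex`: list with `indices` (J x d
#'   integer matrix), `d`, `K`, `J`.
#' @export
build_basis <- function(d, K) {
  stopifnot(d >= 1, K >= 0)
  per_degree <- function(dd, g) {
    if (dd == 1) return(matrix(g, 1, 1))
    out <- NULL
    for (a1 in g:0) {
      rest <- per_degree(dd - 1, g - a1)
      out <- rbind(out, cbind(a1, rest))
    }
    out
  }
  idx <- do.call(rbind, lapply(0:K, function(g) per_degree(d, g)))
  dimnames(idx) <- NULL
  storage.mode(idx) <- "integer"
  structure(list(indices = idx, d = d, K = K, J = nrow(idx)),
            class = "pw_mindex")
}

# orthonormal Legendre values L_0..L_K at points x in [-1,1]
# (orthonormal w.r.t. the uniform density 1/2: L_k = sqrt(2k+1) P_k)
legendre_orthonormal <- function(x, K) {
  n <- length(x)
  P <- matrix(0, n, K + 1)
  P[, 1] <- 1
  if (K >= 1) P[, 2] <- x
  if (K >= 2) for (k in 1:(K - 1))
    P[, k + 2] <- ((2 * k + 1) * x * P[, k + 1] - k * P[, k]) / (k + 1)
  sweep(P, 2, sqrt(2 * (0:K) + 1), `*`)
}

#' Evaluate the multivariate Legendre basis
#'
#' `Psi_j(x) = prod_k L_{alpha_jk}(x_k)` with orthonormal univariate Legendre
#' factors, so Monte-Carlo inner products under the uniform distribution on
#' `[-1,1]^d` approximate the identity matrix.
#'
#' @param x point(s) in `[-1,1]^d`: a d-vector or n x d matrix. Points more
#'   than 1e-9 outside the cube raise an error.
#' @param basis a [build_basis()] result.
#' @return n x J matrix of basis values (J-vector for a single point).
#' @export
eval_basis <- function(x, basis) {
  X <- if (is.null(dim(x))) matrix(x, nrow = 1) else as.matrix(x)
  if (ncol(X) != basis$d) stop("eval_basis: dimension mismatch")
  if (any(abs(X) > 1 + 1e-9))
    stop("eval_basis: input outside [-1,1]^d by more than 1e-9")
  X <- pmin(pmax(X, -1), 1)
  K <- basis$K
  L <- lapply(seq_len(basis$d), function(k) legendre_orthonormal(X[, k], K))
  Psi <- matrix(1, nrow(X), basis$J)
  for (j in seq_len(basis$J))
    for (k in seq_len(basis$d))
      Psi[, j] <- Psi[, j] * L[[k]][, basis$indices[j, k] + 1]
  if (nrow(Psi) == 1 && is.null(dim(x))) drop(Psi) else Psi
}

#' Fit a polynomial-chaos expansion by ordinary least squares
#'
#' Maps the physical design to `[-1,1]^d` via the parameter-space bounds,
#' evaluates the orthonormal Legendre basis, and solves the least-squares
#' problem for every output column independently with a rank-revealing
#' (SVD-based) solver. When `n < J` the system is rank-deficient: the
#' minimum-norm solution is returned and a prominent warning is emitted,
#' since such fits interpolate the training data but generalize poorly.
#'
#' @param Theta n x d design in physical units.
#' @param targets n x p matrix (p = m time points for mode `"time"`, p = q
#'   scores for mode `"pca"`); a vector is treated as one column.
#' @param basis a [build_basis()].
#' @param space the `pw_space` of the inputs.
#' @param mode `"time"` or `"pca"` (recorded for prediction).
#' @return An object of class `pw_pce`: list with `Z` (J x p coefficients),
#'   `basis`, `space`, `mode`, `rank`.
#' @export
fit_pce <- function(Theta, targets, basis, space, mode = c("time", "pca")) {
  mode <- match.arg(mode)
  Theta <- as.matrix(Theta)
  targets <- if (is.null(dim(targets))) matrix(targets, ncol = 1)
             else as.matrix(targets)
  if (anyNA(targets)) stop("fit_pce: NaN/NA in targets")
  if (nrow(targets) != nrow(Theta))
    stop("fit_pce: row count mismatch between design and targets")
  X <- 2 * to_unit_cube(Theta, space) - 1
  Psi <- eval_basis(X, basis)
  sv <- svd(Psi)
  tol <- max(dim(Psi)) * .Machine$double.eps * sv$d[1]
  r <- sum(sv$d > tol)
  if (r < basis$J)
    warning("fit_pce: rank-deficient least squares (n = ", nrow(Psi),
            " < J = ", basis$J, " effective); returning the minimum-norm ",
            "solution - expect poor generalization", call. = FALSE)
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  Z <- sv$v %*% (dinv * crossprod(sv$u, targets))
  structure(list(Z = Z, basis = basis, space = space, mode = mode,
                 rank = r), class = "pw_pce")
}

#' Evaluate a polynomial-chaos emulator
#'
#' Maps new parameter vectors to `[-1,1]^d`, evaluates the polynomial
#' surface, and (for mode `"pca"`) reconstructs waveforms through the PCA
#' basis.
#'
#' @param model a `pw_pce`.
#' @param theta_new vector or matrix of rows, physical units.
#' @param basis a `pw_pca` (required for mode `"pca"`).
#' @return p x n_new matrix: m x n waveforms (time mode, or pca mode with
#'   basis) or q x n scores.
#' @export
predict_pce <- function(model, theta_new, basis = NULL) {
  if (is.null(dim(theta_new))) theta_new <- matrix(theta_new, nrow = 1)
  X <- 2 * to_unit_cube(as.matrix(theta_new), model$space) - 1
  Psi <- eval_basis(X, model$basis)
  out <- t(Psi %*% model$Z)                 # p x n_new
  if (model$mode == "pca") {
    if (is.null(basis)) return(out)
    out <- pca_reconstruct(out, basis)
    if (is.null(dim(out))) out <- matrix(out, ncol = 1)
  }
  out
}

#' Sobol sensitivity indices from PCE coefficients
#'
#' With an orthonormal basis the output variance decomposes as the sum of
#' squared non-constant coefficients. Per output column: first-order index
#' `S_i` sums coefficients whose multi-index involves parameter i alone;
#' total-order `ST_i` sums those with any power of parameter i. Generalized
#' indices aggregate over output columns, weighting each by its variance
#' share.
#'
#' @param model a `pw_pce` fitted with an orthonormal basis.
#' @return An object of class `pw_sobol`: list with `first_order`,
#'   `total_order` (named d-vectors, generalized), `per_output` (list of
#'   d x p matrices `S` and `ST`), `variance` (per-output), `generalized`.
#' @export
sobol_from_pce <- function(model) {
  idx <- model$basis$indices
  d <- model$basis$d
  Z2 <- model$Z^2
  nonconst <- rowSums(idx) > 0
  V <- colSums(Z2[nonconst, , drop = FALSE])
  # effectively-constant output: non-constant energy at round-off level
  if (sum(V) <= 1e-24 * sum(Z2)) {
    warning("sobol_from_pce: zero total variance; indices undefined")
    nm <- model$space$names
    return(structure(list(first_order = stats::setNames(rep(NA_real_, d), nm),
                          total_order = stats::setNames(rep(NA_real_, d), nm),
                          per_output = NULL, variance = V,
                          generalized = TRUE, degenerate = TRUE),
                     class = "pw_sobol"))
  }
  S <- ST <- matrix(0, d, ncol(Z2))
  for (i in seq_len(d)) {
    only_i <- idx[, i] > 0 & rowSums(idx[, -i, drop = FALSE]) == 0
    any_i <- idx[, i] > 0
    S[i, ] <- colSums(Z2[only_i, , drop = FALSE])
    ST[i, ] <- colSums(Z2[any_i, , drop = FALSE])
  }
  Sg <- rowSums(S) / sum(V)
  STg <- rowSums(ST) / sum(V)
  Vsafe <- ifelse(V > 0, V, NA_real_)
  nm <- model$space$names
  structure(list(first_order = stats::setNames(Sg, nm),
                 total_order = stats::setNames(STg, nm),
                 per_output = list(S = sweep(S, 2, Vsafe, `/`),
                                   ST = sweep(ST, 2, Vsafe, `/`)),
                 variance = V, generalized = TRUE, degenerate = FALSE),
            class = "pw_sobol")
}
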