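#' Principal-component basis of a waveform training set
#'
#' Centers the m x n training matrix `F` over columns (design points) and
#' takes the leading `q` left singular vectors as the orthonormal waveform
#' basis. Variance explained uses the 1/(n-1)-normalized covariance
#' eigenvalues, i.e. the squared singular values of the centered matrix. The
#' sign of each basis column is fixed so that its largest-magnitude entry is
#' positive, making the output deterministic across platforms.
#'
#' If all columns are identical the centered matrix is zero: the basis is
#' flagged `degenerate`, its columns are zero, and `var_explained` is defined
#' as 1 (the mean alone reproduces the data exactly).
#'
#' @param F m x n waveform matrix, or a `pw_waveset`.
#' @param q number of components, `q < min(m, n)`.
#' @return An object of class `pw_pca`: list with `mean` (m), `basis`
#'   (m x q), `singular_values` (all, descending), `q`, `var_explained`,
#'   `scores` (q x n training scores), `n_basis`, `degenerate`.
#' @export
fit_pca <- function(F, q = 5) {
  if (inherits(F, "pw_waveset")) F <- F$F
  F <- as.matrix(F)
  m <- nrow(F); n <- ncol(F)
  if (n < q + 1) stop("fit_pca: need n >= q + 1 training columns")
  if (q >= min(m, n)) stop("fit_pca: q must be < min(m, n)")
  mu <- rowMeans(F)
  Fc <- F - mu
  sv <- svd(Fc)
  degenerate <- sv$d[1] < 1e-12 * max(1, max(abs(F)))
  basis <- sv$u[, seq_len(q), drop = FALSE]
  # deterministic sign convention
  for (j in seq_len(q)) {
    k <- which.max(abs(basis[, j]))
    if (basis[k, j] < 0) basis[, j] <- -basis[, j]
  }
  if (degenerate) {
    basis[] <- 0
    ve <- 1
  } else {
    ve <- sum(sv$d[seq_len(q)]^2) / sum(sv$d^2)
  }
  scores <- t(basis) %*% Fc
  structure(list(mean = mu, basis = basis, singular_values = sv$d,
                 q = q, var_explained = ve, scores = scores, n_basis = n,
                 degenerate = degenerate),
            class = "pw_pca")
}

#' Project waveforms onto a PCA basis
#'
#' `c = t(basis) %*% (f - mean)` per column.
#'
#' @param F m-vector or m x n matrix of waveforms.
#' @param basis a `pw_pca`.
#' @return q x n score matrix (q-vector for a single waveform).
#' @export
pca_project <- function(F, basis) {
  F <- if (is.null(dim(F))) matrix(F, ncol = 1) else as.matrix(F)
  if (nrow(F) != length(basis$mean))
    stop("pca_project: waveform length ", nrow(F), " != basis length ",
         length(basis$mean))
  out <- t(basis$basis) %*% (F - basis$mean)
  if (ncol(out) == 1) drop(out) else out
}

#' Reconstruct waveforms from PCA scores
#'
#' `f_hat = mean + basis %*% c`; the reconstruction residual of any waveform
#' is orthogonal to the span of the basis.
#'
#' @param scores q-vector or q x n matrix.
#' @param basis a `pw_pca`.
#' @return m-vector or m x n matrix.
#' @export
pca_reconstruct <- function(scores, basis) {
  scores <- if (is.null(dim(scores))) matrix(scores, ncol = 1)
            else as.matrix(scores)
  if (nrow(scores) != basis$q)
    stop("pca_reconstruct: expected ", basis$q, " scores per column")
  out <- basis$mean + basis$basis %*% scores
  if (ncol(out) == 1) drop(out) else out
}

#' Archive a PCA basis as CSV + JSON
#' @param basis a `pw_pca`.
#' @param path CSV path (mean and basis columns; metadata in `<path>.json`).
#' @export
write_pca <- function(basis, path) {
  df <- data.frame(mean = basis$mean)
  for (j in seq_len(basis$q)) df[[paste0("pc", j)]] <- basis$basis[, j]
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(q = basis$q, var_explained = basis$var_explained,
                            singular_values = basis$singular_values,
                            n_basis = basis$n_basis,
                            degenerate = basis$degenerate),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
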