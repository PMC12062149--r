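#' Canonical correlation analysis
#'
#' Solves for projection weights `wx`, `wy` maximizing
#' `corr(wx' X, wy' Y)` between two multi-channel signals observed over the
#' same `Ns` time samples. Computed by SVD of the whitened cross-covariance
#' `Cxx^{-1/2} Cxy Cyy^{-1/2}` (numerically stabler than a direct
#' eigendecomposition); covariance blocks receive a ridge
#' `1e-10 * trace/dim` when rank-deficient. Each weight vector is scaled so
#' its largest-magnitude entry is positive (eigenvectors are sign-ambiguous;
#' downstream features use signed correlations, so determinism requires the
#' convention) and so the projected variates have unit variance.
#'
#' @param X numeric matrix `[p x Ns]` (variables in rows).
#' @param Y numeric matrix `[q x Ns]`.
#' @return `cca_result`: list with `rho` (canonical correlations, descending),
#'   `Wx` (`[p x k]`), `Wy` (`[q x k]`), `k = min(p, q)`.
#' @export
cca <- function(X, Y) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1L)
  if (!is.matrix(Y)) Y <- matrix(Y, nrow = 1L)
  if (ncol(X) != ncol(Y)) stop("X and Y must share the sample dimension")
  if (!all(is.finite(X)) || !all(is.finite(Y))) stop("inputs must be finite")
  if (all(X == 0) || all(Y == 0)) stop("all-zero input to cca()")
  Xc <- X - rowMeans(X)
  Yc <- Y - rowMeans(Y)
  ns <- ncol(Xc)
  # population (1/Ns) normalization: makes weight scale exactly invariant to
  # tiling the data along time, which the training step relies on
  Cxx <- tcrossprod(Xc) / ns
  Cyy <- tcrossprod(Yc) / ns
  Cxy <- tcrossprod(Xc, Yc) / ns
  if (any(diag(Cxx) == 0) || any(diag(Cyy) == 0))
    warning("zero-variance row(s): covariance regularized")
  Wxx <- inv_sqrt_psd(Cxx)
  Wyy <- inv_sqrt_psd(Cyy)
  K <- Wxx %*% Cxy %*% Wyy
  sv <- svd(K)
  k <- min(nrow(X), nrow(Y))
  rho <- pmin(pmax(sv$d[seq_len(k)], 0), 1 + 1e-10)
  Wx <- Wxx %*% sv$u[, seq_len(k), drop = FALSE]
  Wy <- Wyy %*% sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    Wx[, j] <- fix_sign(Wx[, j])
    Wy[, j] <- fix_sign(Wy[, j])
  }
  structure(list(rho = rho, Wx = Wx, Wy = Wy, k = k), class = "cca_result")
}

#' @export
print.cca_result <- function(x, ...) {
  cat(sprintf("<cca_result> k=%d | rho1=%.4f\n", x$k, x$rho[1L]))
  invisible(x)
}

# Symmetric PSD inverse square root with relative ridge for rank deficiency.
inv_sqrt_psd <- function(C) {
  d <- nrow(C)
  eps <- 1e-10 * sum(diag(C)) / d
  if (eps <= 0 || !is.finite(eps)) eps <- 1e-12
  e <- eigen(C + diag(eps, d), symmetric = TRUE)
  vals <- pmax(e$values, eps)
  e$vectors %*% (t(e$vectors) / sqrt(vals))
}

# Sign convention: largest-magnitude entry positive.
fix_sign <- function(w) {
  i <- which.max(abs(w))
  if (w[i] < 0) -w else w
}

#' First canonical correlation
#'
#' Convenience projection of [cca()]: the maximal correlation attainable
#' between linear combinations of the rows of `X` and of `Y`.
#'
#' @inheritParams cca
#' @return scalar `rho1` in `[0, 1]`.
#' @export
max_canonical_correlation <- function(X, Y) {
  cca(X, Y)$rho[1L]
}

#' Pearson correlation of two vectors
#'
#' Standard centered correlation; a zero-variance input yields 0 with a
#' warning rather than `NA`, so downstream feature vectors stay finite.
#'
#' @param u,v numeric vectors of equal length (>= 2).
#' @return correlation in `[-1, 1]`.
#' @export
pearson <- function(u, v) {
  if (length(u) != length(v)) stop("length mismatch in pearson()")
  if (length(u) < 2L) stop("need at least 2 samples")
  su <- stats::sd(u); sv <- stats::sd(v)
  if (su == 0 || sv == 0) {
    warning("zero-variance input to pearson(); returning 0")
    return(0)
  }
  stats::cor(u, v)
}

#' Two-dimensional (matrix) correlation
#'
#' Pearson correlation of the flattened matrices — the standard reading of
#' the ensemble-filter correlation `rho(X'W, Xbar'W)` between two equally
#' shaped projected signals.
#'
#' @param A,B numeric matrices of identical shape.
#' @return correlation in `[-1, 1]`.
#' @export
matrix_correlation <- function(A, B) {
  if (!identical(dim(A), dim(B))) stop("shape mismatch in matrix_correlation()")
  pearson(as.vector(A), as.vector(B))
}
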