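# Classical canonical correlation analysis.
#
# The first canonical correlation between column-centred X (m x p) and Y
# (m x q) maximizes corr(X nu, Y omega) subject to nu' X'X nu =
# omega' Y'Y omega = 1. It is computed as the largest singular value of the
# whitened cross-covariance Cxx^{-1/2} Cxy Cyy^{-1/2}, with pseudo-inverse
# whitening (relative singular-value cutoff 1e-10) so SNP columns in perfect
# LD do not crash the solver.

#' Centre the columns of a matrix
#'
#' @param M Numeric matrix with at least 2 rows.
#' @return `M` with every column shifted to mean zero.
#' @examples
#' center_columns(matrix(1:6, 3, 2))
#' @export
center_columns <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) < 2) stop("need at least 2 rows to centre")
  sweep(M, 2, colMeans(M))
}

# Symmetric pseudo-inverse square root via eigendecomposition.
# Returns list(W = S^{-1/2} on the attained subspace, rank).
.pinv_sqrt <- function(S, rtol = 1e-10) {
  e <- eigen(S, symmetric = TRUE)
  pos <- e$values > rtol * max(e$values, 0)
  if (!any(pos)) stop("matrix has no positive spectrum (constant columns?)")
  V <- e$vectors[, pos, drop = FALSE]
  list(W = V %*% (t(V) / sqrt(e$values[pos])), rank = sum(pos))
}

#' First canonical correlation between two matrices
#'
#' Computes the first canonical correlation and the associated weight
#' vectors between two sets of variables measured on the same individuals.
#' Inputs are centred internally. Rank-deficient covariance blocks (e.g.
#' SNPs in perfect LD that survived QC) are handled by pseudo-inverse
#' whitening, which returns the maximal correlation on the attained
#' subspace.
#'
#' @param X,Y Numeric matrices (or [genotype_matrix()] objects) with the
#'   same number of rows.
#' @return An object of class `canonical_result`: `r` (first canonical
#'   correlation in \[0, 1\]), `left_vector` (`nu`, length `ncol(X)`),
#'   `right_vector` (`omega`, length `ncol(Y)`), `variates` (list of the
#'   score vectors `a = Xc nu`, `b = Yc omega`, normalized to unit sum of
#'   squares) and `all_r` (the full sequence of canonical correlations, for
#'   diagnostics; only the first feeds the co-association statistic).
#' @details Signs are fixed so that `r >= 0` and the first nonzero entry of
#'   `left_vector` is positive, which makes the output deterministic.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(60), 20, 3)
#' Y <- cbind(X[, 1] + rnorm(20, sd = 0.3), rnorm(20))
#' cca_first(X, Y)$r
#' @export
cca_first <- function(X, Y) {
  if (inherits(X, "genotype_matrix")) X <- X$values
  if (inherits(Y, "genotype_matrix")) Y <- Y$values
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y have different numbers of rows")
  if (nrow(X) < 3) stop("need at least 3 individuals")
  vx <- apply(X, 2, stats::var)
  vy <- apply(Y, 2, stats::var)
  if (any(vx == 0) || any(vy == 0))
    stop("zero-variance column present; run qc_filter first")
  Xc <- center_columns(X)
  Yc <- center_columns(Y)
  Cxx <- crossprod(Xc)
  Cyy <- crossprod(Yc)
  Cxy <- crossprod(Xc, Yc)
  Wx <- .pinv_sqrt(Cxx)$W
  Wy <- .pinv_sqrt(Cyy)$W
  s <- svd(Wx %*% Cxy %*% Wy)
  r <- min(max(s$d[1], 0), 1)
  nu <- drop(Wx %*% s$u[, 1])
  omega <- drop(Wy %*% s$v[, 1])
  # deterministic sign: first nonzero entry of nu positive, omega follows
  nz <- which(abs(nu) > 1e-12)[1]
  if (!is.na(nz) && nu[nz] < 0) {
    nu <- -nu
    omega <- -omega
  }
  a <- drop(Xc %*% nu)
  b <- drop(Yc %*% omega)
  structure(list(r = r,
                 left_vector = nu,
                 right_vector = omega,
                 variates = list(a = a, b = b),
                 all_r = pmin(pmax(s$d, 0), 1)),
            class = "canonical_result")
}

#' @export
print.canonical_result <- function(x, ...) {
  cat("canonical_result: first canonical correlation r =",
      format(x$r, digits = 6), "\n")
  invisible(x)
}
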