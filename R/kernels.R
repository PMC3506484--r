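# Kernel Gram matrices and regularized kernel CCA.
#
# KCCA maximizes alpha' Kx Ky beta subject to the regularized constraints
# alpha'(Kx + eta I)^2 alpha = beta'(Ky + eta I)^2 beta = 1 on centred Gram
# matrices. Without regularization the problem is degenerate whenever the
# Grams are (numerically) invertible on the centred subspace: the optimum is
# then trivially 1. Writing Kx = Ux Lx Ux' (nonzero eigenpairs), the optimum
# reduces to the largest singular value of
#   diag(lx/(lx+eta)) Ux' Uy diag(ly/(ly+eta)),
# which is the basis of both the dense solver and the low-rank solver (the
# latter replaces the eigendecomposition of the m x m Gram by a pivoted
# Cholesky factor, giving O(m rank^2) cost).

#' Kernel specification
#'
#' Bundles a kernel family with its parameters and the KCCA regularization
#' constant.
#'
#' @param family One of `"linear"`, `"polynomial"`, `"rbf"`, `"sigmoid"`,
#'   `"ibs"`, `"weighted_ibs"`.
#' @param sigma RBF bandwidth multiplier: `k(u, v) = exp(-sigma ||u - v||^2)`.
#'   Default 0.5. (Parameterized as the multiplier, not `1/(2 sigma^2)`, so
#'   a sweep over e.g. 0.05, 0.5, 5, 50 maps directly.)
#' @param degree,offset Polynomial kernel `(u.v + offset)^degree`; `offset`
#'   is also the shift of the sigmoid kernel.
#' @param scale Sigmoid kernel `tanh(scale * u.v + offset)`.
#' @param eta Nonnegative KCCA regularization. `NULL` (default) means
#'   "use the data-driven default" `0.1 * m * mean(diag(K))`, computed from
#'   the uncentred Gram at solve time.
#' @return An object of class `kernel_spec`.
#' @export
kernel_spec <- function(family = c("rbf", "linear", "polynomial", "sigmoid",
                                   "ibs", "weighted_ibs"),
                        sigma = 0.5, degree = 2L, offset = 1, scale = 1,
                        eta = NULL) {
  family <- match.arg(family)
  if (family == "rbf" && sigma <= 0) stop("sigma must be > 0 for the RBF kernel")
  if (degree < 1) stop("degree must be >= 1")
  if (!is.null(eta) && eta < 0) stop("eta must be >= 0")
  structure(list(family = family, sigma = sigma, degree = as.integer(degree),
                 offset = offset, scale = scale, eta = eta),
            class = "kernel_spec")
}

#' @export
print.kernel_spec <- function(x, ...) {
  extra <- switch(x$family,
                  rbf = paste0("sigma = ", x$sigma),
                  polynomial = paste0("degree = ", x$degree,
                                      ", offset = ", x$offset),
                  sigmoid = paste0("scale = ", x$scale,
                                   ", offset = ", x$offset),
                  "")
  cat("kernel_spec: ", x$family, if (nzchar(extra)) paste0(" (", extra, ")"),
      ", eta = ", if (is.null(x$eta)) "auto" else x$eta, "\n", sep = "")
  invisible(x)
}

# Kernel matrix between the rows of U (rows x SNPs dosage matrix).
# maf is only used by the weighted IBS kernel.
.kernel_matrix <- function(U, spec, maf = NULL) {
  U <- as.matrix(U)
  p <- ncol(U)
  switch(spec$family,
    linear = tcrossprod(U),
    polynomial = (tcrossprod(U) + spec$offset)^spec$degree,
    sigmoid = tanh(spec$scale * tcrossprod(U) + spec$offset),
    rbf = {
      sq <- rowSums(U * U)
      d2 <- outer(sq, sq, "+") - 2 * tcrossprod(U)
      d2[d2 < 0] <- 0
      exp(-spec$sigma * d2)
    },
    ibs = {
      D <- matrix(0, nrow(U), nrow(U))
      for (s in seq_len(p)) D <- D + abs(outer(U[, s], U[, s], "-"))
      (2 * p - D) / (2 * p)
    },
    weighted_ibs = {
      if (is.null(maf)) maf <- .observed_maf(U)
      maf <- pmax(maf, 1 / (2 * nrow(U) + 2))
      w <- 1 / sqrt(maf)
      Dw <- matrix(0, nrow(U), nrow(U))
      for (s in seq_len(p)) Dw <- Dw + w[s] * abs(outer(U[, s], U[, s], "-"))
      (2 * sum(w) - Dw) / (2 * sum(w))
    },
    stop("unsupported kernel family: ", spec$family))
}

#' Compute a kernel Gram matrix over individuals
#'
#' Evaluates the kernel between every pair of individuals' dosage vectors
#' for one gene, giving the m x m Gram matrix used by KCCA.
#'
#' @param G A [genotype_matrix()] (post-QC: complete) or a plain numeric
#'   matrix of dosages.
#' @param spec A [kernel_spec()].
#' @return An object of class `gram_matrix` with elements `values` (m x m),
#'   `spec` and `centred = FALSE`.
#' @examples
#' G <- matrix(c(0, 1, 2, 1, 1, 0), 3, 2)
#' compute_gram(G, kernel_spec("rbf", sigma = 0.5))
#' @export
compute_gram <- function(G, spec = kernel_spec("rbf")) {
  maf <- NULL
  if (inherits(G, "genotype_matrix")) {
    maf <- G$snps$minor_allele_freq
    G <- G$values
  }
  if (anyNA(G)) stop("genotypes contain missing values; run qc_filter first")
  K <- .kernel_matrix(G, spec, maf)
  structure(list(values = K, spec = spec, centred = FALSE),
            class = "gram_matrix")
}

#' @export
print.gram_matrix <- function(x, ...) {
  cat("gram_matrix: ", nrow(x$values), " x ", ncol(x$values), " (",
      x$spec$family, if (x$centred) ", centred", ")\n", sep = "")
  invisible(x)
}

#' Doubly centre a Gram matrix
#'
#' Applies the feature-space centering `K <- H K H` with
#' `H = I - (1/m) 11'`, so that the implicit feature images have mean zero —
#' the same convention as column-centering the data in classical CCA. Row
#' and column sums of the result are zero.
#'
#' @param K A `gram_matrix` (or plain symmetric matrix).
#' @return The centred `gram_matrix`.
#' @export
center_gram <- function(K) {
  plain <- !inherits(K, "gram_matrix")
  V <- if (plain) as.matrix(K) else K$values
  diag_mean <- mean(diag(V))
  rm_ <- rowMeans(V)
  gm <- mean(rm_)
  V <- V - outer(rm_, rep(1, ncol(V))) - outer(rep(1, nrow(V)), colMeans(V)) + gm
  if (plain) return(V)
  K$values <- V
  K$centred <- TRUE
  # kept so the default regularization rule can refer to the uncentred scale
  if (is.null(K$diag_uncentred_mean)) K$diag_uncentred_mean <- diag_mean
  K
}

# Pivoted-Cholesky low-rank factor: K ~= L %*% t(L), L of size m x rank.
.lowrank_factor <- function(K, tol = 1e-6) {
  n <- nrow(K)
  dtol <- tol * max(diag(K), .Machine$double.eps)
  R <- suppressWarnings(chol(K, pivot = TRUE, tol = dtol))
  rank <- attr(R, "rank")
  piv <- attr(R, "pivot")
  d2 <- diag(R)[seq_len(rank)]^2
  rank <- sum(d2 > dtol)
  if (rank == 0) return(matrix(0, n, 1))
  L <- matrix(0, n, rank)
  L[piv, ] <- t(R[seq_len(rank), , drop = FALSE])
  L
}

# Core reduced solver. Axx = Gx'Gx, Axy = Gx'Gy, Ayy = Gy'Gy for any exact
# factorization Kx = Gx Gx', Ky = Gy Gy' of the centred Grams. Returns the
# maximum kernel canonical coefficient plus the reduced-coordinate weights.
.kcca_from_factors <- function(Axx, Axy, Ayy, eta) {
  ex <- eigen(Axx, symmetric = TRUE)
  ey <- eigen(Ayy, symmetric = TRUE)
  kx <- ex$values > max(ex$values[1], 0) * 1e-12 & ex$values > 0
  ky <- ey$values > max(ey$values[1], 0) * 1e-12 & ey$values > 0
  if (!any(kx) || !any(ky))
    return(list(kr = 0, wx = NULL, wy = NULL))
  lx <- ex$values[kx]; Vx <- ex$vectors[, kx, drop = FALSE]
  ly <- ey$values[ky]; Vy <- ey$vectors[, ky, drop = FALSE]
  dx <- sqrt(lx) / (lx + eta)
  dy <- sqrt(ly) / (ly + eta)
  M <- (dx * t(Vx)) %*% Axy %*% Vy
  M <- M * rep(dy, each = nrow(M))
  s <- svd(M)
  kr <- min(max(s$d[1], 0), 1)
  # factor-space weights: alpha = Gx wx with Ux = Gx Vx Lx^{-1/2} and
  # alpha = Ux (Lx + eta)^{-1} u1
  wx <- drop(Vx %*% (s$u[, 1] / (sqrt(lx) * (lx + eta))))
  wy <- drop(Vy %*% (s$v[, 1] / (sqrt(ly) * (ly + eta))))
  list(kr = kr, wx = wx, wy = wy)
}

# Fast top kernel canonical coefficient from factor-space matrices; value
# only (no expansion vectors). Identical to .kcca_from_factors' kr:
# sigma_max(M)^2 = lambda_max(Fx Axy g(Ayy) Axy' Fx') with
# g(A) = (A + eta I)^{-1} A (A + eta I)^{-1}, so the larger side needs one
# Cholesky solve instead of a full eigendecomposition.
.kcca_top_cor <- function(Axx, Axy, Ayy, eta) {
  if (eta <= 1e-8)
    return(.kcca_from_factors(Axx, Axy, Ayy, eta)$kr)
  if (nrow(Ayy) < nrow(Axx)) {
    tmp <- Axx; Axx <- Ayy; Ayy <- tmp
    Axy <- t(Axy)
  }
  ex <- eigen(Axx, symmetric = TRUE)
  kx <- ex$values > max(ex$values[1], 0) * 1e-12 & ex$values > 0
  if (!any(kx)) return(0)
  lx <- ex$values[kx]
  Fx <- (sqrt(lx) / (lx + eta)) * t(ex$vectors[, kx, drop = FALSE])
  C <- chol(Ayy + diag(eta, nrow(Ayy)))
  Z <- backsolve(C, backsolve(C, t(Axy), transpose = TRUE))
  S <- Fx %*% crossprod(Z, Ayy %*% Z) %*% t(Fx)
  lam <- eigen((S + t(S)) / 2, symmetric = TRUE, only.values = TRUE)$values[1]
  min(sqrt(max(lam, 0)), 1)
}

.default_eta <- function(K_uncentred_diag_mean, m) {
  0.1 * m * K_uncentred_diag_mean
}

#' Maximum kernel canonical coefficient
#'
#' Solves the regularized KCCA problem on two centred Gram matrices:
#' maximize `alpha' Kx Ky beta` subject to
#' `alpha' (Kx + eta I)^2 alpha = beta' (Ky + eta I)^2 beta = 1`, and
#' returns the largest attainable correlation (clipped to \[0, 1\]).
#'
#' @param K_x,K_y Centred `gram_matrix` objects (or plain centred symmetric
#'   matrices) of the same size.
#' @param eta Nonnegative regularization constant. `NULL` uses the default
#'   `0.1 * m * mean(diag K)` where the diagonal mean is taken from the
#'   uncentred kernel stored in the spec if available, else from the centred
#'   input. With `eta = 0` and numerically full-rank Grams the problem is
#'   degenerate and the result is ~1 (a warning is issued).
#' @param path `"dense"` solves the m x m eigenproblem directly;
#'   `"lowrank"` goes through a pivoted-Cholesky factorization with rank
#'   tolerance `rank_tol` (cost `O(m rank^2)`); `"auto"` picks lowrank for
#'   m > 200.
#' @param rank_tol Relative tolerance for rank truncation in the low-rank
#'   path.
#' @return List with `kr` (maximum kernel canonical coefficient), `alpha`,
#'   `beta` (length-m expansion coefficient vectors) and `eta` (the value
#'   actually used).
#' @export
kcca_max_correlation <- function(K_x, K_y, eta = NULL,
                                 path = c("auto", "dense", "lowrank"),
                                 rank_tol = 1e-6) {
  path <- match.arg(path)
  diag_mean <- NULL
  if (inherits(K_x, "gram_matrix")) {
    if (!K_x$centred) stop("K_x must be centred (see center_gram)")
    diag_mean <- K_x$diag_uncentred_mean
    Kx <- K_x$values
  } else Kx <- as.matrix(K_x)
  if (inherits(K_y, "gram_matrix")) {
    if (!K_y$centred) stop("K_y must be centred (see center_gram)")
    Ky <- K_y$values
  } else Ky <- as.matrix(K_y)
  m <- nrow(Kx)
  if (!all(dim(Kx) == dim(Ky)))
    stop("K_x and K_y must have identical dimensions")
  if (max(abs(rowSums(Kx))) > 1e-6 * max(1, max(abs(Kx))) ||
      max(abs(rowSums(Ky))) > 1e-6 * max(1, max(abs(Ky))))
    stop("Gram matrices do not look centred; apply center_gram first")
  if (is.null(eta)) {
    if (is.null(diag_mean)) diag_mean <- mean(diag(Kx))
    eta <- .default_eta(diag_mean, m)
  }
  if (eta == 0)
    warning("eta = 0: KCCA is degenerate for full-rank Gram matrices ",
            "(result will be ~1)")
  if (path == "auto") path <- if (m > 200) "lowrank" else "dense"
  if (path == "dense") {
    ex <- eigen(Kx, symmetric = TRUE)
    ey <- eigen(Ky, symmetric = TRUE)
    kx <- ex$values > max(ex$values[1], 0) * 1e-12 & ex$values > 0
    ky <- ey$values > max(ey$values[1], 0) * 1e-12 & ey$values > 0
    if (!any(kx) || !any(ky))
      return(list(kr = 0, alpha = rep(0, m), beta = rep(0, m), eta = eta))
    lx <- ex$values[kx]; Ux <- ex$vectors[, kx, drop = FALSE]
    ly <- ey$values[ky]; Uy <- ey$vectors[, ky, drop = FALSE]
    M <- ((lx / (lx + eta)) * t(Ux)) %*% Uy
    M <- M * rep(ly / (ly + eta), each = nrow(M))
    s <- svd(M)
    kr <- min(max(s$d[1], 0), 1)
    alpha <- drop(Ux %*% (s$u[, 1] / (lx + eta)))
    beta <- drop(Uy %*% (s$v[, 1] / (ly + eta)))
    return(list(kr = kr, alpha = alpha, beta = beta, eta = eta))
  }
  # low-rank path
  Gx <- .lowrank_factor(Kx, rank_tol)
  Gy <- .lowrank_factor(Ky, rank_tol)
  red <- .kcca_from_factors(crossprod(Gx), crossprod(Gx, Gy), crossprod(Gy),
                            eta)
  if (is.null(red$wx))
    return(list(kr = 0, alpha = rep(0, m), beta = rep(0, m), eta = eta))
  list(kr = red$kr, alpha = drop(Gx %*% red$wx), beta = drop(Gy %*% red$wy),
       eta = eta)
}
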