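test_that("kernel values match their definitions on hand-worked cases", {
  U <- rbind(c(0, 1, 2), c(1, 1, 0))
  # rbf: ||u - v||^2 = 1 + 0 + 4 = 5, sigma = 0.5 -> exp(-2.5)
  K <- compute_gram(U, kernel_spec("rbf", sigma = 0.5))
  expect_equal(K$values[1, 2], exp(-2.5))
  expect_equal(diag(K$values), c(1, 1))  # zero self-distance

  Ki <- compute_gram(rbind(c(0, 0), c(2, 2), c(0, 0)), kernel_spec("ibs"))
  expect_equal(Ki$values[1, 3], 1)  # identical vectors
  expect_equal(Ki$values[1, 2], 0)  # maximally dissimilar

  Kl <- compute_gram(U, kernel_spec("linear"))
  expect_equal(Kl$values, tcrossprod(U))

  Kp <- compute_gram(U, kernel_spec("polynomial", degree = 2, offset = 1))
  expect_equal(Kp$values, (tcrossprod(U) + 1)^2)

  Ks <- compute_gram(U, kernel_spec("sigmoid", scale = 0.1, offset = 0))
  expect_equal(Ks$values, tanh(0.1 * tcrossprod(U)))
})

test_that("weighted IBS weights SNPs by 1/sqrt(MAF) and is 1 on the diagonal", {
  G <- genotype_matrix(random_genotypes(12, 3, seed = 21))
  K <- compute_gram(G, kernel_spec("weighted_ibs"))
  expect_equal(unname(diag(K$values)), rep(1, 12))
  expect_true(all(K$values >= 0 & K$values <= 1))
  # hand recomputation for one off-diagonal pair
  w <- 1 / sqrt(G$snps$minor_allele_freq)
  u <- G$values[1, ]; v <- G$values[2, ]
  expect_equal(K$values[1, 2],
               sum(w * (2 - abs(u - v)) / 2) / sum(w))
})

test_that("gram matrices are symmetric PSD for the bounded kernels", {
  G <- random_genotypes(20, 4, seed = 22)
  for (fam in c("rbf", "ibs", "linear")) {
    K <- compute_gram(G, kernel_spec(fam))$values
    expect_equal(K, t(K))
    expect_gte(min(eigen(K, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("unsupported kernel families are rejected", {
  expect_error(kernel_spec("mystery"))
  bad <- kernel_spec("rbf"); bad$family <- "mystery"
  expect_error(compute_gram(matrix(0:3, 2), bad), "unsupported kernel")
})

test_that("center_gram doubly centres, annihilates constants, idempotent", {
  Kc <- center_gram(matrix(3, 4, 4))
  expect_equal(Kc, matrix(0, 4, 4))

  K <- compute_gram(random_genotypes(10, 3, seed = 23), kernel_spec("rbf"))
  K1 <- center_gram(K)
  expect_true(K1$centred)
  expect_lt(max(abs(rowSums(K1$values))), 1e-8)
  expect_lt(max(abs(colSums(K1$values))), 1e-8)
  expect_equal(center_gram(K1)$values, K1$values, tolerance = 1e-10)

  # linear Gram of an already-centred 1-column matrix is already centred
  x <- matrix(c(-1, 0, 1), 3, 1)
  Kl <- compute_gram(x, kernel_spec("linear"))
  expect_equal(center_gram(Kl)$values, Kl$values, tolerance = 1e-12)
})

test_that("identical centred Grams give kr -> 1 in the small-eta limit", {
  K <- center_gram(compute_gram(random_genotypes(15, 3, seed = 24),
                                kernel_spec("rbf")))
  fit <- kcca_max_correlation(K, K, eta = 1e-10)
  expect_equal(fit$kr, 1, tolerance = 1e-6)
})

test_that("linear-kernel KCCA with eta -> 0 recovers classical CCA", {
  for (s in 1:5) {
    X <- random_genotypes(40, 3, seed = 500 + s)
    Y <- random_genotypes(40, 4, seed = 600 + s)
    Kx <- center_gram(compute_gram(X, kernel_spec("linear")))
    Ky <- center_gram(compute_gram(Y, kernel_spec("linear")))
    expect_equal(kcca_max_correlation(Kx, Ky, eta = 1e-8)$kr,
                 cca_first(X, Y)$r, tolerance = 1e-4)
  }
})

test_that("KCCA matches the closed-form ratio oracle at several eta", {
  X <- random_genotypes(25, 3, seed = 26)
  Y <- random_genotypes(25, 4, seed = 27)
  Kx <- center_gram(compute_gram(X, kernel_spec("rbf")))
  Ky <- center_gram(compute_gram(Y, kernel_spec("rbf")))
  for (eta in c(0.05, 0.5, 5)) {
    expect_equal(kcca_max_correlation(Kx, Ky, eta = eta, path = "dense")$kr,
                 oracle_kcca_kr(Kx$values, Ky$values, eta),
                 tolerance = 1e-8)
  }
})

test_that("eta = 0 with rich feature spaces is degenerate (kr = 1)", {
  # m = 5 and >= 5 independent feature dimensions: overfit to 1 exactly
  set.seed(28)
  X <- matrix(rnorm(5 * 6), 5, 6)
  Y <- matrix(rnorm(5 * 6), 5, 6)
  Kx <- center_gram(compute_gram(X, kernel_spec("linear")))
  Ky <- center_gram(compute_gram(Y, kernel_spec("linear")))
  expect_warning(fit <- kcca_max_correlation(Kx, Ky, eta = 0), "degenerate")
  expect_equal(fit$kr, 1, tolerance = 1e-8)
  expect_equal(fit$kr, oracle_kcca_kr(Kx$values, Ky$values, 0),
               tolerance = 1e-6)
})

test_that("kr is non-increasing in eta, symmetric, permutation-equivariant", {
  X <- random_genotypes(30, 3, seed = 29)
  Y <- random_genotypes(30, 4, seed = 30)
  Kx <- center_gram(compute_gram(X, kernel_spec("rbf")))
  Ky <- center_gram(compute_gram(Y, kernel_spec("rbf")))
  etas <- c(0.01, 0.1, 1, 10, 100)
  krs <- vapply(etas, function(e)
    kcca_max_correlation(Kx, Ky, eta = e)$kr, numeric(1))
  expect_true(all(diff(krs) <= 1e-12))
  expect_true(all(krs >= 0 & krs <= 1))

  expect_equal(kcca_max_correlation(Ky, Kx, eta = 0.3)$kr,
               kcca_max_correlation(Kx, Ky, eta = 0.3)$kr,
               tolerance = 1e-8)

  set.seed(31)
  perm <- sample(30)
  Kxp <- Kx; Kxp$values <- Kx$values[perm, perm]
  Kyp <- Ky; Kyp$values <- Ky$values[perm, perm]
  expect_equal(kcca_max_correlation(Kxp, Kyp, eta = 0.3)$kr,
               kcca_max_correlation(Kx, Ky, eta = 0.3)$kr,
               tolerance = 1e-8)
})

test_that("low-rank path agrees with the dense eigenproblem", {
  for (s in 1:5) {
    m <- c(40, 80, 150, 200, 60)[s]
    X <- random_genotypes(m, 4, seed = 700 + s)
    Y <- random_genotypes(m, 5, seed = 800 + s)
    Kx <- center_gram(compute_gram(X, kernel_spec("rbf")))
    Ky <- center_gram(compute_gram(Y, kernel_spec("rbf")))
    eta <- 0.1 * m
    expect_equal(
      kcca_max_correlation(Kx, Ky, eta = eta, path = "lowrank")$kr,
      kcca_max_correlation(Kx, Ky, eta = eta, path = "dense")$kr,
      tolerance = 1e-6)
  }
})

test_that("uncentred Grams are refused", {
  K <- compute_gram(random_genotypes(10, 2, seed = 32), kernel_spec("rbf"))
  expect_error(kcca_max_correlation(K, K, eta = 1), "centred")
})
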