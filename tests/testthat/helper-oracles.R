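# Independent oracles and fixture builders shared by the test files.
# The oracles deliberately use different formulations than the package
# (ratio-form eigenproblems, explicit inverses) so they can vouch for it.

# First canonical correlation as the largest root of the classical CCA
# eigen-equation Sxx^-1 Sxy Syy^-1 Syx, solved with plain inverses.
oracle_cca_r <- function(X, Y) {
  Xc <- scale(X, scale = FALSE)
  Yc <- scale(Y, scale = FALSE)
  Sxx <- crossprod(Xc); Syy <- crossprod(Yc); Sxy <- crossprod(Xc, Yc)
  M <- solve(Sxx) %*% Sxy %*% solve(Syy) %*% t(Sxy)
  sqrt(max(Re(eigen(M)$values)))
}

# Regularized KCCA optimum from its closed form: the largest singular value
# of (Kx + eta I)^-1 Kx Ky (Ky + eta I)^-1 (pseudo-inverse when eta = 0).
oracle_kcca_kr <- function(Kx, Ky, eta) {
  inv <- function(K) {
    if (eta > 0) return(solve(K + diag(eta, nrow(K))))
    MASS::ginv(K)
  }
  min(max(svd(inv(Kx) %*% Kx %*% Ky %*% inv(Ky))$d[1], 0), 1)
}

# Random complete dosage matrix with no constant column.
random_genotypes <- function(m, p, seed, maf = NULL) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(p, 0.15, 0.45)
  repeat {
    G <- sapply(seq_len(p), function(j) rbinom(m, 2, maf[j]))
    if (all(apply(G, 2, function(x) length(unique(x)) > 1))) return(G)
  }
}

# Dosages for two single-SNP genes with a controlled cross-gene
# correlation, via a thresholded bivariate Gaussian (HWE cutpoints at
# MAF 0.3; latent rho 0.75 yields dosage correlation ~0.6).
correlated_dosage_pair <- function(n, latent_rho) {
  z1 <- rnorm(n)
  z2 <- latent_rho * z1 + sqrt(1 - latent_rho^2) * rnorm(n)
  cuts <- qnorm(cumsum(c(0.49, 0.42)))  # P(0), P(1) under HWE, maf 0.3
  d <- function(z) as.numeric(cut(z, c(-Inf, cuts, Inf))) - 1
  cbind(A = d(z1), B = d(z2))
}

# Minimal VCF text fixture: 4 samples, 3 biallelic SNPs (one with ALT the
# major allele, to exercise minor-allele flipping) and 1 triallelic site.
write_test_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", "S2", "S3", "S4", sep = "\t"),
    paste("1", "100", "rs1", "A", "G", ".", "PASS", ".", "GT",
          "0/0", "0/1", "1/1", "0/1", sep = "\t"),
    paste("1", "200", "rs2", "C", "T", ".", "PASS", ".", "GT",
          "1/1", "1/1", "0/1", "1/1", sep = "\t"),  # ALT freq 7/8: flip
    paste("1", "300", "rs3", "G", "A,C", ".", "PASS", ".", "GT",
          "0/0", "0/1", "0/2", "0/0", sep = "\t"),  # triallelic: dropped
    paste("1", "400", "rs4", "T", "C", ".", "PASS", ".", "GT",
          "0/1", "0/0", "0/0", "1/1", sep = "\t"))
  writeLines(lines, path)
  path
}

# Build-once caches for objects reused across test files.
.kccu_test_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .kccu_test_cache)) {
    assign(name, force(expr), envir = .kccu_test_cache)
  }
  get(name, envir = .kccu_test_cache)
}

test_pools <- function() cached("pools", default_pools())

# One null-model population shared by simulator and acceptance tests.
null_population <- function() {
  cached("null_pop", simulate_case_control(
    test_pools()$region1, test_pools()$region2,
    disease_model(theta = 1), 100000, 100000, seed = 20120801))
}
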