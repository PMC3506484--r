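test_that("fisher_z matches the closed form and guards its domain", {
  expect_identical(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5 * log(3))
  rs <- c(0.1, 0.3, 0.6, 0.9, 0.99)
  expect_equal(fisher_z(rs), 0.5 * (log(1 + rs) - log(1 - rs)))
  expect_gt(fisher_z(0.8), fisher_z(0.5))
  expect_warning(z <- fisher_z(1), "clipped")
  expect_equal(z, atanh(1 - 1e-12))
  expect_error(fisher_z(1.01), "must lie in")
  expect_error(fisher_z(-0.2), "must lie in")
})

test_that("bootstrap_var_z is bit-reproducible and leaves the RNG alone", {
  GA <- random_genotypes(60, 2, seed = 41)
  GB <- random_genotypes(60, 3, seed = 42)
  set.seed(999)
  before <- .Random.seed
  b1 <- bootstrap_var_z(GA, GB, "cca", B = 50, seed = 7)
  expect_identical(.Random.seed, before)
  b2 <- bootstrap_var_z(GA, GB, "cca", B = 50, seed = 7)
  expect_identical(b1$var_z, b2$var_z)
  expect_identical(b1$z_boot, b2$z_boot)
  b3 <- bootstrap_var_z(GA, GB, "kcca", kernel_spec("rbf"), B = 50, seed = 7)
  expect_identical(b3$var_z,
                   bootstrap_var_z(GA, GB, "kcca", kernel_spec("rbf"),
                                   B = 50, seed = 7)$var_z)
})

test_that("identical single-column genes give zero bootstrap variance", {
  x <- cbind(rep(c(0, 1, 2), length.out = 48))
  b <- bootstrap_var_z(x, x, "cca", B = 30, seed = 3)
  expect_equal(b$kr_hat, 1)
  expect_identical(b$var_z, 0)
})

test_that("bootstrap variance tracks the Monte-Carlo truth within factor 2", {
  gen <- function(seed) {
    set.seed(seed)
    list(A = random_genotypes(80, 2, seed = seed),
         B = random_genotypes(80, 2, seed = seed + 10000))
  }
  z <- vapply(1:200, function(s) {
    d <- gen(s)
    cca_first(d$A, d$B)$r
  }, numeric(1))
  truth <- var(atanh(z))
  d0 <- gen(1)
  est <- bootstrap_var_z(d0$A, d0$B, "cca", B = 200, seed = 5)$var_z
  expect_gt(est, truth / 2)
  expect_lt(est, truth * 2)
})

test_that("U is exactly antisymmetric under stratum swap", {
  pools <- test_pools()
  ds <- simulate_case_control(pools$region1, pools$region2,
                              disease_model(theta = 1), 120, 150, seed = 44)
  sp <- as_case_control_split(ds)
  swapped <- sp
  swapped$cases_A <- sp$controls_A; swapped$cases_B <- sp$controls_B
  swapped$controls_A <- sp$cases_A; swapped$controls_B <- sp$cases_B
  for (meth in c("ccu", "kccu")) {
    f1 <- co_association_test(sp, meth, B = 40, seed = 11)
    f2 <- co_association_test(swapped, meth, B = 40, seed = 11)
    expect_identical(f2$U, -f1$U)
    expect_identical(f2$p_value, f1$p_value)
    expect_identical(f2$var_z_cases, f1$var_z_controls)
  }
})

test_that("the stored U reproduces from the stored components", {
  pools <- test_pools()
  ds <- simulate_case_control(pools$region1, pools$region2,
                              disease_model(theta = 1), 100, 100, seed = 45)
  fit <- co_association_test(as_case_control_split(ds), "ccu", B = 40,
                             seed = 2)
  expect_identical(fit$U, (fit$z_cases - fit$z_controls) /
                     sqrt(fit$var_z_cases + fit$var_z_controls))
  expect_identical(fit$p_value, 2 * pnorm(-abs(fit$U)))
  expect_equal(fit$z_cases, atanh(fit$kr_cases))
})

test_that("zero total variance is an explicit error", {
  x <- cbind(rep(c(0, 1, 2), length.out = 60))
  GA <- genotype_matrix(x)
  sp <- split_by_phenotype(GA, GA, rep(c(1, 0), 30))
  expect_error(co_association_test(sp, "ccu", B = 20, seed = 1),
               "zero total bootstrap variance")
})

test_that("an induced case-only cross-gene correlation is detected", {
  hits <- 0L
  for (s in 1:100) {
    set.seed(s)
    ca <- correlated_dosage_pair(500, latent_rho = 0.75)
    co <- correlated_dosage_pair(500, latent_rho = 0)
    GA <- genotype_matrix(rbind(ca[, 1, drop = FALSE], co[, 1, drop = FALSE]))
    GB <- genotype_matrix(rbind(ca[, 2, drop = FALSE], co[, 2, drop = FALSE]),
                          snps = data.frame(id = "y1", region_label = "g2"))
    sp <- split_by_phenotype(GA, GB, c(rep(1, 500), rep(0, 500)))
    fit <- co_association_test(sp, "ccu", B = 60, seed = s)
    if (fit$p_value < 0.05) hits <- hits + 1L
  }
  expect_gte(hits, 90L)
})

test_that("permutation p-values respect their bounds and detect signal", {
  set.seed(77)
  ca <- correlated_dosage_pair(300, latent_rho = 0.8)
  co <- correlated_dosage_pair(300, latent_rho = 0)
  GA <- genotype_matrix(rbind(ca[, 1, drop = FALSE], co[, 1, drop = FALSE]))
  GB <- genotype_matrix(rbind(ca[, 2, drop = FALSE], co[, 2, drop = FALSE]),
                        snps = data.frame(id = "y1", region_label = "g2"))
  sp <- split_by_phenotype(GA, GB, c(rep(1, 300), rep(0, 300)))
  p <- permutation_pvalue(sp, "ccu", B = 30, n_perm = 19, seed = 4)
  # strong planted signal: observed |U| beats all 19 permutations
  expect_equal(as.numeric(p), 1 / 20)
  expect_gte(as.numeric(p), 1 / (19 + 1))
  expect_lte(as.numeric(p), 1)
  expect_equal(attr(p, "n_valid"), 19L)
})

test_that("permutation p-values are roughly uniform under the null", {
  pools <- test_pools()
  ps <- vapply(1:100, function(s) {
    ds <- simulate_case_control(pools$region1, pools$region2,
                                disease_model(theta = 1), 30, 30,
                                seed = 9000 + s)
    as.numeric(permutation_pvalue(as_case_control_split(ds), "ccu",
                                  B = 25, n_perm = 29, seed = s))
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("pairwise_logistic_minp reduces to one glm when p = q = 1", {
  set.seed(55)
  d <- correlated_dosage_pair(400, 0.3)
  y <- rbinom(400, 1, plogis(-0.5 + 0.3 * d[, 1] * d[, 2]))
  GA <- genotype_matrix(d[, 1, drop = FALSE])
  GB <- genotype_matrix(d[, 2, drop = FALSE],
                        snps = data.frame(id = "y1", region_label = "g2"))
  res <- pairwise_logistic_minp(GA, GB, y)
  fit <- glm(y ~ a + b + a:b, family = binomial(),
             data = data.frame(a = d[, 1], b = d[, 2]))
  expect_equal(res$min_p, summary(fit)$coefficients["a:b", "Pr(>|z|)"])
  expect_equal(nrow(res$pairs), 1L)
})

test_that("pairwise_logistic_minp flags inestimable pairs with p = 1", {
  set.seed(66)
  a <- rep(c(0, 1), 20)
  GA <- genotype_matrix(cbind(x1 = a))
  # second gene identical to the first: the product term a*b = a is aliased
  GB <- genotype_matrix(cbind(y1 = a),
                        snps = data.frame(id = "y1", region_label = "g2"))
  y <- rbinom(40, 1, 0.4 + 0.2 * a)
  expect_message(res <- pairwise_logistic_minp(GA, GB, y), "failed")
  expect_equal(res$min_p, 1)
})
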