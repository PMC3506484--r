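test_that("a single-SNP pool is the trivial two-haplotype pool", {
  p <- build_pool("synthetic", n_snps = 1, maf = 0.3)
  expect_equal(nrow(p$haplotypes), 2L)
  expect_equal(sort(p$haplotypes[, 1]), c(0, 1))
  expect_equal(p$frequencies[p$haplotypes[, 1] == 1], 0.3)
  expect_equal(p$frequencies[p$haplotypes[, 1] == 0], 0.7)
})

test_that("pool files round-trip exactly", {
  pool <- test_pools()$region1
  f <- withr::local_tempfile(fileext = ".txt")
  write_pool(pool, f)
  pool2 <- read_pool(f)
  expect_identical(pool2$haplotypes, pool$haplotypes)
  expect_identical(pool2$frequencies, pool$frequencies)
  expect_identical(pool2$snps$id, pool$snps$id)
  expect_equal(pool2$snps$region_label[1], "region1")
})

test_that("reported pool LD matches brute-force haplotype counting", {
  pool <- build_pool("synthetic", n_snps = 4, maf = 0.25,
                     r2_adjacent = 0.4, n_haplotypes = 10, seed = 6)
  hap <- pool$haplotypes; w <- pool$frequencies
  # brute force: accumulate joint allele frequencies haplotype by haplotype
  for (j in 1:3) {
    f1 <- f2 <- f11 <- 0
    for (h in seq_along(w)) {
      f1 <- f1 + w[h] * hap[h, j]
      f2 <- f2 + w[h] * hap[h, j + 1]
      f11 <- f11 + w[h] * hap[h, j] * hap[h, j + 1]
    }
    r2 <- (f11 - f1 * f2)^2 / (f1 * (1 - f1) * f2 * (1 - f2))
    expect_equal(pool$achieved$adjacent_r2[j], unname(r2))
    expect_equal(pool$snps$minor_allele_freq[j], unname(f1))
  }
  # and the construction met its advertised tolerances
  expect_true(all(abs(pool$snps$minor_allele_freq - 0.25) <= 0.02))
  expect_true(all(abs(pool$achieved$adjacent_r2 - 0.4) <= 0.1))
})

test_that("default pools meet the study-region targets", {
  pools <- test_pools()
  expect_equal(ncol(pools$region1$haplotypes), 6L)
  expect_equal(ncol(pools$region2$haplotypes), 7L)
  expect_true(all(abs(pools$region1$snps$minor_allele_freq -
                        c(0.30, 0.25, 0.35, 0.20, 0.40, 0.30)) <= 0.02))
  expect_true(all(abs(pools$region2$snps$minor_allele_freq -
                        c(0.25, 0.35, 0.30, 0.20, 0.40, 0.30, 0.25)) <= 0.02))
})

test_that("draw_genotypes is deterministic and respects the pool", {
  pool <- test_pools()$region1
  G1 <- draw_genotypes(pool, 200, seed = 8)
  G2 <- draw_genotypes(pool, 200, seed = 8)
  expect_identical(G1$values, G2$values)
  expect_true(all(G1$values %in% 0:2))

  # degenerate pool: only all-zero haplotypes -> all genotypes zero
  f <- withr::local_tempfile()
  writeLines(c("#region=null", "#snps=s1,s2", "00\t0.5", "00\t0.5"), f)
  G0 <- draw_genotypes(read_pool(f), 25, seed = 1)
  expect_true(all(G0$values == 0))
})

test_that("empirical allele frequency converges to the pool frequency", {
  pool <- build_pool("synthetic", n_snps = 1, maf = 0.3)
  G <- draw_genotypes(pool, 50000, seed = 9)
  expect_equal(mean(G$values[, 1]) / 2, 0.3, tolerance = 0.01 / 0.3)
})

test_that("penetrance follows the multiplicative form and f0 rescales", {
  m <- disease_model(f0 = 0.01, r1 = 1.2, r2 = 1.3, theta = 1.4)
  expect_equal(penetrance(m, 0, 0), 0.01)
  expect_equal(penetrance(m, 2, 1), 0.01 * 1.2^2 * 1.3 * 1.4^2)
  expect_equal(penetrance(m, 2, 2), 0.01 * 1.2^2 * 1.3^2 * 1.4^4)
  expect_warning(m2 <- disease_model(f0 = 0.5, r1 = 2, r2 = 2, theta = 1.5),
                 "rescaled")
  expect_lte(penetrance(m2, 2, 2), 1)
})

test_that("simulate_case_control removes the causal columns", {
  pools <- test_pools()
  ds <- simulate_case_control(pools$region1, pools$region2,
                              disease_model(theta = 1.2), 80, 90, seed = 10)
  expect_equal(ncol(ds$cases_A$values), 5L)   # 6 - 1
  expect_equal(ncol(ds$cases_B$values), 6L)   # 7 - 1
  expect_false("region1_snp2" %in% ds$cases_A$snps$id)
  expect_false("region2_snp4" %in% ds$cases_B$snps$id)
  expect_equal(nrow(ds$cases_A$values), 80L)
  expect_equal(nrow(ds$controls_B$values), 90L)
  ds2 <- simulate_case_control(pools$region1, pools$region2,
                               disease_model(theta = 1.2), 80, 90, seed = 10)
  expect_identical(ds$cases_A$values, ds2$cases_A$values)
})

test_that("theta = 1 with unit marginals makes phenotype independent", {
  pools <- test_pools()
  ds <- simulate_case_control(pools$region1, pools$region2,
                              disease_model(f0 = 0.05, r1 = 1, r2 = 1,
                                            theta = 1),
                              4000, 4000, seed = 12)
  # pure null: case and control dosage distributions agree per SNP
  ps <- vapply(seq_len(5), function(j) {
    tab <- rbind(tabulate(ds$cases_A$values[, j] + 1, 3),
                 tabulate(ds$controls_A$values[, j] + 1, 3))
    suppressWarnings(chisq.test(tab)$p.value)
  }, numeric(1))
  expect_gt(min(ps), 0.001)
})

test_that("the generating interaction OR is recovered by logistic regression", {
  pools <- test_pools()
  ds <- simulate_case_control(pools$region1, pools$region2,
                              disease_model(theta = 1.5), 20000, 20000,
                              seed = 13)
  x <- rbind(ds$causal_cases, ds$causal_controls)
  y <- c(rep(1, 20000), rep(0, 20000))
  fit <- glm(y ~ x1 + x2 + x1:x2, family = binomial(),
             data = data.frame(x1 = x[, 1], x2 = x[, 2]))
  est <- coef(summary(fit))["x1:x2", ]
  # generating parameter within 4 SE of its estimate at this sample size
  expect_lt(abs(est["Estimate"] - log(1.5)), 4 * est["Std. Error"])
})

test_that("LD leakage: the SNP most correlated with the causal one shifts", {
  pools <- test_pools()
  ds <- simulate_case_control(pools$region1, pools$region2,
                              disease_model(theta = 1.5), 20000, 20000,
                              seed = 14)
  # region 1 causal is snp2; its strongest LD partner is adjacent
  maf_ca <- colMeans(ds$cases_A$values) / 2
  maf_co <- colMeans(ds$controls_A$values) / 2
  expect_gt(max(maf_ca - maf_co), 0)
})

test_that("subsampling preserves structure and validates sizes", {
  pools <- test_pools()
  ds <- simulate_case_control(pools$region1, pools$region2,
                              disease_model(theta = 1), 500, 500, seed = 15)
  sub <- subsample_dataset(ds, 100, 120, seed = 2)
  expect_equal(nrow(sub$cases_A$values), 100L)
  expect_equal(nrow(sub$controls_A$values), 120L)
  expect_equal(nrow(sub$causal_cases), 100L)
  expect_error(subsample_dataset(ds, 600, 100, seed = 2), "larger than")
  sp <- as_case_control_split(sub)
  expect_s3_class(sp, "case_control_split")
  expect_equal(sum(sp$phenotype), 100L)
})

test_that("written datasets reload through the genotype module", {
  pools <- test_pools()
  ds <- simulate_case_control(pools$region1, pools$region2,
                              disease_model(theta = 1), 40, 40, seed = 16)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_dataset(ds, f)
  map <- rbind(data.frame(id = ds$cases_A$snps$id, gene = "region1"),
               data.frame(id = ds$cases_B$snps$id, gene = "region2"))
  G <- load_genotypes(f, "delimited", region_map = map)
  expect_equal(ncol(G$values), 11L)
  expect_equal(nrow(G$values), 80L)
  expect_equal(unname(G$values[1:40, 1:5]), unname(ds$cases_A$values))
})
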