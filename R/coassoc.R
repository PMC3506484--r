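# The CCU / KCCU co-association statistics.
#
# Both statistics compare the first (kernel) canonical correlation of two
# genes between cases and controls:
#   U = (z_D - z_C) / sqrt(var(z_D) + var(z_C)),  z = atanh(kr),
# with the variances estimated by bootstrap over individuals within each
# stratum. U is approximately standard normal under the null of equal
# co-association.
#
# Implementation note: genotype dosage vectors take few distinct values, so
# every stratum is summarized by its unique (row_A, row_B) classes. A
# bootstrap resample only changes the class counts, and both the classical
# CCA and the regularized KCCA reduce to count-weighted small matrices
# (O(#classes x rank^2) per resample instead of O(m^3)). This is an exact
# low-rank factorization of the centred Gram, not an approximation.

.clip_r <- function(r) min(max(r, 0), 1 - 1e-12)

#' Fisher transformation of a (kernel) canonical correlation
#'
#' `z = (1/2) (log(1 + r) - log(1 - r)) = atanh(r)`, the variance-stabilizing
#' transformation applied to the canonical coefficients before differencing.
#'
#' @param r Correlation in `[0, 1)`. Values within `1e-12` of 1 (or
#'   marginally above 1 from floating point) are clipped to `1 - 1e-12` with
#'   a warning; values materially outside `[0, 1]` are an error.
#' @return The transformed value, strictly increasing in `r`.
#' @examples
#' fisher_z(0.5)  # 0.5 * log(3)
#' @export
fisher_z <- function(r) {
  if (any(r < -1e-8) || any(r > 1 + 1e-8))
    stop("r must lie in [0, 1); got ", paste(format(r), collapse = ", "))
  r <- pmax(r, 0)
  if (any(r >= 1 - 1e-12)) {
    warning("correlation within 1e-12 of 1; clipped to keep z finite")
    r <- pmin(r, 1 - 1e-12)
  }
  atanh(r)
}

# ---- unique-row class machinery ------------------------------------------

.row_index <- function(M) {
  key <- do.call(paste, c(as.data.frame(M), sep = ","))
  first <- !duplicated(key)
  list(index = match(key, key[first]), rows = M[first, , drop = FALSE])
}

# Build the per-stratum statistic machine. XA, XB: plain dosage matrices of
# one stratum. engine: "cca" or "kcca". Returns the original class counts
# and stat(counts) -> list(kr, ok).
.coassoc_machine <- function(XA, XB, engine = c("cca", "kcca"),
                             spec = kernel_spec("rbf")) {
  engine <- match.arg(engine)
  m <- nrow(XA)
  if (nrow(XB) != m) stop("strata matrices have different row counts")
  if (anyNA(XA) || anyNA(XB)) stop("missing genotypes; run qc_filter first")
  ua <- .row_index(XA)
  ub <- .row_index(XB)
  pid <- (ua$index - 1L) * max(ub$index) + ub$index
  cls <- .row_index(matrix(pid, ncol = 1))$index
  n_cls <- max(cls)
  cls_first <- match(seq_len(n_cls), cls)
  class_iA <- ua$index[cls_first]
  class_iB <- ub$index[cls_first]
  counts0 <- tabulate(cls, n_cls)
  if (engine == "cca") {
    LA <- ua$rows
    LB <- ub$rows
    dKA <- rowSums(LA * LA)   # unused by cca eta; kept for symmetry
    dKB <- rowSums(LB * LB)
    eta_fun <- function(counts) 0
  } else {
    KuA <- .kernel_matrix(ua$rows, spec, .observed_maf(XA))
    KuB <- .kernel_matrix(ub$rows, spec, .observed_maf(XB))
    LA <- .lowrank_factor(KuA, 1e-10)
    LB <- .lowrank_factor(KuB, 1e-10)
    dKA <- diag(KuA)
    dKB <- diag(KuB)
    if (is.null(spec$eta)) {
      eta_fun <- function(counts)
        .default_eta(0.5 * (sum(counts * dKA[class_iA]) +
                            sum(counts * dKB[class_iB])) / sum(counts),
                     sum(counts))
    } else {
      eta_fun <- function(counts) spec$eta
    }
  }
  MA <- LA[class_iA, , drop = FALSE]
  MB <- LB[class_iB, , drop = FALSE]
  degen_tol <- 1e-10 * m
  stat <- function(counts) {
    mm <- sum(counts)
    nz <- which(counts > 0L)
    cnz <- counts[nz]
    MAn <- MA[nz, , drop = FALSE]
    MBn <- MB[nz, , drop = FALSE]
    MAc <- MAn * cnz
    sA <- colSums(MAc)
    sB <- colSums(MBn * cnz)
    Axx <- crossprod(MAn, MAc) - tcrossprod(sA) / mm
    Ayy <- crossprod(MBn, MBn * cnz) - tcrossprod(sB) / mm
    if (engine == "cca") {
      # a constant column in the resample makes the replicate degenerate
      if (any(diag(Axx) <= degen_tol) || any(diag(Ayy) <= degen_tol))
        return(list(kr = NA_real_, ok = FALSE))
      Axy <- crossprod(MAc, MBn) - tcrossprod(sA, sB) / mm
      return(list(kr = .kcca_from_factors(Axx, Axy, Ayy, 0)$kr, ok = TRUE))
    }
    if (max(diag(Axx)) <= degen_tol || max(diag(Ayy)) <= degen_tol)
      return(list(kr = NA_real_, ok = FALSE))
    Axy <- crossprod(MAc, MBn) - tcrossprod(sA, sB) / mm
    list(kr = .kcca_top_cor(Axx, Axy, Ayy, eta_fun(counts)), ok = TRUE)
  }
  list(stat = stat, counts0 = counts0, cls = cls, m = m, n_cls = n_cls)
}

# ---- bootstrap -----------------------------------------------------------

#' Bootstrap variance of the Fisher-transformed canonical coefficient
#'
#' Estimates the sampling variance of the Fisher-transformed first (kernel)
#' canonical coefficient by a random split-half resampling scheme: in each
#' of `B` iterations the individuals are randomly partitioned into two
#' complementary halves (rows drawn jointly for the two genes, preserving
#' their cross-gene dependence), the coefficient is recomputed and
#' Fisher-transformed on each half, and `(z1 - z2)^2 / 4` is recorded;
#' `var_z` is the mean of these `B` values. Because the two halves are
#' disjoint they behave as independent samples of size m/2, so under the
#' 1/n variance scaling that holds for this statistic the estimator is
#' unbiased for the full-sample variance, and the upward bias that the
#' naive n-out-of-n bootstrap suffers for extremal statistics (under the
#' null all population canonical correlations are equal, where that
#' bootstrap is inconsistent and roughly doubles the variance) cancels
#' between the two halves, whose selection biases are identical.
#' Iterations in which a SNP column becomes constant in a half (classical
#' CCA) or a Gram matrix collapses (KCCA) are redrawn; more than `10 * B`
#' redraws is an error.
#'
#' @param G_A,G_B [genotype_matrix()] objects (or plain dosage matrices)
#'   over the same individuals of one stratum.
#' @param engine `"cca"` (classical, for CCU) or `"kcca"` (kernel, for
#'   KCCU).
#' @param spec [kernel_spec()] used when `engine = "kcca"`.
#' @param B Number of resampling iterations (>= 2).
#' @param seed Integer seed; results are fully reproducible from it and the
#'   caller's RNG state is left untouched.
#' @return List with `var_z`, `z_hat` (Fisher z on the original data),
#'   `kr_hat`, `z_boot` (the B per-iteration half-sample z differences,
#'   scaled, whose mean square is `var_z`) and `n_redraws`.
#' @export
bootstrap_var_z <- function(G_A, G_B, engine = c("cca", "kcca"),
                            spec = kernel_spec("rbf"), B = 200, seed = 1) {
  engine <- match.arg(engine)
  if (inherits(G_A, "genotype_matrix")) G_A <- G_A$values
  if (inherits(G_B, "genotype_matrix")) G_B <- G_B$values
  if (B < 2) stop("B must be >= 2")
  mach <- .coassoc_machine(G_A, G_B, engine, spec)
  s0 <- mach$stat(mach$counts0)
  if (!s0$ok)
    stop("degenerate stratum (constant column or collapsed kernel); ",
         "run qc_filter first")
  z_hat <- atanh(.clip_r(s0$kr))
  m <- mach$m
  h <- m %/% 2L
  z_boot <- numeric(B)
  n_redraws <- 0L
  .with_seed(seed, {
    b <- 1L
    while (b <= B) {
      perm <- sample.int(m)
      s1 <- mach$stat(tabulate(mach$cls[perm[seq_len(h)]], mach$n_cls))
      s2 <- mach$stat(tabulate(mach$cls[perm[(h + 1L):(2L * h)]],
                               mach$n_cls))
      if (!s1$ok || !s2$ok) {
        n_redraws <- n_redraws + 1L
        if (n_redraws > 10L * B)
          stop("more than 10*B degenerate bootstrap replicates")
        next
      }
      z_boot[b] <- (atanh(.clip_r(s1$kr)) - atanh(.clip_r(s2$kr))) / 2
      b <- b + 1L
    }
  })
  if (n_redraws > 0L)
    message("bootstrap_var_z: redrew ", n_redraws, " degenerate replicate(s)")
  list(var_z = mean(z_boot^2), z_hat = z_hat,
       kr_hat = s0$kr, z_boot = z_boot, n_redraws = n_redraws)
}

# ---- the U statistic -----------------------------------------------------

#' CCU / KCCU gene-gene co-association test
#'
#' Computes the first canonical correlation (CCU) or the maximum kernel
#' canonical coefficient (KCCU) between two genes separately in cases and
#' controls, Fisher-transforms both, estimates their variances by a
#' within-stratum bootstrap, and forms
#' `U = (z_D - z_C) / sqrt(var(z_D) + var(z_C))`, which is approximately
#' standard normal when the co-association of the two genes is the same in
#' the two strata. The reported p-value is the two-sided normal tail.
#'
#' @param split A [split_by_phenotype()] result whose strata passed
#'   [qc_filter()].
#' @param method `"kccu"` (kernel, default RBF) or `"ccu"` (classical CCA).
#' @param spec [kernel_spec()] for `method = "kccu"`.
#' @param B Bootstrap resamples per stratum (default 200).
#' @param seed Master seed. Per-stratum bootstrap seeds are derived from it
#'   and a fingerprint of the stratum's data, so swapping the case and
#'   control strata negates `U` exactly.
#' @return An object of class `coassoc_result` with elements `kr_cases`,
#'   `kr_controls`, `z_cases`, `z_controls`, `var_z_cases`,
#'   `var_z_controls`, `U`, `p_value`, `method`, `n_bootstrap`, `kernel`
#'   and `n_redraws`.
#' @examples
#' pools <- default_pools()
#' ds <- simulate_case_control(pools$region1, pools$region2,
#'                             disease_model(theta = 1), 150, 150, seed = 7)
#' sp <- as_case_control_split(ds)
#' co_association_test(sp, method = "ccu", B = 50, seed = 1)
#' @export
co_association_test <- function(split, method = c("kccu", "ccu"),
                                spec = kernel_spec("rbf"), B = 200,
                                seed = 1) {
  method <- match.arg(method)
  stopifnot(inherits(split, "case_control_split"))
  if (B < 2) stop("B must be >= 2")
  engine <- if (method == "kccu") "kcca" else "cca"
  XA_D <- split$cases_A$values;    XB_D <- split$cases_B$values
  XA_C <- split$controls_A$values; XB_C <- split$controls_B$values
  seed_D <- .mix_seed(seed, .data_key(XA_D) %/% 2L + .data_key(XB_D) %/% 2L)
  seed_C <- .mix_seed(seed, .data_key(XA_C) %/% 2L + .data_key(XB_C) %/% 2L)
  bd <- bootstrap_var_z(XA_D, XB_D, engine, spec, B, seed_D)
  bc <- bootstrap_var_z(XA_C, XB_C, engine, spec, B, seed_C)
  tot_var <- bd$var_z + bc$var_z
  if (tot_var == 0)
    stop("zero total bootstrap variance: U is undefined ",
         "(both strata gave constant canonical coefficients)")
  U <- (bd$z_hat - bc$z_hat) / sqrt(tot_var)
  structure(list(kr_cases = bd$kr_hat, kr_controls = bc$kr_hat,
                 z_cases = bd$z_hat, z_controls = bc$z_hat,
                 var_z_cases = bd$var_z, var_z_controls = bc$var_z,
                 U = U, p_value = 2 * stats::pnorm(-abs(U)),
                 method = method, n_bootstrap = as.integer(B),
                 kernel = if (method == "kccu") spec else NULL,
                 n_redraws = bd$n_redraws + bc$n_redraws,
                 seed = as.integer(seed)),
            class = "coassoc_result")
}

#' @export
print.coassoc_result <- function(x, ...) {
  cat(toupper(x$method), "gene-gene co-association test\n")
  cat(sprintf("  kr (cases)    = %.4f   z = %.4f   var(z) = %.3e\n",
              x$kr_cases, x$z_cases, x$var_z_cases))
  cat(sprintf("  kr (controls) = %.4f   z = %.4f   var(z) = %.3e\n",
              x$kr_controls, x$z_controls, x$var_z_controls))
  cat(sprintf("  U = %.4f, two-sided p = %.4g  (B = %d bootstrap)\n",
              x$U, x$p_value, x$n_bootstrap))
  invisible(x)
}

#' @export
as.data.frame.coassoc_result <- function(x, ...) {
  data.frame(method = x$method,
             kr_cases = x$kr_cases, kr_controls = x$kr_controls,
             U = x$U, p_asymptotic = x$p_value,
             p_permutation = if (is.null(x$p_permutation)) NA_real_
                             else x$p_permutation,
             kernel = if (is.null(x$kernel)) NA_character_
                      else x$kernel$family,
             sigma = if (is.null(x$kernel)) NA_real_ else x$kernel$sigma,
             eta = if (is.null(x$kernel) || is.null(x$kernel$eta)) NA_real_
                   else x$kernel$eta,
             B = x$n_bootstrap,
             n_perm = if (is.null(x$n_perm)) NA_integer_ else x$n_perm,
             seed = x$seed,
             stringsAsFactors = FALSE)
}

#' Write a tabular report of co-association results
#'
#' @param results A `coassoc_result` or a list of them (one per gene pair).
#' @param path Output TSV path.
#' @return The assembled `data.frame`, invisibly.
#' @export
write_coassoc_report <- function(results, path) {
  if (inherits(results, "coassoc_result")) results <- list(results)
  tab <- do.call(rbind, lapply(results, as.data.frame))
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(tab)
}

#' Permutation p-value for the co-association statistic
#'
#' Builds the empirical null of `|U|` by repeatedly permuting the
#' case/control labels (stratum sizes preserved) and recomputing the full
#' statistic (including its bootstrap variances). The add-one estimator
#' `(1 + #permuted >= observed) / (1 + n_perm)` avoids zero p-values.
#'
#' @inheritParams co_association_test
#' @param n_perm Number of label permutations (>= 1).
#' @return The permutation p-value, with attributes `U_obs`, `n_valid`
#'   (permutations that completed) and `n_failed`.
#' @export
permutation_pvalue <- function(split, method = c("kccu", "ccu"),
                               spec = kernel_spec("rbf"), B = 200,
                               n_perm = 1000, seed = 1) {
  method <- match.arg(method)
  if (n_perm < 1) stop("n_perm must be >= 1")
  obs <- co_association_test(split, method, spec, B, seed)
  A_full <- rbind(split$cases_A$values, split$controls_A$values)
  B_full <- rbind(split$cases_B$values, split$controls_B$values)
  n_ca <- nrow(split$cases_A$values)
  m <- nrow(A_full)
  perm_seeds <- .derive_seeds(.mix_seed(seed, 104729L), n_perm)
  u_perm <- rep(NA_real_, n_perm)
  base_phen <- c(rep(1L, n_ca), rep(0L, m - n_ca))
  for (i in seq_len(n_perm)) {
    phen <- .with_seed(perm_seeds[i], sample(base_phen))
    u_perm[i] <- tryCatch({
      ca <- phen == 1L
      sp <- .quick_split(A_full, B_full, ca, split)
      co_association_test(sp, method, spec, B, perm_seeds[i])$U
    }, error = function(e) NA_real_)
  }
  n_failed <- sum(is.na(u_perm))
  if (n_failed > 0)
    message("permutation_pvalue: ", n_failed, " permutation(s) failed and ",
            "were dropped")
  u_perm <- u_perm[!is.na(u_perm)]
  p <- (1 + sum(abs(u_perm) >= abs(obs$U))) / (1 + length(u_perm))
  structure(p, U_obs = obs$U, n_valid = length(u_perm), n_failed = n_failed)
}

# Rebuild a split from stacked matrices without re-validating metadata.
.quick_split <- function(A_full, B_full, case_mask, template) {
  structure(list(
    cases_A = genotype_matrix(A_full[case_mask, , drop = FALSE],
                              snps = template$cases_A$snps),
    cases_B = genotype_matrix(B_full[case_mask, , drop = FALSE],
                              snps = template$cases_B$snps),
    controls_A = genotype_matrix(A_full[!case_mask, , drop = FALSE],
                                 snps = template$cases_A$snps),
    controls_B = genotype_matrix(B_full[!case_mask, , drop = FALSE],
                                 snps = template$cases_B$snps),
    phenotype = as.integer(case_mask)),
    class = "case_control_split")
}

#' Pairwise logistic-regression interaction comparator
#'
#' The SNP-level comparator: for every pair of SNPs (one per gene) fits
#' `logit P(case) = b0 + b1 A + b2 B + g A*B` and records the Wald p-value
#' of the product term `g`; the minimum over pairs and the pair attaining
#' it are returned. Pairs with non-convergence (separation) or an
#' inestimable product term get p = 1 and are logged. Significance of the
#' min-p statistic should be judged against a permutation null (see
#' [permutation_pvalue()] for the analogous machinery).
#'
#' @param G_A,G_B [genotype_matrix()] objects over the same individuals.
#' @param phenotype Binary vector (1 = case / 0 = control).
#' @return List with `min_p`, `best_pair` (character vector of the two SNP
#'   ids) and `pairs` (data.frame of all pairwise interaction p-values).
#' @export
pairwise_logistic_minp <- function(G_A, G_B, phenotype) {
  stopifnot(inherits(G_A, "genotype_matrix"), inherits(G_B, "genotype_matrix"))
  y <- as.integer(phenotype)
  XA <- G_A$values
  XB <- G_B$values
  if (anyNA(XA) || anyNA(XB)) stop("missing genotypes; run qc_filter first")
  if (length(y) != nrow(XA)) stop("phenotype length mismatch")
  out <- expand.grid(snp_A = G_A$snps$id, snp_B = G_B$snps$id,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$p <- NA_real_
  n_bad <- 0L
  for (k in seq_len(nrow(out))) {
    a <- XA[, match(out$snp_A[k], G_A$snps$id)]
    b <- XB[, match(out$snp_B[k], G_B$snps$id)]
    p <- tryCatch({
      fit <- suppressWarnings(stats::glm(y ~ a + b + a:b,
                                         family = stats::binomial()))
      co <- summary(fit)$coefficients
      if (!fit$converged || !("a:b" %in% rownames(co))) NA_real_
      else co["a:b", "Pr(>|z|)"]
    }, error = function(e) NA_real_)
    if (is.na(p)) {
      n_bad <- n_bad + 1L
      p <- 1
    }
    out$p[k] <- p
  }
  if (n_bad > 0)
    message("pairwise_logistic_minp: ", n_bad,
            " pair(s) failed to converge; their p set to 1")
  best <- which.min(out$p)
  list(min_p = out$p[best],
       best_pair = c(out$snp_A[best], out$snp_B[best]),
       pairs = out)
}
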