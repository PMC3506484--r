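# Two-locus case-control genotype simulator.
#
# Genotypes come from weighted haplotype pools (two unlinked regions,
# random mating: each individual is the sum of two independent haplotype
# draws). Disease status follows a two-locus multiplicative penetrance
# model on one causal SNP per region,
#   P(case | x1, x2) = f0 * r1^x1 * r2^x2 * theta^(x1 * x2),
# so theta is the interaction odds-ratio parameter and theta = 1 is the
# null of no interaction (penetrance separates multiplicatively and the two
# regions stay independent in both strata). The causal SNPs are removed
# from the output: what remains detectable is the cross-region dependence
# leaked into SNPs in LD with the causal pair.

#' Construct or load a haplotype pool
#'
#' A haplotype pool is a weighted set of phased haplotypes (minor-allele
#' indicator vectors) for one region, from which diploid genotypes are
#' drawn by random mating. Synthetic pools are built by thresholding a
#' first-order autoregressive Gaussian latent chain (which produces a
#' realistic decaying LD structure), truncating to the `n_haplotypes` most
#' frequent haplotypes, and re-weighting by iterative proportional fitting
#' so that realized minor allele frequencies match the targets. The
#' construction is checked: realized MAFs must be within 0.02 of the
#' targets and adjacent-pair r-squared within 0.1, otherwise it is retried
#' with a fresh latent draw (up to `max_attempts`, then an error reports
#' the best achieved summary).
#'
#' @param mode `"synthetic"` (build from targets) or `"from_file"` (read a
#'   phased-haplotype text file written by [write_pool()]).
#' @param n_snps Number of SNPs in the region (synthetic mode).
#' @param maf Target minor allele frequencies, recycled to `n_snps`; each
#'   in (0, 0.5].
#' @param r2_adjacent Target r-squared between adjacent SNPs, recycled to
#'   `n_snps - 1`.
#' @param n_haplotypes Number of distinct haplotypes retained (>= 2).
#' @param seed Integer seed for the latent draw.
#' @param region_label Gene name attached to the SNP metadata.
#' @param snp_ids Optional SNP identifiers (default `<region>_snp<j>`).
#' @param path File path for `mode = "from_file"`.
#' @param n_latent Size of the latent haplotype sample thresholded before
#'   truncation.
#' @param max_attempts Fresh latent draws attempted before giving up.
#' @return An object of class `haplotype_pool`: `haplotypes` (H x p 0/1
#'   matrix), `frequencies` (length-H weights summing to 1), `snps`
#'   (metadata with realized MAFs) and `achieved` (realized adjacent
#'   r-squared).
#' @export
build_pool <- function(mode = c("synthetic", "from_file"),
                       n_snps = 6, maf = 0.3, r2_adjacent = 0.5,
                       n_haplotypes = 12, seed = 1,
                       region_label = "region1", snp_ids = NULL,
                       path = NULL, n_latent = 40000, max_attempts = 1000) {
  mode <- match.arg(mode)
  if (mode == "from_file") {
    if (is.null(path)) stop("mode = 'from_file' needs a path")
    return(read_pool(path))
  }
  p <- as.integer(n_snps)
  maf <- rep_len(maf, p)
  if (any(maf <= 0 | maf > 0.5)) stop("target MAFs must lie in (0, 0.5]")
  if (is.null(snp_ids)) snp_ids <- paste0(region_label, "_snp", seq_len(p))
  snps <- data.frame(id = snp_ids, region_label = region_label,
                     minor_allele_freq = maf, position = NA_integer_,
                     stringsAsFactors = FALSE)
  if (p == 1) {
    # trivial single-SNP pool: two haplotypes at the allele frequencies
    hap <- matrix(c(0, 1), 2, 1, dimnames = list(NULL, snp_ids))
    return(.new_pool(hap, c(1 - maf, maf), snps, achieved_r2 = numeric(0)))
  }
  r2_adjacent <- rep_len(r2_adjacent, p - 1)
  if (any(r2_adjacent < 0 | r2_adjacent >= 1))
    stop("target adjacent r2 must lie in [0, 1)")
  thr <- stats::qnorm(maf)
  seeds <- .derive_seeds(seed, max_attempts)
  best <- NULL
  best_err <- Inf
  # effective latent targets, recalibrated between attempts to compensate
  # for the LD inflation caused by truncating to the top haplotypes
  target_eff <- sqrt(r2_adjacent)
  for (att in seq_len(max_attempts)) {
    rho <- vapply(seq_len(p - 1), function(j)
      .latent_rho(target_eff[j], maf[j], maf[j + 1]), numeric(1))
    pool <- .with_seed(seeds[att], {
      Z <- matrix(stats::rnorm(n_latent * p), n_latent, p)
      for (j in 2:p)
        Z[, j] <- rho[j - 1] * Z[, j - 1] +
          sqrt(1 - rho[j - 1]^2) * Z[, j]
      H <- (Z < rep(thr, each = n_latent)) * 1L
      .condense_pool(H, n_haplotypes, maf)
    })
    if (is.null(pool)) next
    rmaf <- .pool_maf(pool$hap, pool$w)
    rr2 <- .pool_adjacent_r2(pool$hap, pool$w)
    err <- max(abs(rmaf - maf)) / 0.02 + max(abs(rr2 - r2_adjacent)) / 0.1
    if (err < best_err) {
      best_err <- err
      best <- list(pool = pool, rmaf = rmaf, rr2 = rr2)
    }
    if (all(abs(rmaf - maf) <= 0.02) &&
        all(abs(rr2 - r2_adjacent) <= 0.1)) {
      snps$minor_allele_freq <- rmaf
      colnames(pool$hap) <- snp_ids
      return(.new_pool(pool$hap, pool$w, snps, achieved_r2 = rr2))
    }
    ratio <- sqrt(r2_adjacent) / pmax(sqrt(rr2), 1e-3)
    target_eff <- pmin(0.995, pmax(0.01, target_eff * ratio))
  }
  stop("build_pool: could not meet MAF/r2 targets after ", max_attempts,
       " attempts; best achieved MAFs ",
       paste(round(best$rmaf, 3), collapse = ", "), " and adjacent r2 ",
       paste(round(best$rr2, 3), collapse = ", "))
}

.new_pool <- function(hap, w, snps, achieved_r2) {
  w <- as.numeric(w) / sum(w)
  structure(list(haplotypes = hap, frequencies = w, snps = snps,
                 achieved = list(adjacent_r2 = achieved_r2)),
            class = "haplotype_pool")
}

#' @export
print.haplotype_pool <- function(x, ...) {
  cat("haplotype_pool: ", nrow(x$haplotypes), " haplotypes x ",
      ncol(x$haplotypes), " SNPs (", x$snps$region_label[1], ")\n", sep = "")
  cat("realized MAF: ",
      paste(round(.pool_maf(x$haplotypes, x$frequencies), 3),
            collapse = ", "), "\n", sep = "")
  invisible(x)
}

# Latent AR coefficient giving a target indicator correlation r for
# thresholds at MAFs q1, q2 under a bivariate normal copula.
.latent_rho <- function(target_r, q1, q2) {
  if (target_r <= 0) return(0)
  t1 <- stats::qnorm(q1); t2 <- stats::qnorm(q2)
  bin_r <- function(rho) {
    p11 <- stats::integrate(function(z)
      stats::dnorm(z) * stats::pnorm((t2 - rho * z) / sqrt(1 - rho^2)),
      -Inf, t1, rel.tol = 1e-9)$value
    (p11 - q1 * q2) / sqrt(q1 * (1 - q1) * q2 * (1 - q2))
  }
  hi <- 0.999
  if (bin_r(hi) <= target_r) return(hi)
  stats::uniroot(function(rho) bin_r(rho) - target_r, c(0, hi),
                 tol = 1e-6)$root
}

# Collapse a latent 0/1 haplotype sample to its n_keep most frequent
# haplotypes and rake the weights to the target MAFs. Returns NULL when a
# target allele is uncoverable.
.condense_pool <- function(H, n_keep, maf) {
  key <- do.call(paste0, as.data.frame(H))
  tab <- sort(table(key), decreasing = TRUE)
  n_keep <- min(n_keep, length(tab))
  if (n_keep < 2) return(NULL)
  keep <- names(tab)[seq_len(n_keep)]
  hap <- H[match(keep, key), , drop = FALSE]
  w <- as.numeric(tab[seq_len(n_keep)])
  w <- w / sum(w)
  for (it in seq_len(100)) {
    for (j in seq_len(ncol(hap))) {
      carrier <- hap[, j] == 1
      f <- sum(w[carrier])
      if (f <= 0 || f >= 1) return(NULL)
      w[carrier] <- w[carrier] * maf[j] / f
      w[!carrier] <- w[!carrier] * (1 - maf[j]) / (1 - f)
    }
    w <- w / sum(w)
  }
  list(hap = hap, w = w)
}

.pool_maf <- function(hap, w) as.numeric(crossprod(hap, w))

.pool_adjacent_r2 <- function(hap, w) {
  p <- ncol(hap)
  if (p < 2) return(numeric(0))
  vapply(seq_len(p - 1), function(j) {
    f1 <- sum(w[hap[, j] == 1])
    f2 <- sum(w[hap[, j + 1] == 1])
    p11 <- sum(w[hap[, j] == 1 & hap[, j + 1] == 1])
    d <- p11 - f1 * f2
    denom <- f1 * (1 - f1) * f2 * (1 - f2)
    if (denom <= 0) return(NA_real_)
    d^2 / denom
  }, numeric(1))
}

#' Write / read a haplotype pool as plain text
#'
#' One haplotype per line as a 0/1 string plus a weight column; header
#' comment lines carry the region label and SNP ids. Weights are written at
#' full precision so the round trip is exact.
#'
#' @param pool A `haplotype_pool`.
#' @param path File path.
#' @return `write_pool` returns `path` invisibly; `read_pool` returns the
#'   `haplotype_pool`.
#' @export
write_pool <- function(pool, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#region=", pool$snps$region_label[1]), con)
  writeLines(paste0("#snps=", paste(pool$snps$id, collapse = ",")), con)
  writeLines(paste0(apply(pool$haplotypes, 1, paste, collapse = ""), "\t",
                    sprintf("%.17g", pool$frequencies)), con)
  invisible(path)
}

#' @rdname write_pool
#' @export
read_pool <- function(path) {
  lines <- readLines(path)
  region <- sub("^#region=", "", grep("^#region=", lines, value = TRUE)[1])
  snp_line <- grep("^#snps=", lines, value = TRUE)
  lines <- lines[!startsWith(lines, "#")]
  parts <- strsplit(lines, "\t")
  hap <- do.call(rbind, lapply(parts, function(x)
    as.integer(strsplit(x[1], "")[[1]])))
  w <- vapply(parts, function(x) as.numeric(x[2]), numeric(1))
  ids <- if (length(snp_line))
    strsplit(sub("^#snps=", "", snp_line[1]), ",")[[1]]
  else paste0(region, "_snp", seq_len(ncol(hap)))
  colnames(hap) <- ids
  snps <- data.frame(id = ids, region_label = region,
                     minor_allele_freq = .pool_maf(hap, w / sum(w)),
                     position = NA_integer_, stringsAsFactors = FALSE)
  .new_pool(hap, w, snps, achieved_r2 = .pool_adjacent_r2(hap, w / sum(w)))
}

#' Default study-region haplotype pools
#'
#' Deterministically builds the two unlinked regions used throughout the
#' simulation experiments: region 1 with 6 SNPs and region 2 with 7 SNPs,
#' common minor allele frequencies (0.2-0.4) and moderate-to-strong
#' adjacent LD — the typical profile of small genic regions on a GWAS chip.
#'
#' @param seed Seed of the deterministic construction.
#' @return List with elements `region1` and `region2`.
#' @export
default_pools <- function(seed = 101) {
  s <- .derive_seeds(seed, 2)
  list(
    region1 = build_pool("synthetic", n_snps = 6,
                         maf = c(0.30, 0.25, 0.35, 0.20, 0.40, 0.30),
                         r2_adjacent = c(0.50, 0.50, 0.35, 0.30, 0.50),
                         n_haplotypes = 12, seed = s[1],
                         region_label = "region1"),
    region2 = build_pool("synthetic", n_snps = 7,
                         maf = c(0.25, 0.35, 0.30, 0.20, 0.40, 0.30, 0.25),
                         r2_adjacent = c(0.50, 0.50, 0.45, 0.30, 0.50, 0.50),
                         n_haplotypes = 20, seed = s[2],
                         region_label = "region2"))
}

#' Draw diploid genotypes from a haplotype pool
#'
#' Each individual is the sum of two independent weighted haplotype draws
#' (random mating), so dosages lie in \{0, 1, 2\} and the expected allele
#' frequency equals the pool frequency.
#'
#' @param pool A `haplotype_pool`.
#' @param n Number of individuals.
#' @param seed Integer seed (bit-reproducible).
#' @return A [genotype_matrix()].
#' @export
draw_genotypes <- function(pool, n, seed = 1) {
  stopifnot(inherits(pool, "haplotype_pool"), n >= 1)
  H <- nrow(pool$haplotypes)
  idx <- .with_seed(seed, matrix(sample.int(H, 2 * n, replace = TRUE,
                                            prob = pool$frequencies), n, 2))
  vals <- pool$haplotypes[idx[, 1], , drop = FALSE] +
    pool$haplotypes[idx[, 2], , drop = FALSE]
  genotype_matrix(vals, snps = pool$snps)
}

#' Two-locus multiplicative disease model
#'
#' Penetrance `P(case | x1, x2) = f0 * r1^x1 * r2^x2 * theta^(x1 x2)` on
#' the dosages of one causal SNP per region. `theta` is the interaction
#' odds ratio; `theta = 1` recovers purely multiplicative marginal effects
#' (the null of no interaction). If the maximal penetrance exceeds 1, `f0`
#' is rescaled with a warning.
#'
#' @param f0 Baseline penetrance (genotype 0/0), in (0, 1).
#' @param r1,r2 Per-allele multiplicative effects at the two causal SNPs.
#' @param theta Interaction odds ratio (> 0).
#' @param causal1,causal2 Causal SNP index within region 1 / region 2.
#' @return An object of class `disease_model`.
#' @export
disease_model <- function(f0 = 0.01, r1 = 1.2, r2 = 1.2, theta = 1,
                          causal1 = 2L, causal2 = 4L) {
  if (f0 <= 0 || f0 >= 1) stop("f0 must lie in (0, 1)")
  if (r1 <= 0 || r2 <= 0 || theta <= 0)
    stop("r1, r2 and theta must be positive")
  pen_max <- f0 * r1^2 * r2^2 * theta^4
  if (pen_max > 1) {
    f0 <- f0 / pen_max
    warning("penetrance exceeded 1 at the extreme genotype; f0 rescaled to ",
            signif(f0, 4))
  }
  structure(list(f0 = f0, r1 = r1, r2 = r2, theta = theta,
                 causal1 = as.integer(causal1),
                 causal2 = as.integer(causal2)),
            class = "disease_model")
}

#' @export
print.disease_model <- function(x, ...) {
  cat(sprintf(paste0("disease_model: f0 = %g, r1 = %g, r2 = %g, ",
                     "theta = %g, causal SNPs (%d, %d)\n"),
              x$f0, x$r1, x$r2, x$theta, x$causal1, x$causal2))
  invisible(x)
}

#' Penetrance of a disease model
#'
#' @param model A [disease_model()].
#' @param x1,x2 Dosages (0/1/2) at the two causal SNPs (vectorized).
#' @return Disease probabilities, clipped to at most 1.
#' @export
penetrance <- function(model, x1, x2) {
  pmin(model$f0 * model$r1^x1 * model$r2^x2 * model$theta^(x1 * x2), 1)
}

#' Simulate a case-control dataset under the two-locus model
#'
#' Draws individuals from the two (unlinked) regional haplotype pools,
#' assigns disease status by the penetrance of the two causal dosages
#' (rejection sampling), accumulates until both strata are filled, and then
#' removes the causal columns from the output matrices — gene-gene
#' co-association is assessed on the remaining SNPs only. The causal
#' dosages of the retained individuals are kept separately so that
#' generating-parameter recovery can be checked.
#'
#' @param pool1,pool2 `haplotype_pool` objects for the two regions.
#' @param model A [disease_model()].
#' @param n_cases,n_controls Stratum sizes to accumulate.
#' @param seed Integer seed (bit-reproducible).
#' @param max_draws Safety cap on population draws (default 1e8): if the
#'   penetrance accepts almost no cases the simulation aborts.
#' @param chunk_size Individuals drawn per vectorized chunk.
#' @return An object of class `sim_dataset` with genotype matrices
#'   `cases_A`, `cases_B`, `controls_A`, `controls_B` (causal SNPs
#'   removed), matrices `causal_cases` / `causal_controls` (the two causal
#'   dosage columns, kept for diagnostics), plus `model` and `seed`.
#' @export
simulate_case_control <- function(pool1, pool2, model, n_cases, n_controls,
                                  seed = 1, max_draws = 1e8,
                                  chunk_size = 200000L) {
  stopifnot(inherits(pool1, "haplotype_pool"),
            inherits(pool2, "haplotype_pool"),
            inherits(model, "disease_model"))
  p1 <- ncol(pool1$haplotypes); p2 <- ncol(pool2$haplotypes)
  if (model$causal1 < 1 || model$causal1 > p1)
    stop("causal1 outside region 1")
  if (model$causal2 < 1 || model$causal2 > p2)
    stop("causal2 outside region 2")
  H1 <- pool1$haplotypes; w1 <- pool1$frequencies
  H2 <- pool2$haplotypes; w2 <- pool2$frequencies
  c1 <- model$causal1; c2 <- model$causal2
  ca_idx <- vector("list", 0); co_idx <- vector("list", 0)
  got_ca <- 0L; got_co <- 0L; total <- 0
  .with_seed(seed, {
    while (got_ca < n_cases || got_co < n_controls) {
      nc <- as.integer(chunk_size)
      i1a <- sample.int(nrow(H1), nc, TRUE, prob = w1)
      i1b <- sample.int(nrow(H1), nc, TRUE, prob = w1)
      i2a <- sample.int(nrow(H2), nc, TRUE, prob = w2)
      i2b <- sample.int(nrow(H2), nc, TRUE, prob = w2)
      x1 <- H1[i1a, c1] + H1[i1b, c1]
      x2 <- H2[i2a, c2] + H2[i2b, c2]
      is_case <- stats::runif(nc) < penetrance(model, x1, x2)
      if (got_ca < n_cases && any(is_case)) {
        take <- which(is_case)[seq_len(min(sum(is_case), n_cases - got_ca))]
        ca_idx[[length(ca_idx) + 1L]] <- cbind(i1a, i1b, i2a, i2b)[take, ,
                                                                   drop = FALSE]
        got_ca <- got_ca + length(take)
      }
      if (got_co < n_controls && any(!is_case)) {
        take <- which(!is_case)[seq_len(min(sum(!is_case),
                                            n_controls - got_co))]
        co_idx[[length(co_idx) + 1L]] <- cbind(i1a, i1b, i2a, i2b)[take, ,
                                                                   drop = FALSE]
        got_co <- got_co + length(take)
      }
      total <- total + nc
      if (total > max_draws)
        stop("simulate_case_control: exceeded ", max_draws,
             " draws with only ", got_ca, " cases and ", got_co,
             " controls accumulated; is f0 too small?")
    }
  })
  ca <- do.call(rbind, ca_idx)
  co <- do.call(rbind, co_idx)
  mk <- function(idx, pool, cc) {
    vals <- pool$haplotypes[idx[, 1], , drop = FALSE] +
      pool$haplotypes[idx[, 2], , drop = FALSE]
    list(kept = vals[, -cc, drop = FALSE], causal = vals[, cc])
  }
  ca1 <- mk(ca[, 1:2, drop = FALSE], pool1, c1)
  ca2 <- mk(ca[, 3:4, drop = FALSE], pool2, c2)
  co1 <- mk(co[, 1:2, drop = FALSE], pool1, c1)
  co2 <- mk(co[, 3:4, drop = FALSE], pool2, c2)
  snps1 <- pool1$snps[-c1, , drop = FALSE]
  snps2 <- pool2$snps[-c2, , drop = FALSE]
  structure(list(
    cases_A = genotype_matrix(ca1$kept, snps = snps1),
    cases_B = genotype_matrix(ca2$kept, snps = snps2),
    controls_A = genotype_matrix(co1$kept, snps = snps1),
    controls_B = genotype_matrix(co2$kept, snps = snps2),
    causal_cases = cbind(region1 = ca1$causal, region2 = ca2$causal),
    causal_controls = cbind(region1 = co1$causal, region2 = co2$causal),
    model = model, seed = as.integer(seed)),
    class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("sim_dataset: ", nrow(x$cases_A$values), " cases / ",
      nrow(x$controls_A$values), " controls; region SNPs ",
      ncol(x$cases_A$values), " + ", ncol(x$cases_B$values),
      " (causal removed)\n", sep = "")
  print(x$model)
  invisible(x)
}

#' Subsample a simulated dataset
#'
#' Draws a smaller case-control dataset (without replacement) from a large
#' simulated population — the two-step protocol used by the experiment
#' harness: one large population per parameter setting, one subsample per
#' replicate.
#'
#' @param ds A `sim_dataset`.
#' @param n_cases,n_controls Subsample sizes.
#' @param seed Integer seed.
#' @return A `sim_dataset` of the requested size.
#' @export
subsample_dataset <- function(ds, n_cases, n_controls, seed = 1) {
  stopifnot(inherits(ds, "sim_dataset"))
  N_ca <- nrow(ds$cases_A$values); N_co <- nrow(ds$controls_A$values)
  if (n_cases > N_ca || n_controls > N_co)
    stop("subsample larger than the population")
  idx <- .with_seed(seed, list(ca = sample.int(N_ca, n_cases),
                               co = sample.int(N_co, n_controls)))
  structure(list(
    cases_A = .subset_rows(ds$cases_A, idx$ca),
    cases_B = .subset_rows(ds$cases_B, idx$ca),
    controls_A = .subset_rows(ds$controls_A, idx$co),
    controls_B = .subset_rows(ds$controls_B, idx$co),
    causal_cases = ds$causal_cases[idx$ca, , drop = FALSE],
    causal_controls = ds$causal_controls[idx$co, , drop = FALSE],
    model = ds$model, seed = as.integer(seed)),
    class = "sim_dataset")
}

#' Convert a simulated dataset to a case-control split
#'
#' @param ds A `sim_dataset`.
#' @return A `case_control_split` (phenotype 1 for the case rows, 0 for
#'   controls) ready for [co_association_test()].
#' @export
as_case_control_split <- function(ds) {
  stopifnot(inherits(ds, "sim_dataset"))
  structure(list(cases_A = ds$cases_A, cases_B = ds$cases_B,
                 controls_A = ds$controls_A, controls_B = ds$controls_B,
                 phenotype = c(rep(1L, nrow(ds$cases_A$values)),
                               rep(0L, nrow(ds$controls_A$values)))),
            class = "case_control_split")
}

#' Write a simulated dataset as delimited dosage text
#'
#' Concatenates the two regions' dosage columns and appends the phenotype
#' column; the file re-loads with [load_genotypes()] plus a region map
#' built from the SNP metadata.
#'
#' @param ds A `sim_dataset`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dataset <- function(ds, path) {
  vals <- rbind(cbind(ds$cases_A$values, ds$cases_B$values),
                cbind(ds$controls_A$values, ds$controls_B$values))
  n_ca <- nrow(ds$cases_A$values)
  G <- genotype_matrix(vals, snps = rbind(ds$cases_A$snps, ds$cases_B$snps))
  write_genotypes(G, path,
                  phenotype = c(rep(1L, n_ca), rep(0L, nrow(vals) - n_ca)))
}
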