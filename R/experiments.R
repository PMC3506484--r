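# Config-driven simulation experiments: type-I-error calibration under
# theta = 1, and power sweeps over the interaction odds ratio, the sample
# size and the causal-pair choice. The protocol is two-step: one large
# population is generated per (theta, causal pair) setting, and each
# replicate subsamples n/2 cases and n/2 controls from it. All seeds are
# derived from the master seed by cell and replicate index, so any
# execution order gives identical tables.

#' Build an experiment configuration
#'
#' @param methods Subset of `c("kccu", "ccu")` run on every replicate
#'   (shared data, so the methods are compared on identical samples).
#' @param sample_sizes Total sample sizes `n` (each split n/2 cases, n/2
#'   controls; must be even).
#' @param thetas Interaction odds ratios; 1 is the null.
#' @param n_replicates Simulated datasets per cell.
#' @param alpha Nominal significance level.
#' @param B Bootstrap resamples per stratum inside each test.
#' @param kernel [kernel_spec()] for the KCCU runs.
#' @param causal_pairs List of `c(causal1, causal2)` index pairs.
#' @param master_seed Master seed; everything is reproducible from it.
#' @param population_cases,population_controls Size of the large population
#'   generated once per setting and subsampled per replicate.
#' @param f0,r1,r2 Penetrance parameters of the [disease_model()].
#' @param pool1,pool2 Haplotype pools; `NULL` means [default_pools()].
#' @return An object of class `experiment_config`.
#' @export
experiment_config <- function(methods = c("kccu", "ccu"),
                              sample_sizes = 1000, thetas = 1,
                              n_replicates = 200, alpha = 0.05, B = 100,
                              kernel = kernel_spec("rbf"),
                              causal_pairs = list(c(2L, 4L)),
                              master_seed = 1,
                              population_cases = 100000,
                              population_controls = 100000,
                              f0 = 0.01, r1 = 1.2, r2 = 1.2,
                              pool1 = NULL, pool2 = NULL) {
  methods <- match.arg(methods, c("kccu", "ccu"), several.ok = TRUE)
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  if (alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  if (any(sample_sizes %% 2 != 0)) stop("sample sizes must be even")
  if (is.null(pool1) || is.null(pool2)) {
    pools <- default_pools()
    if (is.null(pool1)) pool1 <- pools$region1
    if (is.null(pool2)) pool2 <- pools$region2
  }
  structure(list(methods = methods, sample_sizes = as.integer(sample_sizes),
                 thetas = thetas, n_replicates = as.integer(n_replicates),
                 alpha = alpha, B = as.integer(B), kernel = kernel,
                 causal_pairs = causal_pairs,
                 master_seed = as.integer(master_seed),
                 population_cases = as.integer(population_cases),
                 population_controls = as.integer(population_controls),
                 f0 = f0, r1 = r1, r2 = r2,
                 pool1 = pool1, pool2 = pool2),
            class = "experiment_config")
}

# Shared cell runner. thetas_run selects which theta values to execute.
.run_cells <- function(config, thetas_run) {
  t0 <- proc.time()[["elapsed"]]
  rows <- list()
  u_store <- list()
  for (pi in seq_along(config$causal_pairs)) {
    pair <- config$causal_pairs[[pi]]
    for (ti in seq_along(thetas_run)) {
      theta <- thetas_run[ti]
      model <- disease_model(f0 = config$f0, r1 = config$r1, r2 = config$r2,
                             theta = theta, causal1 = pair[1],
                             causal2 = pair[2])
      pop_seed <- .mix_seed(config$master_seed,
                            1009L * pi + 31L * round(1000 * theta))
      pop <- simulate_case_control(config$pool1, config$pool2, model,
                                   config$population_cases,
                                   config$population_controls,
                                   seed = pop_seed)
      for (n in config$sample_sizes) {
        res <- .run_one_cell(config, pop, n, theta, pair, pi)
        rows <- c(rows, res$rows)
        u_store <- c(u_store, res$u)
      }
    }
  }
  table <- do.call(rbind, rows)
  rownames(table) <- NULL
  structure(list(table = table, U_values = u_store, config = config,
                 runtime_sec = proc.time()[["elapsed"]] - t0),
            class = "experiment_result")
}

.run_one_cell <- function(config, pop, n, theta, pair, pi) {
  R <- config$n_replicates
  pvals <- matrix(NA_real_, R, length(config$methods),
                  dimnames = list(NULL, config$methods))
  uvals <- pvals
  for (rep_i in seq_len(R)) {
    sub_seed <- .mix_seed(config$master_seed,
                          7919L * pi + 131L * round(1000 * theta) +
                            17L * n + rep_i)
    ds <- subsample_dataset(pop, n %/% 2L, n %/% 2L, seed = sub_seed)
    sp <- as_case_control_split(ds)
    for (meth in config$methods) {
      fit <- tryCatch(
        suppressMessages(co_association_test(sp, method = meth,
                                             spec = config$kernel,
                                             B = config$B,
                                             seed = sub_seed)),
        error = function(e) NULL)
      if (!is.null(fit)) {
        pvals[rep_i, meth] <- fit$p_value
        uvals[rep_i, meth] <- fit$U
      }
    }
  }
  rows <- list()
  u <- list()
  for (meth in config$methods) {
    ok <- !is.na(pvals[, meth])
    n_ok <- sum(ok)
    rate <- mean(pvals[ok, meth] < config$alpha)
    norm_p <- if (abs(theta - 1) < 1e-12 && n_ok >= 10)
      suppressWarnings(stats::ks.test(uvals[ok, meth], "pnorm")$p.value)
    else NA_real_
    rows[[meth]] <- data.frame(
      method = meth, n = n, theta = theta,
      causal1 = pair[1], causal2 = pair[2],
      replicates = n_ok, dropped = R - n_ok,
      rejection_rate = rate,
      se = sqrt(rate * (1 - rate) / n_ok),
      normality_p = norm_p,
      valid = (R - n_ok) <= 0.05 * R,
      stringsAsFactors = FALSE)
    u[[paste(meth, n, theta, pair[1], pair[2], sep = "_")]] <-
      uvals[ok, meth]
  }
  list(rows = rows, u = u)
}

#' Type-I-error calibration experiment
#'
#' Runs the null cells (`theta = 1`) of a configuration: per method and
#' sample size, `n_replicates` datasets are simulated under no interaction,
#' the test is applied, and the rejection rate at `alpha` plus a
#' Kolmogorov-Smirnov normality p-value of the observed U sample are
#' recorded. Cells with more than 5% dropped replicates are flagged
#' invalid.
#'
#' @param config An [experiment_config()] whose `thetas` include 1.
#' @return An `experiment_result`: `table` (one row per method x size),
#'   `U_values` (named list of U samples), `config`, `runtime_sec`.
#' @export
run_calibration <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  if (!any(abs(config$thetas - 1) < 1e-12))
    stop("run_calibration needs theta = 1 in the configuration")
  .run_cells(config, thetas_run = 1)
}

#' Power experiment over interaction odds ratios, sizes and causal pairs
#'
#' Runs every `(method, n, theta, causal pair)` cell of the configuration
#' and records rejection rates with binomial standard errors. A `theta = 1`
#' cell inside a power sweep estimates the attained level.
#'
#' @param config An [experiment_config()].
#' @return An `experiment_result` (see [run_calibration()]).
#' @export
run_power <- function(config) {
  stopifnot(inherits(config, "experiment_config"))
  .run_cells(config, thetas_run = config$thetas)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("experiment_result (", nrow(x$table), " cells, ",
      round(x$runtime_sec, 1), " s)\n", sep = "")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Render an experiment result to report files
#'
#' Writes `results.tsv` (all cells), a `calibration.tsv` analogue of a
#' null-hypothesis performance table when null cells are present (sample
#' size rows; per-method type I error and normality p), vector-graphic
#' power plots (power vs theta, power vs n, power by causal pair) when the
#' corresponding sweeps exist, and a `manifest.txt` with the configuration
#' and versions. Tables are written deterministically: re-rendering the
#' same result reproduces them byte for byte.
#'
#' @param result An `experiment_result`.
#' @param dir Output directory (created if needed).
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(result, dir) {
  stopifnot(inherits(result, "experiment_result"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tab <- result$table
  written <- character(0)
  f <- file.path(dir, "results.tsv")
  utils::write.table(tab, f, sep = "\t", quote = FALSE, row.names = FALSE)
  written <- c(written, f)
  null_tab <- tab[abs(tab$theta - 1) < 1e-12, , drop = FALSE]
  if (nrow(null_tab) > 0) {
    wide <- NULL
    for (n in sort(unique(null_tab$n))) {
      row <- data.frame(n = n)
      for (meth in unique(null_tab$method)) {
        sel <- null_tab$n == n & null_tab$method == meth
        if (any(sel)) {
          row[[paste0(meth, "_type1")]] <- null_tab$rejection_rate[sel][1]
          row[[paste0(meth, "_normality_p")]] <- null_tab$normality_p[sel][1]
        }
      }
      wide <- if (is.null(wide)) row else merge(wide, row, all = TRUE)
    }
    f <- file.path(dir, "calibration.tsv")
    utils::write.table(wide, f, sep = "\t", quote = FALSE, row.names = FALSE)
    written <- c(written, f)
  }
  pow <- tab[tab$theta > 1 | length(unique(tab$theta)) > 1, , drop = FALSE]
  if (nrow(pow) > 0 && length(unique(tab$theta)) > 1) {
    f <- file.path(dir, "power_vs_theta.pdf")
    .plot_power(tab, xvar = "theta", f)
    written <- c(written, f)
  }
  if (nrow(pow) > 0 && length(unique(tab$n)) > 1) {
    f <- file.path(dir, "power_vs_n.pdf")
    .plot_power(tab, xvar = "n", f)
    written <- c(written, f)
  }
  pairs_id <- paste(tab$causal1, tab$causal2)
  if (length(unique(pairs_id)) > 1) {
    f <- file.path(dir, "power_by_pair.pdf")
    .plot_pairs(tab, f)
    written <- c(written, f)
  }
  f <- file.path(dir, "manifest.txt")
  cfg <- result$config
  lines <- c("kccu experiment manifest",
             paste0("package_version=", as.character(utils::packageVersion("kccu"))),
             paste0("r_version=", R.version.string),
             paste0("master_seed=", cfg$master_seed),
             paste0("methods=", paste(cfg$methods, collapse = ",")),
             paste0("sample_sizes=", paste(cfg$sample_sizes, collapse = ",")),
             paste0("thetas=", paste(cfg$thetas, collapse = ",")),
             paste0("n_replicates=", cfg$n_replicates),
             paste0("alpha=", cfg$alpha),
             paste0("B=", cfg$B),
             paste0("kernel=", cfg$kernel$family, " sigma=", cfg$kernel$sigma,
                    " eta=", if (is.null(cfg$kernel$eta)) "auto"
                             else cfg$kernel$eta),
             paste0("causal_pairs=",
                    paste(vapply(cfg$causal_pairs, paste, "", collapse = ":"),
                          collapse = ";")),
             paste0("population=", cfg$population_cases, "/",
                    cfg$population_controls),
             paste0("penetrance f0=", cfg$f0, " r1=", cfg$r1, " r2=", cfg$r2),
             "protocol=one population per (theta, causal pair); replicates subsample it")
  writeLines(lines, f)
  written <- c(written, f)
  invisible(written)
}

.plot_power <- function(tab, xvar, path) {
  grDevices::pdf(path, width = 6, height = 5)
  on.exit(grDevices::dev.off())
  other <- if (xvar == "theta") "n" else "theta"
  methods <- unique(tab$method)
  cols <- c(kccu = "firebrick", ccu = "steelblue")
  for (ov in sort(unique(tab[[other]]))) {
    sub <- tab[tab[[other]] == ov, , drop = FALSE]
    if (length(unique(sub[[xvar]])) < 2) next
    plot(range(sub[[xvar]]), c(0, 1), type = "n", xlab = xvar,
         ylab = "rejection rate",
         main = paste0("Power vs ", xvar, " (", other, " = ", ov, ")"))
    for (meth in methods) {
      s2 <- sub[sub$method == meth, , drop = FALSE]
      s2 <- s2[order(s2[[xvar]]), , drop = FALSE]
      lines(s2[[xvar]], s2$rejection_rate, type = "b", pch = 19,
            col = cols[[meth]])
    }
    legend("topleft", legend = methods, col = cols[methods], lty = 1,
           pch = 19, bty = "n")
  }
}

.plot_pairs <- function(tab, path) {
  grDevices::pdf(path, width = 6, height = 5)
  on.exit(grDevices::dev.off())
  tab$pair <- paste0("(", tab$causal1, ",", tab$causal2, ")")
  methods <- unique(tab$method)
  cols <- c(kccu = "firebrick", ccu = "steelblue")
  pairs <- unique(tab$pair)
  plot(c(1, length(pairs)), c(0, 1), type = "n", xaxt = "n",
       xlab = "causal SNP pair", ylab = "rejection rate",
       main = "Power by causal pair")
  axis(1, at = seq_along(pairs), labels = pairs)
  for (meth in methods) {
    s2 <- tab[tab$method == meth, , drop = FALSE]
    rates <- vapply(pairs, function(pp)
      mean(s2$rejection_rate[s2$pair == pp]), numeric(1))
    lines(seq_along(pairs), rates, type = "b", pch = 19, col = cols[[meth]])
  }
  legend("topleft", legend = methods, col = cols[methods], lty = 1,
         pch = 19, bty = "n")
}
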