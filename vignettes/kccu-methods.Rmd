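---
title: "Gene-gene co-association testing with kccu: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-gene co-association testing with kccu}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the statistic

Single-SNP interaction scans are underpowered and hard to interpret when
the functional unit is a gene. `kccu` works at the gene level: given two
SNP sets $X = (X_1, \dots, X_p)$ and $Y = (Y_1, \dots, Y_q)$ coded as
minor-allele dosages (0/1/2) and a binary phenotype, it asks whether the
*joint correlation structure* of the two genes differs between cases and
controls. Unlike the product-term logistic model, this notion of
*co-association* does not assume the two genes are independent in the
population; for unlinked genes a case-control difference in cross-gene
correlation is exactly what statistical interaction leaves behind.

The linear version (CCU) measures co-association in each stratum by the
first canonical correlation: the maximum of
$\mathrm{corr}(X\nu, Y\omega)$ over weight vectors, subject to
$\nu^T X^T X \nu = \omega^T Y^T Y \omega = 1$ on column-centred data. The
kernel version (KCCU) replaces the linear combinations by elements of
kernel-induced feature spaces: with centred Gram matrices $K_x$ and
$K_y$, it maximizes $\alpha^T K_x K_y \beta$ subject to normalization
constraints on $\alpha, \beta$, picking up nonlinear dependence that CCA
misses.

Writing $\kappa r_D$ and $\kappa r_C$ for the (kernel) canonical
coefficient in cases and controls, both are Fisher-transformed,
$\kappa z = \tfrac12 \log\frac{1 + \kappa r}{1 - \kappa r}$, and combined
into

$$U = \frac{\kappa z_D - \kappa z_C}
          {\sqrt{\widehat{\mathrm{var}}(\kappa z_D) +
                 \widehat{\mathrm{var}}(\kappa z_C)}},$$

which is approximately standard normal when co-association is the same in
the two strata. The reported p-value is the two-sided normal tail; a
permutation p-value (case/control labels shuffled, stratum sizes
preserved, add-one estimator) is available when the normal approximation
is in doubt.

Two-sidedness is a deliberate choice: co-association can be stronger in
either stratum, and the null distribution is symmetric, so nothing is
gained by fixing a direction.

## Regularized KCCA

For invertible Gram matrices, unregularized KCCA is vacuous: any
$\alpha$ can be matched by some $\beta$ and the optimum is identically 1.
`kccu` therefore solves the quadratically penalized problem — maximize
$\alpha^T K_x K_y \beta$ subject to
$\alpha^T (K_x + \eta I)^2 \alpha = \beta^T (K_y + \eta I)^2 \beta = 1$ —
whose solution is the largest singular value of
$\mathrm{diag}\!\big(\tfrac{\lambda^x_i}{\lambda^x_i + \eta}\big)
U_x^T U_y\,
\mathrm{diag}\!\big(\tfrac{\lambda^y_j}{\lambda^y_j + \eta}\big)$
in the eigenbases of the two centred Grams. Two consequences worth
knowing:

* as $\eta \to 0$ with a linear kernel, the solution converges to the
  classical first canonical correlation (this is a test oracle in the
  package);
* for $\eta > 0$ the coefficient is shrunk — even identical kernels give
  $\kappa r < 1$. The statistic compares two equally-shrunk strata, so
  shrinkage cancels to first order.

The default $\eta = 0.1\, m \cdot \overline{\mathrm{diag}(K)}$ (with $m$
the stratum size and the diagonal mean taken on the uncentred kernel;
for the RBF kernel this is simply $0.1\,m$) scales with the Gram spectrum
so that the effective amount of shrinkage is sample-size free. It is
exposed as `eta` in `kernel_spec()`. No data-driven tuning is attempted:
kernel parameters are user-supplied, and the practical recommendation
follows the bandwidth sweep idea — run a few `sigma` values and inspect
stability rather than optimizing one.

The default kernel is the RBF, $k(u, v) = \exp(-\sigma \|u - v\|^2)$,
with $\sigma = 0.5$; $\sigma$ is the plain multiplier, so sweeps such as
$\sigma \in \{0.05, 0.5, 5, 50\}$ map directly. Polynomial, sigmoid,
linear, IBS and a $1/\sqrt{\mathrm{MAF}}$-weighted IBS kernel are also
provided; the weighted-IBS weighting is this package's choice of a
standard variance-stabilizing weight.

### Exact low-rank computation

Genotype dosage vectors over a handful of SNPs take few distinct values,
so each stratum is summarized by its unique (row$_A$, row$_B$) classes.
The centred Gram admits the exact factorization
$H K H = (HS L)(HS L)^T$, with $S$ the class-membership indicator and
$L$ a pivoted-Cholesky factor of the kernel on unique rows; every
resampling iteration then only changes class counts and costs
$O(\text{classes} \times \text{rank}^2)$ instead of $O(m^3)$. The public
`kcca_max_correlation()` additionally offers a dense $m \times m$ eigen
path and a generic pivoted-Cholesky low-rank path (rank tolerance
`1e-6`); the two agree to $10^{-6}$ on moderate fixtures, which the test
suite checks. In the hot loop only the top singular value is needed, so
the larger side of the reduced problem is handled by one Cholesky solve
rather than a full eigendecomposition.

Numerical conventions: whitening uses a pseudo-inverse with a relative
singular-value cutoff of $10^{-10}$ (SNPs in perfect LD do not crash the
solver, the maximal correlation on the attained subspace is returned);
canonical coefficients are clipped to $[0, 1]$ and to $1 - 10^{-12}$
before the Fisher transform so $z$ stays finite; CCA vector signs are
fixed (first nonzero left weight positive) for deterministic output; if
the top two eigenvalues tie to $10^{-10}$ the solver-order first is
taken — the statistic only consumes the value.

## Variance estimation: why split halves

No closed form is available for $\mathrm{var}(\kappa z)$, so it is
estimated by resampling. The obvious n-out-of-n bootstrap is, however,
the wrong tool here: under the null the population canonical
correlations are all equal (zero), which is precisely the degenerate
configuration where the bootstrap of an extremal eigenvalue-type
statistic is inconsistent. Measured on this package's own null
simulations it overestimates $\mathrm{var}(\kappa z)$ by roughly a
factor of two — re-maximization over directions in every resample adds
variability the point estimate does not have — which deflates $|U|$,
makes the test badly conservative and destroys power.

`bootstrap_var_z()` therefore uses random complementary split-halves: in
each of $B$ iterations the stratum is randomly partitioned into two
disjoint halves (individuals drawn jointly for both genes), the
statistic is recomputed on each half, and
$\widehat{\mathrm{var}} = \mathrm{mean}\big[(z_1 - z_2)^2 / 4\big]$.
The two halves are disjoint, hence behave as independent samples of size
$m/2$; since $\mathrm{var}(z) \propto 1/n$ for this statistic (checked
empirically over a fourfold size range in the package's diagnostics),
$(z_1 - z_2)^2/4$ is unbiased for the full-sample variance, and the
extremal selection bias — identical in the two halves — cancels in the
difference. Degenerate iterations (a SNP constant in a half, or a
collapsed Gram) are redrawn, with a hard cap of $10B$ redraws.

Each stratum's resampling seed is derived from the master seed *and a
fingerprint of the stratum's data*, so seeds travel with the data:
swapping the case and control strata negates $U$ bit-exactly, and any
run is replayable from its master seed.

## The simulator

The generator mirrors a standard two-locus design:

* **Haplotype pools.** Each region is a weighted pool of phased
  haplotypes. Synthetic pools are built by thresholding a first-order
  autoregressive Gaussian latent chain at the target minor allele
  frequencies, keeping the most frequent haplotypes, and re-weighting by
  iterative proportional fitting so realized MAFs match the targets
  (within 0.02; adjacent-pair $r^2$ within 0.1, with the latent
  correlations recalibrated between attempts because truncation inflates
  LD). Note the feasibility bound
  $r^2_{\max} = \frac{q_1(1 - q_2)}{q_2(1 - q_1)}$ for MAFs
  $q_1 < q_2$: targets above it are unattainable and the builder reports
  the best achieved summary. Real phased haplotypes can be supplied as
  plain text instead (`read_pool()`).
* **Default regions.** Two unlinked regions of 6 and 7 SNPs with common
  MAFs (0.20-0.40) and moderate-to-strong adjacent LD
  ($r^2$ 0.30-0.50) — the profile of small genic regions on a GWAS
  chip. Region 1 keeps 12 haplotypes; region 2 keeps 20 (seven SNPs need
  more haplotype diversity, otherwise truncation pins the LD at its
  feasibility bound).
* **Disease model.** Penetrance
  $f_0\, r_1^{x_1} r_2^{x_2}\, \theta^{x_1 x_2}$ on one causal SNP per
  region ($x_i$ the causal dosages), clipped at 1 with $f_0$ rescaled if
  necessary. $\theta$ is the interaction odds ratio; $\theta = 1$ is the
  null, under which penetrance separates multiplicatively and the two
  regions remain independent in both strata. Defaults
  $f_0 = 0.01$, $r_1 = r_2 = 1.2$; causal SNPs are the 2nd of region 1
  and (by this package's choice, the central SNP) the 4th of region 2,
  both configurable. Case/control status is rejection-sampled, and the
  causal columns are then *removed*: the detectable signal is the
  cross-region dependence leaked into SNPs in LD with the causal pair.
* **Two-step protocol.** One large population (default 100k cases /
  100k controls) is generated per parameter setting; each experiment
  replicate subsamples $n/2$ cases and $n/2$ controls from it. The run
  manifest records this. Whether the original design regenerated
  populations per replicate is not determinable from the study
  description; one fixed population per cell is the cheaper reading and
  is what the harness does.

What the generator does *not* emulate: real block-wise LD (the latent
chain is first-order, so LD decays geometrically and carries no
recombination hotspots), rare variants, genotyping error, missingness,
or population structure. Passing calibration and power checks on these
pools therefore says nothing about robustness to stratification or to
low-MAF SNPs.

## Experiment harness and problem sizes

`run_calibration()` and `run_power()` execute (method, $n$, $\theta$,
causal pair) cells with all seeds derived from a master seed by cell and
replicate index, so results are independent of execution order and
reproducible bit-for-bit. Replicate-level failures are dropped and
counted; a cell with more than 5% drops is flagged invalid.
`render_report()` writes a calibration table, power plots against
$\theta$, $n$ and causal pair, and a manifest.

The package's own experiment profile uses 200 replicates with $B = 100$
for calibration and method comparison, and 60 replicates per cell for
monotonicity sweeps (their acceptance bands scale with the binomial
standard error, so fewer replicates simply mean wider bands); the
acceptance script runs 200/200/150 replicates at $n$ = 1000/3000/5000.
These sizes were chosen so a full desk run completes in minutes per cell
on one core while keeping binomial standard errors below about 0.016 for
the calibrated cells. The full historical profile (500 replicates, five
sample sizes) is a configuration switch away.

## Known limitations

* The normal approximation for $U$ is asymptotic; at stratum sizes below
  a few hundred, or with `eta` far from its default scale, prefer
  `permutation_pvalue()`.
* When the two strata differ in marginal genotype distributions (as they
  do under marginal causal effects even at $\theta = 1$), the
  finite-sample bias of the canonical coefficient need not cancel
  exactly between strata; the residual shows up as a small mean shift of
  $U$, well inside the calibration bands at the sizes tested here.
* The logistic min-p comparator fits every SNP pair without covariates
  and leaves multiple-testing control to its permutation null; it is a
  baseline, not a production interaction scan.
* Gene pairs are tested one at a time; there is no genome-wide pair
  scheduler.
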