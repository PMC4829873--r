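---
title: "Trait-associated gene detection: models and methods"
author: "tagseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trait-associated gene detection: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its orientation

`tagseq` tests, gene by gene, the linear association between a continuous
phenotype and normalized expression:

$$\mathrm{Trait}_i = \beta_0 + \beta_1\,x_{gi} +
  \textstyle\sum_p \gamma_p\,z_{pi} + \varepsilon_i,$$

with $x_{gi}$ the log2 TMM-normalized counts-per-million of gene $g$ in
sample $i$ and $z_{pi}$ optional covariates (sex, age, parity, ...). The
trait is deliberately the *response*: phenotypes like body-mass index or
milk yield are outcomes of gene activity, and putting them on the left
side lets ordinary normal-theory inference apply — the normality
assumption then concerns the trait residuals, not the counts. The scan API
does not offer the reversed orientation. A gene is a trait-associated gene
(TAG) when the two-sided t test of $H_0:\beta_1 = 0$ rejects.

Assumptions, and where they are checked:

* residual normality — screened genome-wide by `shapiroScreen()`
  (Shapiro–Wilk per gene on the OLS residuals, BH-adjusted; valid for
  $3 \le n \le 5000$);
* linearity on the log2-CPM scale — the working scale throughout; the
  synthetic generator builds traits on exactly this scale so recovery is
  assertable;
* independent samples — not checked; cohorts with family or batch
  structure need those covariates in the model.

## Normalization

Between-sample scaling uses the trimmed mean of M-values. For sample $k$
against a reference $r$ (the sample whose upper-quartile CPM is closest to
the cross-sample mean; ties go to the lowest index so the choice is
deterministic), genes expressed in both contribute
$M_g = \log_2\frac{y_{gk}/N_k}{y_{gr}/N_r}$ and
$A_g = \tfrac12\log_2\frac{y_{gk}}{N_k}\frac{y_{gr}}{N_r}$. The extreme
30% of $M$ (each tail) and 5% of $A$ are discarded — the canonical trim
fractions, exposed as `trimM`/`trimA` — and the surviving $M_g$ are
averaged with inverse-asymptotic-variance weights
$w_g = \left[\frac{N_k-y_{gk}}{N_k y_{gk}} +
\frac{N_r-y_{gr}}{N_r y_{gr}}\right]^{-1}$; the factor is $2$ to that
average, and factors are rescaled to geometric mean 1. Genes with a zero
count in either member of a pair are excluded per comparison, not
globally, which keeps factors defined on sparse matrices. A unit test
pins this down against an independently coded oracle at 1e-10 and against
`edgeR::calcNormFactors` at 1e-8.

Expression values are
$\log_2\!\big(\frac{y_{gk}+c}{N_k f_k + 2c}\cdot 10^6\big)$ with prior
count $c = 0.5$ (finite at zero counts) and $f_k$ the TMM factor. No
low-expression filter is applied by default — scans run on the whole gene
set, matching the genome-wide screening stance — but `log2CPM(minCPM=)`
provides an optional mean-CPM floor. The transform and the prior are
design choices: nothing forces $c = 0.5$, but it is standard practice and
any positive value preserves monotonicity and finiteness.

## Robust fitting and Wald-type inference

The OLS scan is efficient when residuals are clean; a single grossly
displaced trait value can, however, dominate the squared-error fit.
`fitHuberIRWLS()` fits the same model with Huber's M-estimator:

1. start at the OLS coefficients;
2. estimate the residual scale by the normal-consistent MAD,
   $\hat\sigma = \mathrm{median}|r - \mathrm{median}(r)|\,/\,0.6745$,
   re-estimated at every iteration;
3. weight each sample $w_i = 1$ if $|r_i| \le k\hat\sigma$, else
   $k\hat\sigma/|r_i|$, with $k = 1.345$ (about 95% Gaussian efficiency);
4. refit by weighted least squares; stop when every coefficient moves by
   less than $10^{-8}\max(1, |\beta_j|)$, or flag non-convergence after
   100 iterations (recorded, not an error — a scan never aborts on one
   gene).

Inference is Wald-type: the slope variance is
$\hat\sigma^2\,\frac{\sum\psi(r_i/\hat\sigma)^2}{n-p}\,
\Big/\Big(\tfrac1n\sum\psi'(r_i/\hat\sigma)\Big)^2$ times the design's
inverse Gram element, with $\psi$ the identity clipped at $\pm k$, and the
statistic is referred to $t_{n-p}$. The residual degrees of freedom in
robust regression are genuinely debatable; $n-p$ is the conservative
conventional choice for small cohorts, and when no standardized residual
exceeds $k$ the whole construction collapses *exactly* to the OLS t test
(asserted in tests, and the `k = 10^6` scan reproduces the OLS table to
1e-6). At $n \approx 30$ the test runs slightly anti-conservative
(empirical size ~0.06 at nominal 0.05 in the null simulations); by
$n \approx 89$ the p-values are indistinguishable from uniform.

Degenerate fits are handled explicitly: zero residual variance with a
nonzero slope (a perfect line) gives $p = 0$; with a zero slope (constant
response) the p-value is NA and the gene is flagged; a zero MAD (more than
half the residuals identical) flags the gene in scans and errors in the
single-gene API.

## Genome-wide scans

`tagScan()` fits every gene through a compiled (RcppArmadillo) engine —
the per-gene R fits remain the reference implementation and the two routes
are asserted equal in tests — and returns a table ordered by p-value with
the original gene order recoverable. Two significance rules are supported
because practice needs both: BH-adjusted FDR < $\alpha$ for well-powered
cohorts, and raw $p < \alpha$ for small cohorts where FDR control leaves
nothing. The BH step-up is the classic
$q_{(i)} = \min_{j\ge i}\min(1, p_{(j)} m/j)$ with missing values passed
through and excluded from $m$. (Note BH adjustment is *not* idempotent —
re-adjusting adjusted values can only raise them; the tests assert the
properties that do hold: monotone, never decreasing, capped at 1.)

`compareScans()` tabulates intersection patterns of significant sets
across methods over an identical gene universe, at raw $p < \alpha$ — the
common yardstick when external two-group methods enter via the plug-in
contract (any named per-gene p-value vector, or a two-column
`gene_id`/`pvalue` file on the command line). With roles assigned
(existing / suggesting / robust) it also labels genes AM, EM, SM or RM
(significant in all methods / only existing / only the regression methods /
only robust).

## The mock comparison

To estimate how many detections would survive chance alone,
`mockComparison()` permutes the trait (jointly with any derived group
label; covariates stay with their samples), reruns the full pipeline —
normalization included — on the permuted copy, and reports

$$\mathrm{PFD} = \frac{|\text{significant in real} \cap
\text{significant in mock}|}{|\text{significant in real}|}$$

per repeat, sweeping the number of biological replicates: at each grid
value $m$ it draws $m$ samples per group without replacement (or $2m$
unstratified when the trait is continuous and no group exists — the grid
stays comparable with two-group tools), over `nRepeats` repeats.
Significance inside the comparison is raw $p < 0.05$ by default
(`useFdr = TRUE` switches to BH). Repeats with an empty real set
contribute NA and are excluded from the mean; a repeat-failure rate above
10% aborts with a summary. Every repeat's subsample and permutation seeds
are derived deterministically from the base seed (repeat and grid indices
mixed in, kept below $2^{31}$), so grid points are independent experiments
and the entire sweep is bit-reproducible. Permutation happens *within* the
subsample: the subsample defines the experiment whose null is being
emulated.

Under a true null both the real and the mock scan are null, so the PFD
estimates the test's size; the acceptance run (2,000 genes × 89 samples,
no planted signal, 200 repeats, grid {10, 20, 37} per group) checks that
the OLS and robust scans' mean PFD at the largest replicate count sits at
the nominal 0.05.

## The synthetic generator

`synthConfig()` describes what the generator emulates: a bulk RNA-seq
cohort with gene base means drawn log-normally (default
$\ln\mu \sim N(\ln 100, 1.5^2)$ on the CPM scale — a realistic dynamic
range for a few-thousand-gene panel), library sizes uniform on 1–3 million,
and counts negative-binomial with variance $\mu + \phi\mu^2$ — the
dispersion convention is stated because two parameterizations circulate.
The default $\phi = 0.1$ (BCV ≈ 0.32) is typical of human bulk cohorts.
The default shape, 2,000 genes × 89 samples, mirrors a human-cohort scale;
a bovine-scale fixture is `synthConfig(nSamples = 21)`.

The trait is assembled directly from the analysis-scale predictor:
`nTags` genes chosen uniformly at random each contribute
`effectSize` × (their log2 TMM-CPM), plus optional covariate terms and
Gaussian noise (`traitNoiseSd`, default 1). Building the trait from
named genes rather than a latent factor makes ground-truth slopes exact
and recovery directly assertable. One caveat discovered while validating:
genes share normalization noise, so with many TAGs the *marginal* slope of
one TAG absorbs a little of the others' signal, and with $T$ equal-effect
TAGs the per-TAG t statistic is bounded near $\sqrt{n/(T-1)}$ because the
other TAGs' contributions act as irreducible noise. Parameter-recovery
experiments therefore use one TAG per simulated dataset (200 datasets in
the acceptance test, mean recovered slope within 0.05 of truth), and the
power/FDR test uses few, strong, homogeneous-variance TAGs.

`injectOutliers()` displaces a fraction of trait values by a multiple of
the trait SD with random sign — the gross-error contamination that
motivates the robust scan; the acceptance suite checks that with 10%
outliers at 10 SD the robust scan's median TAG-slope error is below half
the OLS error over 50 repeats. `dichotomizeTrait()` reproduces the
cutoff-based group coding (e.g. high/low at a threshold) that two-group
comparisons require.

What the generator does **not** emulate: read-level structure, splicing,
GC/length biases, batch effects beyond a single covariate, correlated
gene modules, or outliers in the *counts* (only the trait is
contaminated). Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to every
pathology of real data.

## Numerical choices and problem sizes

* Convergence is declared on coefficients (relative, $10^{-8}$), not on
  weights; fitting is fully deterministic.
* Reference-sample and significance ties break by input order; scans are
  invariant to gene order (tested).
* Missing phenotype values are removed listwise per scan (expression is
  complete once counts exist); removed identifiers are reported.
* All writers emit fixed 6-significant-digit text with a version- and
  parameter-carrying comment header, so identical inputs and seeds give
  byte-identical files (tested across every CLI subcommand).
* Simulation sizes in the test suite were chosen to estimate each quantity
  to well inside its asserted tolerance: 200 mock-comparison repeats put
  the standard error of the mean PFD near 0.0015 against a ±0.015 band;
  200 single-TAG datasets put the mean-slope standard error near 0.015
  against a ±0.05 band; 50 repeats suffice for the factor-two robustness
  comparison, whose observed ratio is near 3.

## Limitations

* The robust Wald test's $t_{n-p}$ reference is an approximation; exact
  numerical parity with F-type robust tests in other software is not
  claimed, and below ~30 samples its size errs slightly liberal.
* TMM assumes most genes are not associated with the trait; a transcriptome
  globally shifted by the phenotype violates normalization and model at
  once.
* External DE methods are compared only through supplied p-values; the
  package deliberately does not re-implement or wrap them.
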