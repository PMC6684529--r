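---
title: "Robust regression with the exponential squared loss: model, tuning and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Robust regression with the exponential squared loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

eslreg fits the linear model $y_i = x_i^\top\beta + \varepsilon_i$ when the
error distribution is unknown and possibly heavy-tailed or contaminated —
the situation that arises, for instance, when a randomized controlled trial
outcome has non-normal residuals and ordinary least squares (OLS) becomes
inefficient or misleading. Instead of minimizing squared error, the
estimator maximizes

$$l_n(\beta) \;=\; \sum_{i=1}^n \exp\!\left(-\frac{(y_i - x_i^\top\beta)^2}{\gamma}\right),$$

equivalently minimizing the total *exponential squared loss*
$\Phi_\gamma(t) = 1 - \exp(-t^2/\gamma)$ over residuals. Because
$\Phi_\gamma$ is bounded by 1, a single observation — however extreme — can
shift the criterion by at most 1: this caps the influence of outliers and
gives the estimator a breakdown point near 50%. The tuning parameter
$\gamma$ trades robustness against efficiency: as $\gamma \to \infty$ the
loss behaves like $t^2/\gamma$ and the fit converges to OLS; small $\gamma$
down-weights moderate residuals aggressively.

## The fitting algorithm

`fit_esl()` iterates three steps until the Euclidean norm of the
coefficient change falls below $10^{-2}$ (at most 50 outer iterations):

1. **Pseudo-outlier set.** From the current residuals, the robust scale
   $S_n = 1.4826 \cdot \mathrm{median}_i\,|r_i - \mathrm{median}_j(r_j)|$
   is computed and observations with $|r_i| \ge 2.5\,S_n$ are flagged. The
   flagging is two-sided: the loss is symmetric, so a large negative
   residual is as outlying as a large positive one.
2. **Tuning-parameter update.** Over a grid of candidate $\gamma$ values,
   those with $\zeta(\gamma) = 2m/n + (2/n)\sum_{i \notin D_m}
   \Phi_\gamma(r_i) \in (0, 1]$ are admissible ($m$ is the pseudo-outlier
   count, and the sum runs over the $n-m$ non-flagged residuals); among
   them, the $\gamma$ minimizing $\det \hat V(\gamma)$ is selected, where
   $\hat V = \hat I_1^{-1} \hat\Sigma\, \hat I_1^{-1}$ is the sandwich
   asymptotic covariance. $\hat I_1$ uses the separable form
   (mean curvature scalar) $\times$ (mean of $x_i x_i^\top$), negated so it
   is positive definite near a maximum, and $\hat\Sigma$ is the empirical
   covariance of the per-observation score contributions
   $(2 r_i/\gamma)\,e^{-r_i^2/\gamma}\,x_i$ — the gradient summands of
   $l_n$, which we validated against numerical differentiation.
3. **Coefficient update.** At the selected $\gamma$, $l_n$ is re-maximized
   by iteratively reweighted least squares (IRLS): stationarity of $l_n$ is
   exactly the weighted normal equations with weights
   $w_i = e^{-r_i^2/\gamma}$. Raw steps that would decrease the objective
   are halved (up to 30 times), so accepted iterations are monotone ascent.

The objective is multimodal, so the answer depends on the start. The
pipeline initializes at the **MM estimator**: an S-stage scans 500
elemental subsamples of $p$ points, keeps the candidate with the smallest
Tukey-bisquare M-scale ($c_0 = 1.547$, consistency constant $b = 0.5$,
~50% breakdown) and refines it by reweighting steps, then an M-stage runs
bisquare IRLS at $c_1 = 4.685$ (95% Gaussian efficiency) with the S-scale
held fixed. These constants follow standard robust-regression practice;
the method reference for the estimator leaves them unspecified, and results
can be mildly sensitive to initialization. A seed in `mm_config()` makes
the subsample sequence, and hence the whole pipeline, fully reproducible.

## Numerical choices

* **Inner solver.** IRLS with step-halving rather than a generic
  quasi-Newton method: stationary points of $l_n$ are weighted
  least-squares fixed points, and monotone ascent is easy to guarantee and
  to test. How the criterion is maximized is left open by the method's
  description; this is our choice.
* **Inner tolerances.** Gradient infinity-norm $\le 10^{-8}$ and step norm
  $\le 10^{-8}$, at most 200 IRLS iterations — deliberately much tighter
  than the outer $10^{-2}$ rule, so outer convergence is never an artifact
  of sloppy inner solves.
* **The $\gamma$ grid.** 40 log-spaced points from $S_n^2/50$ to
  $200\,S_n^2$, rebuilt from the current residuals at every outer
  iteration. $\gamma$ competes with $r^2$ inside the exponent, so the
  squared robust scale is its natural unit; the upper end reaches deep into
  the near-OLS regime and the lower end into hard down-weighting. Whether
  the determinant should be minimized over a grid or analytically is an
  open design point; the grid is transparent and testable. When $S_n = 0$
  with non-zero residuals (half the sample fitting one hyperplane), the
  sample SD of the residuals replaces $S_n$ for grid construction.
* **Degenerate exact fits.** If all residuals vanish, $\zeta \equiv 0$ and
  no $\gamma$ is admissible; `fit_esl()` returns immediately with
  $\gamma = 1$ (all weights 1), which is the global maximum.
* **Ties and conditioning.** Determinant ties resolve to the larger
  $\gamma$ (the more efficient, less aggressive fit). Candidates whose
  curvature matrix is numerically singular (condition number above
  $10^{12}$) or not positive definite are excluded rather than propagated
  as errors; an entirely empty admissible set raises a classed error
  carrying the full $(\gamma, \zeta, \det\hat V)$ table.
* **Compiled core.** The IRLS solver, subsample scan and grid scan are
  C++ (RcppArmadillo); the exported R functions (`esl_objective()`,
  `asymptotic_cov()`, `select_gamma()`, ...) are independent R
  implementations of the same formulas, and the test suite holds the two
  paths to agreement ("double-entry bookkeeping") on random instances.

## Inference

`bootstrap_ci()` uses case (pairs) resampling with the full pipeline —
including re-selection of $\gamma$ — re-run on every resample, and
percentile intervals from interpolated order statistics (type 7). Residual
resampling is deliberately avoided since it assumes the homoscedastic
clean-error structure the method exists to escape. The default
$B = 1000$ resamples is conventional for percentile intervals; a
significance call for a coefficient is "the interval excludes zero".
Rank-deficient resamples are skipped and counted; above 5% failures the
result is flagged unreliable. Whether $\gamma$ should be re-selected
within each resample is genuinely open; re-running the pipeline end to end
treats the tuning step as part of the estimator, which is what the
interval is supposed to cover.

## What the simulator emulates — and what it does not

`simulation_design()` reproduces the benchmark data-generating process:
$n = 300$; six i.i.d. N(0,1) covariates; one categorical covariate uniform
on $\{1,\dots,4\}$ expanded to three indicators with the last level as
reference; true coefficients $(1, 1.2, \dots, 2.8)$ with intercept 1;
clean errors N(0,1); and a contaminated fraction (10/20/30%) whose errors
are replaced by $t(1)$ (Cauchy) draws. Contaminated rows number exactly
`round(contamination * n)` and are chosen by seeded simple random sampling
each replication; the categorical covariate is uniform over its levels.
Replication $r$ of a study uses seed `seed + r`, so every cell of a summary
table is reproducible in isolation.

Because $t(1)$ has no finite moments, OLS summary cells under contamination
are dominated by the luck of the seed — they are not reproducible
quantities, and the package's tests assert the stable comparisons instead
(ESL beating OLS on MSE, narrower error bars) rather than chasing
seed-dependent OLS numbers. `mci_like_fixture()` generates a synthetic
two-arm multi-centre trial table (2:1 allocation, age/BMI/baseline-score
covariates, eight centres with centre 8 as reference, a 90/10
normal/heavy-t error mixture calibrated so Shapiro–Wilk rejects residual
normality at realistic sample sizes). It is a stand-in emulating the
*structure* of trial data — marginals and effect sizes are loosely
realistic, not estimates from any real cohort — so passing tests show the
pipeline handles this covariate structure, not that it reproduces any
particular trial's estimates.

What the generator does **not** emulate: covariate correlation and
measurement error, heteroscedasticity, missing data mechanisms,
centre-by-treatment interaction, or informative dropout. Conclusions from
the simulation study transfer to real data only insofar as contamination
is well-described by a symmetric heavy-tailed error component.

## Problem sizes used by the test suite

The replication studies in the tests and the acceptance script run the
full design at $R = 100$ replications per contamination level (the
benchmark's own replication count) and a clean-data recovery study at
$R = 200$. Bootstrap coverage is assessed with 200 outer replications
$\times\ B = 200$ resamples in the test suite and 100 outer replications in
the acceptance script; at $B = 200$ the Monte-Carlo error of a single 95%
interval's endpoints is still small relative to the (0.90, 0.99)
acceptance band. These sizes are the package's chosen defaults for
verification studies.

## Known limitations

* The objective is non-convex; all guarantees are local. With a poor
  initializer the fit can land in a bad mode — the MM start is not
  optional in practice.
* The determinant criterion needs a positive-definite curvature matrix;
  on tiny samples (n of a few dozen) with severe contamination the
  admissible set can be empty, which surfaces as the classed
  `no_feasible_gamma` error rather than a silent fallback.
* Asymptotic-normality Wald intervals from $\hat V$ are not provided;
  inference is bootstrap-only, mirroring how the method is used.
* Penalized/sparse variants of the loss (variable selection) and
  generalized linear models are out of scope.

## A worked call

```{r example}
library(eslreg)

sim <- simulate_dataset(
  simulation_design(n = 300, contamination = 0.2),
  seed = 1
)
fit <- fit_esl(sim$data, esl_config(mm = mm_config(seed = 1)))
glance(fit)            # selected gamma, pseudo-outlier count, convergence
tidy(fit)              # coefficient table
autoplot(fit)          # weights vs residuals: what was down-weighted

ci <- bootstrap_ci(sim$data, esl_config(mm = mm_config(seed = 1)),
                   B = 1000, seed = 1)
tidy(ci)               # percentile intervals and exclusion-of-zero calls
```
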