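# eslreg

Robust linear regression with the exponential squared loss (ESL), for
outcome analyses — covariate-adjusted treatment-effect estimation in
randomized trials being the motivating case — where residuals are
heavy-tailed or contaminated and ordinary least squares (OLS) loses
efficiency.

## The method

For the linear model $y_i = x_i^\top\beta + \varepsilon_i$, the estimator
maximizes

$$l_n(\beta) = \sum_{i=1}^n \exp\!\big(-(y_i - x_i^\top\beta)^2/\gamma\big),$$

i.e. minimizes the bounded loss $\Phi_\gamma(t) = 1 - e^{-t^2/\gamma}$ over
residuals, so no single observation can dominate the fit. The tuning
parameter $\gamma$ is selected from the data: residuals beyond
$2.5\,S_n$ (with $S_n$ the MAD scale $1.4826\cdot\mathrm{median}|r_i -
\mathrm{median}(r)|$) form a pseudo-outlier set of size $m$; candidates
with $\zeta(\gamma) = 2m/n + (2/n)\sum_{i\notin D_m}\Phi_\gamma(r_i) \in
(0,1]$ are admissible; among them the minimizer of
$\det\hat V(\gamma)$, $\hat V = \hat I_1^{-1}\hat\Sigma\hat I_1^{-1}$ the
sandwich asymptotic covariance, is chosen. Coefficients are re-estimated
at the selected $\gamma$ by monotone IRLS, starting from a high-breakdown
MM estimate, and the outer loop repeats until
$\lVert\beta^{old} - \beta^{new}\rVert < 10^{-2}$. Inference is by case
(pairs) percentile bootstrap with the whole pipeline re-run per resample.

See the methods vignette (`vignettes/esl-robust-regression.Rmd`) for the
algorithm, the defaults and every numerical choice.

## A worked example

```r
library(eslreg)

# the benchmark generator: n = 300, ten coefficients, 20% of rows get
# t(1) (Cauchy) errors
sim <- simulate_dataset(simulation_design(n = 300, contamination = 0.2),
                        seed = 1)
fit <- fit_esl(sim$data, esl_config(mm = mm_config(seed = 1)))
glance(fit)
#> # A tibble: 1 × 7
#>   gamma     m objective converged n_outer_iters     n     p
#>   <dbl> <int>     <dbl> <lgl>             <int> <int> <int>
#> 1  16.6    10      273. TRUE                  2   300    10
tidy(fit)
#> # A tibble: 10 × 2
#>    term        estimate
#>    <chr>          <dbl>
#>  1 (Intercept)     1.12
#>  2 x1              1.06
#>  3 x2              1.27
#>  4 x3              1.62
#>  5 x4              1.79
#>  6 x5              1.96
#>  7 x6              2.32
#>  8 z1              2.25
#>  9 z2              2.37
#> 10 z3              2.56
```

The selected `gamma` is the data-driven robustness/efficiency trade-off;
`m` counts the observations flagged as pseudo-outliers (residuals beyond
`2.5 S_n`) and hard-down-weighted by $w_i = e^{-r_i^2/\gamma}$. On this
draw — 60 of 300 rows Cauchy-contaminated — every ESL estimate lands
within 0.25 of the generating values $(1, 1.2, \ldots, 2.8)$, while the
OLS fit of the same draw errs by up to 5.3. Averaged over 100 such
replications (`run_replications()` below) the ESL means track the truth to
a few thousandths with slope SDs of about 0.06.

Monte-Carlo comparison against OLS, and error-bar figures:

```r
summ <- run_replications(simulation_design(contamination = 0.2,
                                           replications = 100, seed = 42))
error_bar_summary(summ)   # truth, mean, mean ± SD per estimator
autoplot(summ)            # the comparison figure
```

Bootstrap intervals:

```r
ci <- bootstrap_ci(sim$data, esl_config(mm = mm_config(seed = 1)),
                   B = 1000, seed = 1)
tidy(ci)   # estimate, conf.low, conf.high, excludes_zero
```

A thin command-line front end over these functions is installed at
`inst/cli/eslreg.R` (subcommands `fit`, `simulate`, `bootstrap`; delimited
text in, CSV/JSON out; YAML model configuration).

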