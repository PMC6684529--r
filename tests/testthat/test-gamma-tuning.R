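test_that("robust residual scale matches hand-computed values", {
  # median 3, absolute deviations (2, 1, 0, 1, 97), median deviation 1
  expect_equal(residual_scale_sn(c(1, 2, 3, 4, 100)), 1.4826)
  expect_equal(residual_scale_sn(rep(2.5, 10)), 0)
  r <- rnorm(31)
  expect_equal(residual_scale_sn(-3.2 * r),
               3.2 * residual_scale_sn(r))
  expect_error(residual_scale_sn(numeric(0)),
               class = "eslreg_invalid_input")
  expect_error(residual_scale_sn(5), class = "eslreg_invalid_input")
})

test_that("pseudo-outlier rule flags |r| >= 2.5 S_n and nothing else", {
  # median 1, abs deviations (0, 2, 1, 3, 99) -> S_n = 2.9652,
  # threshold 7.413: only the value 100 is flagged
  pos <- pseudo_outlier_set(c(1, -1, 2, -2, 100))
  expect_equal(pos$S_n, 2.9652)
  expect_equal(pos$indices, 5L)
  expect_equal(pos$m, 1L)
  expect_false(pos$degenerate)

  pos0 <- pseudo_outlier_set(rep(0, 10))
  expect_equal(pos0$m, 0L)
  expect_true(pos0$degenerate)

  # exhaustive agreement with a direct filter on random vectors
  set.seed(8)
  for (i in 1:50) {
    r <- rt(40, df = 2)
    pos <- pseudo_outlier_set(r)
    expect_identical(pos$indices,
                     which(abs(r) >= 2.5 * residual_scale_sn(r)))
  }
})

test_that("the two-sided MAD rule flags ~1% of Gaussian residuals", {
  set.seed(9)
  pos <- pseudo_outlier_set(rnorm(1e5))
  expect_gt(pos$m / 1e5, 0.005)
  expect_lt(pos$m / 1e5, 0.025)
})

test_that("zeta has its closed forms, bounds and monotonicity", {
  expect_equal(zeta(1, rep(0, 10)), 0)  # all-zero residuals: infeasible

  r2 <- c(1, 1)
  expect_equal(zeta(1, r2), 2 * (1 - exp(-1)))  # 1.2642... > 1

  set.seed(10)
  r <- c(rnorm(50), 40, -35)
  pos <- pseudo_outlier_set(r)
  n <- length(r); m <- pos$m
  expect_gt(m, 0)
  for (g in 10^seq(-4, 6, by = 1)) {
    z <- zeta(g, r, pos)
    expect_gte(z, 2 * m / n)
    expect_lte(z, 2 * m / n + 2 * (n - m) / n)
  }
  zs <- vapply(10^seq(-2, 4, by = 0.5), zeta, numeric(1),
               residuals = r, outliers = pos)
  expect_true(all(diff(zs) < 0))
  expect_error(zeta(-1, r), class = "eslreg_invalid_gamma")
})

test_that("sandwich covariance behaves at zero residuals and is PSD", {
  ef <- exact_fit_data(n = 30, p = 3, seed = 11)
  ac <- asymptotic_cov(ef$beta, ef$data, 2)
  expect_equal(ac$Sigma, matrix(0, 3, 3), ignore_attr = TRUE)
  expect_equal(ac$V, matrix(0, 3, 3), ignore_attr = TRUE)
  expect_equal(ac$detV, 0)
  expect_true(ac$feasible)

  set.seed(12)
  for (i in 1:20) {
    inst <- noisy_instance(n = 25, p = 3, seed = i)
    ac <- asymptotic_cov(rnorm(3), inst$data, runif(1, 0.5, 5))
    expect_gte(min(eigen(ac$Sigma, symmetric = TRUE,
                         only.values = TRUE)$values), -1e-10)
    if (ac$feasible) {
      expect_lt(max(abs(ac$V - t(ac$V))), 1e-10)
    }
  }
})

test_that("curvature scalar matches a numerical Hessian (intercept-only)", {
  # with a lone intercept column the separable curvature matrix reduces to
  # the exact negated second derivative of the mean objective
  set.seed(13)
  y <- rnorm(20, 1, 0.7)
  d <- regression_data(y, matrix(1, 20, 1))
  beta <- 0.8; gamma <- 1.3; h <- 1e-4
  ac <- asymptotic_cov(beta, d, gamma)
  f <- function(b) esl_objective(b, d, gamma) / 20
  hess <- (f(beta + h) - 2 * f(beta) + f(beta - h)) / h^2
  expect_equal(ac$I1[1, 1], -hess, tolerance = 1e-4)
})

test_that("R and compiled determinant paths agree (double entry)", {
  set.seed(14)
  for (i in 1:50) {
    inst <- noisy_instance(n = 30, p = 3, seed = 100 + i,
                           contaminate = 0.1, shift = 20)
    beta <- inst$beta + rnorm(3, 0, 0.1)
    grid <- 10^seq(-1, 2, length.out = 7)
    tab_cpp <- eslreg:::cpp_gamma_table(inst$data$X, inst$data$y, beta,
                                        grid)
    r <- inst$data$y - drop(inst$data$X %*% beta)
    pos <- pseudo_outlier_set(r)
    for (j in seq_along(grid)) {
      ac <- asymptotic_cov(beta, inst$data, grid[j])
      z <- zeta(grid[j], r, pos)
      expect_equal(tab_cpp$zeta[j], z, tolerance = 1e-10)
      feas <- ac$feasible && z > 0 && z <= 1
      if (feas && tab_cpp$feasible[j]) {
        expect_equal(tab_cpp$detV[j], ac$detV,
                     tolerance = 1e-8 * max(1, abs(ac$detV)))
      }
    }
  }
})

test_that("gamma selection honors feasibility, ties and error contract", {
  inst <- noisy_instance(n = 60, p = 3, seed = 15, contaminate = 0.1,
                         shift = 25)
  fitted_beta <- fit_mm(inst$data, mm_config(seed = 15))

  # singleton feasible grid returns that gamma (large multiple of the
  # squared scale: zeta ~ 2m/n is inside (0, 1] and curvature is positive)
  r <- inst$data$y - drop(inst$data$X %*% fitted_beta)
  s2 <- residual_scale_sn(r)^2
  g <- select_gamma(fitted_beta, inst$data, grid = 100 * s2)
  expect_equal(as.numeric(g), 100 * s2)

  # residuals of constant magnitude, tiny gamma candidates: zeta ~ 2 > 1
  # for every grid point, so the feasible set is empty
  X <- cbind(1, seq_len(12))
  y <- drop(X %*% c(0, 1)) + rep(c(1, -1), 6)
  d <- regression_data(y, X)
  err <- tryCatch(
    select_gamma(c(0, 1), d, grid = c(1e-6, 1e-5, 1e-4)),
    condition = function(c) c
  )
  expect_s3_class(err, "eslreg_no_feasible_gamma")
  expect_s3_class(err$table, "tbl_df")
  expect_true(all(!err$table$feasible))

  expect_error(select_gamma(fitted_beta, inst$data, grid = numeric(0)),
               class = "eslreg_invalid_input")
  expect_error(select_gamma(fitted_beta, inst$data, grid = c(-1, 2)),
               class = "eslreg_invalid_input")
})

test_that("full pipeline: exact fit, determinism, termination", {
  ef <- exact_fit_data(n = 40, p = 4, seed = 16)
  fit <- fit_esl(ef$data, esl_config(mm = mm_config(seed = 16)))
  expect_equal(unname(fit$beta), ef$beta, tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$n_outer_iters, 1L)

  sim <- simulate_dataset(simulation_design(n = 150, contamination = 0.2),
                          seed = 17)
  cfg <- esl_config(mm = mm_config(seed = 17))
  f1 <- fit_esl(sim$data, cfg)
  f2 <- fit_esl(sim$data, cfg)
  expect_identical(f1$beta, f2$beta)
  expect_identical(f1$gamma, f2$gamma)
  expect_true(f1$converged)
  # the convergence rule is on the Euclidean step norm
  expect_lt(tail(f1$trace, 1), 1e-2)

  # iteration cap: never an infinite loop, reported as non-converged
  f3 <- fit_esl(sim$data, esl_config(max_outer = 1,
                                     mm = mm_config(seed = 17)))
  expect_false(f3$converged)
  expect_equal(f3$n_outer_iters, 1L)
})

test_that("on clean data the tuned ESL fit agrees with OLS", {
  sim <- simulate_dataset(simulation_design(n = 300, contamination = 0),
                          seed = 18)
  fit <- fit_esl(sim$data, esl_config(mm = mm_config(seed = 18)))
  expect_lt(max(abs(fit$beta - fit_ols(sim$data))), 0.05)
})

test_that("clean-data recovery: small bias, efficiency close to OLS", {
  design <- simulation_design(n = 300, contamination = 0,
                              replications = 200, seed = 500)
  summ <- run_replications(design)
  esl <- summ[summ$estimator == "esl", ]
  ols <- summ[summ$estimator == "ols", ]
  expect_true(all(abs(esl$bias) < 0.02))
  expect_true(all(esl$mse <= 1.2 * ols$mse))
})
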