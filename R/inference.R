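#' Percentile bootstrap confidence intervals for regression coefficients
#'
#' Case (pairs) resampling: `B` datasets are drawn by resampling rows with
#' replacement, the full estimation pipeline is re-run on each (for ESL that
#' includes re-selecting the tuning parameter), and per-coefficient empirical
#' percentile bounds are taken at levels `(1 - level)/2` and
#' `1 - (1 - level)/2` (interpolated order statistics, the type-7
#' convention). Residual resampling is deliberately avoided: it bakes in the
#' homoscedastic-normal structure the robust fit exists to avoid.
#'
#' Resamples whose design matrix is rank-deficient, or whose fit fails, are
#' skipped and counted in `n_failed`; if more than 5% fail the result is
#' flagged unreliable (with a warning).
#'
#' @param data A [regression_data()] object.
#' @param config An [esl_config()] (used when `method = "esl"`).
#' @param B Number of bootstrap resamples (at least 100).
#' @param level Nominal coverage in (0, 1); default 0.95.
#' @param seed Integer seed governing the resample sequence.
#' @param method `"esl"` (default) or `"ols"`.
#' @return An object of class `esl_bootstrap`: list with `B`, `level`,
#'   `method`, named vectors `point`, `lower`, `upper`, count `n_failed`,
#'   `unreliable` flag, `seed`, and the matrix of replicate estimates
#'   (`replicates`, successful resamples by coefficients). `tidy()` returns
#'   the coefficient table with an `excludes_zero` significance call.
#' @export
bootstrap_ci <- function(data, config = esl_config(), B = 1000,
                         level = 0.95, seed = NULL,
                         method = c("esl", "ols")) {
  assert_regression_data(data)
  method <- match.arg(method)
  if (B < 100) {
    rlang::abort("`B` must be at least 100", class = "eslreg_invalid_input")
  }
  if (level <= 0 || level >= 1) {
    rlang::abort("`level` must lie strictly between 0 and 1",
                 class = "eslreg_invalid_input")
  }
  fit_fun <- switch(method,
    esl = function(d) fit_esl(d, config)$beta,
    ols = function(d) fit_ols(d)
  )
  point <- fit_fun(data)
  with_optional_seed(seed, {
    reps <- matrix(NA_real_, B, data$p,
                   dimnames = list(NULL, data$column_names))
    n_failed <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(data$n, data$n, replace = TRUE)
      d_b <- structure(
        list(y = data$y[idx], X = data$X[idx, , drop = FALSE],
             column_names = data$column_names, n = data$n, p = data$p),
        class = "regression_data"
      )
      est <- tryCatch(fit_fun(d_b), error = function(e) NULL)
      if (is.null(est)) n_failed <- n_failed + 1L else reps[b, ] <- est
    }
    reps <- reps[stats::complete.cases(reps), , drop = FALSE]
    unreliable <- n_failed / B > 0.05
    if (unreliable) {
      rlang::warn(paste0(n_failed, " of ", B,
                         " resamples failed; intervals flagged unreliable"))
    }
    ci <- apply(reps, 2, percentile_interval, level = level)
    structure(
      list(B = B, level = level, method = method, point = point,
           lower = stats::setNames(ci[1, ], data$column_names),
           upper = stats::setNames(ci[2, ], data$column_names),
           n_failed = n_failed, unreliable = unreliable, seed = seed,
           replicates = reps),
      class = "esl_bootstrap"
    )
  })
}

# empirical (alpha/2, 1 - alpha/2) bounds, interpolated order statistics
percentile_interval <- function(estimates, level) {
  alpha <- 1 - level
  stats::quantile(estimates, probs = c(alpha / 2, 1 - alpha / 2),
                  type = 7, names = FALSE)
}

#' @export
print.esl_bootstrap <- function(x, digits = 4, ...) {
  cat("<esl_bootstrap> ", x$method, " fit, B = ", x$B, ", ",
      format(100 * x$level), "% percentile intervals",
      if (x$unreliable) "  [UNRELIABLE]", "\n", sep = "")
  print(tidy(x), n = Inf)
  invisible(x)
}
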