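#' The exponential squared loss
#'
#' \eqn{\Phi_\gamma(t) = 1 - \exp(-t^2/\gamma)}. The loss is bounded by 1, so
#' no single observation can dominate the fit: that boundedness is what gives
#' the estimator its robustness. Small \eqn{\gamma} down-weights outliers
#' hard; as \eqn{\gamma \to \infty} the loss approaches \eqn{t^2/\gamma} and
#' the estimator approaches least squares.
#'
#' @param t Numeric vector of residuals (or any real values).
#' @param gamma Positive tuning parameter.
#' @return Numeric vector in `[0, 1)`, same length as `t`.
#' @examples
#' esl_loss(0, 1)       # 0
#' esl_loss(1, 1)       # 1 - exp(-1)
#' @export
esl_loss <- function(t, gamma) {
  check_gamma(gamma)
  1 - exp(-t^2 / gamma)
}

check_gamma <- function(gamma) {
  if (!is.numeric(gamma) || length(gamma) != 1L || !is.finite(gamma) ||
      gamma <= 0) {
    rlang::abort("`gamma` must be a single positive number",
                 class = "eslreg_invalid_gamma")
  }
  invisible(TRUE)
}

#' ESL objective function
#'
#' The criterion the estimator maximizes:
#' \eqn{l_n(\beta) = \sum_i \exp(-(y_i - x_i^T\beta)^2/\gamma)}.
#' Equivalently \eqn{n - \sum_i \Phi_\gamma(r_i)}, so maximizing it minimizes
#' the total exponential squared loss.
#'
#' @param beta Coefficient vector of length `data$p`.
#' @param data A [regression_data()] object.
#' @param gamma Positive tuning parameter.
#' @return A single number in `(0, n]`.
#' @export
esl_objective <- function(beta, data, gamma) {
  assert_regression_data(data)
  check_gamma(gamma)
  beta <- check_beta(beta, data)
  r <- data$y - drop(data$X %*% beta)
  sum(exp(-r^2 / gamma))
}

check_beta <- function(beta, data) {
  beta <- as.numeric(beta)
  if (length(beta) != data$p) {
    rlang::abort(
      paste0("`beta` has length ", length(beta), " but the design has p = ",
             data$p, " columns"),
      class = "eslreg_dimension_mismatch"
    )
  }
  beta
}

#' Analytic gradient of the ESL objective
#'
#' \eqn{\sum_i (2 r_i/\gamma)\exp(-r_i^2/\gamma)\, x_i}, the exact gradient
#' of [esl_objective()] with respect to `beta`. Used for convergence checks
#' and as the per-observation score whose empirical covariance enters the
#' sandwich matrix of [asymptotic_cov()].
#'
#' @inheritParams esl_objective
#' @return Numeric vector of length `data$p`.
#' @export
esl_score <- function(beta, data, gamma) {
  assert_regression_data(data)
  check_gamma(gamma)
  beta <- check_beta(beta, data)
  r <- data$y - drop(data$X %*% beta)
  drop(crossprod(data$X, (2 * r / gamma) * exp(-r^2 / gamma)))
}

# per-observation score contributions, n x p (rows are s_i)
score_contributions <- function(beta, data, gamma) {
  r <- data$y - drop(data$X %*% beta)
  data$X * ((2 * r / gamma) * exp(-r^2 / gamma))
}

#' Maximize the ESL objective at a fixed tuning parameter
#'
#' Iteratively reweighted least squares: the stationarity condition of the
#' ESL objective is exactly the weighted normal equations with weights
#' \eqn{w_i = \exp(-r_i^2/\gamma)}, so each iteration solves a weighted
#' least-squares problem and re-forms the weights. Raw steps that would
#' decrease the objective are step-halved (up to 30 times), so accepted
#' iterations never decrease it. The objective is multimodal: the fit
#' converges to the local maximum reachable from `beta_init`, which is why
#' the full pipeline starts from the high-breakdown MM estimate.
#'
#' @param data A [regression_data()] object.
#' @param gamma Positive tuning parameter.
#' @param beta_init Starting coefficient vector (length `data$p`).
#' @param tol Convergence tolerance: stop when the gradient infinity-norm or
#'   the step norm falls below it.
#' @param max_iter Maximum IRLS iterations.
#' @param n_restarts Optional number of additional starts jittered around
#'   `beta_init` by `0.5 * S_n` per coordinate (default 0: deterministic
#'   local fit from `beta_init` only); the best local maximum is returned.
#' @return An `esl_fit` object; see [fit_esl()] for the fields.
#' @export
fit_esl_fixed_gamma <- function(data, gamma, beta_init, tol = 1e-8,
                                max_iter = 200, n_restarts = 0) {
  assert_regression_data(data)
  check_gamma(gamma)
  check_full_rank(data)
  beta_init <- check_beta(beta_init, data)

  run1 <- function(b0) {
    cpp_irls_esl(data$X, data$y, gamma, b0, tol, tol, max_iter, 30L)
  }
  res <- run1(beta_init)
  if (res$status != "ok") {
    rlang::abort(
      "degenerate weighted fit: weights concentrate on fewer than p points",
      class = "eslreg_degenerate_fit"
    )
  }
  if (n_restarts > 0) {
    r0 <- data$y - drop(data$X %*% beta_init)
    jitter_sd <- 0.5 * residual_scale_sn(r0)
    if (jitter_sd == 0) jitter_sd <- 0.5 * stats::sd(r0)
    for (k in seq_len(n_restarts)) {
      cand <- tryCatch(
        run1(beta_init + stats::rnorm(data$p, 0, jitter_sd)),
        error = function(e) NULL
      )
      if (!is.null(cand) && cand$status == "ok" &&
          cand$objective > res$objective) {
        res <- cand
      }
    }
  }
  new_esl_fit(data, beta = drop(res$beta), gamma = gamma,
              converged = res$converged, n_outer_iters = res$iterations,
              trace = as.numeric(res$step_trace),
              gamma_trace = gamma, m_trace = NA_real_)
}

# shared esl_fit constructor; residuals/weights/objective/m derived from beta
new_esl_fit <- function(data, beta, gamma, converged, n_outer_iters, trace,
                        gamma_trace, m_trace) {
  beta <- stats::setNames(as.numeric(beta), data$column_names)
  residuals <- data$y - drop(data$X %*% beta)
  weights <- exp(-residuals^2 / gamma)
  pos <- pseudo_outlier_set(residuals)
  structure(
    list(beta = beta, gamma = gamma, residuals = residuals,
         weights = weights, objective = sum(weights), m = pos$m,
         converged = converged, n_outer_iters = n_outer_iters,
         trace = trace, gamma_trace = gamma_trace, m_trace = m_trace,
         data = data),
    class = "esl_fit"
  )
}

#' @export
print.esl_fit <- function(x, digits = 4, ...) {
  cat("<esl_fit>  gamma =", signif(x$gamma, digits),
      " pseudo-outliers m =", x$m,
      if (x$converged) " (converged)" else " (NOT converged)", "\n")
  print(round(x$beta, digits))
  invisible(x)
}
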