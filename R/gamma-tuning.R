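#' Robust residual scale S_n
#'
#' `1.4826 * median(|r_i - median(r)|)`: the median absolute deviation with
#' the Gaussian consistency factor, so S_n estimates the error SD under
#' normality while ignoring up to half the sample.
#'
#' @param residuals Numeric vector, length at least 2.
#' @return A single non-negative number.
#' @examples
#' residual_scale_sn(c(1, 2, 3, 4, 100))  # 1.4826
#' @export
residual_scale_sn <- function(residuals) {
  if (length(residuals) < 2 || anyNA(residuals)) {
    rlang::abort("`residuals` must have length >= 2 and no missing values",
                 class = "eslreg_invalid_input")
  }
  stats::mad(residuals, constant = 1.4826)
}

#' Pseudo-outlier set
#'
#' Flags every observation whose absolute residual is at least `2.5 * S_n`.
#' These observations are excluded from the sum of the feasibility functional
#' [zeta()] and counted in its `2m/n` term. When `S_n = 0` (at least half the
#' residuals identical) the rule is undefined; the set is returned empty with
#' `degenerate = TRUE`.
#'
#' @inheritParams residual_scale_sn
#' @return A list of class `pseudo_outlier_set`: `S_n`, integer `indices`,
#'   count `m`, and flag `degenerate`.
#' @export
pseudo_outlier_set <- function(residuals) {
  S_n <- residual_scale_sn(residuals)
  if (S_n == 0) {
    idx <- integer(0)
    degenerate <- TRUE
  } else {
    idx <- which(abs(residuals) >= 2.5 * S_n)
    degenerate <- FALSE
  }
  structure(list(S_n = S_n, indices = idx, m = length(idx),
                 degenerate = degenerate),
            class = "pseudo_outlier_set")
}

#' Feasibility functional zeta(gamma)
#'
#' \eqn{\zeta(\gamma) = 2m/n + (2/n)\sum \Phi_\gamma(r_i)} with the sum over
#' the `n - m` residuals not flagged as pseudo-outliers. A candidate
#' \eqn{\gamma} is admissible when \eqn{\zeta \in (0, 1]}; this anchors the
#' tuning-parameter search away from values that would treat the bulk of the
#' data as outlying.
#'
#' @param gamma Positive candidate tuning parameter.
#' @param residuals Numeric residual vector.
#' @param outliers A [pseudo_outlier_set()] for these residuals; computed
#'   from them when omitted.
#' @return A single number in `[2m/n, 2m/n + 2(n-m)/n]`.
#' @export
zeta <- function(gamma, residuals, outliers = pseudo_outlier_set(residuals)) {
  check_gamma(gamma)
  n <- length(residuals)
  m <- outliers$m
  r_in <- if (m > 0) residuals[-outliers$indices] else residuals
  2 * m / n + (2 / n) * sum(esl_loss(r_in, gamma))
}

#' Sandwich asymptotic covariance of the ESL estimator
#'
#' For a candidate `gamma`, computes
#' \eqn{\hat V(\gamma) = \hat I_1^{-1}\, \hat\Sigma\, \hat I_1^{-1}} where
#' \eqn{\hat I_1} is the separable curvature matrix
#' (mean scalar second-derivative factor times the mean of \eqn{x_i x_i^T},
#' negated so it is positive definite near a maximum) and \eqn{\hat\Sigma}
#' is the empirical covariance of the per-observation score contributions
#' \eqn{(2 r_i/\gamma) e^{-r_i^2/\gamma} x_i}. The tuning parameter is chosen
#' by minimizing \eqn{\det \hat V(\gamma)} over the admissible set; see
#' [select_gamma()].
#'
#' @inheritParams esl_objective
#' @return A list of class `asymptotic_cov`: `gamma`, matrices `I1`, `Sigma`,
#'   `V`, the determinant `detV`, and a `feasible` flag that is `FALSE` when
#'   `I1` is numerically singular (condition number above 1e12) or not
#'   positive definite.
#' @export
asymptotic_cov <- function(beta, data, gamma) {
  assert_regression_data(data)
  check_gamma(gamma)
  beta <- check_beta(beta, data)
  n <- data$n
  r <- data$y - drop(data$X %*% beta)
  u <- r^2 / gamma
  # negated mean Hessian scalar: positive when the fit sits near a maximum
  a <- mean((2 / gamma) * exp(-u) * (1 - 2 * u))
  Mxx <- crossprod(data$X) / n
  I1 <- a * Mxx
  S <- score_contributions(beta, data, gamma)
  sbar <- colMeans(S)
  Sigma <- crossprod(S) / n - tcrossprod(sbar)
  dimnames(I1) <- dimnames(Sigma) <- list(data$column_names,
                                          data$column_names)
  feasible <- a > 0 && is.finite(kappa(I1)) && kappa(I1) < 1e12
  if (feasible) {
    I1inv <- solve(I1)
    V <- I1inv %*% Sigma %*% I1inv
    detV <- det(V)
    if (!is.finite(detV)) feasible <- FALSE
  } else {
    V <- matrix(NA_real_, data$p, data$p)
    detV <- NA_real_
  }
  structure(list(gamma = gamma, I1 = I1, Sigma = Sigma, V = V, detV = detV,
                 feasible = feasible),
            class = "asymptotic_cov")
}

#' Select the tuning parameter by determinant minimization
#'
#' Computes residuals and the pseudo-outlier set at `beta` once, then, among
#' grid candidates with \eqn{\zeta(\gamma) \in (0, 1]} and a well-conditioned
#' curvature matrix, returns the \eqn{\gamma} with the smallest
#' \eqn{\det \hat V(\gamma)} (ties broken by the larger \eqn{\gamma}).
#'
#' @inheritParams esl_objective
#' @param grid Positive numeric vector of candidate `gamma` values.
#' @return The selected `gamma` (a single number), with the full candidate
#'   table attached as attribute `"table"` (a tibble with columns `gamma`,
#'   `zeta`, `detV`, `feasible`).
#' @export
select_gamma <- function(beta, data, grid) {
  assert_regression_data(data)
  beta <- check_beta(beta, data)
  if (length(grid) == 0 || any(!is.finite(grid)) || any(grid <= 0)) {
    rlang::abort("`grid` must be a non-empty vector of positive values",
                 class = "eslreg_invalid_input")
  }
  r <- data$y - drop(data$X %*% beta)
  pos <- pseudo_outlier_set(r)
  tab <- tibble::tibble(
    gamma = as.numeric(grid),
    zeta = purrr::map_dbl(grid, zeta, residuals = r, outliers = pos),
    cov = purrr::map(grid, asymptotic_cov, beta = beta, data = data)
  )
  tab$detV <- purrr::map_dbl(tab$cov, "detV")
  tab$feasible <- purrr::map_lgl(tab$cov, "feasible") &
    tab$zeta > 0 & tab$zeta <= 1
  tab$cov <- NULL
  ok <- which(tab$feasible)
  if (length(ok) == 0) {
    rlang::abort(
      "no candidate gamma is feasible (zeta outside (0, 1] or singular I1)",
      class = "eslreg_no_feasible_gamma",
      table = tab
    )
  }
  cand <- tab[ok, ]
  cand <- cand[order(cand$detV, -cand$gamma), ]
  structure(cand$gamma[1], table = tab)
}

#' Control parameters of the full ESL pipeline
#'
#' @param outer_tol Outer convergence threshold on the Euclidean norm of the
#'   coefficient change (default `1e-2`).
#' @param max_outer Maximum outer iterations (default 50).
#' @param n_grid Number of log-spaced gamma candidates per outer iteration.
#' @param grid_lo,grid_hi Grid limits as multiples of the squared robust
#'   residual scale: candidates span `S_n^2 * grid_lo` to `S_n^2 * grid_hi`.
#'   Gamma competes with squared residuals inside the exponent, so the
#'   squared scale is its natural unit.
#' @param inner_tol,inner_max_iter Convergence tolerance and iteration cap of
#'   the inner fixed-gamma IRLS solves (tighter than the outer rule).
#' @param mm An [mm_config()] for the initial estimator.
#' @return A list of class `esl_config`.
#' @export
esl_config <- function(outer_tol = 1e-2, max_outer = 50, n_grid = 40,
                       grid_lo = 1 / 50, grid_hi = 200, inner_tol = 1e-8,
                       inner_max_iter = 200, mm = mm_config()) {
  structure(list(outer_tol = outer_tol, max_outer = as.integer(max_outer),
                 n_grid = as.integer(n_grid), grid_lo = grid_lo,
                 grid_hi = grid_hi, inner_tol = inner_tol,
                 inner_max_iter = as.integer(inner_max_iter), mm = mm),
            class = "esl_config")
}

#' Fit the ESL regression with data-driven tuning
#'
#' The full pipeline: start from the MM estimate, then iterate (i) compute
#' residuals and the pseudo-outlier set, (ii) select `gamma` by minimizing
#' the determinant of the sandwich covariance over the admissible grid,
#' (iii) re-maximize the ESL objective at that `gamma`, until the Euclidean
#' norm of the coefficient change drops below `config$outer_tol`.
#'
#' On data the model fits exactly the tuning-parameter search is vacuous
#' (every residual is zero, so \eqn{\zeta \equiv 0} is inadmissible); the fit
#' returns immediately with `gamma = 1`, under which all weights are 1.
#'
#' @param data A [regression_data()] object.
#' @param config An [esl_config()].
#' @param beta_init Optional starting coefficient vector; defaults to the MM
#'   estimate under `config$mm`.
#' @return An object of class `esl_fit` with elements `beta` (named vector),
#'   `gamma`, `residuals`, `weights` (`exp(-r^2/gamma)`), `objective`,
#'   pseudo-outlier count `m`, `converged`, `n_outer_iters`, per-iteration
#'   `trace` of coefficient-change norms, `gamma_trace`, `m_trace`, and the
#'   `data` it was fitted to. Use [tidy()] / [glance()] / [augment()] for
#'   tibble views.
#' @examples
#' sim <- simulate_dataset(simulation_design(n = 120, contamination = 0.1),
#'                         seed = 1)
#' fit <- fit_esl(sim$data, esl_config(mm = mm_config(seed = 1)))
#' tidy(fit)
#' @export
fit_esl <- function(data, config = esl_config(), beta_init = NULL) {
  assert_regression_data(data)
  if (!inherits(config, "esl_config")) {
    rlang::abort("`config` must come from esl_config()",
                 class = "eslreg_invalid_config")
  }
  check_full_rank(data)
  if (is.null(beta_init)) {
    beta_init <- fit_mm(data, config$mm)
  } else {
    beta_init <- check_beta(beta_init, data)
  }
  res <- cpp_fit_esl(data$X, data$y, as.numeric(beta_init),
                     config$outer_tol, config$max_outer, config$n_grid,
                     config$grid_lo, config$grid_hi,
                     config$inner_tol, config$inner_tol,
                     config$inner_max_iter, 30L)
  if (res$status == "no_feasible_gamma") {
    rlang::abort(
      paste0("no feasible gamma at outer iteration ", res$n_outer,
             "; inspect the attached candidate table"),
      class = "eslreg_no_feasible_gamma",
      table = tibble::as_tibble(res$diagnostics)
    )
  }
  if (res$status != "ok") {
    rlang::abort(
      paste0("degenerate weighted fit at outer iteration ", res$n_outer),
      class = "eslreg_degenerate_fit"
    )
  }
  new_esl_fit(data, beta = drop(res$beta), gamma = res$gamma,
              converged = res$converged, n_outer_iters = res$n_outer,
              trace = as.numeric(res$trace),
              gamma_trace = as.numeric(res$gamma_trace),
              m_trace = as.numeric(res$m_trace))
}
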