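#' Tidy an ESL fit
#'
#' @param x An `esl_fit`.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.esl_fit <- function(x, ...) {
  tibble::tibble(term = names(x$beta), estimate = unname(x$beta))
}

#' One-row summary of an ESL fit
#'
#' @param x An `esl_fit`.
#' @param ... Unused.
#' @return A tibble with `gamma`, pseudo-outlier count `m`, `objective`,
#'   `converged`, `n_outer_iters`, `n`, `p`.
#' @export
glance.esl_fit <- function(x, ...) {
  tibble::tibble(gamma = x$gamma, m = x$m, objective = x$objective,
                 converged = x$converged, n_outer_iters = x$n_outer_iters,
                 n = x$data$n, p = x$data$p)
}

#' Per-observation view of an ESL fit
#'
#' @param x An `esl_fit`.
#' @param ... Unused.
#' @return A tibble with the outcome, fitted value, residual, observation
#'   weight `exp(-r^2/gamma)`, and a pseudo-outlier flag.
#' @export
augment.esl_fit <- function(x, ...) {
  pos <- pseudo_outlier_set(x$residuals)
  flag <- rep(FALSE, length(x$residuals))
  flag[pos$indices] <- TRUE
  tibble::tibble(
    y = x$data$y,
    .fitted = x$data$y - x$residuals,
    .resid = x$residuals,
    .weight = x$weights,
    .pseudo_outlier = flag
  )
}

#' Tidy a bootstrap result
#'
#' @param x An `esl_bootstrap`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `conf.low`, `conf.high`, and
#'   `excludes_zero` (the significance call: the interval lies entirely on
#'   one side of zero).
#' @export
tidy.esl_bootstrap <- function(x, ...) {
  tibble::tibble(
    term = names(x$point),
    estimate = unname(x$point),
    conf.low = unname(x$lower),
    conf.high = unname(x$upper),
    excludes_zero = unname(x$lower > 0 | x$upper < 0)
  )
}

#' One-row summary of a bootstrap result
#'
#' @param x An `esl_bootstrap`.
#' @param ... Unused.
#' @return A tibble with `method`, `B`, `level`, `n_failed`, `unreliable`.
#' @export
glance.esl_bootstrap <- function(x, ...) {
  tibble::tibble(method = x$method, B = x$B, level = x$level,
                 n_failed = x$n_failed, unreliable = x$unreliable)
}
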