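#' Configuration for the MM initial estimator
#'
#' The ESL objective is non-convex, so the pipeline starts from a
#' high-breakdown MM regression estimate. The S-stage scans elemental
#' subsamples of `p` observations, keeps the candidate with the smallest
#' Tukey-bisquare M-scale (tuning `bisquare_c0`, consistency constant 0.5,
#' giving ~50% breakdown) and refines it with reweighting steps; the M-stage
#' then runs bisquare IRLS at `bisquare_c1` (95% Gaussian efficiency) holding
#' the S-scale fixed.
#'
#' @param n_subsamples Number of elemental subsamples in the S-stage.
#' @param bisquare_c0 Bisquare tuning constant of the S-scale (default 1.547,
#'   50% breakdown).
#' @param bisquare_c1 Bisquare tuning constant of the efficiency M-step
#'   (default 4.685, 95% Gaussian efficiency).
#' @param seed Optional integer; when supplied, the subsample sequence is
#'   drawn from this seed and the caller's RNG state is left untouched.
#' @return A list of class `mm_config`.
#' @export
mm_config <- function(n_subsamples = 500, bisquare_c0 = 1.547,
                      bisquare_c1 = 4.685, seed = NULL) {
  if (n_subsamples < 50) {
    rlang::abort("`n_subsamples` must be at least 50",
                 class = "eslreg_invalid_config")
  }
  if (!(bisquare_c0 < bisquare_c1)) {
    rlang::abort("`bisquare_c0` must be smaller than `bisquare_c1`",
                 class = "eslreg_invalid_config")
  }
  structure(list(n_subsamples = as.integer(n_subsamples),
                 bisquare_c0 = bisquare_c0, bisquare_c1 = bisquare_c1,
                 seed = seed),
            class = "mm_config")
}

#' High-breakdown MM regression estimate
#'
#' Used as the initial estimator of the ESL pipeline; see [mm_config()] for
#' the construction. With the same seed the subsample sequence, and hence the
#' result, is identical across runs.
#'
#' @param data A [regression_data()] object with `n > 2p`.
#' @param config An [mm_config()].
#' @return Named numeric coefficient vector of length `data$p`, with the
#'   final S-scale attached as attribute `"scale"`.
#' @export
fit_mm <- function(data, config = mm_config()) {
  assert_regression_data(data)
  if (!inherits(config, "mm_config")) {
    rlang::abort("`config` must come from mm_config()",
                 class = "eslreg_invalid_config")
  }
  check_full_rank(data)
  if (data$n <= 2 * data$p) {
    rlang::abort("MM estimation needs n > 2p observations",
                 class = "eslreg_too_few_observations")
  }
  res <- with_optional_seed(config$seed, {
    cpp_mm(data$X, data$y, config$n_subsamples,
           config$bisquare_c0, config$bisquare_c1)
  })
  if (identical(res$status, "all_subsamples_singular")) {
    rlang::abort("every elemental subsample was singular; cannot initialize",
                 class = "eslreg_degenerate_fit"
    )
  }
  beta <- stats::setNames(drop(res$beta), data$column_names)
  attr(beta, "scale") <- res$scale
  beta
}

# run code under a temporary seed, restoring the caller's RNG state
with_optional_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  code
}
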