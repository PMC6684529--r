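#' Monte-Carlo design for the contamination study
#'
#' Defaults reproduce the benchmark design: n = 300 observations, six
#' independent N(0, 1) covariates, one categorical covariate uniform on
#' {1, ..., 4} dummy-coded with the last category as reference, true
#' coefficients (1, 1.2, 1.4, 1.6, 1.8, 2, 2.2, 2.4, 2.6, 2.8) with the
#' leading 1 the intercept, clean errors N(0, 1), and a contaminated
#' fraction whose errors are drawn from a t distribution with 1 degree of
#' freedom (Cauchy: no finite moments, so least squares breaks down).
#'
#' @param n Sample size.
#' @param beta_true True coefficient vector (intercept first).
#' @param n_continuous Number of standard-normal covariates.
#' @param n_categories Number of levels of the categorical covariate.
#' @param contamination Fraction of rows receiving t(1) errors, in `[0, 0.5]`.
#' @param replications Number of Monte-Carlo replications.
#' @param seed Base seed; replication `r` uses `seed + r`.
#' @return A list of class `simulation_design`.
#' @export
simulation_design <- function(n = 300,
                              beta_true = c(1, 1.2, 1.4, 1.6, 1.8, 2,
                                            2.2, 2.4, 2.6, 2.8),
                              n_continuous = 6, n_categories = 4,
                              contamination = 0, replications = 100,
                              seed = 1) {
  p <- 1 + n_continuous + (n_categories - 1)
  if (length(beta_true) != p) {
    rlang::abort(
      paste0("beta_true must have length 1 + n_continuous + (n_categories",
             " - 1) = ", p),
      class = "eslreg_invalid_design"
    )
  }
  if (contamination < 0 || contamination > 0.5) {
    rlang::abort("`contamination` must lie in [0, 0.5]",
                 class = "eslreg_invalid_design")
  }
  structure(list(n = as.integer(n), beta_true = beta_true,
                 n_continuous = as.integer(n_continuous),
                 n_categories = as.integer(n_categories),
                 contamination = contamination,
                 replications = as.integer(replications),
                 seed = as.integer(seed)),
            class = "simulation_design")
}

design_column_names <- function(design) {
  c("(Intercept)", paste0("x", seq_len(design$n_continuous)),
    paste0("z", seq_len(design$n_categories - 1)))
}

#' Draw one dataset from a simulation design
#'
#' Exactly `round(contamination * n)` rows, chosen by seeded simple random
#' sampling, receive t(1) errors in place of the N(0, 1) error; the rest stay
#' Gaussian.
#'
#' @param design A [simulation_design()].
#' @param seed Integer seed for this draw.
#' @return A list with `data` (a [regression_data()]) and `contaminated`
#'   (logical mask of length `n`).
#' @export
simulate_dataset <- function(design, seed) {
  if (!inherits(design, "simulation_design")) {
    rlang::abort("`design` must come from simulation_design()",
                 class = "eslreg_invalid_design")
  }
  with_optional_seed(seed, {
    n <- design$n
    Xc <- matrix(rnorm(n * design$n_continuous), n, design$n_continuous)
    cat_lvl <- sample.int(design$n_categories, n, replace = TRUE)
    Z <- encode_categorical(cat_lvl, levels = seq_len(design$n_categories),
                            reference = design$n_categories)
    X <- cbind(1, Xc, Z)
    colnames(X) <- design_column_names(design)
    n_bad <- round(design$contamination * n)
    mask <- rep(FALSE, n)
    if (n_bad > 0) mask[sample.int(n, n_bad)] <- TRUE
    eps <- rnorm(n)
    if (n_bad > 0) eps[mask] <- rt(n_bad, df = 1)
    y <- drop(X %*% design$beta_true) + eps
    list(data = regression_data(y, X), contaminated = mask)
  })
}

#' Ordinary least squares comparator
#'
#' Exact normal-equations solution via the QR decomposition, as fitted by
#' [stats::lm.fit()].
#'
#' @param data A [regression_data()] object.
#' @return Named numeric coefficient vector.
#' @export
fit_ols <- function(data) {
  assert_regression_data(data)
  check_full_rank(data)
  stats::setNames(stats::lm.fit(data$X, data$y)$coefficients,
                  data$column_names)
}

#' Run the Monte-Carlo replication study
#'
#' For each replication, draws a dataset with `simulate_dataset(design,
#' design$seed + r)`, fits each estimator, and summarizes the coefficient
#' estimates across replications: Mean, Bias (= mean - truth), SD (sample SD
#' with the R - 1 denominator) and MSE (average squared error, so
#' `mse = bias^2 + sd^2 * (R - 1) / R` exactly).
#'
#' @param design A [simulation_design()].
#' @param estimators Either a character vector from `c("esl", "ols")` or a
#'   named list of functions `f(regression_data) -> coefficient vector`.
#' @param esl_control An [esl_config()] used when `"esl"` is requested; its
#'   MM seed is re-derived per replication for reproducibility.
#' @return A tibble of class `replication_summary` with columns `estimator`,
#'   `term`, `true`, `mean`, `bias`, `sd`, `mse`, and attributes
#'   `replications`, `seed`, `n_failed` (named per estimator).
#' @export
run_replications <- function(design, estimators = c("esl", "ols"),
                             esl_control = esl_config()) {
  if (!inherits(design, "simulation_design")) {
    rlang::abort("`design` must come from simulation_design()",
                 class = "eslreg_invalid_design")
  }
  if (design$replications < 2) {
    rlang::abort("need at least 2 replications",
                 class = "eslreg_invalid_design")
  }
  fns <- resolve_estimators(estimators, esl_control, design$seed)
  R <- design$replications
  draws <- purrr::map(seq_len(R), function(r) {
    sim <- simulate_dataset(design, design$seed + r)
    purrr::imap(fns, function(f, nm) {
      tryCatch(f(sim$data, r), error = function(e) NULL)
    })
  })
  n_failed <- purrr::map_int(names(fns), function(nm) {
    sum(purrr::map_lgl(draws, ~ is.null(.x[[nm]])))
  })
  names(n_failed) <- names(fns)
  if (any(n_failed > 0.10 * R)) {
    rlang::abort("more than 10% of replications failed to fit",
                 class = "eslreg_replication_failure")
  }
  terms <- design_column_names(design)
  summ <- purrr::imap_dfr(fns, function(f, nm) {
    B <- do.call(rbind, purrr::map(draws, nm))  # successful reps x p
    tibble::tibble(
      estimator = nm,
      term = terms,
      true = design$beta_true,
      mean = colMeans(B),
      bias = colMeans(B) - design$beta_true,
      sd = apply(B, 2, stats::sd),
      mse = colMeans((B - matrix(design$beta_true, nrow(B), ncol(B),
                                 byrow = TRUE))^2)
    )
  })
  structure(summ, class = c("replication_summary", class(summ)),
            replications = R, seed = design$seed, n_failed = n_failed)
}

resolve_estimators <- function(estimators, esl_control, base_seed) {
  if (is.character(estimators)) {
    estimators <- match.arg(estimators, c("esl", "ols"), several.ok = TRUE)
    fns <- list()
    if ("esl" %in% estimators) {
      fns$esl <- function(data, r) {
        ctrl <- esl_control
        ctrl$mm <- mm_config(
          n_subsamples = esl_control$mm$n_subsamples,
          bisquare_c0 = esl_control$mm$bisquare_c0,
          bisquare_c1 = esl_control$mm$bisquare_c1,
          seed = (base_seed + r) %% .Machine$integer.max
        )
        fit_esl(data, ctrl)$beta
      }
    }
    if ("ols" %in% estimators) {
      fns$ols <- function(data, r) fit_ols(data)
    }
    return(fns)
  }
  if (is.list(estimators) && !is.null(names(estimators)) &&
      all(nzchar(names(estimators)))) {
    return(purrr::map(estimators, function(f) function(data, r) f(data)))
  }
  rlang::abort("`estimators` must be a character vector or a named list",
               class = "eslreg_invalid_input")
}

#' Plot-ready error-bar table
#'
#' Per estimator and coefficient: the true value, the mean across
#' replications, and mean plus/minus one SD — the quantities shown in the
#' study's error-bar figures. Pass the result to [autoplot()] for the figure.
#'
#' @param summary A [run_replications()] result.
#' @return A tibble with columns `estimator`, `term`, `true`, `mean`,
#'   `lower`, `upper`.
#' @export
error_bar_summary <- function(summary) {
  if (!inherits(summary, "replication_summary")) {
    rlang::abort("`summary` must come from run_replications()",
                 class = "eslreg_invalid_input")
  }
  tibble::tibble(
    estimator = summary$estimator,
    term = summary$term,
    true = summary$true,
    mean = summary$mean,
    lower = summary$mean - summary$sd,
    upper = summary$mean + summary$sd
  )
}

#' Synthetic two-arm RCT dataset with non-normal residuals
#'
#' A stand-in generator for a multi-centre randomized controlled trial of
#' cognitive decline: age, BMI, a baseline cognitive score (`adas1`), eight
#' centres (dummy-coded, centre 8 the reference), binary gender, education,
#' occupation and prior-drug indicators, a binary treatment arm, and an
#' outcome (score change) whose error is a 90/10 mixture of N(0, sigma^2)
#' and scaled heavy-tailed t noise, so residual-normality tests reject. All
#' data are synthetic; marginals loosely match a phase-III MCI trial
#' (age ~ N(63, 8^2), baseline score ~ N(15, 6^2), 2:1 arm ratio).
#'
#' @param n_treatment,n_control Arm sizes (each at least 20).
#' @param seed Integer seed; the same seed reproduces the table exactly.
#' @param treatment_effect Coefficient of the treatment indicator in the
#'   generating model (default 0: a null trial).
#' @return A [regression_data()] whose design carries the dummy-coded
#'   covariates; the subject-level tibble is attached as attribute `"table"`
#'   and the generating coefficients as attribute `"beta_true"`.
#' @export
mci_like_fixture <- function(n_treatment, n_control, seed,
                             treatment_effect = 0) {
  if (n_treatment < 20 || n_control < 20) {
    rlang::abort("both arms need at least 20 subjects",
                 class = "eslreg_invalid_design")
  }
  with_optional_seed(seed, {
    n <- n_treatment + n_control
    group <- c(rep(1L, n_treatment), rep(0L, n_control))
    centre_prob <- c(33, 12, 48, 36, 36, 72, 36, 47)
    df <- tibble::tibble(
      group = group,
      age = rnorm(n, 63, 8),
      bmi = rnorm(n, 24, 2.5),
      adas1 = rnorm(n, 15, 6),
      centre = sample(1:8, n, replace = TRUE,
                      prob = centre_prob / sum(centre_prob)),
      gender = rbinom(n, 1, 0.58),
      education = rbinom(n, 1, 0.79),
      occupation = rbinom(n, 1, 0.73),
      drug = rbinom(n, 1, 0.29)
    )
    Z <- encode_categorical(df$centre, levels = 1:8, reference = 8)
    colnames(Z) <- paste0("centre", 1:7)
    X <- cbind(`(Intercept)` = 1, age = df$age, bmi = df$bmi,
               adas1 = df$adas1, group = df$group, Z,
               gender = df$gender, education = df$education,
               occupation = df$occupation, drug = df$drug)
    beta <- c(`(Intercept)` = 0.25, age = -0.05, bmi = 0.07, adas1 = 0.31,
              group = treatment_effect,
              centre1 = 0.0, centre2 = 1.8, centre3 = 1.4, centre4 = -0.5,
              centre5 = 0.6, centre6 = 2.4, centre7 = 1.5,
              gender = -0.5, education = 0.4, occupation = -0.25,
              drug = -0.1)
    stopifnot(identical(names(beta), colnames(X)))
    heavy <- rbinom(n, 1, 0.10) == 1
    eps <- rnorm(n, 0, 2.5)
    eps[heavy] <- 2.5 * rt(sum(heavy), df = 2)
    y <- drop(X %*% beta) + eps
    df$adasfa <- y
    out <- regression_data(y, X)
    attr(out, "table") <- df
    attr(out, "beta_true") <- beta
    out
  })
}
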