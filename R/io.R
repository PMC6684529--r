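#' Declare a regression model over a subject-level table
#'
#' A model specification names the outcome, the continuous covariates, the
#' categorical covariates with their level order and reference level, an
#' optional binary treatment-arm column, and optional derived columns (e.g.
#' BMI from weight and height). [build_regression_data()] and [read_table()]
#' turn a table plus a spec into a [regression_data()] design with the
#' intercept first, continuous columns next (in declared order), then the
#' treatment indicator, then the categorical dummies.
#'
#' @param outcome Name of the outcome column.
#' @param continuous Character vector of continuous covariate names (may
#'   include derived columns).
#' @param categorical Named list; each element is
#'   `list(levels = ..., reference = ...)` for one categorical column. The
#'   reference level maps to the all-zero dummy row and dummy columns follow
#'   the declared level order.
#' @param treatment Optional name of the binary (0/1) treatment-arm column.
#' @param derive Named list of one-sided formulas evaluated in the table,
#'   e.g. `list(bmi = ~ weight / (height / 100)^2)` with height in cm.
#' @return A list of class `esl_model_spec`.
#' @examples
#' spec <- model_spec(
#'   outcome = "adasfa",
#'   continuous = c("age", "adas1"),
#'   categorical = list(centre = list(levels = 1:8, reference = 8)),
#'   treatment = "group"
#' )
#' @export
model_spec <- function(outcome, continuous = character(),
                       categorical = list(), treatment = NULL,
                       derive = list()) {
  if (length(categorical) > 0 &&
      (is.null(names(categorical)) || any(!nzchar(names(categorical))))) {
    rlang::abort("`categorical` must be a named list",
                 class = "eslreg_invalid_spec")
  }
  for (nm in names(categorical)) {
    el <- categorical[[nm]]
    if (!all(c("levels", "reference") %in% names(el))) {
      rlang::abort(paste0("categorical entry '", nm,
                          "' needs `levels` and `reference`"),
                   class = "eslreg_invalid_spec")
    }
    if (!el$reference %in% el$levels) {
      rlang::abort(paste0("reference level of '", nm,
                          "' is not among its declared levels"),
                   class = "eslreg_invalid_spec")
    }
  }
  cols <- c(outcome, continuous, names(categorical), treatment)
  if (anyDuplicated(cols)) {
    rlang::abort("a column is listed twice in the model specification",
                 class = "eslreg_invalid_spec")
  }
  structure(list(outcome = outcome, continuous = continuous,
                 categorical = categorical, treatment = treatment,
                 derive = derive),
            class = "esl_model_spec")
}

#' Dummy-code a categorical column
#'
#' `k` declared levels become `k - 1` binary indicator columns in declared
#' level order; the reference level maps to the all-zero row.
#'
#' @param values Vector of observed values.
#' @param levels Ordered vector of declared levels.
#' @param reference The reference level (must be among `levels`).
#' @return An integer matrix with `length(values)` rows and `k - 1` columns,
#'   named `<level>` for each non-reference level.
#' @examples
#' encode_categorical(c(1, 4, 2), levels = 1:4, reference = 4)
#' @export
encode_categorical <- function(values, levels, reference) {
  if (!reference %in% levels) {
    rlang::abort("`reference` must be one of `levels`",
                 class = "eslreg_invalid_spec")
  }
  unseen <- setdiff(unique(values), levels)
  if (length(unseen) > 0) {
    rlang::abort(paste0("undeclared level(s): ",
                        paste(unseen, collapse = ", ")),
                 class = "eslreg_unseen_level")
  }
  keep <- levels[levels != reference]
  Z <- vapply(keep, function(l) as.integer(values == l),
              integer(length(values)))
  Z <- matrix(Z, nrow = length(values),
              dimnames = list(NULL, as.character(keep)))
  Z
}

#' Build a regression design from a data frame and a model specification
#'
#' Applies the declared derivations, drops rows with missing values in any
#' model column (reporting the count), encodes categoricals, and assembles
#' `y` and `X` with the intercept first, continuous covariates next, then
#' the treatment indicator, then the dummies.
#'
#' @param df A data frame.
#' @param spec An [model_spec()].
#' @return A [regression_data()] object.
#' @export
build_regression_data <- function(df, spec) {
  if (!inherits(spec, "esl_model_spec")) {
    rlang::abort("`spec` must come from model_spec()",
                 class = "eslreg_invalid_spec")
  }
  df <- tibble::as_tibble(df)
  for (nm in names(spec$derive)) {
    df[[nm]] <- rlang::eval_tidy(rlang::f_rhs(spec$derive[[nm]]), data = df)
  }
  needed <- c(spec$outcome, spec$continuous, names(spec$categorical),
              spec$treatment)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    rlang::abort(paste0("missing column(s): ",
                        paste(missing_cols, collapse = ", ")),
                 class = "eslreg_missing_columns")
  }
  complete <- stats::complete.cases(df[needed])
  if (any(!complete)) {
    rlang::inform(paste0("dropping ", sum(!complete),
                         " row(s) with missing values in model columns"))
    df <- df[complete, ]
  }
  if (nrow(df) == 0) {
    rlang::abort("no complete rows left after filtering",
                 class = "eslreg_empty_data")
  }
  y <- as.numeric(df[[spec$outcome]])
  parts <- list(`(Intercept)` = rep(1, nrow(df)))
  for (nm in spec$continuous) parts[[nm]] <- as.numeric(df[[nm]])
  if (!is.null(spec$treatment)) {
    tr <- df[[spec$treatment]]
    utr <- sort(unique(tr))
    if (length(utr) > 2) {
      rlang::abort("treatment column is not binary",
                   class = "eslreg_invalid_spec")
    }
    parts[[spec$treatment]] <- as.integer(tr == max(utr))
  }
  X <- do.call(cbind, parts)
  for (nm in names(spec$categorical)) {
    el <- spec$categorical[[nm]]
    Z <- encode_categorical(df[[nm]], el$levels, el$reference)
    colnames(Z) <- paste0(nm, colnames(Z))
    X <- cbind(X, Z)
  }
  regression_data(y, X)
}

#' Read a delimited table and build the regression design
#'
#' Accepts comma- or tab-separated text with a header row (the delimiter is
#' auto-detected from the first line).
#'
#' @param path Path to the delimited file.
#' @param spec An [model_spec()].
#' @return A [regression_data()] object.
#' @export
read_table <- function(path, spec) {
  first <- readLines(path, n = 1L)
  delim <- if (grepl("\t", first)) "\t" else ","
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  build_regression_data(df, spec)
}

#' Write a fitted model's coefficient table to CSV and JSON
#'
#' The CSV holds the coefficient table at full precision (re-reading it
#' reproduces the estimates bit-exactly); the JSON carries the same table
#' plus fit metadata (selected gamma, pseudo-outlier count, convergence,
#' schema version).
#'
#' @param fit An `esl_fit` object.
#' @param path_csv,path_json Output paths; either may be `NULL` to skip.
#' @return The coefficient tibble, invisibly.
#' @export
write_results <- function(fit, path_csv = NULL, path_json = NULL) {
  if (!inherits(fit, "esl_fit")) {
    rlang::abort("`fit` must be an esl_fit", class = "eslreg_invalid_input")
  }
  tab <- tidy(fit)
  if (!is.null(path_csv)) readr::write_csv(tab, path_csv)
  if (!is.null(path_json)) {
    jsonlite::write_json(
      list(schema_version = "1.0",
           coefficients = tab,
           gamma = fit$gamma, m = fit$m, objective = fit$objective,
           converged = fit$converged, n_outer_iters = fit$n_outer_iters),
      path_json, auto_unbox = TRUE, digits = NA
    )
  }
  invisible(tab)
}
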