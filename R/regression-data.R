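#' Bundle an outcome vector and design matrix for regression
#'
#' `regression_data()` is the light container every fitter in eslreg consumes:
#' a numeric outcome `y` and a design matrix `X` whose first column is the
#' intercept (all ones). Most users will not call it directly but build it
#' from a data frame with [build_regression_data()] or get one from
#' [simulate_dataset()].
#'
#' @param y Numeric outcome vector of length `n`.
#' @param X Numeric design matrix with `n` rows; the first column must be the
#'   intercept column of ones.
#' @param column_names Optional character vector of coefficient labels; taken
#'   from `colnames(X)` when present, otherwise `(Intercept)`, `x1`, ...
#'
#' @return An object of class `regression_data`: a list with elements `y`,
#'   `X`, `column_names`, `n` and `p`.
#' @examples
#' X <- cbind(1, rnorm(20))
#' d <- regression_data(rnorm(20), X)
#' d$n
#' @export
regression_data <- function(y, X, column_names = NULL) {
  y <- as.numeric(y)
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (length(y) != nrow(X)) {
    stop("length(y) must equal nrow(X)", call. = FALSE)
  }
  if (nrow(X) <= ncol(X)) {
    stop("need more observations than coefficients (n > p)", call. = FALSE)
  }
  if (anyNA(y) || anyNA(X)) {
    stop("regression_data does not accept missing values; drop or impute first",
         call. = FALSE)
  }
  if (any(X[, 1] != 1)) {
    stop("the first column of X must be an intercept column of ones",
         call. = FALSE)
  }
  if (is.null(column_names)) {
    column_names <- colnames(X)
    if (is.null(column_names)) {
      column_names <- c("(Intercept)",
                        if (ncol(X) > 1L)
                          paste0("x", seq_len(ncol(X) - 1L)))
    }
  }
  if (length(column_names) != ncol(X)) {
    stop("column_names must have one entry per column of X", call. = FALSE)
  }
  colnames(X) <- column_names
  structure(
    list(y = y, X = X, column_names = column_names,
         n = nrow(X), p = ncol(X)),
    class = "regression_data"
  )
}

#' @export
print.regression_data <- function(x, ...) {
  cat("<regression_data> n =", x$n, ", p =", x$p, "\n")
  cat("  columns:", paste(x$column_names, collapse = ", "), "\n")
  invisible(x)
}

# Fitters call this: rank deficiency is an error, not a warning.
check_full_rank <- function(data) {
  r <- qr(data$X)$rank
  if (r < data$p) {
    rlang::abort(
      paste0("design matrix is rank-deficient (rank ", r, " < p = ",
             data$p, ")"),
      class = "eslreg_rank_deficient"
    )
  }
  invisible(TRUE)
}

assert_regression_data <- function(data) {
  if (!inherits(data, "regression_data")) {
    stop("`data` must be a regression_data object; see build_regression_data()",
         call. = FALSE)
  }
  invisible(TRUE)
}
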