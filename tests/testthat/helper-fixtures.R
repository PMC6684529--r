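# In-code fixtures shared across test files.

# data the model fits exactly: y = X %*% beta with no noise
exact_fit_data <- function(n = 40, p = 4, seed = 1) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
  beta <- seq_len(p)
  list(data = regression_data(drop(X %*% beta), X), beta = beta)
}

# a generic noisy instance; contamination shifts a fraction of y by `shift`
noisy_instance <- function(n = 50, p = 3, seed = 1, sd = 1,
                           contaminate = 0, shift = 50) {
  set.seed(seed)
  X <- cbind(1, matrix(rnorm(n * (p - 1)), n, p - 1))
  beta <- rnorm(p)
  y <- drop(X %*% beta) + rnorm(n, 0, sd)
  if (contaminate > 0) {
    idx <- sample.int(n, round(contaminate * n))
    y[idx] <- y[idx] + shift
  }
  list(data = regression_data(y, X), beta = beta)
}

ols_solve <- function(data) {
  drop(solve(crossprod(data$X), crossprod(data$X, data$y)))
}
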