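#' Configuration of the general location simulation
#'
#' Describes the three-variable generating model used throughout the
#' package's simulation study: a binary `Y ~ Bernoulli(gamma)` and two
#' continuous variables
#' `W1 | Y ~ N(mu_w1 + beta*Y, var_w1)` and
#' `W2 | W1, Y ~ N(intercept_w2 + slope_w1*W1 + beta*Y, var_w2)`.
#' The defaults are the study conditions: gamma = 3/10, W1 intercept 10
#' with variance 9, W2 intercept 9 + 8/9, slope 1/9 on W1 and residual
#' variance 8 + 8/9, with n = 100 subjects of which the first 50 have Y
#' and W1 set missing completely at random.
#'
#' @param n number of subjects.
#' @param beta effect of Y on both W1 and W2 (the analysis-model
#'   coefficient of interest); the study uses 1 and 3.
#' @param gamma Bernoulli success probability of Y.
#' @param mu_w1,var_w1 intercept and residual variance of W1 | Y.
#' @param intercept_w2,slope_w1,var_w2 intercept, W1 slope and residual
#'   variance of W2 | W1, Y.
#' @param n_missing number of leading rows whose Y and W1 are masked.
#' @param seed optional RNG seed for reproducibility.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(n = 100L, beta = 1, gamma = 3 / 10,
                       mu_w1 = 10, var_w1 = 9,
                       intercept_w2 = 9 + 8 / 9, slope_w1 = 1 / 9,
                       var_w2 = 8 + 8 / 9,
                       n_missing = NULL, seed = NULL) {
  n <- as.integer(n)
  if (is.null(n_missing)) n_missing <- n %/% 2L   # study: 50 of 100
  n_missing <- as.integer(n_missing)
  if (n < 1L) stop("n must be positive")
  if (!(gamma > 0 && gamma < 1)) stop("gamma must lie in (0, 1)")
  if (var_w1 <= 0 || var_w2 <= 0) stop("variances must be positive")
  if (n_missing < 0L || n_missing > n)
    stop("n_missing must lie in [0, n]")
  structure(list(n = n, beta = beta, gamma = gamma, mu_w1 = mu_w1,
                 var_w1 = var_w1, intercept_w2 = intercept_w2,
                 slope_w1 = slope_w1, var_w2 = var_w2,
                 n_missing = n_missing, seed = seed),
            class = "sim_config")
}

#' Simulate a complete dataset from the general location model
#'
#' Rows are iid draws of (Y, W1, W2) under the model described in
#' [sim_config()].  The result is fully observed; apply
#' [apply_mcar_mask()] to install the study's missingness pattern.
#'
#' @param config a [sim_config()].
#' @return a fully observed [md_dataset] with columns `Y`, `W1`, `W2`.
#' @export
simulate_complete <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  y  <- stats::rbinom(n, 1L, config$gamma)
  w1 <- stats::rnorm(n, config$mu_w1 + config$beta * y,
                     sqrt(config$var_w1))
  w2 <- stats::rnorm(n, config$intercept_w2 + config$slope_w1 * w1 +
                       config$beta * y, sqrt(config$var_w2))
  md_dataset(cbind(Y = y, W1 = w1, W2 = w2),
             types = c("binary", "continuous", "continuous"))
}

#' Set leading rows of selected columns missing completely at random
#'
#' Masks rows `1..n_missing` of `target_columns`.  The missingness is
#' MCAR by design: which rows are masked does not depend on any value.
#' The pre-masking values are retained in the dataset's `truth` field for
#' validation only and are never visible to imputation routines.
#'
#' @param data a fully observed [md_dataset].
#' @param n_missing how many leading rows to mask.
#' @param target_columns column names to mask; default `c("Y", "W1")`.
#' @return an [md_dataset] with the mask applied.
#' @export
apply_mcar_mask <- function(data, n_missing,
                            target_columns = c("Y", "W1")) {
  stopifnot(inherits(data, "md_dataset"))
  n_missing <- as.integer(n_missing)
  if (n_missing > nrow(data$values)) stop("n_missing exceeds row count")
  if (!all(target_columns %in% colnames(data$values)))
    stop("unknown target column")
  truth <- if (is.null(data$truth)) data$values else data$truth
  mask <- data$mask
  if (n_missing > 0L)
    mask[seq_len(n_missing), target_columns] <- FALSE
  values <- data$values
  values[!mask] <- NA_real_
  md_dataset(values, mask = mask, types = data$types, truth = truth)
}

#' Simulate the study's masked dataset in one call
#'
#' Convenience wrapper: [simulate_complete()] followed by
#' [apply_mcar_mask()] with the config's `n_missing`.
#'
#' @param config a [sim_config()].
#' @return a masked [md_dataset].
#' @export
simulate_masked <- function(config) {
  apply_mcar_mask(simulate_complete(config), config$n_missing)
}
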