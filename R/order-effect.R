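#' Analysis-model fit: one OLS coefficient from a completed dataset
#'
#' Ordinary least squares of `response` on `covariates` (intercept
#' included) on the full data, returning the coefficient named `coef` —
#' by default the Y coefficient of the regression of W2 on W1 and Y.
#'
#' @param data a completed [md_dataset] or a numeric value matrix with
#'   named columns.
#' @param response,covariates,coef column names.
#' @return a single OLS coefficient.
#' @export
analysis_fit <- function(data, response = "W2", covariates = c("W1", "Y"),
                         coef = "Y") {
  vals <- if (inherits(data, "md_dataset")) data$values else as.matrix(data)
  if (anyNA(vals[, c(response, covariates)]))
    stop("analysis_fit requires completed data")
  b <- ols_coef(vals[, response], vals[, covariates, drop = FALSE])
  b[[1L + match(coef, covariates)]]
}

#' Batch-means Monte Carlo standard error
#'
#' Splits a (serially correlated) series into `n_batches` consecutive
#' batches of equal length and estimates the Monte Carlo standard error
#' of the series mean as `sd(batch means) / sqrt(n_batches)`.
#'
#' @param x numeric series.
#' @param n_batches number of batches; the series length must be an
#'   exact multiple, with batches of length at least 2.
#' @return the MCSE of `mean(x)`.
#' @export
batch_means_se <- function(x, n_batches) {
  n <- length(x); n_batches <- as.integer(n_batches)
  if (n_batches < 2L) stop("need at least 2 batches")
  if (n %% n_batches != 0L)
    stop("series length must be divisible into equal batches")
  if (n / n_batches < 2L) stop("batches must have length >= 2")
  bm <- colMeans(matrix(x, ncol = n_batches))
  stats::sd(bm) / sqrt(n_batches)
}

# Default batch count: the largest divisor of the series length not
# exceeding floor(sqrt(length)) (100 batches for the study's 10000
# retained iterations), so batches are long and nearly independent.
default_n_batches <- function(n) {
  for (k in seq.int(min(floor(sqrt(n)), n %/% 2L), 2L))
    if (n %% k == 0L) return(k)
  stop("series too short for batch means")
}

#' Order-effect estimate for one imputation run
#'
#' The augmented chained-equations sampler records two analysis-model
#' estimates per iteration: one taken immediately after updating the
#' first-visited variable (beta_b) and one after the second (beta_c).
#' A systematic difference between their long-run means is an order
#' effect.  This test computes both means, the per-iteration difference
#' series d_t = beta_b_t - beta_c_t, its mean, a batch-means MCSE, the
#' 95% normal-theory confidence interval mean +/- 1.96 * MCSE, and a
#' significance flag (interval excludes zero).
#'
#' @param x an `imputation_trace` from [run_chain()] (uses the first
#'   hook's records for the first two visited columns), or a numeric
#'   vector of beta_b values.
#' @param beta_c numeric vector of beta_c values when `x` is a vector.
#' @param n_batches batch count; defaults to the largest divisor of the
#'   series length not exceeding the square root of the length.
#' @return an object of class `order_effect_result` with fields
#'   `beta_bar_b`, `beta_bar_c`, `diff`, `mcse`, `ci_low`, `ci_high`,
#'   `significant`, `n`.
#' @export
order_effect_test <- function(x, beta_c = NULL, n_batches = NULL) {
  if (inherits(x, "imputation_trace")) {
    rec <- x$records[[1L]]
    if (ncol(rec) < 2L)
      stop("trace must carry records for two updated variables")
    beta_b <- rec[, 1L]
    beta_c <- rec[, 2L]
  } else {
    beta_b <- as.numeric(x)
  }
  if (length(beta_b) == 0L) stop("empty trace")
  if (length(beta_b) != length(beta_c))
    stop("beta_b and beta_c must be paired")
  d <- beta_b - beta_c
  if (is.null(n_batches)) n_batches <- default_n_batches(length(d))
  mcse <- batch_means_se(d, n_batches)
  diff <- mean(d)
  ci <- diff + c(-1, 1) * 1.96 * mcse
  structure(list(beta_bar_b = mean(beta_b), beta_bar_c = mean(beta_c),
                 diff = diff, mcse = mcse, ci_low = ci[1L],
                 ci_high = ci[2L],
                 significant = ci[1L] > 0 || ci[2L] < 0,
                 n = length(d), n_batches = n_batches),
            class = "order_effect_result")
}

#' @export
print.order_effect_result <- function(x, ...) {
  cat(sprintf(paste0("order effect: diff = %.5f (MCSE %.5f), 95%% CI ",
                     "[%.5f, %.5f]%s\n"),
              x$diff, x$mcse, x$ci_low, x$ci_high,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Count significant order effects
#'
#' @param results list of `order_effect_result`s, or a data frame with a
#'   logical `significant` column.
#' @return number of results whose 95% CI excludes zero.
#' @export
count_significant <- function(results) {
  if (is.data.frame(results)) return(sum(results$significant))
  if (length(results) == 0L) stop("empty result list")
  sum(vapply(results, function(r) isTRUE(r$significant), logical(1)))
}

#' Forest plot of per-dataset order effects
#'
#' One row per dataset: the estimated order effect (difference of the
#' two within-iteration analysis estimates) with its 95% batch-means
#' confidence interval; intervals excluding zero are drawn solid.
#'
#' @param results list of `order_effect_result`s or a data frame with
#'   columns `diff`, `ci_low`, `ci_high`.
#' @param max_datasets plot at most this many leading datasets.
#' @param ... passed to [graphics::plot()].
#' @export
plot_order_effects <- function(results, max_datasets = 30L, ...) {
  if (!is.data.frame(results))
    results <- do.call(rbind, lapply(results, function(r)
      data.frame(diff = r$diff, ci_low = r$ci_low, ci_high = r$ci_high)))
  results <- utils::head(results, max_datasets)
  k <- nrow(results)
  ylim <- rev(range(seq_len(k)))
  graphics::plot(results$diff, seq_len(k), xlim = range(results$ci_low,
                                                        results$ci_high, 0),
                 ylim = ylim, pch = 15, xlab = "order effect (beta_b - beta_c)",
                 ylab = "dataset", ...)
  sig <- results$ci_low > 0 | results$ci_high < 0
  graphics::segments(results$ci_low, seq_len(k), results$ci_high,
                     seq_len(k), lty = ifelse(sig, 1, 3))
  graphics::abline(v = 0, col = "grey50")
  invisible(results)
}
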