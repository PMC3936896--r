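#' Joint-model imputation by data augmentation under the general location model
#'
#' Tanner-Wong data augmentation: starting from missing cells filled by
#' random draws of observed values ([initialize_missing()]), each
#' iteration draws theta from the complete-data posterior
#' ([draw_theta_complete()]) and then redraws the missing cells from
#' their posterior predictive given theta ([draw_missing_glom()]).
#' After `burn_in` iterations one completed dataset is retained every
#' `thin` iterations until `m` have been collected, so the total number
#' of iterations is `burn_in + m * thin` (the study's schedule
#' m = burn_in = thin = 100 gives 10100).  The first dataset is retained
#' one full thinning gap after the burn-in ends.
#'
#' @param data an [md_dataset] with exactly one binary column.
#' @param prior a [glom_prior()].
#' @param m number of completed datasets.
#' @param burn_in discarded leading iterations.
#' @param thin iterations between retained datasets.
#' @param seed optional RNG seed.
#' @return list of `m` completed [md_dataset]s.
#' @export
run_data_augmentation <- function(data, prior = glom_prior(), m = 100L,
                                  burn_in = 100L, thin = 100L,
                                  seed = NULL) {
  stopifnot(inherits(data, "md_dataset"))
  m <- as.integer(m); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (m < 1L || thin < 1L || burn_in < 0L)
    stop("m >= 1, thin >= 1 and burn_in >= 0 required")
  if (!is.null(seed)) set.seed(seed)
  if (is_complete(data)) return(rep(list(data), m))
  cur <- initialize_missing(data)
  out <- vector("list", m)
  k <- 0L
  total <- burn_in + m * thin
  for (t in seq_len(total)) {
    theta <- draw_theta_complete(cur, prior)
    cur <- draw_missing_glom(data, theta)
    if (t > burn_in && (t - burn_in) %% thin == 0L) {
      k <- k + 1L
      out[[k]] <- cur
    }
  }
  out
}

#' Pool analysis-model estimates across completed datasets
#'
#' Fits the analysis regression (by default W2 on W1 and Y) by least
#' squares on each completed dataset and returns the mean of the chosen
#' coefficient across datasets — the study pools point estimates only.
#'
#' @param completed list of completed [md_dataset]s.
#' @param response,covariates,coef analysis-model columns.
#' @return pooled (mean) coefficient, a single number.
#' @export
pool_estimates <- function(completed, response = "W2",
                           covariates = c("W1", "Y"), coef = "Y") {
  if (length(completed) < 1L) stop("need at least one completed dataset")
  ests <- vapply(completed, analysis_fit, numeric(1),
                 response = response, covariates = covariates,
                 coef = coef)
  mean(ests)
}
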