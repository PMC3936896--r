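#' Configuration of the order-effect simulation study
#'
#' The full study design: `n_datasets` replicate datasets per value of
#' `beta`, each simulated from the general location model
#' ([sim_config()]) and masked MCAR, then analysed by each requested
#' arm on the identical masked data:
#' \describe{
#'   \item{CCA}{complete-case analysis — OLS of W2 on (W1, Y) on the
#'     fully observed rows.}
#'   \item{JM}{joint-model imputation by data augmentation under the
#'     general location model, point estimates pooled across `jm_m`
#'     completed datasets.}
#'   \item{CE_LR}{augmented chained equations with the logistic
#'     conditional for Y, visit order (Y, W1), with the order-effect
#'     diagnostic.}
#'   \item{CE_LDA}{as CE_LR with the linear-discriminant conditional
#'     for Y.}
#' }
#' Defaults reproduce the published design: 500 datasets of n = 100
#' (first 50 rows missing Y and W1), CE chains of 10010 iterations with
#' 10 burn-in, JM schedule 100/100/100, proper imputation, prior
#' tau = nu = 1/2 and kappa = 3/2.
#'
#' @param n_datasets replicate datasets per beta value.
#' @param n sample size per dataset.
#' @param beta vector of effect sizes (the study uses c(1, 3)).
#' @param n_missing rows masked per dataset (default n/2).
#' @param arms subset of c("CCA", "JM", "CE_LR", "CE_LDA").
#' @param ce_n_iter,ce_burn_in,ce_thin chained-equations schedule.
#' @param jm_m,jm_burn_in,jm_thin data-augmentation schedule.
#' @param proper `FALSE` runs the improper (ML plug-in) variant.
#' @param prior a [glom_prior()].
#' @param n_batches batch count for the order-effect MCSE (default:
#'   largest divisor of the retained length not exceeding its square
#'   root; 100 for the full 10000).
#' @param seed base RNG seed; per-dataset and per-arm substreams are
#'   derived from it so that every arm sees the same datasets and the
#'   arm execution order is immaterial.
#' @return an object of class `study_config`.
#' @export
study_config <- function(n_datasets = 500L, n = 100L, beta = c(1, 3),
                         n_missing = NULL,
                         arms = c("CCA", "JM", "CE_LR", "CE_LDA"),
                         ce_n_iter = 10010L, ce_burn_in = 10L,
                         ce_thin = 1L,
                         jm_m = 100L, jm_burn_in = 100L, jm_thin = 100L,
                         proper = TRUE, prior = glom_prior(),
                         n_batches = NULL, seed = 1L) {
  arms <- match.arg(arms, several.ok = TRUE)
  if (is.null(n_missing)) n_missing <- as.integer(n) %/% 2L
  if (n_datasets < 1L) stop("n_datasets must be >= 1")
  structure(list(n_datasets = as.integer(n_datasets), n = as.integer(n),
                 beta = beta, n_missing = as.integer(n_missing),
                 arms = arms, ce_n_iter = as.integer(ce_n_iter),
                 ce_burn_in = as.integer(ce_burn_in),
                 ce_thin = as.integer(ce_thin),
                 jm_m = as.integer(jm_m),
                 jm_burn_in = as.integer(jm_burn_in),
                 jm_thin = as.integer(jm_thin), proper = proper,
                 prior = prior, n_batches = n_batches,
                 seed = as.integer(seed)),
            class = "study_config")
}

#' Complete-case estimate of the analysis-model Y coefficient
#'
#' OLS of W2 on (W1, Y) restricted to the rows with no missing values.
#'
#' @param data an [md_dataset].
#' @inheritParams analysis_fit
#' @return a single coefficient.
#' @export
complete_case_estimate <- function(data, response = "W2",
                                   covariates = c("W1", "Y"),
                                   coef = "Y") {
  cc <- complete_rows(data)
  if (sum(cc) < 4L) stop("fewer than 4 complete rows")
  analysis_fit(data$values[cc, , drop = FALSE], response, covariates,
               coef)
}

ce_specs <- function(y_family, proper, prior) {
  list(conditional_spec("Y", c("W1", "W2"), y_family, proper = proper,
                        prior = prior),
       conditional_spec("W1", c("Y", "W2"), "normal_linear",
                        proper = proper))
}

run_arm <- function(arm, data, cfg) {
  if (arm == "CCA")
    return(list(est = complete_case_estimate(data)))
  if (is_complete(data))               # nothing to impute in any arm
    return(list(est = analysis_fit(data)))
  if (arm == "JM") {
    completed <- run_data_augmentation(data, cfg$prior, cfg$jm_m,
                                       cfg$jm_burn_in, cfg$jm_thin)
    return(list(est = pool_estimates(completed)))
  }
  fam <- if (arm == "CE_LR") "logistic_mvn" else "lda_glom"
  tr <- run_chain(data, ce_specs(fam, cfg$proper, cfg$prior),
                  chain_config(cfg$ce_n_iter, cfg$ce_burn_in,
                               cfg$ce_thin,
                               visit_order = c("Y", "W1")))
  oe <- order_effect_test(tr, n_batches = cfg$n_batches)
  list(est = mean(c(oe$beta_bar_b, oe$beta_bar_c)), oe = oe,
       separation = tr$separation_events)
}

#' Run the order-effect simulation study
#'
#' For each beta value and each replicate dataset: simulate from the
#' general location model, apply the MCAR mask, and run every requested
#' arm on the identical masked dataset with its own RNG substream (so
#' arm order is immaterial and results are reproducible).  Arm failures
#' are caught and counted; the study continues.
#'
#' @param cfg a [study_config()].
#' @param out_dir optional directory; per-dataset results are appended
#'   to `per_dataset.csv` there so long runs can be inspected/resumed.
#' @param verbose print a line per completed dataset block.
#' @return an object of class `study_summary`: list with `per_dataset`
#'   (one row per dataset x arm) and `summary` (per arm and beta: mean
#'   estimate with the across-dataset 95% CI mean +/- 1.96 sd/sqrt(D);
#'   for CE arms also mean beta_bar_b / beta_bar_c, mean |beta_bar_b -
#'   beta_bar_c| with CIs, and the count of datasets with a significant
#'   order effect).
#' @export
run_study <- function(cfg, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(cfg, "study_config"))
  rows <- list()
  for (b in cfg$beta) {
    set.seed(cfg$seed + 1000L * match(b, cfg$beta))
    dataset_seeds <- sample.int(.Machine$integer.max - 1L,
                                cfg$n_datasets)
    for (i in seq_len(cfg$n_datasets)) {
      set.seed(dataset_seeds[i])
      arm_seeds <- sample.int(.Machine$integer.max - 1L, 4L)
      names(arm_seeds) <- c("CCA", "JM", "CE_LR", "CE_LDA")
      data <- simulate_masked(sim_config(n = cfg$n, beta = b,
                                         n_missing = cfg$n_missing))
      for (arm in cfg$arms) {
        set.seed(arm_seeds[[arm]])
        res <- tryCatch(run_arm(arm, data, cfg), error = identity)
        failed <- inherits(res, "error")
        oe <- if (!failed && !is.null(res$oe)) res$oe else NULL
        rows[[length(rows) + 1L]] <- data.frame(
          beta = b, dataset = i, arm = arm,
          est = if (failed) NA_real_ else res$est,
          beta_bar_b = if (is.null(oe)) NA_real_ else oe$beta_bar_b,
          beta_bar_c = if (is.null(oe)) NA_real_ else oe$beta_bar_c,
          diff = if (is.null(oe)) NA_real_ else oe$diff,
          abs_diff = if (is.null(oe)) NA_real_ else abs(oe$diff),
          mcse = if (is.null(oe)) NA_real_ else oe$mcse,
          ci_low = if (is.null(oe)) NA_real_ else oe$ci_low,
          ci_high = if (is.null(oe)) NA_real_ else oe$ci_high,
          significant = if (is.null(oe)) NA else oe$significant,
          failed = failed)
      }
      if (verbose && i %% 25L == 0L)
        message(sprintf("beta = %g: %d/%d datasets done", b, i,
                        cfg$n_datasets))
    }
  }
  per_dataset <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(per_dataset, file.path(out_dir, "per_dataset.csv"),
                     row.names = FALSE)
  }
  summary <- summarize_study(per_dataset)
  if (!is.null(out_dir))
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE)
  structure(list(per_dataset = per_dataset, summary = summary,
                 config = cfg),
            class = "study_summary")
}

mean_ci <- function(x) {
  x <- x[!is.na(x)]
  half <- 1.96 * stats::sd(x) / sqrt(length(x))
  c(mean = mean(x), lo = mean(x) - half, hi = mean(x) + half)
}

summarize_study <- function(per_dataset) {
  out <- list()
  for (b in unique(per_dataset$beta)) {
    for (arm in unique(per_dataset$arm)) {
      d <- per_dataset[per_dataset$beta == b & per_dataset$arm == arm, ]
      est <- mean_ci(d$est)
      row <- data.frame(beta = b, arm = arm, n_datasets = nrow(d),
                        n_failed = sum(d$failed),
                        est = est["mean"], est_lo = est["lo"],
                        est_hi = est["hi"])
      if (any(!is.na(d$diff))) {
        bb <- mean_ci(d$beta_bar_b); bc <- mean_ci(d$beta_bar_c)
        ad <- mean_ci(d$abs_diff)
        row$beta_bar_b <- bb["mean"]; row$bb_lo <- bb["lo"]
        row$bb_hi <- bb["hi"]
        row$beta_bar_c <- bc["mean"]; row$bc_lo <- bc["lo"]
        row$bc_hi <- bc["hi"]
        row$mean_abs_diff <- ad["mean"]; row$ad_lo <- ad["lo"]
        row$ad_hi <- ad["hi"]
        row$n_significant <- sum(d$significant, na.rm = TRUE)
      } else {
        row[c("beta_bar_b", "bb_lo", "bb_hi", "beta_bar_c", "bc_lo",
              "bc_hi", "mean_abs_diff", "ad_lo", "ad_hi")] <- NA_real_
        row$n_significant <- NA_integer_
      }
      out[[length(out) + 1L]] <- row
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @export
print.study_summary <- function(x, ...) {
  cat("order-effect simulation study\n")
  print(x$summary, digits = 4)
  invisible(x)
}
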