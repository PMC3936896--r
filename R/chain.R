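#' Fill missing cells with random draws from observed values
#'
#' Standard chained-equations start: each missing cell is replaced by a
#' value sampled uniformly, with replacement, from the observed values of
#' its own column.  The mask is preserved so the engine still knows which
#' cells to update.
#'
#' @param data an [md_dataset].
#' @return an [md_dataset] with all cells filled.
#' @export
initialize_missing <- function(data) {
  stopifnot(inherits(data, "md_dataset"))
  vals <- data$values
  for (j in seq_len(ncol(vals))) {
    mis <- !data$mask[, j]
    if (!any(mis)) next
    obs <- vals[data$mask[, j], j]
    if (length(obs) == 0L)
      stop("cannot initialize: column ", colnames(vals)[j],
           " is entirely missing")
    vals[mis, j] <- sample(obs, sum(mis), replace = TRUE)
  }
  out <- data
  out$values <- vals
  out
}

#' Configuration of a chained-equations run
#'
#' @param n_iter total iterations (the study uses 10010).
#' @param burn_in leading iterations whose hook records are discarded
#'   (the study uses 10).
#' @param thin retention stride for hook records and stored imputations.
#' @param visit_order column names of the incomplete variables in update
#'   order; defaults to the order of `specs` in [run_chain()].
#' @param hooks named list of callbacks `f(values, iter, col)` fired
#'   after every single-variable update; each must return a scalar.
#'   Defaults to the study's analysis hook (coefficient of Y from the
#'   regression of W2 on W1 and Y), see [analysis_hook()].
#' @param seed optional RNG seed.
#' @param max_store maximum number of completed datasets retained for
#'   [extract_imputations()] (the most recent thinned iterations).
#' @return an object of class `chain_config`.
#' @export
chain_config <- function(n_iter, burn_in = 0L, thin = 1L,
                         visit_order = NULL, hooks = NULL, seed = NULL,
                         max_store = 1L) {
  n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= n_iter) stop("burn_in must be smaller than n_iter")
  if (thin < 1L) stop("thin must be >= 1")
  structure(list(n_iter = n_iter, burn_in = burn_in, thin = thin,
                 visit_order = visit_order, hooks = hooks, seed = seed,
                 max_store = as.integer(max_store)),
            class = "chain_config")
}

#' Hook fitting an analysis regression after each update
#'
#' Returns a callback for [chain_config()] that fits the analysis model
#' (OLS of `response` on `covariates`, intercept included) to the full
#' current completed data and returns the coefficient named `coef`.
#'
#' @param response,covariates,coef column names.
#' @return a function `f(values, iter, col)`.
#' @export
analysis_hook <- function(response = "W2", covariates = c("W1", "Y"),
                          coef = "Y") {
  function(values, iter, col) {
    b <- ols_coef(values[, response], values[, covariates, drop = FALSE])
    b[[1L + match(coef, covariates)]]
  }
}

#' Run the chained-equations sampler
#'
#' After initializing missing cells with [initialize_missing()], each
#' iteration visits the incomplete variables in `visit_order`; for each
#' one it draws imputation-model parameters from the rows where that
#' variable is observed, conditioning on the current values of all other
#' variables (step CE1), and then redraws that variable's missing cells
#' from the fitted predictive distribution (step CE2).  Hooks fire after
#' every single-variable update.  Observed cells are never modified.
#'
#' @param data an [md_dataset].
#' @param specs list of [conditional_spec()]s covering every incomplete
#'   column.
#' @param cfg a [chain_config()].
#' @return an `imputation_trace`: list with `records` (named list of
#'   retained-iteration x visited-column matrices, one per hook),
#'   `imputations` (most recent completed datasets at thinned
#'   iterations), `visit_order`, `n_retained`, `separation_events` and
#'   the config.
#' @export
run_chain <- function(data, specs, cfg) {
  stopifnot(inherits(data, "md_dataset"), inherits(cfg, "chain_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  if (inherits(specs, "conditional_spec")) specs <- list(specs)
  spec_targets <- vapply(specs, function(s) s$target, character(1))
  incomplete <- colnames(data$values)[colSums(!data$mask) > 0L]
  visit <- cfg$visit_order
  if (is.null(visit)) visit <- spec_targets[spec_targets %in% incomplete]
  if (!setequal(visit, incomplete))
    stop("visit_order must cover exactly the incomplete columns")
  if (!all(visit %in% spec_targets))
    stop("no conditional spec for: ",
         paste(setdiff(visit, spec_targets), collapse = ", "))
  hooks <- cfg$hooks
  if (is.null(hooks)) hooks <- list(beta = analysis_hook())
  filled <- initialize_missing(data)
  vals <- filled$values
  mask <- data$mask
  ycol_all <- which(data$types == "binary")

  retained <- seq.int(cfg$burn_in + cfg$thin, cfg$n_iter, by = cfg$thin)
  n_ret <- length(retained)
  rec_cols <- if (length(visit) > 0L) visit else "none"
  records <- lapply(hooks, function(h)
    matrix(NA_real_, n_ret, length(rec_cols),
           dimnames = list(NULL, rec_cols)))
  imputations <- vector("list", 0L)
  separation_events <- 0L
  ret_i <- 0L

  for (t in seq_len(cfg$n_iter)) {
    for (j in visit) {
      sp <- specs[[match(j, spec_targets)]]
      obs <- mask[, j]
      mis <- !obs
      if (sp$family == "lda_glom") {
        wcols <- sp$covariates
        theta <- glom_fit_draw(vals[obs, j],
                               vals[obs, wcols, drop = FALSE],
                               sp$prior, sp$proper)
        p1 <- glom_class_prob(theta, vals[mis, wcols, drop = FALSE])
        vals[mis, j] <- stats::rbinom(sum(mis), 1L, p1)
      } else {
        Xall <- cbind(1, vals[, sp$covariates, drop = FALSE])
        if (sp$family == "logistic_mvn") {
          dr <- draw_logistic_mvn(vals[obs, j], Xall[obs, , drop = FALSE],
                                  proper = sp$proper)
          if (isTRUE(dr$meta$separation))
            separation_events <- separation_events + 1L
          vals[mis, j] <- impute_binary(Xall[mis, , drop = FALSE], dr)
        } else {
          dr <- draw_normal_linear(vals[obs, j], Xall[obs, , drop = FALSE],
                                   proper = sp$proper, kappa = sp$kappa)
          vals[mis, j] <- impute_continuous(Xall[mis, , drop = FALSE], dr)
        }
      }
      if (t > cfg$burn_in && (t - cfg$burn_in) %% cfg$thin == 0L) {
        if (j == visit[1L]) ret_row <- ret_i + 1L
        for (h in names(hooks))
          records[[h]][ret_row, j] <- hooks[[h]](vals, t, j)
      }
    }
    if (t > cfg$burn_in && (t - cfg$burn_in) %% cfg$thin == 0L) {
      ret_i <- ret_i + 1L
      if (length(visit) == 0L)  # nothing to impute: record the fixed fit
        for (h in names(hooks))
          records[[h]][ret_i, 1L] <- hooks[[h]](vals, t, NA_character_)
      if (cfg$max_store > 0L) {
        imputations[[length(imputations) + 1L]] <- vals
        if (length(imputations) > cfg$max_store)
          imputations <- imputations[-1L]
      }
    }
  }
  structure(list(records = records, imputations = imputations,
                 visit_order = visit, n_retained = n_ret,
                 separation_events = separation_events,
                 mask = mask, types = data$types, config = cfg),
            class = "imputation_trace")
}

#' @export
print.imputation_trace <- function(x, ...) {
  cat(sprintf(paste0("imputation_trace: %d retained iterations, visit ",
                     "order (%s), %d stored imputations\n"),
              x$n_retained, paste(x$visit_order, collapse = ", "),
              length(x$imputations)))
  if (x$separation_events > 0L)
    cat(sprintf("  %d separation fallback(s) in logistic updates\n",
                x$separation_events))
  invisible(x)
}

#' Extract completed datasets from a trace
#'
#' Returns the `m` most recent completed datasets stored at the
#' retained (thinned) iterations; with `m = 1` this is the final
#' iteration's completed dataset, the conventional single imputation.
#'
#' @param trace an `imputation_trace` from [run_chain()].
#' @param m number of completed datasets.
#' @return list of completed [md_dataset]s (original mask preserved).
#' @export
extract_imputations <- function(trace, m) {
  m <- as.integer(m)
  if (m < 1L) stop("m must be >= 1")
  k <- length(trace$imputations)
  if (m > k)
    stop("only ", k, " completed datasets stored (raise max_store)")
  lapply(trace$imputations[seq.int(k - m + 1L, k)], function(v) {
    d <- md_dataset(v, types = trace$types)
    d$mask <- trace$mask
    d
  })
}
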