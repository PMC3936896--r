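#' Specify one incomplete variable's imputation model
#'
#' A conditional spec names the target column, its covariates, the model
#' family and whether parameter draws are proper (Bayesian posterior
#' draw) or improper (maximum-likelihood plug-in).
#'
#' Families:
#' \describe{
#'   \item{`normal_linear`}{normal linear regression with prior
#'     \eqn{p(\text{coefficients}, \omega) \propto \omega^{-\kappa}}
#'     on the residual variance (the study uses kappa = 3/2, i.e.
#'     \eqn{\omega^{-3/2}}).}
#'   \item{`logistic_mvn`}{logistic regression fitted by maximum
#'     likelihood; proper draws come from the multivariate normal
#'     approximation N(MLE, inverse observed information).}
#'   \item{`lda_glom`}{linear discriminant analysis: the general
#'     location model fitted to all rows with the target observed, with
#'     the same prior as joint-model imputation; the target is imputed
#'     from the implied class posterior pr(Y = 1 | W).}
#' }
#'
#' @param target column name of the incomplete variable.
#' @param covariates column names entering the linear predictor (main
#'   effects only).
#' @param family one of `"normal_linear"`, `"logistic_mvn"`,
#'   `"lda_glom"`.
#' @param proper logical; `FALSE` uses ML plug-in estimates.
#' @param kappa exponent of the residual-variance prior
#'   (`normal_linear` only).
#' @param prior a [glom_prior()] (`lda_glom` only).
#' @return an object of class `conditional_spec`.
#' @export
conditional_spec <- function(target, covariates,
                             family = c("normal_linear", "logistic_mvn",
                                        "lda_glom"),
                             proper = TRUE, kappa = 3 / 2,
                             prior = glom_prior()) {
  family <- match.arg(family)
  if (target %in% covariates) stop("target cannot be its own covariate")
  structure(list(target = target, covariates = covariates,
                 family = family, proper = proper, kappa = kappa,
                 prior = prior),
            class = "conditional_spec")
}

param_draw <- function(coefficients, scale = NULL, meta = list()) {
  if (!is.null(scale) && scale <= 0) stop("scale must be positive")
  structure(list(coefficients = coefficients, scale = scale, meta = meta),
            class = "param_draw")
}

#' Normal linear regression: posterior draw or ML plug-in
#'
#' Proper mode draws the residual variance from its marginal posterior
#' under the prior \eqn{\propto \omega^{-\kappa}} with flat priors on the
#' coefficients — a scaled inverse chi-square with
#' `df = n - p + 2*kappa - 2` degrees of freedom and scale equal to the
#' residual sum of squares (at the study's kappa = 3/2 this is
#' `n - p + 1`) — then the coefficients from their conditional normal
#' N(OLS, omega * (X'X)^{-1}).  Improper mode returns the OLS
#' coefficients and the ML residual variance RSS/n.
#'
#' @param y numeric response (observed rows of the target).
#' @param X design matrix including the intercept column.
#' @param proper logical.
#' @param kappa residual-variance prior exponent.
#' @return a `param_draw` with fields `coefficients` and `scale`.
#' @export
draw_normal_linear <- function(y, X, proper = TRUE, kappa = 3 / 2) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  if (n < p + 2L) stop("need at least p + 2 observed rows")
  qr_ <- qr(X)
  if (qr_$rank < p) stop("rank-deficient design")
  bhat <- qr.coef(qr_, y)
  rss <- sum(qr.resid(qr_, y)^2)
  if (!proper)
    return(param_draw(bhat, scale = max(rss / n, .Machine$double.xmin),
                      meta = list(rss = rss, df = n - p)))
  if (rss <= 1e-12 * (sum(y^2) + 1))
    stop("degenerate posterior: residuals identically zero")
  df <- n - p + 2 * kappa - 2
  if (df <= 0) stop("improper omega posterior (df <= 0)")
  omega <- rss / stats::rchisq(1L, df)
  Rm <- qr.R(qr_)
  b <- bhat + sqrt(omega) * backsolve(Rm, stats::rnorm(p))
  param_draw(b, scale = omega, meta = list(rss = rss, df = df))
}

# Ridge-penalised IRLS fallback for separated logistic fits.
logistic_ridge <- function(y, X, lambda = 1e-4, maxit = 200L) {
  p <- ncol(X)
  b <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- stats::plogis(eta)
    wt <- pmax(mu * (1 - mu), 1e-12)
    H <- crossprod(X * wt, X) + diag(lambda, p)
    g <- crossprod(X, y - mu) - lambda * b
    step <- solve(H, g)
    b <- b + drop(step)
    if (max(abs(step)) < 1e-10) break
  }
  list(coef = b, vcov = solve(H))
}

#' Logistic regression: MVN-approximation draw or ML plug-in
#'
#' Fits logistic regression by maximum likelihood on the rows with the
#' target observed.  Proper mode returns one draw from the multivariate
#' normal approximation N(MLE, V) with V the inverse observed
#' information at the MLE; improper mode returns the MLE itself.
#' Separation (non-convergence or any |coefficient| > 15) triggers a
#' ridge-penalised refit (penalty 1e-4) recorded in `meta$separation`,
#' so a chained-equations run never aborts mid-chain.
#'
#' @inheritParams draw_normal_linear
#' @return a `param_draw`; `meta$separation` flags the fallback.
#' @export
draw_logistic_mvn <- function(y, X, proper = TRUE) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2L)
    stop("class degeneracy: target has a single observed class")
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial(),
                   control = list(maxit = 100L)))
  separated <- !fit$converged || max(abs(fit$coefficients)) > 15 ||
    anyNA(fit$coefficients)
  if (separated) {
    rf <- logistic_ridge(y, X)
    coefs <- rf$coef
    V <- rf$vcov
  } else {
    coefs <- fit$coefficients
    mu <- fit$fitted.values
    # canonical link: observed information = X' diag(mu(1-mu)) X
    V <- chol2inv(chol(crossprod(X * (mu * (1 - mu)), X)))
  }
  if (proper)
    coefs <- coefs + drop(t(chol(V)) %*% stats::rnorm(ncol(X)))
  param_draw(coefs, meta = list(vcov = V, separation = separated))
}

#' Predictive draws for a binary target
#'
#' Each missing entry is drawn Bernoulli(expit(x' coefficients)).
#'
#' @param X covariate matrix (intercept included) for the rows to impute.
#' @param draw a `param_draw` from a binary-family fit.
#' @return 0/1 vector of imputations.
#' @export
impute_binary <- function(X, draw) {
  p <- stats::plogis(drop(as.matrix(X) %*% draw$coefficients))
  stats::rbinom(length(p), 1L, p)
}

#' Predictive draws for a continuous target
#'
#' Each missing entry is drawn N(x' coefficients, scale).
#'
#' @inheritParams impute_binary
#' @return numeric vector of imputations.
#' @export
impute_continuous <- function(X, draw) {
  mu <- drop(as.matrix(X) %*% draw$coefficients)
  stats::rnorm(length(mu), mu, sqrt(draw$scale))
}

#' Linear discriminant conditional: general location fit on observed-target rows
#'
#' Fits the general location model to all rows in which the binary
#' target is observed, using the current values of the continuous
#' columns, under the same prior as joint-model imputation.  Proper mode
#' draws (gamma, mu0, mu1, Sigma) from the posterior; improper mode uses
#' the MLEs.  Imputation of the target then uses the implied class
#' posterior [glom_class_prob()].
#'
#' @param y observed 0/1 values of the target.
#' @param w matrix of the continuous covariates for the same rows.
#' @param prior a [glom_prior()].
#' @param proper logical.
#' @return a [glom_params()].
#' @export
draw_lda_glom <- function(y, w, prior = glom_prior(), proper = TRUE) {
  glom_fit_draw(y, w, prior, proper)
}
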