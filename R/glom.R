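#' Prior for the general location model
#'
#' The joint prior is
#' \deqn{p(\gamma, \mu_0, \mu_1, \Sigma) \propto
#'       \gamma^{\tau-1} (1-\gamma)^{\nu-1} |\Sigma|^{-\kappa},}
#' i.e. a Beta(tau, nu) factor for the Bernoulli probability, a flat
#' prior on the class means, and a power-of-determinant prior on the
#' shared covariance.  The study's hyperparameters are tau = nu = 1/2,
#' kappa = 3/2.
#'
#' @param tau,nu positive Beta hyperparameters for gamma.
#' @param kappa exponent of the determinant prior on Sigma.
#' @return an object of class `glom_prior`.
#' @export
glom_prior <- function(tau = 1 / 2, nu = 1 / 2, kappa = 3 / 2) {
  if (tau <= 0 || nu <= 0) stop("tau and nu must be positive")
  structure(list(tau = tau, nu = nu, kappa = kappa),
            class = "glom_prior")
}

#' Parameters of the general location model
#'
#' `Y ~ Bernoulli(gamma)` and `W | Y ~ N(mu0 + mu1 * Y, Sigma)` with a
#' covariance matrix shared between the two classes.
#'
#' @param gamma Bernoulli probability in (0, 1).
#' @param mu0 class-0 mean vector of W.
#' @param mu1 additive effect of Y = 1 on the mean of W.
#' @param Sigma symmetric positive-definite covariance of W given Y.
#' @return an object of class `glom_params`.
#' @export
glom_params <- function(gamma, mu0, mu1, Sigma) {
  Sigma <- as.matrix(Sigma)
  if (!(gamma > 0 && gamma < 1)) stop("gamma must lie in (0, 1)")
  if (length(mu0) != nrow(Sigma) || length(mu1) != nrow(Sigma))
    stop("mean vectors must match Sigma's dimension")
  if (max(abs(Sigma - t(Sigma))) > 1e-8 ||
      inherits(tryCatch(chol(Sigma), error = identity), "error"))
    stop("Sigma must be symmetric positive definite")
  structure(list(gamma = gamma, mu0 = as.numeric(mu0),
                 mu1 = as.numeric(mu1), Sigma = Sigma),
            class = "glom_params")
}

# Core posterior draw / ML fit shared by joint-model imputation and the
# linear-discriminant conditional.  y: 0/1 vector, w: matrix of
# continuous columns for the same rows.
glom_fit_draw <- function(y, w, prior = glom_prior(), proper = TRUE) {
  w <- as.matrix(w)
  n <- length(y); q <- ncol(w)
  if (nrow(w) != n) stop("y and w must have matching rows")
  n1 <- sum(y)
  if (n1 == 0L || n1 == n)
    stop("degenerate posterior: only one class of Y present")
  X <- cbind(1, y); p <- 2L
  if (n < p + q) stop("too few rows for the regression of W on (1, Y)")
  XtX <- crossprod(X)
  Bhat <- solve(XtX, crossprod(X, w))
  R <- w - X %*% Bhat
  S <- crossprod(R)
  if (rcond(S) < 1e-12)
    stop("degenerate posterior: W residual variation is (numerically) zero")
  if (!proper) {
    return(glom_params(gamma = n1 / n, mu0 = Bhat[1, ], mu1 = Bhat[2, ],
                       Sigma = S / n))
  }
  gamma <- stats::rbeta(1, prior$tau + n1, prior$nu + n - n1)
  # Marginal posterior of Sigma after integrating the regression
  # coefficients: IW(n - p + 2*kappa - q - 1, S).
  df <- n - p + 2 * prior$kappa - q - 1
  if (df <= q - 1)
    stop("improper Sigma posterior: increase n or kappa")
  Sigma <- rinvwishart(df, S)
  # B | Sigma ~ matrix normal MN(Bhat, (X'X)^{-1}, Sigma).
  U <- chol2inv(chol(XtX))
  B <- Bhat + t(chol(U)) %*% matrix(stats::rnorm(p * q), p, q) %*%
    chol(Sigma)
  glom_params(gamma = gamma, mu0 = B[1, ], mu1 = B[2, ], Sigma = Sigma)
}

#' Draw general location parameters from the complete-data posterior
#'
#' One draw from \eqn{p(\theta | \text{completed data})} under the
#' [glom_prior()].  The Bernoulli probability has the conjugate
#' Beta(tau + n1, nu + n0) posterior, independent of (mu0, mu1, Sigma);
#' the latter come from the normal-regression posterior of W on (1, Y):
#' Sigma from the inverse-Wishart implied by the determinant prior and B
#' from its matrix-normal conditional given Sigma.
#'
#' @param data a fully completed [md_dataset] with exactly one binary
#'   column.
#' @param prior a [glom_prior()].
#' @return a [glom_params()] draw.
#' @export
draw_theta_complete <- function(data, prior = glom_prior()) {
  stopifnot(inherits(data, "md_dataset"))
  if (anyNA(data$values)) stop("data must be fully completed")
  ycol <- glom_binary_col(data)
  glom_fit_draw(data$values[, ycol],
                data$values[, setdiff(seq_len(ncol(data$values)), ycol),
                            drop = FALSE],
                prior, proper = TRUE)
}

glom_binary_col <- function(data) {
  ycol <- which(data$types == "binary")
  if (length(ycol) != 1L)
    stop("general location routines require exactly one binary column")
  ycol
}

# log-odds of Y = 1 given an observed subset of W (columns `O` of the
# continuous block).  Affine in W because the two classes share Sigma:
#   log gamma/(1-gamma) + mu1_O' SigmaOO^{-1} (W_O - mu0_O)
#     - mu1_O' SigmaOO^{-1} mu1_O / 2.
glom_logodds <- function(theta, W_O, O = seq_along(theta$mu0)) {
  base <- log(theta$gamma / (1 - theta$gamma))
  if (length(O) == 0L) return(rep(base, nrow(W_O)))
  b <- solve(theta$Sigma[O, O, drop = FALSE], theta$mu1[O])
  dev <- sweep(W_O, 2L, theta$mu0[O])
  drop(base + dev %*% b - 0.5 * sum(theta$mu1[O] * b))
}

#' Class posterior probability pr(Y = 1 | W) under the general location model
#'
#' Computed from Bayes' rule applied to the two class-conditional normal
#' densities and the class probability; because the classes share a
#' covariance matrix this reduces to a logistic (affine) function of W.
#'
#' @param theta a [glom_params()].
#' @param W matrix of continuous values (rows = subjects); may cover a
#'   subset of the W columns, named by `O`.
#' @param O integer indices of the W columns supplied.
#' @return numeric vector of probabilities.
#' @export
glom_class_prob <- function(theta, W, O = seq_along(theta$mu0)) {
  stats::plogis(glom_logodds(theta, as.matrix(W), O))
}

#' Draw the missing cells from their posterior predictive given theta
#'
#' For every row, missing components are drawn from their exact
#' conditional distribution under the general location model given that
#' row's observed components: a missing Y from pr(Y = 1 | observed W)
#' (Bayes' rule on the class-conditional normals), then missing W
#' components from the conditional normal given Y and the observed W
#' components.  Rows missing both Y and W1 therefore draw Y | W2 first,
#' then W1 | Y, W2.  Given theta the rows are independent of each other
#' and of the current fills, so only genuinely observed cells are read.
#'
#' @param data an [md_dataset] (current fills, if any, are ignored).
#' @param theta a [glom_params()].
#' @return an [md_dataset] whose masked cells are replaced by fresh
#'   draws; the mask itself is unchanged.
#' @export
draw_missing_glom <- function(data, theta) {
  stopifnot(inherits(data, "md_dataset"), inherits(theta, "glom_params"))
  ycol <- glom_binary_col(data)
  wcols <- setdiff(seq_len(ncol(data$values)), ycol)
  vals <- data$values
  miss <- !data$mask
  rows <- which(rowSums(miss) > 0L)
  if (length(rows) == 0L) return(data)
  sig <- apply(miss[rows, , drop = FALSE], 1L, paste, collapse = "")
  for (s in unique(sig)) {
    r <- rows[sig == s]
    miss_cols <- which(miss[r[1L], ])
    y_missing <- ycol %in% miss_cols
    M <- match(setdiff(miss_cols, ycol), wcols)   # missing W (W-block idx)
    O <- match(setdiff(wcols, miss_cols), wcols)  # observed W
    W_O <- vals[r, wcols[O], drop = FALSE]
    if (y_missing) {
      p1 <- glom_class_prob(theta, W_O, O)
      yr <- stats::rbinom(length(r), 1L, p1)
      vals[r, ycol] <- yr
    } else {
      yr <- vals[r, ycol]
    }
    if (length(M) > 0L) {
      cp <- mvn_cond_parts(theta$Sigma, M, O)
      mu_M <- matrix(theta$mu0[M], length(r), length(M), byrow = TRUE) +
        yr %o% theta$mu1[M]
      if (length(O) > 0L) {
        dev_O <- W_O -
          matrix(theta$mu0[O], length(r), length(O), byrow = TRUE) -
          yr %o% theta$mu1[O]
        mu_M <- mu_M + dev_O %*% t(cp$A)
      }
      vals[r, wcols[M]] <- mu_M + rmvn0(length(r), cp$V)
    }
  }
  out <- data
  out$values <- vals
  out
}
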