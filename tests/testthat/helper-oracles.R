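# Independent oracles used to validate the package's samplers and fits.
# Everything here is deliberately brute-force and shares no code with
# the implementation under test.

# OLS via the normal equations.
ols_oracle <- function(y, X) {
  Xd <- cbind(1, X)
  drop(solve(t(Xd) %*% Xd, t(Xd) %*% y))
}

# Logistic MLE by hand-rolled Newton (IRLS) iterations.
irls_oracle <- function(y, X, maxit = 50, tol = 1e-12) {
  b <- rep(0, ncol(X))
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    W <- mu * (1 - mu)
    step <- solve(t(X) %*% (X * W), t(X) %*% (y - mu))
    b <- b + drop(step)
    if (max(abs(step)) < tol) break
  }
  b
}

# Generic random-walk Metropolis returning the chain (rows = states).
rw_metropolis <- function(logpost, init, n_iter, step_sd) {
  d <- length(init)
  out <- matrix(NA_real_, n_iter, d)
  cur <- init
  lp_cur <- logpost(cur)
  acc <- 0L
  for (t in seq_len(n_iter)) {
    prop <- cur + rnorm(d, 0, step_sd)
    lp_prop <- logpost(prop)
    if (is.finite(lp_prop) && log(runif(1)) < lp_prop - lp_cur) {
      cur <- prop; lp_cur <- lp_prop; acc <- acc + 1L
    }
    out[t, ] <- cur
  }
  attr(out, "acc_rate") <- acc / n_iter
  out
}

# MCSE of a correlated chain's mean via non-overlapping batch means
# (local copy, independent of the package's estimator).
chain_mcse <- function(x, n_batches = 50) {
  n <- length(x)
  bs <- n %/% n_batches
  bm <- colMeans(matrix(x[seq_len(bs * n_batches)], bs))
  sd(bm) / sqrt(n_batches)
}

# Metropolis oracle for the normal linear model with prior
# p(b, omega) propto omega^(-kappa): samples (b, log omega).
oracle_normal_linear_chain <- function(y, X, kappa, n_iter = 6e4,
                                       step_sd = NULL) {
  X <- as.matrix(X)
  n <- length(y); p <- ncol(X)
  logpost <- function(th) {
    b <- th[seq_len(p)]; u <- th[p + 1L]      # u = log omega
    r <- y - drop(X %*% b)
    # prior omega^(-kappa) with Jacobian omega for the log scale
    (1 - kappa) * u - n * u / 2 - sum(r^2) / (2 * exp(u))
  }
  fit <- lm.fit(X, y)
  s2 <- sum(fit$residuals^2) / n
  init <- c(fit$coefficients, log(s2))
  if (is.null(step_sd))
    step_sd <- c(sqrt(diag(chol2inv(chol(t(X) %*% X))) * s2), sqrt(2 / n)) * 1.2
  rw_metropolis(logpost, init, n_iter, step_sd)
}

# Metropolis oracle for the general location regression block
# (mu0, mu1, Sigma) with prior |Sigma|^(-kappa), q = 2 continuous
# columns.  Parameterized as (B[4], l11, l21, l22) with
# Sigma = L L', L = [[exp(l11), 0], [l21, exp(l22)]];
# the change of variables contributes log-Jacobian
# log 4 + 3*l11 + 2*l22.
oracle_glom_chain <- function(y, w, kappa, n_iter = 8e4, step_mult = 1) {
  w <- as.matrix(w)
  stopifnot(ncol(w) == 2)
  n <- length(y)
  X <- cbind(1, y)
  logpost <- function(th) {
    B <- matrix(th[1:4], 2)                    # rows: (mu0, mu1)
    L <- matrix(c(exp(th[5]), th[6], 0, exp(th[7])), 2)
    logdet <- 2 * (th[5] + th[7])              # log |Sigma|
    R <- w - X %*% B
    # solve Sigma^{-1} via L: tr(Sigma^{-1} R'R) = sum((R L^{-T})^2)
    RLinv <- t(forwardsolve(L, t(R)))
    -kappa * logdet - n * logdet / 2 - sum(RLinv^2) / 2 +
      3 * th[5] + 2 * th[7]
  }
  fit <- lm.fit(X, w)
  S <- crossprod(w - X %*% fit$coefficients) / n
  Lh <- t(chol(S))
  init <- c(fit$coefficients, log(Lh[1, 1]), Lh[2, 1], log(Lh[2, 2]))
  step_sd <- step_mult * c(rep(0.35, 4) * sqrt(diag(S))[c(1, 1, 2, 2)] /
                             sqrt(n), rep(0.9 / sqrt(n), 3))
  ch <- rw_metropolis(logpost, init, n_iter, step_sd)
  # return draws mapped back to (mu0_1, mu0_2, mu1_1, mu1_2, s11, s21, s22)
  t(apply(ch, 1, function(th) {
    L <- matrix(c(exp(th[5]), th[6], 0, exp(th[7])), 2)
    S <- L %*% t(L)
    c(th[1:4], S[1, 1], S[2, 1], S[2, 2])
  }))
}

# Log-density of N(mu, Sigma) evaluated at rows of x (used to check the
# affine log-odds identity directly from the densities).
dmvnorm_log <- function(x, mu, Sigma) {
  x <- as.matrix(x)
  q <- ncol(x)
  L <- t(chol(Sigma))
  dev <- t(forwardsolve(L, t(sweep(x, 2, mu))))
  -q * log(2 * pi) / 2 - sum(log(diag(L))) - rowSums(dev^2) / 2
}

# Random SPD matrix with eigenvalues bounded away from zero.
random_spd <- function(q) {
  A <- matrix(rnorm(q * q), q)
  crossprod(A) + diag(q) * 0.5
}

# Small fixed toy regression fixture.
toy_regression <- function(n = 20, seed = 42) {
  set.seed(seed)
  X <- cbind(1, rnorm(n), rnorm(n))
  y <- drop(X %*% c(1, 2, -1)) + rnorm(n, sd = 1.5)
  list(y = y, X = X)
}

# Small fixed GLOM fixture (one binary + two continuous columns).
toy_glom <- function(n = 30, seed = 11) {
  set.seed(seed)
  y <- rbinom(n, 1, 0.4)
  if (sum(y) < 3) y[1:3] <- 1
  w1 <- 1 + 0.8 * y + rnorm(n)
  w2 <- -0.5 + 0.5 * w1 + 0.6 * y + rnorm(n, sd = 0.8)
  list(y = y, w = cbind(w1, w2))
}
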