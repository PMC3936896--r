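# Internal numerical utilities: Wishart draws via the Bartlett
# decomposition (valid for any real df > q - 1), inverse-Wishart draws,
# Dirichlet draws and a bare-metal OLS coefficient extractor used in the
# inner simulation loops.

# W ~ Wishart(df, S): E[W] = df * S.
rwishart_bartlett <- function(df, S) {
  q <- nrow(S)
  if (df <= q - 1) stop("Wishart df must exceed q - 1")
  A <- matrix(0, q, q)
  diag(A) <- sqrt(stats::rchisq(q, df - seq_len(q) + 1))
  if (q > 1L) A[lower.tri(A)] <- stats::rnorm(q * (q - 1) / 2)
  C <- chol(S)                      # S = C'C, C upper triangular
  crossprod(t(A) %*% C)             # C' A A' C  ~  Wishart(df, S)
}

# Sigma ~ IW(df, S): density  |Sigma|^{-(df+q+1)/2} exp(-tr(Sigma^{-1} S)/2).
rinvwishart <- function(df, S) {
  q <- nrow(S)
  Sinv <- tryCatch(chol2inv(chol(S)),
                   error = function(e) stop("scale matrix not positive definite"))
  W <- rwishart_bartlett(df, Sinv)
  chol2inv(chol(W))
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

# OLS coefficients of y on cbind(1, X); errors on rank deficiency.
ols_coef <- function(y, X) {
  Xd <- cbind(1, X)
  fit <- stats::lm.fit(Xd, y)
  if (fit$rank < ncol(Xd)) stop("rank-deficient design")
  fit$coefficients
}

# Conditional N(mean, V) of x[M] given x[O] under N(mu, Sigma):
# returns the regression matrix A = Sigma[M,O] Sigma[O,O]^{-1} and
# residual covariance V = Sigma[M,M] - A Sigma[O,M].
mvn_cond_parts <- function(Sigma, M, O) {
  if (length(O) == 0L)
    return(list(A = matrix(0, length(M), 0L),
                V = Sigma[M, M, drop = FALSE]))
  A <- Sigma[M, O, drop = FALSE] %*%
    chol2inv(chol(Sigma[O, O, drop = FALSE]))
  V <- Sigma[M, M, drop = FALSE] - A %*% Sigma[O, M, drop = FALSE]
  V <- (V + t(V)) / 2
  list(A = A, V = V)
}

# n draws from N(0, V), rows are draws.
rmvn0 <- function(n, V) {
  if (ncol(V) == 0L) return(matrix(0, n, 0L))
  matrix(stats::rnorm(n * ncol(V)), n) %*% chol(V)
}
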