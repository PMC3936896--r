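test_that("improper normal-linear draw is exactly the OLS fit", {
  tr <- toy_regression()
  d <- draw_normal_linear(tr$y, tr$X, proper = FALSE)
  expect_equal(unname(d$coefficients), unname(ols_oracle(tr$y, tr$X[, -1])),
               tolerance = 1e-12)
  expect_equal(d$scale,
               sum((tr$y - tr$X %*% d$coefficients)^2) / length(tr$y))
})

test_that("proper normal-linear draws match a Metropolis oracle of the written density", {
  tr <- toy_regression()
  set.seed(501)
  draws <- t(replicate(8000, {
    d <- draw_normal_linear(tr$y, tr$X, proper = TRUE)
    c(d$coefficients, d$scale)
  }))
  och <- oracle_normal_linear_chain(tr$y, tr$X, kappa = 3 / 2,
                                    n_iter = 4e4)
  och <- och[-seq_len(4000), ]
  om <- cbind(och[, 1:3], exp(och[, 4]))
  for (k in 1:4) {
    se <- sqrt(sd(draws[, k])^2 / nrow(draws) + chain_mcse(om[, k])^2)
    expect_lt(abs(mean(draws[, k]) - mean(om[, k])), 4 * se)
  }
})

test_that("normal-linear guards reject degenerate inputs", {
  tr <- toy_regression()
  expect_error(draw_normal_linear(tr$y[1:4], tr$X[1:4, ]), "p \\+ 2")
  Xr <- cbind(tr$X, tr$X[, 2])                     # collinear
  expect_error(draw_normal_linear(tr$y, Xr), "rank")
  y0 <- drop(tr$X %*% c(1, 2, 3))                  # zero residuals
  expect_error(draw_normal_linear(y0, tr$X, proper = TRUE), "degenerate")
})

test_that("logistic MLE matches closed form and an IRLS oracle", {
  # intercept-only: MLE = logit(n1/n); balanced data gives exactly 0
  y <- rep(c(0, 1), each = 25)
  d <- draw_logistic_mvn(y, matrix(1, 50), proper = FALSE)
  expect_equal(unname(d$coefficients), 0, tolerance = 1e-10)

  set.seed(77)
  X <- cbind(1, rnorm(60), rnorm(60))
  yb <- rbinom(60, 1, plogis(X %*% c(-0.3, 1, 0.5)))
  fit <- draw_logistic_mvn(yb, X, proper = FALSE)
  expect_equal(unname(fit$coefficients), unname(irls_oracle(yb, X)),
               tolerance = 1e-8)
  expect_false(fit$meta$separation)
  expect_error(draw_logistic_mvn(rep(1, 20), matrix(1, 20)), "class")
})

test_that("proper logistic draws have the MVN approximation's covariance", {
  set.seed(78)
  X <- cbind(1, rnorm(80), rnorm(80))
  yb <- rbinom(80, 1, plogis(X %*% c(0, 0.8, -0.5)))
  mle <- draw_logistic_mvn(yb, X, proper = FALSE)
  V <- mle$meta$vcov
  draws <- t(replicate(2e4, draw_logistic_mvn(yb, X, proper = TRUE)$coefficients))
  Vemp <- cov(draws)
  for (i in 1:3) for (j in 1:3) {
    se <- sqrt((V[i, i] * V[j, j] + V[i, j]^2) / nrow(draws))
    expect_lt(abs(Vemp[i, j] - V[i, j]), 4 * se)
  }
  expect_true(all(abs(colMeans(draws) - mle$coefficients) <
                    4 * sqrt(diag(V) / nrow(draws))))
})

test_that("separation triggers the ridge fallback instead of aborting", {
  x <- c(rep(-1, 10), rep(1, 10))
  y <- as.numeric(x > 0)                           # perfectly separated
  d <- draw_logistic_mvn(y, cbind(1, x), proper = FALSE)
  expect_true(d$meta$separation)
  expect_true(all(is.finite(d$coefficients)))
})

test_that("predictive draws follow the fitted conditional", {
  dr <- structure(list(coefficients = c(0, 0), scale = NULL,
                       meta = list()), class = "param_draw")
  set.seed(80)
  X <- cbind(1, rnorm(1e5))
  # zero coefficients: imputation probability exactly 1/2
  z <- impute_binary(X, dr)
  expect_lt(abs(mean(z) - 0.5), 4 * sqrt(0.25 / 1e5))
  # saturated linear predictor
  dr50 <- dr; dr50$coefficients <- c(50, 0)
  expect_true(all(impute_binary(X, dr50) == 1))
  # frequency at linear predictor 1.0
  dr1 <- dr; dr1$coefficients <- c(1, 0)
  p <- plogis(1)
  expect_lt(abs(mean(impute_binary(X, dr1)) - p),
            4 * sqrt(p * (1 - p) / 1e5))
  # continuous: moments at fixed covariates
  drc <- dr; drc$coefficients <- c(2, 1); drc$scale <- 4
  w <- impute_continuous(cbind(1, rep(3, 1e5)), drc)
  expect_lt(abs(mean(w) - 5), 4 * 2 / sqrt(1e5))
  expect_lt(abs(var(w) - 4), 4 * 4 * sqrt(2 / 1e5))
  # scale -> 0 limit: imputations collapse onto the linear predictor
  drc$scale <- 1e-20
  expect_equal(impute_continuous(cbind(1, 3), drc), 5, tolerance = 1e-8)
})

test_that("improper mode is the deterministic centre of proper mode", {
  tr <- toy_regression()
  plug <- draw_normal_linear(tr$y, tr$X, proper = FALSE)$coefficients
  set.seed(82)
  draws <- replicate(4000,
    draw_normal_linear(tr$y, tr$X, proper = TRUE)$coefficients)
  # posterior mean of the coefficients equals OLS under the flat prior
  se <- apply(draws, 1, sd) / sqrt(ncol(draws))
  expect_true(all(abs(rowMeans(draws) - plug) < 4 * se))
})

test_that("LDA conditional: identical class means give pr(Y=1|W) = gamma", {
  tg <- toy_glom()
  th <- glom_params(gamma = 0.35, mu0 = c(1, 2), mu1 = c(0, 0),
                    Sigma = diag(2))
  p <- glom_class_prob(th, tg$w)
  expect_equal(p, rep(0.35, nrow(tg$w)))
  # draw_lda_glom with a single observed class must fail
  expect_error(draw_lda_glom(rep(1, 10), tg$w[1:10, ]), "one class")
})

test_that("GLOM log-odds are affine in W, matching the density ratio", {
  set.seed(83)
  for (rep in 1:5) {
    Sigma <- random_spd(2)
    th <- glom_params(gamma = runif(1, .2, .8), mu0 = rnorm(2),
                      mu1 = rnorm(2), Sigma = Sigma)
    W <- matrix(rnorm(200), 100)
    lo_pkg <- qlogis(glom_class_prob(th, W))
    lo_dens <- log(th$gamma) +
      dmvnorm_log(W, th$mu0 + th$mu1, Sigma) -
      log(1 - th$gamma) - dmvnorm_log(W, th$mu0, Sigma)
    expect_lt(max(abs(lo_pkg - lo_dens)), 1e-10)
    # affine in W: residual from a linear fit is numerically zero
    fit <- lm.fit(cbind(1, W), lo_dens)
    expect_lt(max(abs(fit$residuals)), 1e-10)
  }
  # worked case: Sigma = I, mu0 = 0, mu1 = (1, 0), gamma = 1/2
  th <- glom_params(0.5, c(0, 0), c(1, 0), diag(2))
  expect_equal(glom_class_prob(th, cbind(0.5, 99)), plogis(0.5 - 0.5))
})
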