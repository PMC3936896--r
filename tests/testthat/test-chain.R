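study_specs <- function(fam = "logistic_mvn", proper = TRUE)
  list(conditional_spec("Y", c("W1", "W2"), fam, proper = proper),
       conditional_spec("W1", c("Y", "W2"), "normal_linear",
                        proper = proper))

test_that("initialization samples from each column's observed values", {
  # constant observed column: every fill equals the constant
  vals <- cbind(A = c(rep(5, 6), NA, NA), B = rnorm(8))
  d <- md_dataset(vals, types = c("continuous", "continuous"))
  expect_true(all(initialize_missing(d)$values[7:8, "A"] == 5))

  # binary column: fill frequency matches the observed proportion
  y <- c(rep(1, 6), rep(0, 4), rep(NA, 10))
  d2 <- md_dataset(cbind(Y = y, W = rnorm(20)),
                   types = c("binary", "continuous"))
  set.seed(401)
  fills <- replicate(4000, initialize_missing(d2)$values[11:20, "Y"])
  expect_lt(abs(mean(fills) - 0.6), 4 * sqrt(0.6 * 0.4 / length(fills)))

  # fully observed data: identity
  dc <- simulate_complete(sim_config(n = 10, seed = 402))
  expect_identical(initialize_missing(dc)$values, dc$values)
})

test_that("chain record counts follow n_iter, burn_in and thin", {
  d <- simulate_masked(sim_config(n = 60, n_missing = 20, seed = 403))
  tr <- run_chain(d, study_specs(),
                  chain_config(110, 10, visit_order = c("Y", "W1"),
                               seed = 404))
  expect_equal(dim(tr$records$beta), c(100, 2))
  expect_false(anyNA(tr$records$beta))
  expect_identical(colnames(tr$records$beta), c("Y", "W1"))

  # thinning: retained records 5 iterations apart
  tr5 <- run_chain(d, study_specs(),
                   chain_config(110, 10, thin = 5, seed = 404,
                                max_store = 100))
  expect_equal(nrow(tr5$records$beta), 20)
  expect_length(tr5$imputations, 20)
})

test_that("chains are reproducible and never touch observed cells", {
  d <- simulate_masked(sim_config(n = 60, n_missing = 20, seed = 405))
  cfg <- chain_config(60, 10, seed = 406, max_store = 5)
  tr1 <- run_chain(d, study_specs(), cfg)
  tr2 <- run_chain(d, study_specs(), cfg)
  expect_identical(tr1$records, tr2$records)
  expect_identical(tr1$imputations, tr2$imputations)

  for (imp in extract_imputations(tr1, 5)) {
    expect_identical(imp$values[d$mask], d$values[d$mask])
    expect_true(all(imp$values[1:20, "Y"] %in% c(0, 1)))
  }
})

test_that("a chain with nothing to impute is a no-op", {
  d <- simulate_complete(sim_config(n = 50, seed = 407))
  tr <- run_chain(d, study_specs(), chain_config(20, 5, seed = 408))
  # hooks see the same analysis fit at every retained iteration
  expect_equal(length(unique(tr$records$beta[, 1])), 1L)
  expect_equal(unname(tr$records$beta[1, 1]), analysis_fit(d))
})

test_that("imputation extraction respects its bounds", {
  d <- simulate_masked(sim_config(n = 60, n_missing = 20, seed = 409))
  tr <- run_chain(d, study_specs(),
                  chain_config(30, 5, seed = 410, max_store = 3))
  expect_length(extract_imputations(tr, 1), 1)
  expect_length(extract_imputations(tr, 3), 3)
  expect_error(extract_imputations(tr, 0), "m must be")
  expect_error(extract_imputations(tr, 10), "stored")
})

test_that("configuration errors are caught", {
  d <- simulate_masked(sim_config(n = 60, n_missing = 20, seed = 411))
  expect_error(chain_config(10, 10), "burn_in")
  expect_error(run_chain(d, study_specs(),
                         chain_config(20, 5, visit_order = "Y")),
               "visit_order")
  expect_error(run_chain(d, study_specs()[1],
                         chain_config(20, 5,
                                      visit_order = c("Y", "W1"))),
               "no conditional spec")
})

test_that("the LDA conditional runs inside the chain", {
  d <- simulate_masked(sim_config(n = 80, n_missing = 30, seed = 412))
  tr <- run_chain(d, study_specs("lda_glom"),
                  chain_config(60, 10, seed = 413))
  expect_equal(dim(tr$records$beta), c(50, 2))
  expect_false(anyNA(tr$records$beta))
})
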