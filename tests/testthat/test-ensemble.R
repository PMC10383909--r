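test_that("a single boosting round reduces exactly to plain OLS", {
  sim <- make_regression_dataset(40, 3, k = 3, sigma = 0.5, seed = 141)
  boost <- adaboost_fit(sim$data, "y", n_estimators = 1)
  ols <- fit_ols(sim$data, "y")
  expect_equal(predict(boost, sim$data), predict(ols, sim$data),
               tolerance = 1e-10)
})

test_that("boosting terminates early on exactly linear data", {
  sim <- make_regression_dataset(40, 3, k = 3, sigma = 0, seed = 142)
  boost <- adaboost_fit(sim$data, "y", n_estimators = 25)
  expect_true(boost$terminated_early)
  expect_equal(boost$n_estimators_used, 1)
  r2 <- r2_metrics(sim$data$y, predict(boost, sim$data), 3)$r_squared
  expect_equal(r2, 1, tolerance = 1e-9)
})

test_that("boosting never fits the training data worse than one MLR", {
  # piecewise-linear response a single linear fit cannot capture
  set.seed(143)
  d <- tibble::tibble(
    compound_id = as.character(1:60),
    x = sort(runif(60, -2, 2))
  )
  d$y <- ifelse(d$x < 0, -1 + 0.2 * d$x, 2 + 1.5 * d$x) + rnorm(60, 0, 0.05)
  single <- fit_ols(d, "y")
  boosted <- adaboost_fit(d, "y", n_estimators = 30)
  sse_single <- sum((d$y - predict(single, d))^2)
  sse_boost <- sum((d$y - predict(boosted, d))^2)
  expect_lte(sse_boost, sse_single + 1e-10)

  # stump base learners capture a step response far better than one MLR
  d$ystep <- ifelse(d$x < 0, 0, 3) + rnorm(60, 0, 0.05)
  s_lin <- fit_ols(d, "ystep", descriptors = "x")
  b_stump <- adaboost_fit(d, "ystep", descriptors = "x", n_estimators = 30,
                          base_learner = "stump")
  expect_lt(sum((d$ystep - predict(b_stump, d))^2),
            sum((d$ystep - predict(s_lin, d))^2))
})

test_that("nonlinear regression forms fit their generating functions", {
  sim <- make_regression_dataset(30, 2, k = 2, sigma = 0.3, seed = 151)
  # polynomial degree 1 == OLS
  p1 <- nonlinear_fit(sim$data, "y", form = "polynomial", degree = 1)
  ols <- fit_ols(sim$data, "y")
  expect_equal(predict(p1, sim$data), predict(ols, sim$data), tolerance = 1e-10)

  # y = exp(2x): exponential fit recovers the rate exactly
  d <- tibble::tibble(compound_id = as.character(1:20),
                      x = seq(-1, 1, length.out = 20))
  d$y <- exp(2 * d$x)
  ef <- nonlinear_fit(d, "y", form = "exponential")
  expect_equal(unname(ef$beta[2]), 2, tolerance = 1e-8)
  expect_equal(predict(ef, d), d$y, tolerance = 1e-8)

  # logarithmic form rejects non-positive predictors
  d$x[1] <- 0
  expect_error(nonlinear_fit(d, "y", form = "logarithmic"), "positive")
  # exponential form rejects non-positive responses
  d2 <- tibble::tibble(compound_id = as.character(1:5),
                       x = 1:5, y = c(-1, 1, 2, 3, 4))
  expect_error(nonlinear_fit(d2, "y", form = "exponential"), "positive")
})

test_that("regressor adapters plug into the pipeline deterministically", {
  sim <- split_dataset(make_regression_dataset(60, 4, k = 2, sigma = 0.3,
                                               seed = 161)$data,
                       0.25, seed = 1)

  # identity adapter wrapping OLS scores exactly like the direct fit
  register_regressor(
    "ols_adapter",
    fit = function(X, y, seed) {
      d <- dplyr::bind_cols(tibble::tibble(.y = y), tibble::as_tibble(X))
      fit_ols(d, ".y")
    },
    predict = function(object, X) predict(object, tibble::as_tibble(X))
  )
  expect_true("ols_adapter" %in% list_regressors())
  fitted <- fit_regressor("ols_adapter", sim, "y", seed = 1)
  direct <- fit_ols(sim, "y")
  expect_equal(predict(fitted, sim), predict(direct, sim), tolerance = 1e-10)
  expect_equal(score_regressor(fitted, sim, "y", n_params = 4),
               score_regressor(direct, sim, "y"), tolerance = 1e-10)

  # a mean-only adapter earns R2 = 0 through the full scoring path
  register_regressor(
    "mean_only",
    fit = function(X, y, seed) mean(y),
    predict = function(object, X) rep(object, nrow(X))
  )
  s <- score_regressor(fit_regressor("mean_only", sim, "y"), sim, "y")
  expect_equal(s$r_squared, 0, tolerance = 1e-12)

  # two registrations of a seeded stochastic adapter give identical scores
  register_regressor(
    "noisy_but_seeded",
    fit = function(X, y, seed) {
      set.seed(seed)
      list(b = coef(lm(y ~ X)) + rnorm(ncol(X) + 1, 0, 0.01))
    },
    predict = function(object, X) drop(cbind(1, X) %*% object$b)
  )
  f1 <- fit_regressor("noisy_but_seeded", sim, "y", seed = 7)
  f2 <- fit_regressor("noisy_but_seeded", sim, "y", seed = 7)
  expect_identical(score_regressor(f1, sim, "y"), score_regressor(f2, sim, "y"))

  # an adapter violating determinism-under-seed is refused at registration
  expect_error(
    register_regressor(
      "nondeterministic",
      fit = function(X, y, seed) rnorm(1),
      predict = function(object, X) rep(object, nrow(X))
    ),
    "not deterministic"
  )
  expect_false("nondeterministic" %in% list_regressors())
})

test_that("an external tree-ensemble adapter passes the contract", {
  skip_if_not_installed("ranger")
  register_regressor(
    "random_forest",
    fit = function(X, y, seed) {
      ranger::ranger(
        y = y, x = as.data.frame(X), num.trees = 100, seed = seed
      )
    },
    predict = function(object, X) {
      predict(object, data = as.data.frame(X))$predictions
    }
  )
  sim <- split_dataset(make_regression_dataset(80, 4, k = 2, sigma = 0.3,
                                               seed = 171)$data,
                       0.25, seed = 2)
  s <- score_regressor(fit_regressor("random_forest", sim, "y", seed = 5),
                       sim, "y")
  expect_gt(s$r_squared, 0.5)
})
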