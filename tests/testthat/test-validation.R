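test_that("R-squared metrics follow their defining sums of squares", {
  y <- c(1, 2, 3, 4)
  expect_equal(r2_metrics(y, y, p = 1)$r_squared, 1)
  expect_equal(r2_metrics(y, y, p = 1)$adj_r_squared, 1)
  expect_equal(r2_metrics(y, rep(mean(y), 4), p = 1)$r_squared, 0)

  yhat <- c(1.1, 1.9, 3.2, 3.8)
  sse <- sum((y - yhat)^2)
  sst <- sum((y - mean(y))^2)
  m <- r2_metrics(y, yhat, p = 1)
  expect_equal(m$r_squared, 1 - sse / sst, tolerance = 1e-12)
  expect_equal(m$adj_r_squared, 1 - (1 - m$r_squared) * 3 / 2, tolerance = 1e-12)
  expect_lte(m$adj_r_squared, m$r_squared)

  expect_error(r2_metrics(rep(1, 4), yhat, 1), "constant")
})

test_that("Friedman LOF matches direct substitution and its limits", {
  expect_equal(friedman_lof(0, 10, 2, 1), 0)
  # SSE=2, N=10, c=2, p=1, lambda=1, d=1: (2/10)/(1 - 3/10)^2
  expect_equal(friedman_lof(2, 10, 2, 1), (2 / 10) / (1 - 3 / 10)^2,
               tolerance = 1e-12)
  # large-N limit: LOF -> SSE/N within 1%
  n <- 1e4
  expect_equal(friedman_lof(123, n, 2, 1) / (123 / n), 1, tolerance = 0.01)
  expect_error(friedman_lof(1, 4, 3, 1), "too large")
})

test_that("global F-test agrees with lm's overall F statistic", {
  sim <- random_dataset(n = 25, m = 3, sigma = 0.4, seed = 51)
  fit <- fit_ols(sim$data, "y")
  yhat <- predict(fit, sim$data)
  ours <- global_f_test(sim$data$y, yhat, p = 3)
  lmfit <- lm(y ~ d001 + d002 + d003, data = sim$data)
  fs <- summary(lmfit)$fstatistic
  expect_equal(ours$f_statistic, unname(fs["value"]), tolerance = 1e-8)
  expect_equal(ours$p_value,
               pf(fs["value"], fs["numdf"], fs["dendf"], lower.tail = FALSE),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("Q2 leave-one-out PRESS shortcut equals explicit refits", {
  sim <- make_regression_dataset(30, 4, k = 3, sigma = 0.3, seed = 61)
  desc <- descriptor_names(sim$data, "y")
  shortcut <- q2_loo(sim$data, "y")
  oracle <- loo_refit_oracle(sim$data, "y", desc)
  expect_equal(shortcut, oracle, tolerance = 1e-10)

  # exact noiseless data -> Q2 = 1
  sim0 <- make_regression_dataset(30, 3, k = 3, sigma = 0, seed = 62)
  expect_equal(q2_loo(sim0$data, "y"), 1, tolerance = 1e-9)

  # permuted responses give Q2 < 0 nearly always
  neg <- 0
  n_trials <- 200
  set.seed(63)
  for (i in seq_len(n_trials)) {
    d <- sim$data
    d$y <- sample(d$y)
    if (q2_loo(d, "y") < 0) neg <- neg + 1
  }
  expect_gte(neg / n_trials, 0.95)
})

test_that("Q2 leave-many-out distribution behaves and reproduces", {
  sim <- make_regression_dataset(100, 5, k = 3, sigma = 0.2, seed = 71)
  lmo <- q2_lmo(sim$data, "y", iterations = 300, seed = 9)
  expect_equal(nrow(lmo$q2), 300)
  expect_true(all(lmo$q2$q2 <= 1))
  # close to the leave-one-out value on well-specified data
  expect_lte(abs(lmo$mean - q2_loo(sim$data, "y")), 0.05)
  # bit-reproducible
  lmo2 <- q2_lmo(sim$data, "y", iterations = 300, seed = 9)
  expect_identical(lmo$q2, lmo2$q2)

  expect_error(q2_lmo(sim$data, "y", train_frac = 1.0), "fewer than 2")
})

test_that("Y-randomization separates real signal from scrambled responses", {
  sim <- make_regression_dataset(60, 5, k = 3, sigma = 0.2, seed = 81)
  yr <- y_randomization(sim$data, "y", iterations = 500, seed = 4)
  fit <- fit_ols(sim$data, "y")
  # the unpermuted fit through the same code path reproduces the model R2
  expect_equal(yr$original$r_squared, fit$stats$r_squared, tolerance = 1e-10)
  # strong signal: every permuted R2 falls below the original
  expect_lt(max(yr$permuted$r_squared), yr$original$r_squared)
  expect_lt(max(yr$permuted$q2_loo), yr$original$q2_loo)
  # reproducible
  yr2 <- y_randomization(sim$data, "y", iterations = 500, seed = 4)
  expect_identical(yr$permuted, yr2$permuted)
})

test_that("permuted-null R2 has the p/(n-1) expectation on noise data", {
  # pure-noise response: R2 of a p-descriptor OLS fit has expectation
  # p/(n-1) under exchangeability
  n <- 40
  p <- 4
  noise <- make_regression_dataset(n, p, k = 0, sigma = 1, seed = 91,
                                   coefficients = NULL)
  d <- noise$data
  set.seed(92)
  d$y <- rnorm(n)
  yr <- y_randomization(d, "y", iterations = 500, seed = 5)
  mc_sigma <- sd(yr$permuted$r_squared) / sqrt(500)
  expect_lte(abs(mean(yr$permuted$r_squared) - p / (n - 1)), 3 * mc_sigma)
})

test_that("external Q2 family matches hand computation and its algebra", {
  y_tr <- c(1, 2, 3, 4, 5)
  y_te <- c(1.5, 2.5, 4.5)
  yhat <- c(1.4, 2.8, 4.2)
  q <- q2_external(y_te, yhat, y_tr)
  sse <- sum((y_te - yhat)^2)
  expect_equal(q$q2_f1, 1 - sse / sum((y_te - mean(y_tr))^2), tolerance = 1e-12)
  expect_equal(q$q2_f2, 1 - sse / sum((y_te - mean(y_te))^2), tolerance = 1e-12)
  expect_equal(q$q2_f3,
               1 - (sse / 3) / (sum((y_tr - mean(y_tr))^2) / 5),
               tolerance = 1e-12)

  # perfect predictions -> all three are 1
  q1 <- q2_external(y_te, y_te, y_tr)
  expect_equal(unlist(q1), c(q2_f1 = 1, q2_f2 = 1, q2_f3 = 1))

  # ybar_EXT == ybar_Tr makes F1 and F2 identical
  y_te2 <- c(2, 3, 4)  # mean 3 == mean(y_tr)
  q2 <- q2_external(y_te2, c(2.2, 2.9, 4.3), y_tr)
  expect_equal(q2$q2_f1, q2$q2_f2, tolerance = 1e-12)

  # Q2F2 <= Q2F1 always on random splits
  set.seed(13)
  for (i in 1:50) {
    yt <- rnorm(8)
    yh <- yt + rnorm(8, 0, 0.5)
    ytr <- rnorm(20)
    qq <- q2_external(yt, yh, ytr)
    expect_lte(qq$q2_f2, qq$q2_f1 + 1e-12)
  }

  # single-valued test response: F2 undefined, others returned
  qs <- q2_external(c(2, 2), c(1.9, 2.1), y_tr)
  expect_true(is.na(qs$q2_f2))
  expect_false(is.na(qs$q2_f1))
  expect_false(is.na(qs$q2_f3))
})

test_that("the full validation report assembles the battery coherently", {
  sim <- make_published_dataset("Pb_PS", n = 80, sigma = 3, seed = 101)
  d <- split_dataset(sim$data, 0.2, seed = 7)
  rep <- validate_model(d, "PS", lmo_iterations = 100, yrand_iterations = 100,
                        seed = 3)
  g <- glance(rep)
  expect_equal(g$n_train, 64)
  expect_equal(g$n_test, 16)
  expect_gt(g$r_squared, 0.9)
  expect_lte(g$q2_loo, g$r_squared)  # PRESS residuals dominate ordinary ones
  expect_true(all(c(g$q2_f1, g$q2_f2, g$q2_f3) <= 1))
  expect_lte(g$q2_f2, g$q2_f1 + 1e-12)
  expect_equal(nrow(rep$lmo$q2), 100)
  expect_equal(nrow(rep$y_randomization$permuted), 100)
  # deterministic under the same seed
  rep2 <- validate_model(d, "PS", lmo_iterations = 100, yrand_iterations = 100,
                         seed = 3)
  expect_identical(glance(rep), glance(rep2))
})
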