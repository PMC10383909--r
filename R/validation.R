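#' Fit metrics: R-squared and adjusted R-squared
#'
#' \eqn{R^2 = 1 - \sum(y_i-\hat y_i)^2 / \sum(y_i-\bar y)^2} and
#' \eqn{R^2_{adj} = 1 - (1-R^2)(n-1)/(n-p-1)}.
#'
#' @param y Observed response values.
#' @param y_hat Predicted values, same length.
#' @param p Number of descriptors in the model.
#' @return A named list with `r_squared` and `adj_r_squared`.
#' @export
r2_metrics <- function(y, y_hat, p) {
  stopifnot(length(y) == length(y_hat))
  n <- length(y)
  if (n <= p + 1) abort("Need n > p + 1 observations.")
  sst <- sum((y - mean(y))^2)
  if (sst == 0) abort("Response is constant; R-squared is undefined.")
  r2 <- 1 - sum((y - y_hat)^2) / sst
  list(
    r_squared = r2,
    adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - p - 1)
  )
}

#' Friedman lack-of-fit score
#'
#' \eqn{LOF = (SSE/N) / (1 - \lambda (c + d\,p)/N)^2}, penalizing model
#' size relative to the training-set size. `lambda` is a safety factor
#' and `d` a scaled smoothing parameter, both defaulting to 1.
#'
#' @param sse Training sum of squared errors.
#' @param n_rows Number of training rows N.
#' @param n_terms Number of model terms c (intercept excluded here;
#'   pass what your convention counts as "terms").
#' @param n_descriptors Total number of descriptors p in the model.
#' @param lambda,d Penalty parameters.
#' @return The LOF score (non-negative scalar).
#' @export
friedman_lof <- function(sse, n_rows, n_terms, n_descriptors,
                         lambda = 1, d = 1) {
  stopifnot(sse >= 0, n_rows > 0, n_terms >= 1)
  pen <- 1 - lambda * (n_terms + d * n_descriptors) / n_rows
  if (pen <= 0) {
    abort("Model too large for the training set: 1 - lambda*(c + d*p)/N <= 0.")
  }
  (sse / n_rows) / pen^2
}

#' Global regression F-test
#'
#' The overall significance test of a fitted regression,
#' \eqn{F = (SSR/p) / (SSE/(n-p-1))}, with its p-value; reported
#' alongside the lack-of-fit score as the model-significance measure.
#'
#' @inheritParams r2_metrics
#' @return Named list with `f_statistic`, `df1`, `df2`, `p_value`.
#' @export
global_f_test <- function(y, y_hat, p) {
  n <- length(y)
  if (n <= p + 1) abort("Need n > p + 1 observations.")
  sse <- sum((y - y_hat)^2)
  ssr <- sum((y_hat - mean(y))^2)
  f <- (ssr / p) / (sse / (n - p - 1))
  list(
    f_statistic = f, df1 = p, df2 = n - p - 1,
    p_value = pf(f, p, n - p - 1, lower.tail = FALSE)
  )
}

# Internal OLS on a plain matrix: coefficients, fitted values, hat diagonal.
ols_core <- function(X, y) {
  Xa <- cbind(1, X)
  qrx <- qr(Xa, tol = 1e-10)
  if (qrx$rank < ncol(Xa)) abort("Rank-deficient design in refit.")
  beta <- qr.coef(qrx, y)
  yhat <- drop(Xa %*% beta)
  R <- qr.R(qrx)
  V <- backsolve(R, t(Xa[, qrx$pivot, drop = FALSE]), transpose = TRUE)
  list(beta = beta, fitted = yhat, hat = colSums(V^2))
}

#' Leave-one-out cross-validated Q-squared
#'
#' \eqn{Q^2_{LOO} = 1 - \sum(y_i - \hat y_{i/i})^2 / \sum(y_i - \bar y)^2},
#' where \eqn{\hat y_{i/i}} is predicted by the model refitted without
#' compound i. For OLS the deleted residuals come from the PRESS
#' shortcut \eqn{e_i / (1 - h_i)}, which is algebraically identical to
#' the n explicit refits.
#'
#' @inheritParams fit_ols
#' @return The Q-squared value (at most 1, possibly negative).
#' @export
q2_loo <- function(data, response, descriptors = NULL) {
  if ("split" %in% names(data)) data <- data[data$split == "train", , drop = FALSE]
  descriptors <- descriptors %||% descriptor_names(data, response = response)
  y <- data[[response]]
  X <- descriptor_matrix(data, descriptors)
  if (nrow(X) <= ncol(X) + 2) abort("Need n > p + 2 for leave-one-out.")
  fit <- ols_core(X, y)
  press_resid <- (y - fit$fitted) / (1 - fit$hat)
  1 - sum(press_resid^2) / sum((y - mean(y))^2)
}

#' Leave-many-out cross-validation
#'
#' Repeatedly retains a random `train_frac` of the training compounds,
#' refits, and scores the held-out remainder with
#' \eqn{Q^2 = 1 - \sum(y-\hat y)^2 / \sum(y - \bar y_{retained})^2}
#' (the denominator uses the retained-subset mean). The distribution's
#' mean should sit close to the leave-one-out value for a stable model.
#'
#' @inheritParams fit_ols
#' @param iterations Number of random splits (published protocol: 2000).
#' @param train_frac Fraction retained per iteration (published: 0.7).
#' @param seed Integer seed; results are bit-reproducible.
#' @return A list with `q2` (tibble: iteration, q2), `mean`, and the
#'   settings used.
#' @export
q2_lmo <- function(data, response, descriptors = NULL,
                   iterations = 2000, train_frac = 0.7, seed = 1) {
  if ("split" %in% names(data)) data <- data[data$split == "train", , drop = FALSE]
  descriptors <- descriptors %||% descriptor_names(data, response = response)
  y <- data[[response]]
  X <- descriptor_matrix(data, descriptors)
  n <- nrow(X)
  n_keep <- floor(n * train_frac + 0.5)
  if (n - n_keep < 2) {
    abort("`train_frac` leaves fewer than 2 compounds out per iteration.")
  }
  if (n_keep <= ncol(X) + 1) abort("Retained subset too small to refit.")
  vals <- with_seed(seed, vapply(seq_len(iterations), function(i) {
    keep <- sample.int(n, n_keep)
    fit <- ols_core(X[keep, , drop = FALSE], y[keep])
    out <- setdiff(seq_len(n), keep)
    pred <- drop(cbind(1, X[out, , drop = FALSE]) %*% fit$beta)
    1 - sum((y[out] - pred)^2) / sum((y[out] - mean(y[keep]))^2)
  }, numeric(1)))
  list(
    q2 = tibble(iteration = seq_len(iterations), q2 = vals),
    mean = mean(vals),
    iterations = iterations, train_frac = train_frac, seed = seed
  )
}

#' Y-randomization (response scrambling)
#'
#' Refits the model on randomly permuted responses (descriptor subset
#' fixed, no re-selection) and records the R-squared, leave-one-out
#' Q-squared and K_XY of each permuted fit. For a real structure-property
#' relationship every permuted score should fall well below the original.
#' The identity permutation is excluded.
#'
#' @inheritParams fit_ols
#' @param iterations Number of permutations (published protocol: 2000).
#' @param seed Integer seed.
#' @return A list with `original` (r_squared, q2_loo, k_xy of the
#'   unpermuted fit) and `permuted` (tibble: iteration, r_squared,
#'   q2_loo, k_xy).
#' @export
y_randomization <- function(data, response, descriptors = NULL,
                            iterations = 2000, seed = 1) {
  if ("split" %in% names(data)) data <- data[data$split == "train", , drop = FALSE]
  descriptors <- descriptors %||% descriptor_names(data, response = response)
  y <- data[[response]]
  X <- descriptor_matrix(data, descriptors)
  n <- nrow(X)
  if (n < 5) abort("Need at least 5 compounds for a meaningful permutation test.")
  score <- function(yy) {
    fit <- ols_core(X, yy)
    sst <- sum((yy - mean(yy))^2)
    press <- (yy - fit$fitted) / (1 - fit$hat)
    c(
      r_squared = 1 - sum((yy - fit$fitted)^2) / sst,
      q2_loo = 1 - sum(press^2) / sst,
      k_xy = k_index(cbind(X, y = yy))
    )
  }
  orig <- score(y)
  perm <- with_seed(seed, t(vapply(seq_len(iterations), function(i) {
    repeat {
      yy <- y[sample.int(n)]
      if (!identical(yy, y)) break
    }
    score(yy)
  }, numeric(3))))
  list(
    original = as.list(orig),
    permuted = tibble(
      iteration = seq_len(iterations),
      r_squared = perm[, "r_squared"],
      q2_loo = perm[, "q2_loo"],
      k_xy = perm[, "k_xy"]
    ),
    iterations = iterations, seed = seed
  )
}

#' External validation Q-squared family
#'
#' Three external determination coefficients that differ in their
#' reference variance:
#' \itemize{
#'   \item \eqn{Q^2_{F1} = 1 - \sum(y_i-\hat y_i)^2 / \sum(y_i-\bar y_{Tr})^2}
#'   \item \eqn{Q^2_{F2} = 1 - \sum(y_i-\hat y_i)^2 / \sum(y_i-\bar y_{EXT})^2}
#'   \item \eqn{Q^2_{F3} = 1 - (SSE/n_{EXT}) / (SST_{Tr}/n_{Tr})}
#' }
#' Sums in F1/F2 run over the external (test) compounds. If the test
#' response is single-valued, Q2F2 is undefined and returned as `NA`.
#'
#' @param y_test Observed test-set responses.
#' @param y_hat_test Model predictions for the test set.
#' @param y_train Observed training-set responses (supplies the training
#'   mean and total sum of squares).
#' @return Named list with `q2_f1`, `q2_f2`, `q2_f3`.
#' @export
q2_external <- function(y_test, y_hat_test, y_train) {
  stopifnot(length(y_test) == length(y_hat_test))
  if (length(y_test) == 0) abort("Test set is empty.")
  sse <- sum((y_test - y_hat_test)^2)
  ybar_tr <- mean(y_train)
  sst_tr <- sum((y_train - ybar_tr)^2)
  sst_ext <- sum((y_test - mean(y_test))^2)
  list(
    q2_f1 = 1 - sse / sum((y_test - ybar_tr)^2),
    q2_f2 = if (sst_ext > 0) 1 - sse / sst_ext else NA_real_,
    q2_f3 = 1 - (sse / length(y_test)) / (sst_tr / length(y_train))
  )
}

#' Full validation report for one model on one split
#'
#' Runs the complete battery on a dataset carrying a `split` column:
#' training fit metrics (R2, adjusted R2, Friedman LOF, global F-test),
#' internal validation (leave-one-out Q2, leave-many-out distribution,
#' Y-randomization distributions) and external validation (Q2F1/F2/F3,
#' test RMSE).
#'
#' @inheritParams fit_ols
#' @param model Optional pre-fitted [qspr_model()]; by default an OLS
#'   model is fitted on the training rows with `descriptors`.
#' @param lmo_iterations,yrand_iterations Resampling sizes (published
#'   protocol: 2000 each).
#' @param lmo_train_frac Retained fraction for leave-many-out.
#' @param seed Integer seed driving both resampling procedures (on
#'   separate derived streams).
#' @return A `qspr_validation` object; use [glance()] for a one-row
#'   summary tibble and `$lmo` / `$y_randomization` for distributions.
#' @export
validate_model <- function(data, response, descriptors = NULL, model = NULL,
                           lmo_iterations = 2000, lmo_train_frac = 0.7,
                           yrand_iterations = 2000, seed = 1) {
  if (!"split" %in% names(data)) {
    abort("`data` needs a `split` column; see split_dataset().")
  }
  train <- data[data$split == "train", , drop = FALSE]
  test <- data[data$split == "test", , drop = FALSE]
  model <- model %||% fit_ols(train, response, descriptors)
  descriptors <- names(model$coefficients)
  p <- length(descriptors)
  y_tr <- train[[response]]
  yhat_tr <- predict(model, train)
  fitm <- r2_metrics(y_tr, yhat_tr, p)
  sse <- sum((y_tr - yhat_tr)^2)
  lof <- friedman_lof(sse, nrow(train), n_terms = p + 1, n_descriptors = p)
  ftest <- global_f_test(y_tr, yhat_tr, p)
  q2loo <- q2_loo(train, response, descriptors)
  lmo <- q2_lmo(train, response, descriptors,
                iterations = lmo_iterations, train_frac = lmo_train_frac,
                seed = seed)
  yrand <- y_randomization(train, response, descriptors,
                           iterations = yrand_iterations, seed = seed + 1L)
  ext <- if (nrow(test) > 0) {
    q2_external(test[[response]], predict(model, test), y_tr)
  } else {
    list(q2_f1 = NA_real_, q2_f2 = NA_real_, q2_f3 = NA_real_)
  }
  structure(
    list(
      model = model,
      response = response,
      n_train = nrow(train), n_test = nrow(test),
      r_squared = fitm$r_squared, adj_r_squared = fitm$adj_r_squared,
      lof = lof, f_test = ftest,
      q2_loo = q2loo, lmo = lmo, y_randomization = yrand,
      q2_f1 = ext$q2_f1, q2_f2 = ext$q2_f2, q2_f3 = ext$q2_f3,
      rmse_train = sqrt(sse / nrow(train)),
      rmse_test = if (nrow(test) > 0) {
        sqrt(mean((test[[response]] - predict(model, test))^2))
      } else NA_real_,
      seed = seed
    ),
    class = "qspr_validation"
  )
}

#' @export
print.qspr_validation <- function(x, ...) {
  cat("<qspr_validation>  n_train=", x$n_train, "  n_test=", x$n_test, "\n", sep = "")
  cat(sprintf("  R2=%.4f  R2adj=%.4f  LOF=%.4f  F=%.2f (p=%.3g)\n",
              x$r_squared, x$adj_r_squared, x$lof,
              x$f_test$f_statistic, x$f_test$p_value))
  cat(sprintf("  Q2loo=%.4f  Q2lmo(mean of %d)=%.4f\n",
              x$q2_loo, x$lmo$iterations, x$lmo$mean))
  cat(sprintf("  Q2F1=%.4f  Q2F2=%.4f  Q2F3=%.4f\n",
              x$q2_f1, x$q2_f2, x$q2_f3))
  invisible(x)
}

#' @export
glance.qspr_validation <- function(x, ...) {
  tibble(
    n_train = x$n_train, n_test = x$n_test,
    r_squared = x$r_squared, adj_r_squared = x$adj_r_squared,
    lof = x$lof,
    f_statistic = x$f_test$f_statistic, f_p_value = x$f_test$p_value,
    q2_loo = x$q2_loo, q2_lmo_mean = x$lmo$mean,
    yrand_max_r_squared = max(x$y_randomization$permuted$r_squared),
    q2_f1 = x$q2_f1, q2_f2 = x$q2_f2, q2_f3 = x$q2_f3,
    rmse_train = x$rmse_train, rmse_test = x$rmse_test
  )
}

#' @export
tidy.qspr_validation <- function(x, ...) {
  g <- glance(x)
  tibble(statistic = names(g), value = as.numeric(g[1, ]))
}

#' Resampling distribution plots for a validation report
#'
#' Histograms of the leave-many-out Q2 distribution and the
#' Y-randomization R2/Q2 distributions, with the original model's values
#' marked.
#'
#' @param object A `qspr_validation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qspr_validation <- function(object, ...) {
  d <- dplyr::bind_rows(
    tibble(panel = "LMO Q2", value = object$lmo$q2$q2,
           ref = object$q2_loo),
    tibble(panel = "Y-rand R2", value = object$y_randomization$permuted$r_squared,
           ref = object$y_randomization$original$r_squared),
    tibble(panel = "Y-rand Q2", value = object$y_randomization$permuted$q2_loo,
           ref = object$y_randomization$original$q2_loo)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$value)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey65", colour = "grey30") +
    ggplot2::geom_vline(ggplot2::aes(xintercept = .data$ref),
                        colour = "red", linetype = 2) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = "count",
                  title = "Resampling validation distributions",
                  subtitle = "dashed line: original model")
}
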