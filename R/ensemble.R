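#' AdaBoost.R2 boosting over linear base learners
#'
#' Drucker's AdaBoost.R2 for regression: each round fits the base
#' learner (OLS by default, a single-split regression stump optionally)
#' under the current sample weights, computes the loss-scaled errors of
#' all compounds, and reweights towards the hardest cases. Base learners
#' are fitted by weighted least squares rather than weighted bootstrap
#' resampling, so the procedure is deterministic and a single round with
#' uniform weights reduces exactly to [fit_ols()]. Prediction is the
#' weighted median of the base learners' outputs with weights
#' log(1/beta). Sample weights remain a probability distribution after
#' every round.
#'
#' A round whose weighted loss reaches 0 ends boosting early (the
#' learner is kept with a capped weight); a round with loss >= 0.5 is
#' discarded and boosting stops — if that happens in round 1 the single
#' base model is returned with a warning.
#'
#' @inheritParams fit_ols
#' @param n_estimators Maximum boosting rounds (default 50).
#' @param loss `"linear"`, `"square"` or `"exponential"` loss scaling.
#' @param base_learner `"ols"` (default) or `"stump"`.
#' @param seed Integer seed, accepted for interface uniformity with the
#'   other learners; the weighted-fit algorithm is deterministic.
#' @return A `qspr_boost` object with `predict()`, `glance()` support.
#' @export
adaboost_fit <- function(data, response, descriptors = NULL,
                         n_estimators = 50,
                         loss = c("linear", "square", "exponential"),
                         base_learner = c("ols", "stump"), seed = 1) {
  loss <- match.arg(loss)
  base_learner <- match.arg(base_learner)
  stopifnot(n_estimators >= 1)
  if ("split" %in% names(data)) data <- data[data$split == "train", , drop = FALSE]
  descriptors <- descriptors %||% descriptor_names(data, response = response)
  X <- descriptor_matrix(data, descriptors)
  y <- data[[response]]
  n <- nrow(X)
  if (base_learner == "ols" && n < 2 * (ncol(X) + 1)) {
    abort("Need n >= 2 * (p + 1) training compounds for boosted OLS.")
  }
  fit_base <- function(w) {
    if (base_learner == "ols") {
      sw <- sqrt(w)
      fit <- ols_core_weighted(X, y, sw)
      beta <- fit$beta
      function(Q) drop(cbind(1, Q) %*% beta)
    } else {
      fit_stump(X, y, w)
    }
  }
  state <- {
    w <- rep(1 / n, n)
    learners <- list()
    betas <- numeric(0)
    early <- FALSE
    for (t in seq_len(n_estimators)) {
      learner <- fit_base(w)
      err <- abs(y - learner(X))
      D <- max(err)
      # a residual spread at numerical-noise level counts as a perfect fit
      if (D <= 1e-10 * max(1, max(abs(y)))) D <- 0
      L <- if (D == 0) rep(0, n) else switch(loss,
        linear = err / D,
        square = (err / D)^2,
        exponential = 1 - exp(-err / D)
      )
      ebar <- sum(w * L)
      if (ebar >= 0.5) {
        if (t == 1) {
          warn("Base learner loss >= 0.5 in round 1; returning the single base model.")
          learners <- list(learner)
          betas <- 0.5  # log(1/0.5) > 0
        }
        break
      }
      learners[[length(learners) + 1]] <- learner
      if (ebar == 0) {
        # perfect learner: cap beta to keep a finite dominant weight
        betas <- c(betas, 1e-10)
        early <- TRUE
        break
      }
      beta_t <- ebar / (1 - ebar)
      betas <- c(betas, beta_t)
      w <- w * beta_t^(1 - L)
      w <- w / sum(w)
    }
    list(learners = learners, betas = betas, early = early)
  }
  structure(
    list(
      learners = state$learners,
      log_inv_beta = log(1 / state$betas),
      descriptors = descriptors,
      response = response,
      loss = loss, base_learner = base_learner,
      n_estimators_used = length(state$learners),
      terminated_early = state$early,
      seed = seed
    ),
    class = "qspr_boost"
  )
}

# Weighted-median combination of base predictions.
weighted_median_predict <- function(pred_matrix, weights) {
  apply(pred_matrix, 1, function(p) {
    ord <- order(p)
    cw <- cumsum(weights[ord])
    p[ord][which(cw >= sum(weights) / 2)[1]]
  })
}

#' @export
predict.qspr_boost <- function(object, newdata, ...) {
  Q <- descriptor_matrix(newdata, object$descriptors)
  preds <- vapply(object$learners, function(f) f(Q), numeric(nrow(Q)))
  if (nrow(Q) == 1) preds <- matrix(preds, nrow = 1)
  unname(weighted_median_predict(preds, object$log_inv_beta))
}

#' @export
print.qspr_boost <- function(x, ...) {
  cat("<qspr_boost>  AdaBoost.R2, ", x$n_estimators_used, " ",
      x$base_learner, " learner(s), ", x$loss, " loss\n", sep = "")
  invisible(x)
}

#' @export
glance.qspr_boost <- function(x, ...) {
  tibble(
    n_estimators = x$n_estimators_used,
    base_learner = x$base_learner,
    loss = x$loss,
    terminated_early = x$terminated_early
  )
}

# Weighted OLS via row scaling: minimizes sum w_i (y_i - x_i'b)^2.
ols_core_weighted <- function(X, y, sqrt_w) {
  Xa <- cbind(1, X) * sqrt_w
  qrx <- qr(Xa, tol = 1e-10)
  if (qrx$rank < ncol(Xa)) abort("Rank-deficient weighted design.")
  list(beta = qr.coef(qrx, y * sqrt_w))
}

# Single-split regression stump: best (column, threshold) minimizing
# weighted SSE; leaf values are weighted means.
fit_stump <- function(X, y, w = rep(1 / length(y), length(y))) {
  best <- list(sse = Inf)
  for (j in seq_len(ncol(X))) {
    xs <- sort(unique(X[, j]))
    if (length(xs) < 2) next
    cuts <- (head(xs, -1) + xs[-1]) / 2
    for (cut in cuts) {
      left <- X[, j] <= cut
      m1 <- sum(w[left] * y[left]) / sum(w[left])
      m2 <- sum(w[!left] * y[!left]) / sum(w[!left])
      sse <- sum(w[left] * (y[left] - m1)^2) + sum(w[!left] * (y[!left] - m2)^2)
      if (sse < best$sse) best <- list(sse = sse, j = j, cut = cut, m1 = m1, m2 = m2)
    }
  }
  if (!is.finite(best$sse)) {
    m <- sum(w * y) / sum(w)
    return(function(Q) rep(m, nrow(Q)))
  }
  function(Q) ifelse(Q[, best$j] <= best$cut, best$m1, best$m2)
}

#' Simple nonlinear regression forms
#'
#' Three classical alternatives to the linear model, each solved by
#' least squares in a transformed space:
#' * `polynomial`: raw powers of each descriptor up to `degree` (no
#'   cross terms); degree 1 is identical to [fit_ols()].
#' * `logarithmic`: `y ~ a + sum_j b_j log(x_j)`; all predictors must be
#'   strictly positive.
#' * `exponential`: `y = a * exp(b' x)` fitted as `log y ~ linear`; the
#'   response must be strictly positive. Predictions are back-transformed.
#'
#' @inheritParams fit_ols
#' @param form One of `"polynomial"`, `"logarithmic"`, `"exponential"`.
#' @param degree Polynomial degree (default 2).
#' @return A `qspr_nonlinear` object supporting `predict()`.
#' @export
nonlinear_fit <- function(data, response, descriptors = NULL,
                          form = c("polynomial", "logarithmic", "exponential"),
                          degree = 2) {
  form <- match.arg(form)
  if ("split" %in% names(data)) data <- data[data$split == "train", , drop = FALSE]
  descriptors <- descriptors %||% descriptor_names(data, response = response)
  X <- descriptor_matrix(data, descriptors)
  y <- data[[response]]
  transform_x <- switch(form,
    polynomial = function(Q) {
      do.call(cbind, lapply(seq_len(degree), function(d) Q^d))
    },
    logarithmic = function(Q) {
      if (any(Q <= 0)) abort("Logarithmic form requires strictly positive predictors.")
      log(Q)
    },
    exponential = function(Q) Q
  )
  if (form == "exponential") {
    if (any(y <= 0)) abort("Exponential form requires a strictly positive response.")
    yt <- log(y)
  } else {
    yt <- y
  }
  fit <- ols_core(transform_x(X), yt)
  beta <- fit$beta
  structure(
    list(
      form = form, degree = degree, beta = beta,
      descriptors = descriptors, response = response,
      transform_x = transform_x
    ),
    class = "qspr_nonlinear"
  )
}

#' @export
predict.qspr_nonlinear <- function(object, newdata, ...) {
  Q <- descriptor_matrix(newdata, object$descriptors)
  eta <- unname(drop(cbind(1, object$transform_x(Q)) %*% object$beta))
  if (object$form == "exponential") exp(eta) else eta
}

#' @export
print.qspr_nonlinear <- function(x, ...) {
  cat("<qspr_nonlinear>  form: ", x$form,
      if (x$form == "polynomial") paste0(" (degree ", x$degree, ")"), "\n", sep = "")
  invisible(x)
}

# ---- pluggable regressor adapters ------------------------------------------

the_registry <- new.env(parent = emptyenv())

#' Pluggable regressor adapters
#'
#' Third-party regressors (random forests, kernel machines, gradient
#' boosting, ...) enter the train/validate/screen pipeline through a
#' minimal adapter contract: a `fit(X, y, seed)` function returning any
#' object, and a `predict(object, X)` function returning a numeric
#' vector. Registration runs a determinism self-test — fitting twice
#' with the same seed on a small probe dataset must give identical
#' predictions — and fails otherwise.
#'
#' @param name Adapter name (registry key).
#' @param fit Function `(X, y, seed)` -> fitted object; `X` is a plain
#'   numeric matrix.
#' @param predict Function `(object, X)` -> numeric vector.
#' @return `register_regressor()` returns `name` invisibly;
#'   `list_regressors()` the registered names; `fit_regressor()` a
#'   `qspr_adapter_fit` supporting `predict()`.
#' @export
register_regressor <- function(name, fit, predict) {
  stopifnot(is.character(name), length(name) == 1L,
            is.function(fit), is.function(predict))
  probe_x <- matrix(c(seq(-1, 1, length.out = 12),
                      seq(1, -1, length.out = 12)^2), ncol = 2)
  colnames(probe_x) <- c("v1", "v2")
  probe_y <- 0.5 + probe_x[, 1] - 2 * probe_x[, 2]
  p1 <- predict(fit(probe_x, probe_y, seed = 42L), probe_x)
  p2 <- predict(fit(probe_x, probe_y, seed = 42L), probe_x)
  if (!isTRUE(all.equal(p1, p2, tolerance = 0)) || !identical(p1, p2)) {
    abort(paste0("Adapter `", name,
                 "` is not deterministic under a fixed seed; registration refused."))
  }
  assign(name, list(fit = fit, predict = predict), envir = the_registry)
  invisible(name)
}

#' @rdname register_regressor
#' @export
list_regressors <- function() sort(ls(the_registry))

#' @rdname register_regressor
#' @inheritParams fit_ols
#' @param seed Integer seed forwarded to the adapter's fit function.
#' @export
fit_regressor <- function(name, data, response, descriptors = NULL, seed = 1) {
  if (!exists(name, envir = the_registry, inherits = FALSE)) {
    abort(paste0("No adapter registered under `", name, "`."))
  }
  adapter <- get(name, envir = the_registry)
  if ("split" %in% names(data)) data <- data[data$split == "train", , drop = FALSE]
  descriptors <- descriptors %||% descriptor_names(data, response = response)
  X <- descriptor_matrix(data, descriptors)
  obj <- adapter$fit(X, data[[response]], seed = seed)
  structure(
    list(name = name, object = obj, predict_fn = adapter$predict,
         descriptors = descriptors, response = response, seed = seed),
    class = "qspr_adapter_fit"
  )
}

#' @export
predict.qspr_adapter_fit <- function(object, newdata, ...) {
  Q <- descriptor_matrix(newdata, object$descriptors)
  as.numeric(object$predict_fn(object$object, Q))
}

#' Score any fitted regressor with the validation battery's external
#' metrics
#'
#' Convenience wrapper: predicts the train and test rows of a split
#' dataset with any object supporting `predict(object, newdata)` and
#' returns the fit and external statistics as a one-row tibble.
#'
#' @param object A fitted model (`qspr_model`, `qspr_boost`,
#'   `qspr_nonlinear`, `qspr_adapter_fit`, ...).
#' @param data A dataset tibble with a `split` column.
#' @param response Response column name.
#' @param n_params Parameter count used for adjusted R2 (defaults to the
#'   number of descriptors for linear models, otherwise 1).
#' @return One-row tibble: r_squared, adj_r_squared, q2_f1/f2/f3,
#'   rmse_train, rmse_test.
#' @export
score_regressor <- function(object, data, response, n_params = NULL) {
  if (!"split" %in% names(data)) abort("`data` needs a `split` column.")
  train <- data[data$split == "train", , drop = FALSE]
  test <- data[data$split == "test", , drop = FALSE]
  n_params <- n_params %||% if (inherits(object, "qspr_model")) {
    length(object$coefficients)
  } else 1L
  yhat_tr <- predict(object, train)
  fitm <- r2_metrics(train[[response]], yhat_tr, n_params)
  ext <- if (nrow(test) > 0) {
    q2_external(test[[response]], predict(object, test), train[[response]])
  } else {
    list(q2_f1 = NA_real_, q2_f2 = NA_real_, q2_f3 = NA_real_)
  }
  tibble(
    r_squared = fitm$r_squared, adj_r_squared = fitm$adj_r_squared,
    q2_f1 = ext$q2_f1, q2_f2 = ext$q2_f2, q2_f3 = ext$q2_f3,
    rmse_train = sqrt(mean((train[[response]] - yhat_tr)^2)),
    rmse_test = if (nrow(test) > 0) {
      sqrt(mean((test[[response]] - predict(object, test))^2))
    } else NA_real_
  )
}
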