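#' Fit a multiple linear regression model
#'
#' Ordinary least squares with intercept, solved by rank-revealing QR
#' (relative rank tolerance 1e-10) rather than the normal equations.
#' Rank deficiency is an error naming the collinear columns.
#'
#' @param data A dataset tibble; if it carries a `split` column, only
#'   `"train"` rows are used.
#' @param response Name of the numeric response column.
#' @param descriptors Character vector of descriptor columns to use;
#'   defaults to all descriptor columns.
#' @param property,metal Optional labels recorded on the model.
#' @return A [qspr_model()] with training statistics (`n`, `r_squared`,
#'   `adj_r_squared`, `sigma`, `sse`) in `$stats`.
#' @export
fit_ols <- function(data, response, descriptors = NULL,
                    property = NA_character_, metal = NA_character_) {
  if ("split" %in% names(data)) data <- data[data$split == "train", , drop = FALSE]
  descriptors <- descriptors %||% descriptor_names(data, response = response)
  y <- data[[response]]
  if (is.null(y)) abort(paste0("Response column `", response, "` not found."))
  X <- descriptor_matrix(data, descriptors)
  n <- nrow(X)
  p <- ncol(X)
  if (n <= p + 1) {
    warn("Fewer observations than recommended (n <= p + 1); fit is exact or unstable.")
  }
  Xa <- cbind(`(Intercept)` = 1, X)
  qrx <- qr(Xa, tol = 1e-10)
  if (qrx$rank < ncol(Xa)) {
    bad <- colnames(Xa)[qrx$pivot[(qrx$rank + 1):ncol(Xa)]]
    abort(paste0("Design matrix is rank deficient; collinear column(s): ",
                 paste(bad, collapse = ", ")))
  }
  beta <- qr.coef(qrx, y)
  yhat <- drop(Xa %*% beta)
  e <- y - yhat
  sse <- sum(e^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  df_resid <- n - p - 1
  qspr_model(
    intercept = beta[[1]],
    coefficients = beta[-1],
    property = property,
    metal = metal,
    algorithm = "ols",
    stats = list(
      n = n, p = p, sse = sse, sst = sst,
      r_squared = r2,
      adj_r_squared = if (!is.na(r2) && df_resid > 0) 1 - (1 - r2) * (n - 1) / df_resid else NA_real_,
      sigma = if (df_resid > 0) sqrt(sse / df_resid) else NA_real_,
      rmse = sqrt(sse / n)
    )
  )
}

#' Leverage of query compounds
#'
#' Hat values \eqn{h_i = x_i^T (X^T X)^{-1} x_i} with the descriptor
#' vector augmented by a leading 1 for the intercept, computed through
#' the QR factor of the training design for numerical stability. For
#' training rows, \eqn{0 \le h_i \le 1} and the leverages sum to
#' \eqn{p' = p + 1}.
#'
#' @param train Training dataset tibble (rows define the model space).
#' @param query Query tibble whose rows are assessed; defaults to the
#'   training table itself.
#' @param descriptors Descriptor columns defining the model; defaults to
#'   all descriptors of `train`.
#' @param response Optional response name to exclude from the default
#'   descriptor set.
#' @return Numeric vector of leverages, one per query row.
#' @export
leverage <- function(train, query = NULL, descriptors = NULL, response = NULL) {
  descriptors <- descriptors %||% descriptor_names(train, response = response)
  query <- query %||% train
  Xa <- cbind(1, descriptor_matrix(train, descriptors))
  Qa <- cbind(1, descriptor_matrix(query, descriptors))
  qrx <- qr(Xa, tol = 1e-10)
  if (qrx$rank < ncol(Xa)) {
    abort("Training cross-product matrix is singular (collinear descriptors).")
  }
  R <- qr.R(qrx)
  # h_i = ||R^-T x_i||^2 since (X'X)^{-1} = R^{-1} R^{-T}; columns follow
  # the QR pivot order, so the query rows are permuted to match.
  V <- backsolve(R, t(Qa[, qrx$pivot, drop = FALSE]), transpose = TRUE)
  colSums(V^2)
}
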