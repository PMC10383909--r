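#' Leverage-based applicability domain assessment
#'
#' Computes each query compound's leverage against the model's training
#' design (intercept-augmented hat values) and compares it with the
#' warning threshold \eqn{h^* = 3 p' / n} where \eqn{p'} is the number of
#' model variables plus one and n the training-set size. Where the query
#' response is known, residuals are standardized by the training RMSE
#' and compounds with |standardized residual| > 3 are response outliers.
#'
#' Classes: `in_domain`; `X_outlier` (leverage above h*); `Y_outlier`
#' (standardized residual beyond +/-3); `XY_outlier` (both). Compounds
#' without a known response can only be X-classified — screening
#' candidates are gated on leverage alone.
#'
#' @param model A [qspr_model()] defining the descriptor set.
#' @param train Training dataset tibble (rows with `split == "train"` if
#'   a split column is present).
#' @param query Query tibble; defaults to the training table.
#' @param response Optional name of a response column present in both
#'   `train` (for the RMSE) and `query` (for residuals).
#' @return A `qspr_ad` tibble: `compound_id`, `leverage`, `h_star`,
#'   `std_residual`, `class`; attributes `h_star`, `rmse_train`.
#' @export
assess_domain <- function(model, train, query = NULL, response = NULL) {
  stopifnot(inherits(model, "qspr_model"))
  if ("split" %in% names(train)) train <- train[train$split == "train", , drop = FALSE]
  query <- query %||% train
  desc <- names(model$coefficients)
  h <- leverage(train, query, descriptors = desc)
  n <- nrow(train)
  p_prime <- length(desc) + 1
  h_star <- 3 * p_prime / n
  rmse <- if (!is.null(response)) {
    sqrt(mean((train[[response]] - predict(model, train))^2))
  } else {
    model$stats$rmse %||% NA_real_
  }
  std_resid <- if (!is.null(response) && response %in% names(query)) {
    (query[[response]] - predict(model, query)) / rmse
  } else {
    rep(NA_real_, nrow(query))
  }
  x_out <- h > h_star
  y_out <- !is.na(std_resid) & abs(std_resid) > 3
  cls <- dplyr::case_when(
    x_out & y_out ~ "XY_outlier",
    x_out ~ "X_outlier",
    y_out ~ "Y_outlier",
    TRUE ~ "in_domain"
  )
  out <- tibble(
    compound_id = if ("compound_id" %in% names(query)) {
      as.character(query$compound_id)
    } else {
      as.character(seq_len(nrow(query)))
    },
    leverage = unname(h),
    h_star = h_star,
    std_residual = std_resid,
    class = cls
  )
  structure(out, class = c("qspr_ad", class(out)),
            h_star = h_star, rmse_train = rmse, n_train = n,
            p_prime = p_prime)
}

#' Williams plot
#'
#' Leverage versus standardized residual with the h* and +/-3 boundary
#' lines; the standard visual summary of a leverage applicability
#' domain.
#'
#' @param object A `qspr_ad` tibble from [assess_domain()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qspr_ad <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$leverage,
                                       y = .data$std_residual,
                                       colour = .data$class)) +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = attr(object, "h_star"), linetype = 2) +
    ggplot2::geom_hline(yintercept = c(-3, 3), linetype = 3) +
    ggplot2::labs(x = "leverage h", y = "standardized residual",
                  title = "Williams plot",
                  subtitle = paste0("h* = ", signif(attr(object, "h_star"), 4)))
}
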