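# Small in-code fixtures shared across test files.

# Tiny hand-enterable dataset: 3 compounds, 2 descriptors, 1 response.
tiny_dataset <- function() {
  tibble::tibble(
    compound_id = c("a", "b", "c"),
    RBN = c(1, 2, 3),
    SPI = c(0.5, 0.1, 0.9),
    logB = c(5, 6, 7)
  )
}

# Random well-conditioned dataset with a linear truth.
random_dataset <- function(n = 30, m = 4, sigma = 0.2, seed = 42) {
  make_regression_dataset(n = n, m = m, k = min(3, m), sigma = sigma,
                          seed = seed)
}

# Zero-descriptor row covering a model's terms (for intercept evaluation).
zero_row <- function(model) {
  tibble::as_tibble(as.list(stats::setNames(
    rep(0, length(model$coefficients)), names(model$coefficients)
  )))
}

# Independent leave-one-out oracle: n explicit lm() refits.
loo_refit_oracle <- function(data, response, descriptors) {
  n <- nrow(data)
  press <- vapply(seq_len(n), function(i) {
    train <- data[-i, , drop = FALSE]
    f <- stats::as.formula(paste0(
      "`", response, "` ~ ", paste0("`", descriptors, "`", collapse = " + ")
    ))
    fit <- stats::lm(f, data = train)
    (data[[response]][i] - stats::predict(fit, data[i, , drop = FALSE]))^2
  }, numeric(1))
  y <- data[[response]]
  1 - sum(press) / sum((y - mean(y))^2)
}

# Independent 2-D Pareto oracle: staircase sweep over descending
# objective 1, tracking the best objective 2 among points with strictly
# greater objective 1. Both objectives maximized; ties handled explicitly
# (equal points are mutually non-dominating).
pareto_staircase_oracle <- function(pts) {
  nd <- rep(NA, nrow(pts))
  best_y_prev <- -Inf
  for (x in sort(unique(pts[, 1]), decreasing = TRUE)) {
    grp <- which(pts[, 1] == x)
    max_y_grp <- max(pts[grp, 2])
    for (j in grp) {
      nd[j] <- pts[j, 2] > best_y_prev && pts[j, 2] >= max_y_grp
    }
    best_y_prev <- max(best_y_prev, max_y_grp)
  }
  nd
}
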