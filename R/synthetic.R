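#' Synthetic descriptor/response datasets
#'
#' Generates a compound-by-descriptor table with the statistical
#' structure the modeling pipeline assumes: block-correlated Gaussian
#' descriptors (population mean 0, std 1 — the standard-scaled space),
#' a sparse linear ground truth driving the response with homoscedastic
#' Gaussian noise, and optional pathological columns (near-constant and
#' exact duplicates) for exercising the cleaning filters. A pure
#' function of its arguments and seed.
#'
#' @param n Number of compounds.
#' @param m Number of informative-pool descriptors (named `d001`, ...).
#' @param k Number of true descriptors (the first k of the pool).
#' @param rho Within-block equicorrelation of the descriptors, in
#'   \[0, 1); blocks of `block_size` consecutive descriptors share a
#'   common factor, blocks are independent.
#' @param block_size Descriptors per correlated block (default 5).
#' @param sigma Response noise standard deviation (response units).
#' @param n_near_constant Number of near-constant columns to append
#'   (named `nc_*`; std ~ 0.01, well under the 0.1 cleaning threshold).
#' @param n_duplicate Number of exact duplicate columns to append
#'   (named `dup_*`, copies of pool columns).
#' @param coefficients Optional named numeric vector of true
#'   coefficients (names must be pool descriptor names); by default k
#'   coefficients are drawn uniformly from `coef_range`.
#' @param intercept True intercept (default 0).
#' @param coef_range Range for random true coefficients.
#' @param seed Integer seed.
#' @return List with `data` (tibble: `compound_id`, descriptors, `y`)
#'   and `truth` (list: `descriptors`, `intercept`, `coefficients`,
#'   `sigma`).
#' @export
make_regression_dataset <- function(n, m, k = 3, rho = 0, block_size = 5,
                                    sigma = 0, n_near_constant = 0,
                                    n_duplicate = 0, coefficients = NULL,
                                    intercept = 0, coef_range = c(-5, 5),
                                    seed = 1) {
  stopifnot(n >= 2, m >= 1, k >= 0, k <= m, sigma >= 0,
            rho >= 0, rho < 1, block_size >= 1,
            n_near_constant >= 0, n_duplicate >= 0)
  with_seed(seed, {
    desc_names <- sprintf("d%03d", seq_len(m))
    X <- matrix(rnorm(n * m), n, m)
    if (rho > 0) {
      n_blocks <- ceiling(m / block_size)
      common <- matrix(rnorm(n * n_blocks), n, n_blocks)
      block_of <- rep(seq_len(n_blocks), each = block_size)[seq_len(m)]
      X <- sqrt(rho) * common[, block_of, drop = FALSE] + sqrt(1 - rho) * X
    }
    colnames(X) <- desc_names
    if (is.null(coefficients)) {
      true_names <- desc_names[seq_len(k)]
      coefficients <- setNames(runif(k, coef_range[1], coef_range[2]), true_names)
    } else {
      if (!all(names(coefficients) %in% desc_names)) {
        abort("Names of `coefficients` must be pool descriptor names.")
      }
      true_names <- names(coefficients)
    }
    y <- intercept +
      drop(X[, true_names, drop = FALSE] %*% coefficients) +
      rnorm(n, 0, sigma)
    data <- dplyr::bind_cols(
      tibble(compound_id = sprintf("cpd%04d", seq_len(n))),
      as_tibble(X)
    )
    if (n_near_constant > 0) {
      for (i in seq_len(n_near_constant)) {
        data[[sprintf("nc_%02d", i)]] <- 1 + rnorm(n, 0, 0.01)
      }
    }
    if (n_duplicate > 0) {
      src <- sample(desc_names, n_duplicate, replace = n_duplicate > m)
      for (i in seq_len(n_duplicate)) {
        data[[sprintf("dup_%02d", i)]] <- data[[src[i]]]
      }
    }
    data$y <- y
    list(
      data = data,
      truth = list(
        descriptors = true_names,
        intercept = intercept,
        coefficients = coefficients,
        sigma = sigma
      )
    )
  })
}

#' Simulate a dataset from a published bank equation
#'
#' Draws standard-normal values (the already-normalized descriptor
#' space the bank operates in) for the descriptors of one published
#' model and computes the response from the printed equation plus
#' Gaussian noise. The ground truth carries the printed coefficients,
#' so refitting recovers them exactly at `sigma = 0`.
#'
#' @param key Bank key, e.g. `"Cd_logB"` (see [published_models()]).
#' @param n Number of compounds.
#' @param sigma Noise standard deviation (response units).
#' @param seed Integer seed.
#' @return List with `data` (tibble: `compound_id`, the model's
#'   descriptors, response column named `logB` or `PS`) and `truth`
#'   (the generating [qspr_model()] plus `sigma`).
#' @export
make_published_dataset <- function(key, n, sigma = 0, seed = 1) {
  model <- published_models(key)
  desc <- names(model$coefficients)
  with_seed(seed, {
    X <- matrix(rnorm(n * length(desc)), n, length(desc),
                dimnames = list(NULL, desc))
    data <- dplyr::bind_cols(
      tibble(compound_id = sprintf("cpd%04d", seq_len(n))),
      as_tibble(X)
    )
    y <- predict(model, data) + rnorm(n, 0, sigma)
    data[[model$property]] <- y
    list(data = data, truth = list(model = model, sigma = sigma))
  })
}
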