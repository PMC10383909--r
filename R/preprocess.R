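#' Remove constant and near-constant descriptors
#'
#' Drops every descriptor column whose sample standard deviation (n-1
#' denominator) is strictly below `std_threshold`; a column with std
#' exactly at the threshold is retained. Column order is otherwise
#' preserved, and the operation is idempotent.
#'
#' @param data A dataset tibble (see [validate_qspr_dataset()]).
#' @param response Optional response column name, excluded from filtering.
#' @param std_threshold Removal threshold on the sample std (default 0.1).
#' @return The tibble with offending descriptor columns removed.
#' @export
remove_near_constant <- function(data, response = NULL, std_threshold = 0.1) {
  desc <- descriptor_names(data, response = response)
  if (length(desc) == 0) abort("No descriptor columns found.")
  stds <- vapply(desc, function(j) sd(data[[j]]), numeric(1))
  drop <- desc[stds < std_threshold]
  if (length(drop) == length(desc)) {
    abort("All descriptor columns are (near-)constant; nothing would remain.")
  }
  data[, setdiff(names(data), drop), drop = FALSE]
}

#' Remove highly correlated descriptors
#'
#' Scans descriptor pairs in table order; whenever a pair has absolute
#' Pearson correlation strictly above `r_threshold`, the later column is
#' dropped. A pair at exactly the threshold is kept. The surviving set
#' contains no pair above the threshold, and the pass is deterministic
#' and idempotent.
#'
#' The choice of which column of an offending pair to drop is
#' order-based (the later one); correlation with the response is not
#' consulted.
#'
#' @inheritParams remove_near_constant
#' @param r_threshold Absolute-correlation removal threshold (default 0.95).
#' @return The tibble with correlated descriptor columns removed.
#' @export
remove_correlated <- function(data, response = NULL, r_threshold = 0.95) {
  desc <- descriptor_names(data, response = response)
  if (nrow(data) < 2) abort("Need at least 2 compounds to compute correlations.")
  stds <- vapply(desc, function(j) sd(data[[j]]), numeric(1))
  if (any(stds == 0)) {
    abort(paste0(
      "Constant column(s) make correlations undefined: ",
      paste(desc[stds == 0], collapse = ", "),
      ". Run remove_near_constant() first."
    ))
  }
  X <- descriptor_matrix(data, desc)
  r <- abs(cor(X))
  keep <- character(0)
  for (j in desc) {
    if (length(keep) == 0 || all(r[j, keep] <= r_threshold)) {
      keep <- c(keep, j)
    }
  }
  drop <- setdiff(desc, keep)
  data[, setdiff(names(data), drop), drop = FALSE]
}

#' Standard scaling of descriptors
#'
#' `fit_scaler()` learns per-descriptor means and sample standard
#' deviations (n-1 denominator) from a training table;
#' `apply_scaler()` centres and scales any table with those *training*
#' statistics (never the query table's own), and `invert_scaler()`
#' undoes the transform. Applying a scaler to its own fitting table
#' yields columns with mean 0 and sample std 1.
#'
#' @param data A dataset tibble with at least 2 rows and no zero-variance
#'   descriptor columns.
#' @param response Optional response column name, excluded from scaling.
#' @return `fit_scaler()` returns a `qspr_scaler`; the other two return
#'   the transformed tibble.
#' @export
fit_scaler <- function(data, response = NULL) {
  if (nrow(data) < 2) abort("Need at least 2 compounds to fit a scaler.")
  desc <- descriptor_names(data, response = response)
  means <- vapply(desc, function(j) mean(data[[j]]), numeric(1))
  stds <- vapply(desc, function(j) sd(data[[j]]), numeric(1))
  if (any(stds == 0)) {
    abort(paste0("Zero-variance column(s): ",
                 paste(desc[stds == 0], collapse = ", ")))
  }
  structure(list(mean = means, std = stds), class = "qspr_scaler")
}

#' @export
print.qspr_scaler <- function(x, ...) {
  cat("<qspr_scaler> ", length(x$mean), " descriptors\n", sep = "")
  invisible(x)
}

#' @rdname fit_scaler
#' @param scaler A `qspr_scaler` from [fit_scaler()].
#' @export
apply_scaler <- function(data, scaler) {
  stopifnot(inherits(scaler, "qspr_scaler"))
  missing <- setdiff(names(scaler$mean), names(data))
  if (length(missing) > 0) {
    abort(paste0("Scaler descriptors absent from table: ",
                 paste(missing, collapse = ", ")))
  }
  for (j in names(scaler$mean)) {
    data[[j]] <- (data[[j]] - scaler$mean[[j]]) / scaler$std[[j]]
  }
  data
}

#' @rdname fit_scaler
#' @export
invert_scaler <- function(data, scaler) {
  stopifnot(inherits(scaler, "qspr_scaler"))
  missing <- setdiff(names(scaler$mean), names(data))
  if (length(missing) > 0) {
    abort(paste0("Scaler descriptors absent from table: ",
                 paste(missing, collapse = ", ")))
  }
  for (j in names(scaler$mean)) {
    data[[j]] <- data[[j]] * scaler$std[[j]] + scaler$mean[[j]]
  }
  data
}

#' Random train/test split
#'
#' Assigns each compound to the training or test set by simple random
#' sampling without replacement. The test-set size is `n * test_fraction`
#' rounded half away from zero. Reproducible for a fixed seed; the
#' session RNG state is left untouched.
#'
#' @param data A dataset tibble.
#' @param test_fraction Fraction of compounds held out, in (0, 1);
#'   values below 0.5 are the intended regime.
#' @param seed Integer seed.
#' @return The tibble with a `split` column of `"train"`/`"test"` labels.
#' @export
split_dataset <- function(data, test_fraction, seed) {
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must lie strictly between 0 and 1.")
  }
  n <- nrow(data)
  n_test <- floor(n * test_fraction + 0.5)
  if (n_test < 1) abort("Test fraction too small: no test compounds.")
  if (n_test >= n) abort("Test fraction too large: empty training set.")
  idx <- with_seed(seed, sample.int(n, n_test))
  data$split <- "train"
  data$split[idx] <- "test"
  data
}
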