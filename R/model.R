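#' Construct a linear QSPR model
#'
#' A `qspr_model` is the package's exchange format for a fitted (or
#' transcribed) multiple linear regression: an intercept plus named
#' descriptor coefficients, tagged with the property it predicts and the
#' target metal ion. Both GA-fitted models and the published equation bank
#' use this class.
#'
#' @param intercept Numeric scalar intercept.
#' @param coefficients Named numeric vector of descriptor coefficients;
#'   names must be unique and non-empty (an intercept-only model has a
#'   zero-length vector).
#' @param property `"logB"` (log10 stability constant) or `"PS"`
#'   (potentiometric sensitivity, mV/dec), or `NA` if untagged.
#' @param metal `"Cd2+"`, `"Cu2+"` or `"Pb2+"`, or `NA`.
#' @param algorithm Free-text label of the fitting algorithm.
#' @param stats Optional list of training statistics (kept as-is).
#' @param fitted_on Optional fingerprint of the training data.
#' @return An object of class `qspr_model`.
#' @export
qspr_model <- function(intercept, coefficients = numeric(0),
                       property = NA_character_, metal = NA_character_,
                       algorithm = "ols", stats = list(), fitted_on = NULL) {
  stopifnot(is.numeric(intercept), length(intercept) == 1L, is.finite(intercept))
  coefficients <- unlist(coefficients)
  if (length(coefficients) > 0) {
    if (is.null(names(coefficients)) || any(names(coefficients) == "")) {
      abort("All coefficients must be named.")
    }
    if (anyDuplicated(names(coefficients))) {
      abort("Coefficient names must be unique.")
    }
    if (!all(is.finite(coefficients))) abort("Coefficients must be finite.")
  }
  if (!is.na(property) && !property %in% c("logB", "PS")) {
    abort('`property` must be "logB" or "PS".')
  }
  if (!is.na(metal) && !metal %in% c("Cd2+", "Cu2+", "Pb2+")) {
    abort('`metal` must be one of "Cd2+", "Cu2+", "Pb2+".')
  }
  structure(
    list(
      intercept = unname(intercept),
      coefficients = coefficients,
      property = property,
      metal = metal,
      algorithm = algorithm,
      stats = stats,
      fitted_on = fitted_on
    ),
    class = "qspr_model"
  )
}

#' @export
print.qspr_model <- function(x, ...) {
  tag <- if (!is.na(x$metal) || !is.na(x$property)) {
    paste0(" [", x$metal, " ", x$property, "]")
  } else ""
  cat("<qspr_model>", tag, "  algorithm: ", x$algorithm, "\n", sep = "")
  cat("  intercept: ", format(x$intercept), "\n", sep = "")
  if (length(x$coefficients) > 0) {
    cat("  terms (", length(x$coefficients), "):\n", sep = "")
    print(x$coefficients)
  } else {
    cat("  (intercept-only)\n")
  }
  invisible(x)
}

#' Predict from a linear QSPR model
#'
#' Evaluates \eqn{\hat y_i = \alpha_0 + \sum_j \alpha_j x_{ij}} row-wise.
#' `newdata` must contain every descriptor the model uses; units/scaling
#' must match the space the model was fitted in.
#'
#' @param object A [qspr_model()].
#' @param newdata A data frame with the model's descriptor columns.
#' @param ... Unused.
#' @return Numeric vector of predictions, one per row of `newdata`.
#' @export
predict.qspr_model <- function(object, newdata, ...) {
  if (length(object$coefficients) == 0) {
    return(rep(object$intercept, nrow(newdata)))
  }
  missing <- setdiff(names(object$coefficients), names(newdata))
  if (length(missing) > 0) {
    abort(paste0(
      "`newdata` is missing model descriptor(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  X <- descriptor_matrix(newdata, names(object$coefficients))
  unname(drop(object$intercept + X %*% object$coefficients))
}

#' @export
tidy.qspr_model <- function(x, ...) {
  tibble(
    term = c("(Intercept)", names(x$coefficients)),
    estimate = c(x$intercept, unname(x$coefficients))
  )
}

#' @export
glance.qspr_model <- function(x, ...) {
  s <- x$stats
  tibble(
    algorithm = x$algorithm,
    property = x$property,
    metal = x$metal,
    n_terms = length(x$coefficients),
    n_train = s$n %||% NA_integer_,
    r_squared = s$r_squared %||% NA_real_,
    adj_r_squared = s$adj_r_squared %||% NA_real_,
    sigma = s$sigma %||% NA_real_
  )
}

MODEL_SCHEMA <- "qspr-model/1"

#' Serialize / deserialize a model as JSON
#'
#' Models are exchanged as a small versioned JSON document. Coefficients
#' are written at full decimal precision, so a round-trip preserves them
#' to better than 1e-12 (in practice exactly).
#'
#' @param model A [qspr_model()].
#' @param path File path for the JSON document.
#' @return `write_qspr_model()` returns `model` invisibly;
#'   `read_qspr_model()` returns the deserialized [qspr_model()].
#' @export
write_qspr_model <- function(model, path) {
  stopifnot(inherits(model, "qspr_model"))
  doc <- list(
    schema = MODEL_SCHEMA,
    intercept = model$intercept,
    terms = if (length(model$coefficients) > 0) {
      purrr::map2(
        names(model$coefficients), unname(model$coefficients),
        function(nm, b) list(name = nm, coefficient = b)
      )
    } else {
      list()
    },
    property = model$property,
    metal = model$metal,
    algorithm = model$algorithm,
    fitted_on = model$fitted_on
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(model)
}

#' @rdname write_qspr_model
#' @export
read_qspr_model <- function(path) {
  doc <- jsonlite::read_json(path)
  if (is.null(doc$schema) || !identical(doc$schema, MODEL_SCHEMA)) {
    abort(paste0(
      "Unknown model schema version: ", doc$schema %||% "<missing>",
      " (expected ", MODEL_SCHEMA, ")."
    ))
  }
  coefs <- vapply(doc$terms, function(t) as.numeric(t$coefficient), numeric(1))
  if (length(coefs) > 0) {
    names(coefs) <- vapply(doc$terms, function(t) as.character(t$name), character(1))
  }
  qspr_model(
    intercept = as.numeric(doc$intercept),
    coefficients = coefs,
    property = doc$property %||% NA_character_,
    metal = doc$metal %||% NA_character_,
    algorithm = doc$algorithm %||% "ols",
    fitted_on = doc$fitted_on
  )
}
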