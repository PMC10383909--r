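#' Descriptor datasets
#'
#' A qspr dataset is an ordinary tibble with a small column contract rather
#' than a bespoke container, so it moves freely through dplyr pipelines:
#'
#' * `compound_id` (character, unique) — required;
#' * `smiles` (character) — optional;
#' * `split` (character, `"train"`/`"test"`) — optional until
#'   [split_dataset()] assigns it;
#' * one numeric response column, named by the caller in each operation
#'   (e.g. a log10 stability constant, or a potentiometric sensitivity in
#'   mV/dec);
#' * every remaining numeric column is a molecular descriptor. Descriptor
#'   names are opaque labels (Dragon-style names such as `"H_D/Dt"` or
#'   `"B06[C-O]"` are fine); the pipeline never interprets them.
#'
#' `validate_qspr_dataset()` asserts the contract and returns its input
#' invisibly, so it can be dropped into a pipe.
#'
#' @param data A data frame following the contract above.
#' @param response Optional name of the response column to validate.
#'
#' @return `data`, invisibly, if all checks pass; otherwise an error naming
#'   the offending row/column.
#' @export
#' @examples
#' d <- tibble::tibble(
#'   compound_id = c("a", "b", "c"),
#'   RBN = c(1, 2, 3), SPI = c(0.5, 0.1, 0.9), logB = c(5, 6, 7)
#' )
#' validate_qspr_dataset(d, response = "logB")
validate_qspr_dataset <- function(data, response = NULL) {
  if (!is.data.frame(data)) abort("`data` must be a data frame.")
  nm <- names(data)
  dup <- nm[duplicated(nm)]
  if (length(dup) > 0) {
    abort(paste0("Duplicate column names: ", paste(unique(dup), collapse = ", ")))
  }
  if (!"compound_id" %in% nm) abort("Column `compound_id` is required.")
  ids <- as.character(data$compound_id)
  if (anyDuplicated(ids)) {
    abort(paste0(
      "Duplicate compound ids: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", ")
    ))
  }
  if ("split" %in% nm && !all(data$split %in% c("train", "test"))) {
    abort("`split` values must be \"train\" or \"test\".")
  }
  if (!is.null(response)) {
    if (!response %in% nm) {
      abort(paste0("Response column `", response, "` not found."))
    }
    if (!is.numeric(data[[response]])) {
      abort(paste0("Response column `", response, "` must be numeric."))
    }
  }
  desc <- descriptor_names(data, response = response)
  for (j in desc) {
    col <- data[[j]]
    if (!is.numeric(col)) {
      abort(paste0("Descriptor column `", j, "` is not numeric."))
    }
    bad <- which(!is.finite(col))
    if (length(bad) > 0) {
      abort(paste0(
        "Non-finite descriptor value in column `", j,
        "` for compound `", ids[bad[1]], "`."
      ))
    }
  }
  if (!is.null(response)) {
    bad <- which(!is.finite(data[[response]]))
    if (length(bad) > 0) {
      abort(paste0(
        "Non-finite response value for compound `", ids[bad[1]], "`."
      ))
    }
  }
  invisible(data)
}

#' List descriptor columns of a dataset
#'
#' Every numeric column that is not reserved (`compound_id`, `smiles`,
#' `split`) and is not the response is a descriptor.
#'
#' @inheritParams validate_qspr_dataset
#' @return Character vector of descriptor column names, in table order.
#' @export
descriptor_names <- function(data, response = NULL) {
  nm <- setdiff(names(data), c(reserved_columns(), response))
  nm[vapply(data[nm], is.numeric, logical(1))]
}

# Numeric descriptor matrix (rows = compounds) for a given descriptor set.
descriptor_matrix <- function(data, descriptors) {
  missing <- setdiff(descriptors, names(data))
  if (length(missing) > 0) {
    abort(paste0(
      "Missing descriptor column(s): ", paste(missing, collapse = ", ")
    ))
  }
  m <- as.matrix(as.data.frame(data)[, descriptors, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- if ("compound_id" %in% names(data)) data$compound_id else NULL
  m
}

#' Read a descriptor table from CSV
#'
#' Reads a comma-separated descriptor table (UTF-8, header row; first column
#' taken as the compound id, a column named `smiles` recognized as SMILES).
#' All other columns must be fully numeric; empty or non-numeric cells are a
#' load error naming the compound and column, never silent `NA`s.
#'
#' @param path Path to a CSV file.
#' @param response Name of the response column that must be present.
#' @return A validated tibble following the dataset contract, with a
#'   `split` column defaulting to `"train"`.
#' @export
read_descriptor_table <- function(path, response) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE, name_repair = "minimal")
  nm <- names(raw)
  if (anyDuplicated(nm)) {
    abort(paste0("Duplicate header(s) in ", path, ": ",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")))
  }
  if (length(nm) < 2) abort("Table must have an id column and at least one data column.")
  names(raw)[1] <- "compound_id"
  if (!response %in% names(raw)) {
    abort(paste0("Response column `", response, "` not found in ", path, "."))
  }
  out <- tibble(compound_id = as.character(raw$compound_id))
  for (j in setdiff(names(raw), "compound_id")) {
    if (j == "smiles") {
      out[[j]] <- raw[[j]]
      next
    }
    txt <- raw[[j]]
    num <- suppressWarnings(as.numeric(txt))
    bad <- which(is.na(num))
    if (length(bad) > 0) {
      abort(paste0(
        "Non-numeric or empty cell in column `", j, "` for compound `",
        out$compound_id[bad[1]], "`."
      ))
    }
    out[[j]] <- num
  }
  if (!"split" %in% names(out)) out$split <- "train"
  validate_qspr_dataset(out, response = response)
  out
}

#' Write a descriptor table to CSV
#'
#' Values are written in shortest round-trip decimal representation, so a
#' write/read cycle reproduces the numeric values bitwise.
#'
#' @param data A dataset tibble.
#' @param path Output CSV path.
#' @return `data`, invisibly.
#' @export
write_descriptor_table <- function(data, path) {
  readr::write_csv(data, path, progress = FALSE)
  invisible(data)
}
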