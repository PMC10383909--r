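#' The published model bank
#'
#' Six published GA-MLR equations predicting, for each of Cd2+, Cu2+ and
#' Pb2+, the log10 stability constant (logB) of the 1:1 metal-ligand
#' complex and the potentiometric sensitivity (PS, mV/dec) of the
#' corresponding ion-selective sensor. The bank ships as a versioned JSON
#' resource and is loaded into [qspr_model()] objects.
#'
#' The equations operate in standard-scaled descriptor space (each
#' descriptor centred by its training mean and divided by its training
#' sample standard deviation). The original training scaling statistics
#' were not published, so the bank's contract is that inputs are already
#' normalized; evaluating a model at the all-zero vector (the training
#' centroid in that space) returns its intercept.
#'
#' Two descriptor names in the PS/logB equations carry typesetting damage
#' in the printed source; they are stored under their standard Dragon
#' block names (`B06[C-O]`, `DLS_01`, `LLS_01`, `Eta_F_A`).
#'
#' @param key Optional bank key. One of `"Cd_logB"`, `"Cu_logB"`,
#'   `"Pb_logB"`, `"Cd_PS"`, `"Cu_PS"`, `"Pb_PS"`.
#' @return With `key = NULL`, a named list of the six [qspr_model()]
#'   objects; otherwise the single requested model.
#' @export
#' @examples
#' bank <- published_models()
#' names(bank)
#' zero <- tibble::tibble(compound_id = "x",
#'   !!!stats::setNames(as.list(rep(0, 6)), names(bank$Cd_logB$coefficients)))
#' predict(bank$Cd_logB, zero)  # the published intercept, 9.2894
published_models <- function(key = NULL) {
  path <- system.file("extdata", "published_models.json", package = "qsprscreen",
                      mustWork = TRUE)
  doc <- jsonlite::read_json(path)
  if (!identical(doc$schema, "qspr-model-bank/1")) {
    abort("Unrecognized model-bank schema version.")
  }
  bank <- purrr::imap(doc$models, function(entry, nm) {
    qspr_model(
      intercept = as.numeric(entry$intercept),
      coefficients = unlist(entry$terms),
      property = entry$property,
      metal = entry$metal,
      algorithm = "published"
    )
  })
  stopifnot(length(bank) == 6L)
  if (is.null(key)) return(bank)
  if (!key %in% names(bank)) {
    abort(paste0("Unknown bank key `", key, "`. Available: ",
                 paste(names(bank), collapse = ", ")))
  }
  bank[[key]]
}
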