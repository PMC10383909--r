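#' Enumerate an R-group substitution library
#'
#' Builds candidate SMILES by substituting every combination of the
#' supplied fragments into numbered attachment points of a core
#' template. Substitution is string-template based: placeholders are
#' written `[R1]`, `[R2]`, ... in the core and matched by the names of
#' `substituents`. The result is the Cartesian product of the fragment
#' lists in deterministic row-major order, with duplicate strings
#' removed (first occurrence kept).
#'
#' With `canonicalize = TRUE` and the ChemmineOB package available,
#' structures are additionally converted to canonical SMILES before
#' deduplication.
#'
#' @param core Core SMILES string containing each placeholder once.
#' @param substituents Named list, one character vector of fragment
#'   strings per placeholder (names `"R1"`, `"R2"`, ...).
#' @param canonicalize Canonicalize SMILES before deduplication
#'   (requires ChemmineOB; default `FALSE`, purely syntactic).
#' @return A tibble: `candidate_id`, `smiles`, plus one column per
#'   placeholder recording the fragment used.
#' @export
#' @examples
#' enumerate_library("c1ccc([R1])cc1[R2]",
#'                   list(R1 = c("O", "N"), R2 = c("C", "Cl", "Br")))
enumerate_library <- function(core, substituents, canonicalize = FALSE) {
  stopifnot(is.character(core), length(core) == 1L)
  if (length(substituents) == 0 || is.null(names(substituents)) ||
      any(names(substituents) == "")) {
    abort("`substituents` must be a named list with one entry per placeholder.")
  }
  if (anyDuplicated(names(substituents))) abort("Placeholder names must be unique.")
  for (nm in names(substituents)) {
    token <- paste0("[", nm, "]")
    if (!grepl(token, core, fixed = TRUE)) {
      abort(paste0("Placeholder ", token, " not found in the core template."))
    }
    if (length(substituents[[nm]]) < 1) {
      abort(paste0("Placeholder ", token, " has no substituents."))
    }
  }
  stray <- regmatches(core, gregexpr("\\[R[0-9]+\\]", core))[[1]]
  known <- paste0("[", names(substituents), "]")
  if (!all(stray %in% known)) {
    abort(paste0("Core placeholder(s) without substituent lists: ",
                 paste(setdiff(stray, known), collapse = ", ")))
  }
  grid <- tidyr::expand_grid(!!!substituents)
  smiles <- purrr::pmap_chr(grid, function(...) {
    frags <- list(...)
    s <- core
    for (nm in names(frags)) {
      s <- sub(paste0("[", nm, "]"), frags[[nm]], s, fixed = TRUE)
    }
    s
  })
  if (canonicalize) {
    if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
      abort("`canonicalize = TRUE` requires the ChemmineOB package.")
    }
    smiles <- vapply(smiles, function(s) {
      out <- tryCatch(
        ChemmineOB::convertFormat("SMI", "CAN", source = s),
        error = function(e) s
      )
      trimws(strsplit(out, "\t|\n")[[1]][1])
    }, character(1), USE.NAMES = FALSE)
  }
  keep <- !duplicated(smiles)
  out <- dplyr::bind_cols(
    tibble(smiles = smiles[keep]),
    grid[keep, , drop = FALSE]
  )
  dplyr::bind_cols(
    tibble(candidate_id = sprintf("NEW%02d", seq_len(nrow(out)))),
    out
  )
}

#' Predict screening candidates with a set of models
#'
#' Evaluates every model of a bank (or any named list of
#' [qspr_model()]s) on a candidate descriptor table and, where training
#' tables are supplied, gates each candidate on the leverage
#' applicability domain of the corresponding model (`h_i <= h*`, the
#' leverage-only gate used for candidates without measured responses).
#'
#' @param candidates Descriptor tibble of the candidates (must contain
#'   every descriptor any model uses, in the models' scaled space).
#' @param models Named list of [qspr_model()]s (e.g. [published_models()]).
#' @param train_data Optional named list (same names as `models`) of
#'   training tibbles used for the leverage gates; models without an
#'   entry are not gated (gate recorded as `NA`).
#' @return A `qspr_screen` tibble: `compound_id`, one `pred_<key>` and
#'   one `in_ad_<key>` column per model.
#' @export
predict_candidates <- function(candidates, models, train_data = NULL) {
  stopifnot(is.list(models), length(models) > 0, !is.null(names(models)))
  all_desc <- unique(unlist(lapply(models, function(m) names(m$coefficients))))
  missing <- setdiff(all_desc, names(candidates))
  if (length(missing) > 0) {
    abort(paste0("Candidates are missing descriptor(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble(
    compound_id = if ("compound_id" %in% names(candidates)) {
      as.character(candidates$compound_id)
    } else {
      as.character(seq_len(nrow(candidates)))
    }
  )
  for (key in names(models)) {
    m <- models[[key]]
    out[[paste0("pred_", key)]] <- predict(m, candidates)
    gate <- rep(NA, nrow(candidates))
    if (!is.null(train_data) && key %in% names(train_data)) {
      ad <- assess_domain(m, train_data[[key]], candidates)
      gate <- ad$leverage <= ad$h_star
    }
    out[[paste0("in_ad_", key)]] <- gate
  }
  structure(out, class = c("qspr_screen", class(out)),
            model_keys = names(models),
            properties = vapply(models, function(m) m$property, character(1)),
            metals = vapply(models, function(m) m$metal, character(1)))
}

#' Non-dominated (Pareto) front of a point set
#'
#' A point is on the front when no other point is at least as good on
#' every objective and strictly better on one. All objectives are
#' maximized; flip signs to minimize.
#'
#' @param points Numeric matrix or data frame, one row per candidate,
#'   one column per objective (maximized).
#' @return Logical vector: `TRUE` for non-dominated rows. Identical rows
#'   are all on the front.
#' @export
pareto_front <- function(points) {
  pts <- as.matrix(points)
  n <- nrow(pts)
  nd <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!nd[i]) next
    dominated <- vapply(seq_len(n), function(j) {
      j != i && all(pts[j, ] >= pts[i, ]) && any(pts[j, ] > pts[i, ])
    }, logical(1))
    if (any(dominated)) nd[i] <- FALSE
  }
  nd
}

# Non-dominated sorting: rank 1 = front, rank 2 = front after removing
# rank 1, etc.
pareto_ranks <- function(points) {
  pts <- as.matrix(points)
  rank <- rep(NA_integer_, nrow(pts))
  remaining <- seq_len(nrow(pts))
  r <- 1L
  while (length(remaining) > 0) {
    on_front <- pareto_front(pts[remaining, , drop = FALSE])
    rank[remaining[on_front]] <- r
    remaining <- remaining[!on_front]
    r <- r + 1L
  }
  rank
}

#' Pareto-consensus candidate selection
#'
#' For each metal, ranks the AD-passing candidates by non-dominated
#' sorting on the two objectives (stability constant logB, maximized;
#' potentiometric sensitivity PS in the configured direction — the
#' default minimizes PS, equivalent to maximizing 1/PS for positive PS
#' but order-safe when predictions go negative). The consensus set is
#' the candidates on the first front for every metal; within fronts,
#' candidates are ordered by normalized Euclidean distance to the ideal
#' point. Candidates failing any applicability-domain gate are excluded
#' from ranking altogether.
#'
#' @param screen A `qspr_screen` from [predict_candidates()].
#' @param ps_direction `"min"` (default) or `"max"`: whether a low or a
#'   high PS is desirable.
#' @return A tibble: `compound_id`, `pareto_rank_<metal>` per metal,
#'   `ideal_distance` (summed normalized distance across metals),
#'   `consensus` flag, sorted with consensus candidates first by
#'   ascending distance.
#' @export
pareto_select <- function(screen, ps_direction = c("min", "max")) {
  ps_direction <- match.arg(ps_direction)
  keys <- attr(screen, "model_keys")
  props <- attr(screen, "properties")
  metals <- attr(screen, "metals")
  if (is.null(keys)) abort("`screen` must come from predict_candidates().")
  gate_cols <- paste0("in_ad_", keys)
  gates <- as.matrix(as.data.frame(screen)[, gate_cols, drop = FALSE])
  eligible <- apply(gates, 1, function(g) all(is.na(g) | g))
  if (!any(eligible)) abort("No candidate passes all applicability-domain gates.")
  out <- tibble(compound_id = screen$compound_id)
  metals_u <- unique(metals)
  dist_total <- rep(0, nrow(screen))
  front_all <- rep(TRUE, nrow(screen))
  for (met in metals_u) {
    k_logb <- keys[metals == met & props == "logB"]
    k_ps <- keys[metals == met & props == "PS"]
    if (length(k_logb) != 1 || length(k_ps) != 1) {
      abort(paste0("Need exactly one logB and one PS model for metal ", met, "."))
    }
    obj <- cbind(
      screen[[paste0("pred_", k_logb)]],
      screen[[paste0("pred_", k_ps)]] * if (ps_direction == "min") -1 else 1
    )
    ranks <- rep(NA_integer_, nrow(screen))
    ranks[eligible] <- pareto_ranks(obj[eligible, , drop = FALSE])
    metal_label <- sub("\\d\\+$", "", met)
    out[[paste0("pareto_rank_", metal_label)]] <- ranks
    rng <- apply(obj[eligible, , drop = FALSE], 2, function(v) {
      r <- diff(range(v))
      if (r == 0) 1 else r
    })
    ideal <- apply(obj[eligible, , drop = FALSE], 2, max)
    d <- sqrt(rowSums(((t(t(obj) - ideal)) / rep(rng, each = nrow(obj)))^2))
    dist_total <- dist_total + d
    front_all <- front_all & !is.na(ranks) & ranks == 1L
  }
  out$ideal_distance <- ifelse(eligible, dist_total, NA_real_)
  out$consensus <- front_all & eligible
  dplyr::arrange(out, dplyr::desc(.data$consensus), .data$ideal_distance)
}

#' Trade-off plot of screening predictions
#'
#' Scatter of predicted stability constant against predicted
#' potentiometric sensitivity for each metal, highlighting consensus
#' candidates; the screening analogue of a trade-off plot where better
#' candidates sit towards high logB and the preferred PS direction.
#'
#' @param object A `qspr_screen` from [predict_candidates()].
#' @param selection Optional output of [pareto_select()] used to label
#'   consensus candidates.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qspr_screen <- function(object, selection = NULL, ...) {
  keys <- attr(object, "model_keys")
  props <- attr(object, "properties")
  metals <- attr(object, "metals")
  d <- purrr::map_dfr(unique(metals), function(met) {
    k_logb <- keys[metals == met & props == "logB"][1]
    k_ps <- keys[metals == met & props == "PS"][1]
    tibble(
      compound_id = object$compound_id,
      metal = met,
      logB = object[[paste0("pred_", k_logb)]],
      PS = object[[paste0("pred_", k_ps)]]
    )
  })
  if (!is.null(selection)) {
    d <- dplyr::left_join(
      d, dplyr::select(selection, "compound_id", "consensus"),
      by = "compound_id"
    )
  } else {
    d$consensus <- FALSE
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$PS, y = .data$logB,
                                  colour = .data$consensus)) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~metal, scales = "free") +
    ggplot2::labs(title = "Screening trade-off: stability vs sensitivity",
                  x = "predicted PS (mV/dec)", y = "predicted logB")
}
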