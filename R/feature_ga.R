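#' Multivariate K correlation index
#'
#' Todeschini's K index of total correlation among the columns of a
#' matrix: with \eqn{\lambda_j} the eigenvalues of the column correlation
#' matrix and p the number of columns,
#' \deqn{K = \frac{\sum_j |\lambda_j/\sum\lambda - 1/p|}{2(p-1)/p} \in [0, 1].}
#' K is 0 for pairwise-uncorrelated columns and 1 when the correlation
#' matrix has rank one (e.g. duplicated columns).
#'
#' @param x Numeric matrix with at least two non-constant columns.
#' @return The K index, a scalar in \[0, 1\].
#' @export
k_index <- function(x) {
  x <- as.matrix(x)
  if (ncol(x) < 2) abort("Need at least 2 columns.")
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    abort(paste0("Constant column(s) make the correlation matrix undefined: ",
                 paste(colnames(x)[sds == 0] %||% which(sds == 0), collapse = ", ")))
  }
  p <- ncol(x)
  lam <- eigen(cor(x), symmetric = TRUE, only.values = TRUE)$values
  lam <- pmax(lam, 0)
  sum(abs(lam / sum(lam) - 1 / p)) / (2 * (p - 1) / p)
}

#' QUIK rule check
#'
#' The QUIK collinearity rule compares the K correlation index of the
#' descriptor block alone (K_XX) with that of the block augmented by the
#' response (K_XY). A model is rejected when K_XY - K_XX < delta_K: its
#' apparent fit adds less correlation with the response than the
#' descriptors already share among themselves, the signature of a
#' collinearity artifact.
#'
#' @param data A dataset tibble (or anything [descriptor_matrix()] accepts).
#' @param response Response column name.
#' @param descriptors Descriptor subset to check; defaults to all.
#' @param delta_k Rejection threshold (default 0.05).
#' @return List with `pass` (logical), `k_xx`, `k_xy`.
#' @export
quik_check <- function(data, response, descriptors = NULL, delta_k = 0.05) {
  descriptors <- descriptors %||% descriptor_names(data, response = response)
  if (length(descriptors) == 0) abort("Empty descriptor subset.")
  X <- descriptor_matrix(data, descriptors)
  y <- data[[response]]
  k_xx <- if (ncol(X) >= 2) k_index(X) else 0
  k_xy <- k_index(cbind(X, .y = y))
  list(pass = (k_xy - k_xx) >= delta_k, k_xx = k_xx, k_xy = k_xy)
}

#' GA configuration
#'
#' @param population_size Chromosomes per generation (default 100).
#' @param generations Maximum generations (default 500).
#' @param crossover_rate Probability a mating pair recombines (default 0.8).
#' @param mutation_rate Per-gene bit-flip probability (default 0.05).
#' @param subset_size_max Largest allowed descriptor subset; defaults at
#'   run time to `floor(n_train / 5)` (the 5-observations-per-variable
#'   rule against overfitting).
#' @param delta_k QUIK rejection threshold (default 0.05).
#' @param fitness `"q2_loo"` (default) or `"r2_adj"`.
#' @param convergence_share Stop early once at least this share of a
#'   generation attains the generation's best fitness (default 0.9).
#' @param elite Number of top chromosomes copied unchanged (default 1).
#' @return A list of class `ga_config`.
#' @export
ga_config <- function(population_size = 100, generations = 500,
                      crossover_rate = 0.8, mutation_rate = 0.05,
                      subset_size_max = NULL, delta_k = 0.05,
                      fitness = c("q2_loo", "r2_adj"),
                      convergence_share = 0.9, elite = 1) {
  fitness <- match.arg(fitness)
  stopifnot(
    population_size >= 4, generations >= 1,
    crossover_rate >= 0, crossover_rate <= 1,
    mutation_rate >= 0, mutation_rate <= 1,
    is.null(subset_size_max) || subset_size_max >= 1,
    convergence_share > 0, convergence_share <= 1, elite >= 0
  )
  structure(
    list(
      population_size = population_size, generations = generations,
      crossover_rate = crossover_rate, mutation_rate = mutation_rate,
      subset_size_max = subset_size_max, delta_k = delta_k,
      fitness = fitness, convergence_share = convergence_share,
      elite = elite
    ),
    class = "ga_config"
  )
}

# Fitness of one descriptor subset (logical mask over the pool).
# Infeasible chromosomes (empty, oversized, violating the 5n rule or the
# QUIK rule, or rank-deficient) score -Inf rather than being repaired.
ga_fitness_one <- function(mask, Xmat, yvec, config, n_train, cache) {
  key <- paste0("s", paste(which(mask), collapse = ","))
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  size <- sum(mask)
  val <- -Inf
  if (size >= 1 && size <= config$subset_size_max && 5 * size <= n_train) {
    Xs <- Xmat[, mask, drop = FALSE]
    ok <- tryCatch({
      k_xx <- if (size >= 2) k_index(Xs) else 0
      k_xy <- k_index(cbind(Xs, .y = yvec))
      (k_xy - k_xx) >= config$delta_k
    }, error = function(e) FALSE)
    if (ok) {
      val <- tryCatch({
        fit <- ols_core(Xs, yvec)
        sst <- sum((yvec - mean(yvec))^2)
        if (config$fitness == "q2_loo") {
          press <- (yvec - fit$fitted) / (1 - fit$hat)
          1 - sum(press^2) / sst
        } else {
          r2 <- 1 - sum((yvec - fit$fitted)^2) / sst
          1 - (1 - r2) * (n_train - 1) / (n_train - size - 1)
        }
      }, error = function(e) -Inf)
    }
  }
  cache[[key]] <- val
  val
}

#' Genetic-algorithm descriptor selection for MLR
#'
#' Evolves descriptor-membership bitmasks towards subsets whose OLS model
#' maximizes the chosen fitness, subject to the QUIK collinearity rule
#' and the 5-observations-per-variable size cap. Mechanics: tournament
#' selection (size 2), uniform crossover, per-gene bit-flip mutation,
#' elitism; infeasible chromosomes score `-Inf`. Evolution stops when a
#' generation converges (a `convergence_share` majority at the best
#' fitness) or generations are exhausted. The top subsets then undergo a
#' deterministic backward-elimination refinement: a member is dropped
#' whenever doing so does not lower the fitness (to 1e-10), trimming
#' redundant descriptors that ride along with a well-fitting core.
#'
#' @inheritParams fit_ols
#' @param config A [ga_config()].
#' @param seed Integer seed; the run is fully reproducible.
#' @param n_keep Number of top distinct subsets returned (default 10).
#' @return A `qspr_ga` object: `$ranking` (tibble with rank, subset
#'   string, size, fitness), `$models` (list of [qspr_model()]s in rank
#'   order), `$trace` (per-generation best/mean fitness), `$converged`.
#'   `tidy()` returns the ranking tibble.
#' @export
ga_select <- function(data, response, descriptors = NULL,
                      config = ga_config(), seed = 1, n_keep = 10) {
  if ("split" %in% names(data)) data <- data[data$split == "train", , drop = FALSE]
  descriptors <- descriptors %||% descriptor_names(data, response = response)
  m <- length(descriptors)
  if (m < 2) abort("Need at least 2 candidate descriptors.")
  X <- descriptor_matrix(data, descriptors)
  y <- data[[response]]
  n_train <- nrow(X)
  if (is.null(config$subset_size_max)) {
    config$subset_size_max <- max(1L, floor(n_train / 5))
  }
  cache <- new.env(parent = emptyenv())

  run <- with_seed(seed, {
    pop <- lapply(seq_len(config$population_size), function(i) {
      size <- sample.int(min(config$subset_size_max, m), 1)
      mask <- rep(FALSE, m)
      mask[sample.int(m, size)] <- TRUE
      mask
    })
    trace <- list()
    converged <- FALSE
    fit <- vapply(pop, ga_fitness_one, numeric(1),
                  Xmat = X, yvec = y, config = config, n_train = n_train,
                  cache = cache)
    for (gen in seq_len(config$generations)) {
      best <- max(fit)
      trace[[gen]] <- tibble(
        generation = gen, best = best,
        mean = mean(fit[is.finite(fit)])
      )
      if (is.finite(best) &&
          mean(fit == best) >= config$convergence_share) {
        converged <- TRUE
        break
      }
      if (gen == config$generations) break
      ord <- order(fit, decreasing = TRUE)
      elite <- pop[ord[seq_len(min(config$elite, length(pop)))]]
      tournament <- function() {
        ij <- sample.int(length(pop), 2)
        if (fit[ij[1]] >= fit[ij[2]]) pop[[ij[1]]] else pop[[ij[2]]]
      }
      children <- list()
      while (length(children) < config$population_size - length(elite)) {
        p1 <- tournament()
        p2 <- tournament()
        if (runif(1) < config$crossover_rate) {
          swap <- runif(m) < 0.5
          c1 <- ifelse(swap, p2, p1)
          c2 <- ifelse(swap, p1, p2)
        } else {
          c1 <- p1
          c2 <- p2
        }
        for (child in list(c1, c2)) {
          flip <- runif(m) < config$mutation_rate
          children[[length(children) + 1]] <- xor(child, flip)
        }
      }
      pop <- c(elite, children[seq_len(config$population_size - length(elite))])
      fit <- vapply(pop, ga_fitness_one, numeric(1),
                    Xmat = X, yvec = y, config = config, n_train = n_train,
                    cache = cache)
    }
    list(trace = dplyr::bind_rows(trace), converged = converged)
  })

  evaluated <- as.list(cache)
  vals <- unlist(evaluated, use.names = TRUE)
  vals <- vals[is.finite(vals)]
  if (length(vals) == 0) {
    abort("No QUIK-feasible descriptor subset found within the configured generations.")
  }
  # Parsimony refinement: backward-eliminate each top subset, dropping a
  # member whenever the (rounded) fitness does not decrease, so redundant
  # descriptors riding along with a perfect-fitting core are trimmed.
  refine <- function(idx) {
    repeat {
      cur <- ga_fitness_one(seq_len(m) %in% idx, X, y, config, n_train, cache)
      improved <- FALSE
      for (drop_i in idx) {
        cand <- setdiff(idx, drop_i)
        if (length(cand) == 0) next
        f <- ga_fitness_one(seq_len(m) %in% cand, X, y, config, n_train, cache)
        if (round(f, 10) >= round(cur, 10)) {
          idx <- cand
          improved <- TRUE
          break
        }
      }
      if (!improved) return(idx)
    }
  }
  pool <- names(vals)[order(-round(vals, 10), names(vals))]
  pool <- pool[seq_len(min(3 * n_keep, length(pool)))]
  refined_keys <- unique(vapply(pool, function(k) {
    idx <- refine(as.integer(strsplit(sub("^s", "", k), ",")[[1]]))
    paste0("s", paste(idx, collapse = ","))
  }, character(1)))
  vals <- vapply(refined_keys, function(k) cache[[k]], numeric(1))
  # rank by fitness; fitness ties (within 1e-10, e.g. noiseless data where
  # any superset of the truth also fits perfectly) break towards the
  # smaller subset, then the subset key, so the ranking is deterministic
  # and parsimonious
  sizes <- vapply(names(vals), function(k) {
    length(strsplit(sub("^s", "", k), ",")[[1]])
  }, integer(1))
  vals <- vals[order(-round(vals, 10), sizes, names(vals))]
  vals <- vals[seq_len(min(n_keep, length(vals)))]
  subsets <- lapply(names(vals), function(k) {
    descriptors[as.integer(strsplit(sub("^s", "", k), ",")[[1]])]
  })
  models <- lapply(subsets, function(s) fit_ols(data, response, s))
  structure(
    list(
      ranking = tibble(
        rank = seq_along(vals),
        subset = vapply(subsets, paste, character(1), collapse = " + "),
        size = lengths(subsets),
        fitness = unname(vals)
      ),
      subsets = subsets,
      models = models,
      fitness_measure = config$fitness,
      trace = run$trace,
      converged = run$converged,
      config = config,
      seed = seed
    ),
    class = "qspr_ga"
  )
}

#' @export
print.qspr_ga <- function(x, ...) {
  cat("<qspr_ga>  ", nrow(x$trace), " generations (converged: ",
      x$converged, ")\n", sep = "")
  print(head(x$ranking, 5))
  invisible(x)
}

#' @export
tidy.qspr_ga <- function(x, ...) x$ranking

#' @export
glance.qspr_ga <- function(x, ...) {
  tibble(
    generations_run = nrow(x$trace),
    converged = x$converged,
    best_fitness = x$ranking$fitness[1],
    best_size = x$ranking$size[1],
    fitness_measure = x$fitness_measure
  )
}

#' Fitness-trace plot for a GA run
#'
#' @param object A `qspr_ga` object.
#' @param ... Unused.
#' @return A ggplot object showing best and mean fitness per generation.
#' @export
autoplot.qspr_ga <- function(object, ...) {
  d <- tidyr::pivot_longer(object$trace, c("best", "mean"),
                           names_to = "statistic", values_to = "fitness")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                  colour = .data$statistic)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = "GA fitness trace", y = object$fitness_measure)
}
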