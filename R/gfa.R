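#' Configuration for the genetic model search
#'
#' Defaults follow the canonical desk-scale GFA setup: population 100,
#' 500 generations, at most 5 basis terms per model (the published spline
#' model has 5), tournament selection of size 2, mutation probability 0.1,
#' crossover probability 0.9, Friedman smoothness `d = 1`. Spline knots are
#' drawn from the observed training values of each descriptor with the
#' minimum and maximum excluded, unless an explicit grid is supplied.
#'
#' @param population_size Individuals per generation (>= 2).
#' @param generations Number of generations.
#' @param max_terms Maximum basis terms per model.
#' @param spline_enabled Allow truncated-power spline terms?
#' @param knot_candidates Optional named list: descriptor -> numeric knot
#'   grid. `NULL` derives grids from the data.
#' @param lof_smoothness_d Friedman smoothness factor.
#' @param mutation_rate,crossover_rate GA probabilities.
#' @param tournament_size Tournament size for parent selection.
#' @param seed Integer seed; the whole search is deterministic given it.
#' @return An object of class `gfa_config`.
#' @export
gfa_config <- function(population_size = 100, generations = 500,
                       max_terms = 5, spline_enabled = TRUE,
                       knot_candidates = NULL, lof_smoothness_d = 1,
                       mutation_rate = 0.1, crossover_rate = 0.9,
                       tournament_size = 2, seed = 1) {
  stopifnot(population_size >= 2, generations >= 1, max_terms >= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1)
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 max_terms = as.integer(max_terms),
                 spline_enabled = isTRUE(spline_enabled),
                 knot_candidates = knot_candidates,
                 lof_smoothness_d = lof_smoothness_d,
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 tournament_size = as.integer(tournament_size),
                 seed = as.integer(seed)),
            class = "gfa_config")
}

term_key <- function(term) format(term)

individual_key <- function(terms) {
  paste(sort(vapply(terms, term_key, character(1))), collapse = "|")
}

default_knot_grid <- function(x) {
  v <- sort(unique(x))
  if (length(v) <= 2L) return(numeric(0))
  v[-c(1L, length(v))]
}

random_term <- function(table, config) {
  d <- sample(table$descriptor_names, 1L)
  grid <- if (!is.null(config$knot_candidates)) config$knot_candidates[[d]]
          else default_knot_grid(table$values[, d])
  use_spline <- config$spline_enabled && length(grid) > 0 &&
    stats::runif(1) < 0.5
  if (!use_spline) return(basis_term(d))
  basis_term(d, form = "spline", knot = sample(grid, 1L),
             orientation = sample(c("x_minus_knot", "knot_minus_x"), 1L))
}

dedupe_terms <- function(terms) {
  terms[!duplicated(vapply(terms, term_key, character(1)))]
}

mutate_individual <- function(terms, table, config) {
  moves <- c("add", "remove", "replace")
  has_spline <- any(vapply(terms, function(t) t$form == "spline", logical(1)))
  if (has_spline) moves <- c(moves, "knot")
  move <- sample(moves, 1L)
  if (move == "add" && length(terms) < config$max_terms) {
    terms <- c(terms, list(random_term(table, config)))
  } else if (move == "remove" && length(terms) > 1L) {
    terms <- terms[-sample.int(length(terms), 1L)]
  } else if (move == "knot") {
    idx <- which(vapply(terms, function(t) t$form == "spline", logical(1)))
    i <- if (length(idx) == 1L) idx else sample(idx, 1L)
    t <- terms[[i]]
    grid <- if (!is.null(config$knot_candidates)) config$knot_candidates[[t$descriptor]]
            else default_knot_grid(table$values[, t$descriptor])
    if (length(grid) > 1L) {
      pos <- which.min(abs(grid - t$knot))
      step <- sample(c(-1L, 1L), 1L)
      pos <- min(max(pos + step, 1L), length(grid))
      terms[[i]] <- basis_term(t$descriptor, form = "spline",
                               knot = grid[pos], orientation = t$orientation)
    }
  } else {
    i <- sample.int(length(terms), 1L)
    terms[[i]] <- random_term(table, config)
  }
  dedupe_terms(terms)
}

crossover_individuals <- function(a, b, config) {
  pool <- dedupe_terms(c(a, b))
  child <- function() {
    pick <- pool[stats::runif(length(pool)) < 0.5]
    if (!length(pick)) pick <- pool[sample.int(length(pool), 1L)]
    if (length(pick) > config$max_terms)
      pick <- pick[sample.int(length(pick), config$max_terms)]
    pick
  }
  list(child(), child())
}

rank_models <- function(models) {
  lofs <- vapply(models, `[[`, numeric(1), "lof")
  sizes <- vapply(models, function(m) length(m$terms), integer(1))
  keys <- vapply(models, function(m) individual_key(m$terms), character(1))
  models[order(lofs, sizes, keys)]
}

#' Genetic function approximation model search
#'
#' Evolves a population of basis-term subsets (linear and, optionally,
#' truncated-power spline terms with data-derived knot grids) by tournament
#' selection, subset-exchange crossover, and add/remove/replace/knot-shift
#' mutation. Individuals are scored by ordinary least squares and Friedman's
#' lack-of-fit ([lof_score()] with `c` = term count, `p = c + 1` counting the
#' intercept); rank-deficient candidates score `Inf` and die out. The best
#' individual is carried over unchanged each generation, so the best score
#' never worsens. Deterministic under `config$seed`.
#'
#' @param table A [descriptor_table()] with at least 10 compounds.
#' @param config A [gfa_config()].
#' @return Ranked list (ascending LOF, then fewer terms, then term labels) of
#'   fitted `qsar_lm` models, each carrying `lof` and `r2`; attribute
#'   `best_lof_trace` records the per-generation best score.
#' @export
gfa_search <- function(table, config = gfa_config()) {
  gx_search(table, config, fitness = "ols")
}

#' Genetic PLS model search
#'
#' Same genetic machinery as [gfa_search()] but each candidate term set is
#' fitted by NIPALS PLS ([pls_fit()], centered and unit-variance scaled for
#' descriptor blocks) at the latent-variable count that maximizes
#' leave-one-out Q^2 (up to `max_components`), and the lack-of-fit is taken
#' on the PLS residuals. With `component_selection = "max"` every candidate
#' uses `min(max_components, rank)` components, in which case full-rank PLS
#' equals OLS and the ranking reduces to [gfa_search()]'s on the same seed.
#'
#' @inheritParams gfa_search
#' @param max_components Upper bound on latent variables.
#' @param component_selection `"loo"` (Q^2-optimal) or `"max"`.
#' @return Ranked list of models; each carries `lof`, `r2`, `n_components`,
#'   and the underlying `pls` fit.
#' @export
gpls_search <- function(table, config = gfa_config(), max_components = 3,
                        component_selection = c("loo", "max")) {
  component_selection <- match.arg(component_selection)
  gx_search(table, config, fitness = "pls",
            max_components = max_components,
            component_selection = component_selection)
}

gx_search <- function(table, config, fitness = c("ols", "pls"),
                      max_components = 3,
                      component_selection = "loo") {
  fitness <- match.arg(fitness)
  stopifnot(inherits(table, "descriptor_table"), inherits(config, "gfa_config"))
  n <- nrow(table$values)
  if (n < 10L) stop("genetic search needs at least 10 training compounds")
  if (config$max_terms >= n - 1L) stop("max_terms must be below n - 1")
  if (length(table$descriptor_names) == 0L) stop("empty candidate descriptor pool")
  set.seed(config$seed)

  cache <- new.env(parent = emptyenv())
  evaluate <- function(terms) {
    key <- individual_key(terms)
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    res <- tryCatch({
      if (fitness == "ols") {
        fit <- fit_ols(table, terms)
        lof <- lof_score(fit$rss, c = length(terms), p = length(terms) + 1L,
                         m = n, d = config$lof_smoothness_d)
        list(lof = lof, model = fit)
      } else {
        X <- term_matrix(table, terms)
        rank <- qr(cbind(1, X))$rank - 1L
        if (rank < 1L) stop("degenerate term block")
        cap <- min(max_components, rank, n - 1L)
        ncomp <- if (component_selection == "max") cap else {
          q2s <- vapply(seq_len(cap), function(k)
            pls_loo_q2(X, table$activity, k, scale = TRUE)$q2, numeric(1))
          which.max(q2s)
        }
        pm <- pls_fit(X, table$activity, ncomp, scale = TRUE)
        res_fit <- table$activity - predict(pm, X)
        rss <- sum(res_fit^2)
        lof <- lof_score(rss, c = length(terms), p = length(terms) + 1L,
                         m = n, d = config$lof_smoothness_d)
        mdl <- linear_model(pm$intercept, terms, pm$coefficients,
                            fitted_on = table$compound_ids)
        mdl$fitted <- predict(pm, X)
        mdl$rss <- rss
        tss <- sum((table$activity - mean(table$activity))^2)
        mdl$r2 <- 1 - rss / tss
        mdl$n_components <- pm$n_components
        mdl$pls <- pm
        list(lof = lof, model = mdl)
      }
    }, error = function(e) list(lof = Inf, model = NULL))
    if (!is.null(res$model)) {
      res$model$lof <- res$lof
    }
    cache[[key]] <- res
    res
  }

  new_individual <- function() {
    k <- sample.int(config$max_terms, 1L)
    dedupe_terms(replicate(k, random_term(table, config), simplify = FALSE))
  }
  pop <- replicate(config$population_size, new_individual(), simplify = FALSE)
  fits <- vapply(pop, function(ind) evaluate(ind)$lof, numeric(1))
  if (all(!is.finite(fits))) stop("no feasible model in the initial population")

  tournament <- function() {
    idx <- sample.int(length(pop), config$tournament_size, replace = TRUE)
    pop[[idx[which.min(fits[idx])]]]
  }

  best_trace <- numeric(config$generations)
  for (g in seq_len(config$generations)) {
    newpop <- list(pop[[which.min(fits)]])   # elitism
    while (length(newpop) < config$population_size) {
      p1 <- tournament(); p2 <- tournament()
      kids <- if (stats::runif(1) < config$crossover_rate)
        crossover_individuals(p1, p2, config) else list(p1, p2)
      kids <- lapply(kids, function(k) {
        if (stats::runif(1) < config$mutation_rate)
          mutate_individual(k, table, config) else k
      })
      newpop <- c(newpop, kids)
    }
    pop <- newpop[seq_len(config$population_size)]
    fits <- vapply(pop, function(ind) evaluate(ind)$lof, numeric(1))
    best_trace[g] <- min(fits)
  }

  evaluated <- as.list(cache)
  models <- Filter(Negate(is.null), lapply(evaluated, `[[`, "model"))
  models <- models[vapply(models, function(m) is.finite(m$lof), logical(1))]
  if (!length(models)) stop("no feasible model found")
  out <- rank_models(models)
  attr(out, "best_lof_trace") <- best_trace
  out
}
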