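#' Genetic-algorithm configuration
#'
#' Hyperparameters of the real-coded accelerating genetic algorithm (RAGA):
#' a GA on \[0, 1\]-coded genes with rank-based geometric fitness, roulette
#' selection, arithmetic crossover, directional mutation, and a periodic
#' "acceleration" that shrinks the search box around the current elites.
#'
#' @param population_size number of individuals N.
#' @param crossover_prob probability Pc that an individual joins the
#'   crossover parent pool.
#' @param mutation_prob probability Pm that an individual spawns a mutant.
#' @param selection_pressure rank-fitness parameter alpha in (0, 1); the
#'   rank-i individual gets fitness `alpha * (1 - alpha)^(i - 1)`.
#' @param max_iterations generation cap.
#' @param acceleration_period generations between bound-shrinking steps.
#' @param elite_fraction fraction of the population whose decoded values
#'   define the shrunken bounds.
#' @param bounds optional `n x 2` matrix of per-variable lower/upper bounds;
#'   default \[0, 1\] for every variable.
#' @param stagnation_tol,stagnation_window stop early when the best objective
#'   improves by less than `stagnation_tol` over `stagnation_window`
#'   generations.
#' @param seed integer RNG seed; identical seeds give identical results.
#' @return A list of class `"ga_config"`.
#' @export
ga_config <- function(population_size = 40L,
                      crossover_prob = 0.8,
                      mutation_prob = 0.2,
                      selection_pressure = 0.05,
                      max_iterations = 100L,
                      acceleration_period = 20L,
                      elite_fraction = 0.2,
                      bounds = NULL,
                      stagnation_tol = 1e-10,
                      stagnation_window = 20L,
                      seed = 1L) {
  stopifnot(population_size >= 2L,
            crossover_prob >= 0, crossover_prob <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            selection_pressure > 0, selection_pressure < 1,
            max_iterations >= 1L, acceleration_period >= 1L,
            elite_fraction > 0, elite_fraction <= 1)
  if (!is.null(bounds)) {
    bounds <- as.matrix(bounds)
    stopifnot(ncol(bounds) == 2L, all(bounds[, 1L] < bounds[, 2L]))
  }
  structure(list(population_size = as.integer(population_size),
                 crossover_prob = crossover_prob,
                 mutation_prob = mutation_prob,
                 selection_pressure = selection_pressure,
                 max_iterations = as.integer(max_iterations),
                 acceleration_period = as.integer(acceleration_period),
                 elite_fraction = elite_fraction,
                 bounds = bounds,
                 stagnation_tol = stagnation_tol,
                 stagnation_window = as.integer(stagnation_window),
                 seed = as.integer(seed)),
            class = "ga_config")
}

#' Decode unit-interval genes to bounded variables
#'
#' Linear map `x(j) = a(j) + z(j) (b(j) - a(j))` from the \[0, 1\] gene scale
#' to per-variable bounds.
#'
#' @param z numeric vector or matrix of genes in \[0, 1\] (individuals in
#'   rows when a matrix).
#' @param bounds `n x 2` matrix of lower/upper bounds.
#' @return Decoded values, same shape as `z`.
#' @export
raga_decode <- function(z, bounds) {
  if (any(z < 0 | z > 1)) {
    stop_resilpp("genes outside [0, 1]", class = "resilpp_ga_error")
  }
  lo <- bounds[, 1L]; span <- bounds[, 2L] - bounds[, 1L]
  if (is.matrix(z)) {
    sweep(sweep(z, 2L, span, "*"), 2L, lo, "+")
  } else {
    lo + z * span
  }
}

#' Rank-based geometric fitness
#'
#' Individuals are ranked best-first by objective (ties broken by stable
#' input order) and the rank-i individual receives fitness
#' `alpha * (1 - alpha)^(i - 1)`, a strictly decreasing geometric series.
#'
#' @param objectives numeric vector of objective values (larger is better).
#' @param alpha selection pressure in (0, 1).
#' @return Positive fitness values aligned with the input order.
#' @export
rank_fitness <- function(objectives, alpha) {
  stopifnot(alpha > 0, alpha < 1)
  ord <- order(objectives, decreasing = TRUE)  # stable for ties
  fit <- numeric(length(objectives))
  fit[ord] <- alpha * (1 - alpha)^(seq_along(objectives) - 1L)
  fit
}

#' Roulette-wheel selection
#'
#' Builds the cumulative fitness sums `q_i` and, for each draw, takes a
#' uniform `r` on `(0, q_N]` and selects the individual `i` with
#' `q_(i-1) < r <= q_i`, so selection probability is proportional to fitness.
#'
#' @param fitness positive fitness values.
#' @param count number of selections.
#' @param seed optional seed; when `NULL` the current RNG stream is used.
#' @return Integer vector of selected indices.
#' @export
roulette_select <- function(fitness, count, seed = NULL) {
  if (any(fitness < 0) || all(fitness == 0)) {
    stop_resilpp("fitness must be nonnegative with positive total",
                 class = "resilpp_ga_error")
  }
  with_seed(seed, {
    q <- cumsum(fitness)
    r <- stats::runif(count) * q[length(q)]
    findInterval(r, q, left.open = TRUE) + 1L
  })
}

# Internal: arithmetic-blend crossover over a parent pool.
# Each individual enters the pool with probability Pc; pooled parents are
# shuffled and paired; each pair yields two complementary per-gene blends.
raga_crossover <- function(genes, pc) {
  pool <- which(stats::runif(nrow(genes)) < pc)
  if (length(pool) < 2L) return(genes[0, , drop = FALSE])
  pool <- sample(pool)
  if (length(pool) %% 2L == 1L) pool <- pool[-length(pool)]
  n <- ncol(genes)
  kids <- matrix(NA_real_, length(pool), n)
  for (k in seq(1L, length(pool), by = 2L)) {
    p1 <- genes[pool[k], ]; p2 <- genes[pool[k + 1L], ]
    u <- stats::runif(n)
    kids[k, ] <- u * p1 + (1 - u) * p2
    kids[k + 1L, ] <- (1 - u) * p1 + u * p2
  }
  pmin(pmax(kids, 0), 1)
}

# Internal: directional mutation.  Each selected parent moves a uniform step
# M in (0,1) along a uniformly random unit direction in n-space; coordinates
# are clamped back into the unit box.
raga_mutate <- function(genes, pm) {
  sel <- which(stats::runif(nrow(genes)) < pm)
  if (!length(sel)) return(genes[0, , drop = FALSE])
  n <- ncol(genes)
  mut <- genes[sel, , drop = FALSE]
  for (k in seq_along(sel)) {
    d <- stats::rnorm(n)
    d <- d / sqrt(sum(d^2))
    mut[k, ] <- mut[k, ] + stats::runif(1L) * d
  }
  pmin(pmax(mut, 0), 1)
}

#' Shrink variable bounds around elite solutions
#'
#' The "acceleration" step: per variable the new interval is the envelope
#' (min, max) of the elite decoded values, intersected with the current
#' bounds.  A collapsed interval is widened symmetrically by `1e-6` of the
#' original span so the variable stays searchable.
#'
#' @param elite_decoded matrix of elite decoded values (individuals in rows).
#' @param bounds current `n x 2` bounds.
#' @param original_span per-variable span of the initial bounds (used by the
#'   collapse rule); defaults to the current span.
#' @return New `n x 2` bounds matrix.
#' @export
raga_accelerate <- function(elite_decoded, bounds,
                            original_span = bounds[, 2L] - bounds[, 1L]) {
  stopifnot(nrow(elite_decoded) >= 1L)
  lo <- pmax(bounds[, 1L], apply(elite_decoded, 2L, min))
  hi <- pmin(bounds[, 2L], apply(elite_decoded, 2L, max))
  collapsed <- hi - lo <= 0
  if (any(collapsed)) {
    centre <- (lo + hi) / 2
    w <- 1e-6 * original_span
    lo[collapsed] <- centre[collapsed] - w[collapsed]
    hi[collapsed] <- centre[collapsed] + w[collapsed]
  }
  cbind(lo, hi, deparse.level = 0)
}

#' Maximize a black-box objective with the accelerating genetic algorithm
#'
#' Each generation the current population is ranked, roulette-selected,
#' crossed and mutated; parents, offspring and mutants are pooled together
#' with the best solution found so far and the best `N` survive (elitist
#' truncation), so the best objective never decreases.  Every
#' `acceleration_period` generations the variable bounds contract to the
#' envelope of the elite decoded values and the cycle restarts with a fresh
#' uniform population inside the shrunken box (the best-so-far point kept),
#' which preserves diversity while the box shrinks geometrically.  The run
#' stops at `max_iterations` or when the best objective stagnates.
#'
#' @param objective_fn function taking a decoded n-vector, returning a
#'   scalar to maximize; must be finite-or-`-Inf` on the box.
#' @param n_vars number of variables.
#' @param config a [ga_config()].
#' @return A list of class `"raga_result"`: `best_x`, `best_objective`,
#'   `trace` (best objective per generation, non-decreasing),
#'   `n_accelerations`, `final_bounds`, `generations`, `converged`.
#' @examples
#' res <- raga_optimize(function(x) -(x - 0.3)^2, 1, ga_config(seed = 7))
#' res$best_x
#' @export
raga_optimize <- function(objective_fn, n_vars, config = ga_config()) {
  n_vars <- as.integer(n_vars)
  stopifnot(n_vars >= 1L)
  bounds <- config$bounds %||% cbind(rep(0, n_vars), rep(1, n_vars))
  if (nrow(bounds) != n_vars) {
    stop_resilpp("bounds have %d rows but n_vars is %d", nrow(bounds), n_vars,
                 class = "resilpp_ga_error")
  }
  original_span <- bounds[, 2L] - bounds[, 1L]
  N <- config$population_size
  eval_pop <- function(genes, bounds) {
    dec <- raga_decode(genes, bounds)
    apply(dec, 1L, objective_fn)
  }
  with_seed(config$seed, {
    genes <- matrix(stats::runif(N * n_vars), N, n_vars)
    obj <- eval_pop(genes, bounds)
    best_i <- which.max(obj)
    best_obj <- obj[best_i]
    best_x <- raga_decode(genes[best_i, ], bounds)
    trace <- numeric(0)
    n_acc <- 0L
    converged <- FALSE
    gen <- 0L
    n_elite <- max(2L, ceiling(config$elite_fraction * N))
    elite_archive <- raga_decode(genes[order(obj, decreasing = TRUE)[seq_len(n_elite)], ,
                                       drop = FALSE], bounds)
    while (gen < config$max_iterations) {
      gen <- gen + 1L
      fit <- rank_fitness(obj, config$selection_pressure)
      sel <- roulette_select(fit, N)
      parents <- genes[sel, , drop = FALSE]
      parent_obj <- obj[sel]
      kids <- raga_crossover(parents, config$crossover_prob)
      muts <- raga_mutate(parents, config$mutation_prob)
      # elitist pool: parents + offspring + mutants + best-so-far
      best_gene <- pmin(pmax((best_x - bounds[, 1L]) / (bounds[, 2L] - bounds[, 1L]), 0), 1)
      pool <- rbind(parents, kids, muts, matrix(best_gene, 1L))
      pool_obj <- c(parent_obj,
                    if (nrow(kids)) eval_pop(kids, bounds) else numeric(0),
                    if (nrow(muts)) eval_pop(muts, bounds) else numeric(0),
                    best_obj)
      # survivor truncation, distinct genes first so the population (and the
      # elite envelope used by acceleration) never degenerates to one point
      ord <- order(pool_obj, decreasing = TRUE)
      uniq <- ord[!duplicated(pool[ord, , drop = FALSE])]
      keep <- c(uniq, setdiff(ord, uniq))[seq_len(N)]
      genes <- pool[keep, , drop = FALSE]
      obj <- pool_obj[keep]
      if (obj[1L] > best_obj) {
        best_obj <- obj[1L]
        best_x <- raga_decode(genes[1L, ], bounds)
      }
      trace <- c(trace, best_obj)
      # archive this generation's elites; the acceleration envelope spans the
      # whole period, not just the final (already clustered) generation
      elite_archive <- rbind(elite_archive,
                             raga_decode(genes[order(obj, decreasing = TRUE)[seq_len(n_elite)], ,
                                               drop = FALSE], bounds))
      if (gen %% config$acceleration_period == 0L) {
        new_bounds <- raga_accelerate(elite_archive, bounds, original_span)
        # keep the best-so-far point representable in the new box
        new_bounds[, 1L] <- pmin(new_bounds[, 1L], best_x)
        new_bounds[, 2L] <- pmax(new_bounds[, 2L], best_x)
        bounds <- new_bounds
        # restart the cycle: fresh random population inside the shrunken box
        genes <- matrix(stats::runif(N * n_vars), N, n_vars)
        genes[1L, ] <- (best_x - bounds[, 1L]) / (bounds[, 2L] - bounds[, 1L])
        obj <- eval_pop(genes, bounds)
        n_acc <- n_acc + 1L
        elite_archive <- raga_decode(genes[order(obj, decreasing = TRUE)[seq_len(n_elite)], ,
                                           drop = FALSE], bounds)
      }
      if (gen >= config$stagnation_window &&
          trace[gen] - trace[gen - config$stagnation_window + 1L] < config$stagnation_tol) {
        converged <- TRUE
        break
      }
    }
    structure(list(best_x = best_x, best_objective = best_obj, trace = trace,
                   n_accelerations = n_acc, final_bounds = bounds,
                   generations = gen, converged = converged),
              class = "raga_result")
  })
}

#' @export
print.raga_result <- function(x, ...) {
  cat(sprintf("raga_result: best objective %.6g after %d generation(s), %d acceleration(s)%s\n",
              x$best_objective, x$generations, x$n_accelerations,
              if (x$converged) " (converged)" else ""))
  invisible(x)
}
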