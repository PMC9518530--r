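#' Projection-pursuit indicator weights
#'
#' Runs the projection-pursuit optimization in the indicator orientation:
#' the transposed standardized matrix is the observation set (indicators as
#' observations, regions as variables), so the optimal projection value of
#' each indicator measures how much discriminating structure it carries.
#' The raw projection values are the indicator weights in this framework;
#' they are additionally normalized to sum to one for interpretability.
#'
#' @param std a [standardize()]d panel.
#' @param config a [ga_config()]; the number of GA variables equals the
#'   number of regions.
#' @param radius_rule,radius_value,include_self projection-index settings,
#'   see [projection_objective()].
#' @return A list of class `"weight_result"`: `projection_values` (raw, one
#'   per indicator), `weights` (normalized to sum 1), `direction` (optimal
#'   unit direction over regions), `objective`, `optimizer` (the full
#'   [raga_optimize()] result).
#' @export
index_weights <- function(std, config = ga_config(max_iterations = 250L),
                          radius_rule = "fraction_of_spread",
                          radius_value = 0.1, include_self = FALSE) {
  assert_complete(std, "index_weights")
  Xt <- t(std$values)  # indicators as observations, regions as variables
  run <- run_ppm(Xt, config, radius_rule, radius_value, include_self)
  pv <- run$projections
  names(pv) <- std$scheme$code
  total <- sum(pv)
  if (total <= 0) {
    stop_resilpp("projection values sum to %g; cannot normalize weights", total,
                 class = "resilpp_measure_error")
  }
  structure(list(projection_values = pv, weights = pv / total,
                 direction = run$direction, objective = run$objective,
                 optimizer = run$optimizer),
            class = "weight_result")
}

#' Projection-pursuit region resilience scores
#'
#' Runs the optimization in the region orientation: regions are the
#' observations, indicators the variables, and the optimal projection value
#' of each region is its composite resilience score.
#'
#' @inheritParams index_weights
#' @return A list of class `"score_result"`: `scores` (one per region),
#'   `direction` (optimal unit direction over indicators), `objective`,
#'   `optimizer`.
#' @export
resilience_scores <- function(std, config = ga_config(),
                              radius_rule = "fraction_of_spread",
                              radius_value = 0.1, include_self = FALSE) {
  assert_complete(std, "resilience_scores")
  run <- run_ppm(std$values, config, radius_rule, radius_value, include_self)
  sc <- run$projections
  names(sc) <- std$region_labels
  structure(list(scores = sc, direction = run$direction,
                 objective = run$objective, optimizer = run$optimizer),
            class = "score_result")
}

# Internal: optimize the projection index over unit directions for an
# observation matrix; GA genes live in [0,1]^n (nonnegative direction
# components, renormalized to the unit sphere inside the objective).
run_ppm <- function(X, config, radius_rule, radius_value, include_self) {
  n_vars <- ncol(X)
  fn <- function(a) {
    if (sqrt(sum(a^2)) < 1e-12) return(-Inf)
    projection_objective(X, a, radius_rule, radius_value, include_self)$objective
  }
  opt <- raga_optimize(fn, n_vars, config)
  po <- projection_objective(X, opt$best_x, radius_rule, radius_value, include_self)
  list(projections = po$projections, direction = po$direction,
       objective = po$objective, optimizer = opt)
}

#' Per-dimension resilience scores
#'
#' [resilience_scores()] restricted to one dimension's indicator columns.
#' Per-dimension generation caps default to the heavier schedules the full
#' measurement uses for the restore and adaptability blocks.
#'
#' @param std a [standardize()]d panel.
#' @param dimension one of [resilience_dimensions()].
#' @param config a [ga_config()]; its `max_iterations` is replaced by the
#'   dimension's entry in `iterations` unless `iterations` is `NULL`.
#' @param iterations named per-dimension generation caps.
#' @param ... passed to [resilience_scores()].
#' @return A `"score_result"` for the dimension's indicator subset.
#' @export
dimension_scores <- function(std, dimension, config = ga_config(),
                             iterations = c(resistance = 15L, restore = 200L,
                                            adaptability = 400L,
                                            collaborative = 150L),
                             ...) {
  dimension <- match.arg(dimension, resilience_dimensions())
  keep <- std$scheme$dimension == dimension
  if (sum(keep) < 2L) {
    stop_resilpp("dimension '%s' has %d indicator(s); need at least 2",
                 dimension, sum(keep), class = "resilpp_measure_error")
  }
  sub <- std
  sub$values <- std$values[, keep, drop = FALSE]
  sub$scheme <- std$scheme[keep, , drop = FALSE]
  sub$missing_mask <- std$missing_mask[, keep, drop = FALSE]
  if (!is.null(iterations)) {
    config$max_iterations <- as.integer(iterations[[dimension]])
  }
  resilience_scores(sub, config, ...)
}

#' Entropy-weight TOPSIS comparator
#'
#' The conventional objective-weighting comparator: entropy
#' `e_j = -(1/ln m) sum_i p_ij ln p_ij` over column shares `p_ij` (zero
#' shares contribute zero), weights `w_j = (1 - e_j) / sum_k (1 - e_k)`, and
#' TOPSIS closeness `d- / (d+ + d-)` to the weighted ideal and anti-ideal
#' points.  Columns are already oriented by standardization, so the ideal is
#' the per-column maximum.
#'
#' @param std a [standardize()]d panel with non-degenerate columns.
#' @return A list of class `"entropy_topsis_result"`: `entropy`, `weights`
#'   (per indicator), `closeness` (per region).
#' @export
entropy_topsis <- function(std) {
  assert_complete(std, "entropy_topsis")
  v <- std$values
  m <- nrow(v)
  colsum <- colSums(v)
  if (any(colsum <= 0)) {
    stop_resilpp("degenerate column(s): %s",
                 paste(std$scheme$code[colsum <= 0], collapse = ", "),
                 class = "resilpp_degenerate_error")
  }
  p <- sweep(v, 2L, colsum, "/")
  plogp <- ifelse(p > 0, p * log(p), 0)
  e <- -colSums(plogp) / log(m)
  w <- (1 - e) / sum(1 - e)
  vw <- sweep(v, 2L, w, "*")
  ideal <- apply(vw, 2L, max)
  anti <- apply(vw, 2L, min)
  dpos <- sqrt(rowSums(sweep(vw, 2L, ideal, "-")^2))
  dneg <- sqrt(rowSums(sweep(vw, 2L, anti, "-")^2))
  closeness <- dneg / (dpos + dneg)
  names(closeness) <- std$region_labels
  names(w) <- names(e) <- std$scheme$code
  structure(list(entropy = e, weights = w, closeness = closeness),
            class = "entropy_topsis_result")
}

#' Full resilience measurement report
#'
#' Orchestrates the two projection-pursuit orientations, the per-dimension
#' runs, the five-level Jenks classification, and the entropy-TOPSIS
#' comparator into one report.  The weighted mean of the dimension scores is
#' reported next to the all-indicator score so their difference — composite
#' resilience is not the additive sum of its dimensions — is visible.
#'
#' @param std a [standardize()]d panel.
#' @param config a [ga_config()] template; each stage derives its own seed
#'   from `config$seed` so stages are independently reproducible.
#' @param weight_iterations generation cap for the indicator-orientation run.
#' @param score_iterations generation cap for the region-orientation run.
#' @param dimension_iterations named per-dimension generation caps (see
#'   [dimension_scores()]).
#' @param k number of Jenks classes.
#' @param comparator include the entropy-TOPSIS comparator.
#' @param ... projection-index settings passed through.
#' @return A list of class `"measure_report"` with elements `weights`
#'   (a `weight_result`), `scores` (a `score_result`), `dimension_scores`
#'   (m x 4 matrix), `dimension_weighted_mean`, `nonadditivity_gap`,
#'   `classification` (a `jenks_result`), `comparator`, `config`.
#' @export
measure_resilience <- function(std, config = ga_config(),
                               weight_iterations = 250L,
                               score_iterations = 100L,
                               dimension_iterations = c(resistance = 15L,
                                                        restore = 200L,
                                                        adaptability = 400L,
                                                        collaborative = 150L),
                               k = 5L, comparator = TRUE, ...) {
  assert_complete(std, "measure_resilience")
  cfg_w <- config; cfg_w$max_iterations <- as.integer(weight_iterations)
  cfg_w$seed <- derive_seed(config$seed, "weights")
  cfg_s <- config; cfg_s$max_iterations <- as.integer(score_iterations)
  cfg_s$seed <- derive_seed(config$seed, "scores")
  w <- index_weights(std, cfg_w, ...)
  s <- resilience_scores(std, cfg_s, ...)

  dims <- intersect(resilience_dimensions(), unique(std$scheme$dimension))
  dim_runs <- lapply(dims, function(d) {
    cfg_d <- config
    cfg_d$seed <- derive_seed(config$seed, paste0("dim_", d))
    dimension_scores(std, d, cfg_d, iterations = dimension_iterations, ...)
  })
  names(dim_runs) <- dims
  dmat <- do.call(cbind, lapply(dim_runs, `[[`, "scores"))

  # weight each dimension by the summed normalized indicator weights it owns
  dim_w <- vapply(dims, function(d) sum(w$weights[std$scheme$dimension == d]), 0)
  dim_w <- dim_w / sum(dim_w)
  wmean <- drop(dmat %*% dim_w)
  gap <- s$scores - wmean

  cls <- if (length(s$scores) >= k && length(unique(s$scores)) >= k) {
    jenks_breaks(s$scores, k)
  } else NULL
  cmp <- if (comparator) entropy_topsis(std) else NULL
  structure(list(weights = w, scores = s, dimension_scores = dmat,
                 dimension_weights = dim_w, dimension_weighted_mean = wmean,
                 nonadditivity_gap = gap, classification = cls,
                 comparator = cmp, config = config),
            class = "measure_report")
}

#' @export
print.measure_report <- function(x, ...) {
  cat(sprintf("measure_report: %d regions, %d indicators\n",
              length(x$scores$scores), length(x$weights$weights)))
  cat(sprintf("objective (region orientation): %.6g\n", x$scores$objective))
  if (!is.null(x$classification)) {
    cat(sprintf("Jenks %d-level breaks: %s (gvf %.3f)\n", x$classification$k,
                paste(signif(x$classification$breaks, 4), collapse = ", "),
                x$classification$gvf))
  }
  cat(sprintf("mean |score - dimension weighted mean| = %.4g\n",
              mean(abs(x$nonadditivity_gap))))
  invisible(x)
}
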