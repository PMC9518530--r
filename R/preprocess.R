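#' Min-max standardization with indicator orientation
#'
#' Rescales every indicator column to \[0, 1\] while orienting it so that
#' larger always means better: positive indicators are mapped
#' `(x - min) / (max - min)`, negative indicators `(max - x) / (max - min)`.
#' Each non-degenerate column therefore attains both 0 and 1.
#'
#' @param panel a complete [indicator_panel()] (no missing cells).
#' @param on_degenerate what to do with a constant column (zero range):
#'   `"error"` (default) or `"drop"` with a warning.
#' @return An object of class `"standardized_panel"`: like the input panel
#'   but with `values` in \[0, 1\] and a `provenance` data frame recording the
#'   per-column min and max used.
#' @examples
#' sch <- indicator_scheme(c("P1", "N1"), "resistance", c("positive", "negative"))
#' p <- indicator_panel(cbind(c(0, 5, 10), c(0, 5, 10)), c("a", "b", "c"), sch)
#' standardize(p)$values
#' @export
standardize <- function(panel, on_degenerate = c("error", "drop")) {
  on_degenerate <- match.arg(on_degenerate)
  assert_complete(panel, "standardize")
  v <- panel$values
  mins <- apply(v, 2L, min)
  maxs <- apply(v, 2L, max)
  degenerate <- (maxs - mins) == 0
  if (any(degenerate)) {
    codes <- panel$scheme$code[degenerate]
    if (on_degenerate == "error") {
      stop_resilpp("degenerate (constant) column(s): %s",
                   paste(codes, collapse = ", "),
                   class = "resilpp_degenerate_error")
    }
    warning(sprintf("dropping degenerate column(s): %s",
                    paste(codes, collapse = ", ")))
    keep <- !degenerate
    v <- v[, keep, drop = FALSE]
    panel$scheme <- panel$scheme[keep, , drop = FALSE]
    mins <- mins[keep]; maxs <- maxs[keep]
  }
  rng <- maxs - mins
  std <- sweep(sweep(v, 2L, mins, "-"), 2L, rng, "/")
  neg <- panel$scheme$attribute == "negative"
  std[, neg] <- 1 - std[, neg, drop = FALSE]
  dimnames(std) <- list(panel$region_labels, panel$scheme$code)
  structure(list(values = std,
                 region_labels = panel$region_labels,
                 scheme = panel$scheme,
                 missing_mask = matrix(FALSE, nrow(std), ncol(std)),
                 provenance = data.frame(code = panel$scheme$code,
                                         min = unname(mins), max = unname(maxs))),
            class = c("standardized_panel", "indicator_panel"))
}

#' Imputation configuration
#'
#' @param n_candidates number of noisy candidate draws per missing cell.
#' @param noise_scale Gaussian noise scale as a multiple of the regression
#'   residual standard deviation.
#' @param selection_rule `"closest_to_mean"` keeps the candidate nearest the
#'   candidate mean; `"pooled_mean"` keeps the mean of all candidates.
#' @param seed integer RNG seed; fixed seed gives identical imputations.
#' @return A list of class `"imputation_config"`.
#' @export
imputation_config <- function(n_candidates = 5L, noise_scale = 1,
                              selection_rule = c("closest_to_mean", "pooled_mean"),
                              seed = 1L) {
  selection_rule <- match.arg(selection_rule)
  stopifnot(n_candidates >= 1L, noise_scale >= 0)
  structure(list(n_candidates = as.integer(n_candidates),
                 noise_scale = noise_scale,
                 selection_rule = selection_rule,
                 seed = as.integer(seed)),
            class = "imputation_config")
}

#' Regression-based multiple imputation with noise draws
#'
#' Fills each missing cell with a predictive value: the cell's column is
#' regressed (ordinary least squares) on the fully observed columns, the
#' fitted value at the missing row is perturbed with Gaussian noise scaled to
#' the residual standard deviation, several candidate draws are formed, and
#' one value is kept per the configured selection rule.  Observed cells are
#' never modified, and the result is deterministic under a fixed seed.
#'
#' When no column is fully observed, the intercept-only model (column mean of
#' the observed cells) is used as the predictor.
#'
#' @param panel an [indicator_panel()]; columns with missing cells must have
#'   at least 3 observed values and no row may be entirely missing.
#' @param config an [imputation_config()].
#' @return A complete `indicator_panel` with all missing cells filled.
#' @export
impute <- function(panel, config = imputation_config()) {
  mask <- panel$missing_mask
  if (!any(mask)) return(panel)
  v <- panel$values
  m <- nrow(v); n <- ncol(v)
  obs_per_col <- colSums(!mask)
  short <- which(mask & matrix(obs_per_col < 3L, m, n, byrow = TRUE), arr.ind = TRUE)
  if (nrow(short)) {
    stop_resilpp("column(s) with missing cells but fewer than 3 observed values: %s",
                 paste(unique(panel$scheme$code[short[, 2L]]), collapse = ", "),
                 class = "resilpp_insufficient_data_error")
  }
  if (any(rowSums(!mask) == 0L)) {
    stop_resilpp("fully missing row(s) present",
                 class = "resilpp_insufficient_data_error")
  }
  complete_cols <- which(colSums(mask) == 0L)
  filled <- v
  with_seed(config$seed, {
    for (j in which(colSums(mask) > 0L)) {
      obs <- !mask[, j]
      y <- v[obs, j]
      if (length(complete_cols)) {
        X <- cbind(1, v[, complete_cols, drop = FALSE])
        fit <- stats::lm.fit(X[obs, , drop = FALSE], y)
        coef <- fit$coefficients
        coef[is.na(coef)] <- 0
        pred_all <- drop(X %*% coef)
        resid_sd <- if (fit$df.residual > 0) {
          sqrt(sum(fit$residuals^2) / fit$df.residual)
        } else 0
      } else {
        pred_all <- rep(mean(y), m)
        resid_sd <- stats::sd(y)
      }
      for (i in which(mask[, j])) {
        cand <- pred_all[i] +
          stats::rnorm(config$n_candidates, 0, config$noise_scale * resid_sd)
        filled[i, j] <- switch(config$selection_rule,
          closest_to_mean = cand[which.min(abs(cand - mean(cand)))],
          pooled_mean = mean(cand))
      }
    }
  })
  indicator_panel(filled, panel$region_labels, panel$scheme)
}
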