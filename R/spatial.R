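#' Build a spatial weights matrix from point coordinates
#'
#' Pairwise weights from Euclidean distances between region points.
#' `inverse_distance` gives `w_ij = 1 / d_ij^power` for `d_ij` within the
#' cutoff; the default cutoff is the smallest distance guaranteeing every
#' region at least one neighbor (the max over regions of the nearest-neighbor
#' distance).  `distance_band` gives binary weights within the cutoff; `knn`
#' links each region to its `k` nearest neighbors (asymmetric).
#'
#' @param coords two-column matrix or data frame of point coordinates, with
#'   region labels as row names or in a `label` column.
#' @param method `"inverse_distance"` (default), `"distance_band"`, `"knn"`.
#' @param power exponent for inverse-distance weights.
#' @param cutoff distance cutoff; `NULL` means the minimum-coverage default
#'   (ignored by `knn`). `Inf` keeps all pairs.
#' @param k neighbor count for `knn`.
#' @param row_standardize divide each row by its sum.
#' @return A list of class `"spatial_weights"`: `labels`, `matrix` (zero
#'   diagonal), `standardized`, `s0` (sum of all weights).
#' @export
spatial_weights <- function(coords,
                            method = c("inverse_distance", "distance_band", "knn"),
                            power = 1, cutoff = NULL, k = 4L,
                            row_standardize = FALSE) {
  method <- match.arg(method)
  labels <- NULL
  if (is.data.frame(coords) && "label" %in% names(coords)) {
    labels <- as.character(coords$label)
    coords <- as.matrix(coords[, setdiff(names(coords), "label")[1:2]])
  } else {
    coords <- as.matrix(coords)
    labels <- rownames(coords) %||% as.character(seq_len(nrow(coords)))
  }
  n <- nrow(coords)
  if (n < 2L) stop_resilpp("need at least 2 points", class = "resilpp_spatial_error")
  d <- as.matrix(stats::dist(coords))
  off <- d[upper.tri(d) | lower.tri(d)]
  if (method %in% c("inverse_distance", "distance_band")) {
    if (any(off == 0)) {
      pair <- which(d == 0 & row(d) != col(d), arr.ind = TRUE)[1L, ]
      stop_resilpp("coincident points: '%s' and '%s'",
                   labels[pair[1L]], labels[pair[2L]],
                   class = "resilpp_spatial_error")
    }
    if (is.null(cutoff)) {
      nn <- apply(d + diag(Inf, n), 1L, min)
      cutoff <- max(nn)
    }
    W <- matrix(0, n, n)
    within <- d <= cutoff & row(d) != col(d)
    W[within] <- if (method == "inverse_distance") 1 / d[within]^power else 1
  } else {
    k <- min(as.integer(k), n - 1L)
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      nb <- order(d[i, ])[2:(k + 1L)]
      W[i, nb] <- 1
    }
  }
  if (all(W == 0)) stop_resilpp("empty weight matrix", class = "resilpp_spatial_error")
  if (row_standardize) {
    rs <- rowSums(W)
    W[rs > 0, ] <- W[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  structure(list(labels = labels, matrix = W,
                 standardized = isTRUE(row_standardize), s0 = sum(W)),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  cat(sprintf("spatial_weights: %d regions, s0 = %.4g%s\n",
              length(x$labels), x$s0,
              if (x$standardized) ", row-standardized" else ""))
  invisible(x)
}

#' Global Moran's I with inference
#'
#' The global spatial autocorrelation statistic
#' `I = n / s0 * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i - xbar)^2`.
#' Its expectation under the null is `-1/(n - 1)`; the variance is computed
#' under either the normality or the randomization null via the standard
#' S0/S1/S2 moment formulas, giving a z-score and a two-sided normal p-value.
#'
#' @param x numeric vector of region values (not constant).
#' @param W a [spatial_weights()] object (or bare matrix).
#' @param variance_method `"randomization"` (default) or `"normality"`.
#' @return A list of class `"global_moran"`: `I`, `expected`, `variance`,
#'   `variance_method`, `z`, `p_two_sided`, `n`.
#' @export
global_moran <- function(x, W, variance_method = c("randomization", "normality")) {
  variance_method <- match.arg(variance_method)
  w <- weights_matrix(W)
  n <- length(x)
  stopifnot(nrow(w) == n)
  z <- x - mean(x)
  ss <- sum(z^2)
  if (ss == 0) stop_resilpp("constant x has no spatial structure",
                            class = "resilpp_spatial_error")
  s0 <- sum(w)
  I <- (n / s0) * drop(crossprod(z, w %*% z)) / ss
  expected <- -1 / (n - 1)
  variance <- moran_variance(x, w, variance_method)
  zscore <- (I - expected) / sqrt(variance)
  p <- 2 * stats::pnorm(-abs(zscore))
  structure(list(I = I, expected = expected, variance = variance,
                 variance_method = variance_method, z = zscore,
                 p_two_sided = p, n = n),
            class = "global_moran")
}

#' Null variance of global Moran's I
#'
#' Standard moment formulas using `S0 = sum w`, `S1 = (1/2) sum (w_ij +
#' w_ji)^2`, `S2 = sum_i (row_i + col_i)^2`.  The randomization variance
#' additionally involves the sample kurtosis `b2`; it equals the normality
#' variance exactly when `b2 = 3`.
#'
#' @param x region values (needed only under randomization, for `b2`).
#' @param W spatial weights.
#' @param method `"normality"` or `"randomization"`.
#' @return Positive scalar variance.
#' @export
moran_variance <- function(x, W, method = c("randomization", "normality")) {
  method <- match.arg(method)
  w <- weights_matrix(W)
  n <- nrow(w)
  if (n < 3L) stop_resilpp("need at least 3 regions for the variance",
                           class = "resilpp_spatial_error")
  s0 <- sum(w)
  s1 <- 0.5 * sum((w + t(w))^2)
  s2 <- sum((rowSums(w) + colSums(w))^2)
  E <- -1 / (n - 1)
  if (method == "normality") {
    (n^2 * s1 - n * s2 + 3 * s0^2) / (s0^2 * (n^2 - 1)) - E^2
  } else {
    z <- x - mean(x)
    b2 <- n * sum(z^4) / sum(z^2)^2
    num <- n * ((n^2 - 3 * n + 3) * s1 - n * s2 + 3 * s0^2) -
      b2 * ((n^2 - n) * s1 - 2 * n * s2 + 6 * s0^2)
    num / ((n - 1) * (n - 2) * (n - 3) * s0^2) - E^2
  }
}

#' Moran z-score from report fields
#'
#' Recomputes the standard score `z = (I - E) / sqrt(Var)` from the three
#' report fields, as printed in GIS-style global autocorrelation reports.
#'
#' @param I observed Moran's I.
#' @param expected null expectation (`-1/(n-1)`).
#' @param variance null variance.
#' @return The z-score.
#' @examples
#' moran_zscore(-0.106476, -0.0625, 0.019146)
#' @export
moran_zscore <- function(I, expected, variance) {
  stopifnot(variance > 0)
  (I - expected) / sqrt(variance)
}

#' Permutation test for global Moran's I
#'
#' Recomputes I under random relabelings of the regions and returns the
#' pseudo p-value `(1 + #{|I_perm - E| >= |I_obs - E|}) / (n_perm + 1)`.
#'
#' @param x region values.
#' @param W spatial weights.
#' @param n_perm number of permutations (at least 99).
#' @param seed RNG seed.
#' @return A list with `pseudo_p`, `I_obs`, `perm_I` (the permuted values).
#' @export
moran_permutation_test <- function(x, W, n_perm = 999L, seed = 1L) {
  stopifnot(n_perm >= 99L)
  w <- weights_matrix(W)
  n <- length(x)
  z <- x - mean(x)
  ss <- sum(z^2)
  if (ss == 0) stop_resilpp("constant x", class = "resilpp_spatial_error")
  s0 <- sum(w)
  I_obs <- (n / s0) * drop(crossprod(z, w %*% z)) / ss
  E <- -1 / (n - 1)
  with_seed(seed, {
    Z <- vapply(seq_len(n_perm), function(b) sample(z), numeric(n))
    perm_I <- (n / s0) * colSums(Z * (w %*% Z)) / ss
    p <- (1 + sum(abs(perm_I - E) >= abs(I_obs - E))) / (n_perm + 1)
    list(pseudo_p = p, I_obs = I_obs, perm_I = perm_I)
  })
}

#' Local Moran's I (LISA)
#'
#' Per-region decomposition
#' `I_i = n (x_i - xbar) sum_j w_ij (x_j - xbar) / sum_i (x_i - xbar)^2`,
#' which satisfies `sum_i I_i = s0 * I`.  Each region is assigned a LISA
#' quadrant from the signs of its deviation and its spatial lag: HH
#' ("strong-strong" aggregation), LL ("weak-weak"), HL and LH for the
#' discordant cases.  Per-region pseudo p-values come from conditional
#' permutation (the region's own value held fixed, neighbors relabeled).
#'
#' @param x region values.
#' @param W spatial weights.
#' @param n_perm conditional permutations per region (0 skips inference).
#' @param seed RNG seed for the conditional permutations.
#' @return A list of class `"local_moran"` with a data frame `table`
#'   (columns `label`, `I_i`, `deviation`, `lag`, `quadrant`, `pseudo_p`)
#'   plus `global_I` and `s0`.
#' @export
local_moran <- function(x, W, n_perm = 999L, seed = 1L) {
  w <- weights_matrix(W)
  n <- length(x)
  labels <- if (inherits(W, "spatial_weights")) W$labels else
    (names(x) %||% as.character(seq_len(n)))
  z <- x - mean(x)
  ss <- sum(z^2)
  if (ss == 0) stop_resilpp("constant x", class = "resilpp_spatial_error")
  lag <- drop(w %*% z)
  Ii <- n * z * lag / ss
  quadrant <- ifelse(z >= 0 & lag >= 0, "HH",
              ifelse(z < 0 & lag < 0, "LL",
              ifelse(z >= 0, "HL", "LH")))
  pseudo_p <- rep(NA_real_, n)
  if (n_perm > 0L) {
    with_seed(seed, {
      for (i in seq_len(n)) {
        others <- z[-i]
        wi <- w[i, -i]
        perm_lag <- vapply(seq_len(n_perm),
                           function(b) sum(wi * sample(others)), 0)
        perm_Ii <- n * z[i] * perm_lag / ss
        pseudo_p[i] <- (1 + sum(abs(perm_Ii) >= abs(Ii[i]))) / (n_perm + 1)
      }
    })
  }
  s0 <- sum(w)
  structure(list(table = data.frame(label = labels, I_i = Ii, deviation = z,
                                    lag = lag, quadrant = quadrant,
                                    pseudo_p = pseudo_p,
                                    stringsAsFactors = FALSE),
                 global_I = sum(Ii) / s0, s0 = s0),
            class = "local_moran")
}

#' Moran statistics on a subset of regions
#'
#' Restricts the weights to the subset (re-standardizing rows when the full
#' matrix was row-standardized) and reports both the subset's global I and
#' the mean of its local I values, labeling each convention, since a single
#' per-group number can mean either.
#'
#' @param x region values, named or aligned with `W$labels`.
#' @param W a [spatial_weights()] object.
#' @param subset_labels labels of the subset regions (at least 3).
#' @return A list of class `"subset_moran"`: `global_I` (subset global
#'   Moran's I), `mean_local_I` (mean of subset local I), `local` (the
#'   subset [local_moran()] result), `labels`.
#' @export
subset_moran <- function(x, W, subset_labels) {
  stopifnot(inherits(W, "spatial_weights"))
  idx <- match(subset_labels, W$labels)
  if (anyNA(idx)) {
    stop_resilpp("unknown region label(s): %s",
                 paste(subset_labels[is.na(idx)], collapse = ", "),
                 class = "resilpp_spatial_error")
  }
  if (length(idx) < 3L) stop_resilpp("subset needs at least 3 regions",
                                     class = "resilpp_spatial_error")
  sub_w <- W$matrix[idx, idx, drop = FALSE]
  if (W$standardized) {
    rs <- rowSums(sub_w)
    sub_w[rs > 0, ] <- sub_w[rs > 0, , drop = FALSE] / rs[rs > 0]
  }
  sw <- structure(list(labels = W$labels[idx], matrix = sub_w,
                       standardized = W$standardized, s0 = sum(sub_w)),
                  class = "spatial_weights")
  xs <- x[idx]
  gm <- global_moran(xs, sw)
  lm <- local_moran(xs, sw, n_perm = 0L)
  structure(list(global_I = gm$I, mean_local_I = mean(lm$table$I_i),
                 global = gm, local = lm, labels = W$labels[idx]),
            class = "subset_moran")
}

#' Exact attainable range of Moran's I for a weight matrix
#'
#' Moran's I is often described as ranging over \[-1, 1\], but its exact
#' bounds are set by the extreme eigenvalues of the symmetrized, doubly
#' centered weight matrix: `I` ranges over `(n / s0) * [lambda_min,
#' lambda_max]`.  This diagnostic reports those bounds.
#'
#' @param W spatial weights.
#' @return Numeric vector `c(lower, upper)`.
#' @export
moran_bounds <- function(W) {
  w <- weights_matrix(W)
  n <- nrow(w)
  M <- diag(n) - matrix(1 / n, n, n)
  sym <- M %*% ((w + t(w)) / 2) %*% M
  ev <- eigen(sym, symmetric = TRUE, only.values = TRUE)$values
  (n / sum(w)) * c(min(ev), max(ev))
}

# Internal: accept either a spatial_weights object or a bare matrix.
weights_matrix <- function(W) {
  w <- if (inherits(W, "spatial_weights")) W$matrix else as.matrix(W)
  if (any(diag(w) != 0) || any(w < 0)) {
    stop_resilpp("weights must be nonnegative with zero diagonal",
                 class = "resilpp_spatial_error")
  }
  w
}

#' @export
print.global_moran <- function(x, ...) {
  cat(sprintf("global Moran's I: %.6f\nexpected: %.6f\nvariance (%s): %.6f\nz-score: %.6f\np-value: %.6f\n",
              x$I, x$expected, x$variance_method, x$variance, x$z, x$p_two_sided))
  invisible(x)
}

#' @export
print.local_moran <- function(x, ...) {
  cat(sprintf("local Moran's I for %d regions (sum I_i / s0 = %.6f)\n",
              nrow(x$table), x$global_I))
  print(x$table, row.names = FALSE)
  invisible(x)
}
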