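#' Project observations onto a direction
#'
#' Computes the one-dimensional projection `y(i) = sum_j a(j) x(i, j)` of the
#' rows of `X` onto direction `a`.
#'
#' @param X numeric matrix, observations in rows.
#' @param a numeric direction vector with `ncol(X)` components.
#' @return Numeric vector of projection values, one per row of `X`.
#' @export
project <- function(X, a) {
  X <- as.matrix(X)
  if (length(a) != ncol(X)) {
    stop_resilpp("direction has %d components but matrix has %d columns",
                 length(a), ncol(X), class = "resilpp_dim_error")
  }
  drop(X %*% a)
}

#' Spread of projection values
#'
#' The sample standard deviation (denominator `m - 1`) of the projected
#' values; the first factor of the projection index.
#'
#' @param y numeric vector of projection values, length at least 2.
#' @return Non-negative scalar.
#' @export
projection_spread <- function(y) {
  if (length(y) < 2L) {
    stop_resilpp("spread needs at least 2 projection values",
                 class = "resilpp_dim_error")
  }
  stats::sd(y)
}

#' Local density of projection values
#'
#' The windowed pairwise density `D = sum_{i,j} (R - r_ij) u(R - r_ij)` over
#' ordered pairs, where `r_ij = |y_i - y_j|` and `u` is the unit step
#' (`u(0) = 1`, so a pair exactly at the window edge contributes zero
#' weight).  Self-pairs each contribute `R` when included.
#'
#' @param y numeric vector of projection values.
#' @param R positive window radius.
#' @param include_self include the `i = j` pairs (adds `length(y) * R`).
#' @return Non-negative scalar.
#' @export
local_density <- function(y, R, include_self = FALSE) {
  stopifnot(R > 0)
  r <- abs(outer(y, y, "-"))
  contrib <- (R - r) * (r <= R)
  if (!include_self) diag(contrib) <- 0
  sum(contrib)
}

#' Projection index objective
#'
#' The projection-pursuit objective `F(a) = S * D`: the spread of the
#' projected values times their local density.  The direction is renormalized
#' to unit Euclidean norm before evaluation, so the unit-sphere constraint is
#' enforced exactly rather than by penalty.  Under the `fraction_of_spread`
#' radius rule the density window is `R = radius_value * S`, tying the
#' window to the projection's own scale; under `fixed` it is `radius_value`.
#'
#' @param X numeric matrix of standardized observations (rows) by variables
#'   (columns).
#' @param a direction vector; must be nonzero.
#' @param radius_rule `"fraction_of_spread"` (default) or `"fixed"`.
#' @param radius_value positive scalar: the fraction of the spread, or the
#'   fixed radius.
#' @param include_self passed to [local_density()].
#' @return A list with `objective` (F), `spread` (S), `density` (D),
#'   `radius` (R) and the normalized `direction`.
#' @export
projection_objective <- function(X, a,
                                 radius_rule = c("fraction_of_spread", "fixed"),
                                 radius_value = 0.1,
                                 include_self = FALSE) {
  radius_rule <- match.arg(radius_rule)
  stopifnot(radius_value > 0)
  nrm <- sqrt(sum(a^2))
  if (nrm < 1e-12) {
    stop_resilpp("zero direction vector", class = "resilpp_direction_error")
  }
  a <- a / nrm
  y <- project(X, a)
  S <- projection_spread(y)
  R <- if (radius_rule == "fraction_of_spread") radius_value * S else radius_value
  if (R <= 0) {
    # degenerate spread under the fraction rule: no window, no structure
    return(list(objective = 0, spread = S, density = 0, radius = 0,
                direction = a, projections = y))
  }
  D <- local_density(y, R, include_self)
  list(objective = S * D, spread = S, density = D, radius = R,
       direction = a, projections = y)
}
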