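# Independent brute-force oracles, written directly from the defining
# formulas with explicit loops so they share no code path with the package.

# Projection index F(a) = S * D evaluated from scratch.
brute_projection_index <- function(X, a, R_frac = 0.1, fixed_R = NULL,
                                   include_self = FALSE) {
  a <- a / sqrt(sum(a^2))
  m <- nrow(X)
  y <- numeric(m)
  for (i in seq_len(m)) y[i] <- sum(a * X[i, ])
  ybar <- sum(y) / m
  S <- sqrt(sum((y - ybar)^2) / (m - 1))
  R <- if (is.null(fixed_R)) R_frac * S else fixed_R
  D <- 0
  if (R > 0) {
    for (i in seq_len(m)) {
      for (j in seq_len(m)) {
        if (!include_self && i == j) next
        r <- abs(y[i] - y[j])
        if (R - r >= 0) D <- D + (R - r)
      }
    }
  }
  list(F = S * D, S = S, D = D, R = R)
}

# Global Moran's I from the double sum.
brute_global_moran <- function(x, w) {
  n <- length(x)
  xbar <- mean(x)
  num <- 0; s0 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      num <- num + w[i, j] * (x[i] - xbar) * (x[j] - xbar)
      s0 <- s0 + w[i, j]
    }
  }
  (n / s0) * num / sum((x - xbar)^2)
}

# Local Moran's I_i from the per-unit formula.
brute_local_moran <- function(x, w) {
  n <- length(x)
  xbar <- mean(x)
  denom <- sum((x - xbar)^2)
  out <- numeric(n)
  for (i in seq_len(n)) {
    lag <- 0
    for (j in seq_len(n)) lag <- lag + w[i, j] * (x[j] - xbar)
    out[i] <- n * (x[i] - xbar) * lag / denom
  }
  out
}

# Normality-null variance of Moran's I from the textbook moment formulas,
# with the S-sums accumulated by explicit loops.
brute_moran_variance_normality <- function(w) {
  n <- nrow(w)
  s0 <- 0; s1 <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      s0 <- s0 + w[i, j]
      s1 <- s1 + (w[i, j] + w[j, i])^2 / 2
    }
  }
  s2 <- 0
  for (i in seq_len(n)) {
    ri <- sum(w[i, ]); ci <- sum(w[, i])
    s2 <- s2 + (ri + ci)^2
  }
  (n^2 * s1 - n * s2 + 3 * s0^2) / (s0^2 * (n^2 - 1)) - (1 / (n - 1))^2
}

# Exhaustive Jenks: minimal within-class SSE over all contiguous partitions
# of the sorted values into k nonempty blocks.
brute_jenks_sse <- function(values, k) {
  x <- sort(values)
  m <- length(x)
  sse_run <- function(v) sum((v - mean(v))^2)
  best <- Inf
  # choose k-1 cut positions among the m-1 gaps
  cuts <- utils::combn(m - 1L, k - 1L)
  for (c in seq_len(ncol(cuts))) {
    bnd <- c(0L, cuts[, c], m)
    sse <- 0
    for (b in seq_len(k)) sse <- sse + sse_run(x[(bnd[b] + 1L):bnd[b + 1L]])
    if (sse < best) best <- sse
  }
  best
}

# A length-n vector (n even, >= 8) with sample kurtosis
# b2 = n * sum(z^4) / sum(z^2)^2 exactly 3.
kurtosis3_vector <- function(n = 8L) {
  stopifnot(n %% 2L == 0L, n >= 8L)
  base <- rep(c(1, -1), each = (n - 2L) / 2L)
  b2 <- function(M) {
    x <- c(M, -M, base)
    z <- x - mean(x)
    length(x) * sum(z^4) / sum(z^2)^2
  }
  M <- stats::uniroot(function(M) b2(M) - 3, c(1.01, 50), tol = 1e-14)$root
  c(M, -M, base)
}

# Small fixed fixtures.
toy_scheme <- function(n = 2L, attribute = "positive") {
  indicator_scheme(sprintf("T%d", seq_len(n)), "resistance",
                   rep_len(attribute, n))
}

toy_panel <- function(values, attribute = "positive") {
  values <- as.matrix(values)
  indicator_panel(values, sprintf("r%d", seq_len(nrow(values))),
                  toy_scheme(ncol(values), attribute))
}

grid_coords <- function(side = 7L) {
  g <- expand.grid(x = seq_len(side), y = seq_len(side))
  rownames(g) <- sprintf("g%02d", seq_len(nrow(g)))
  as.matrix(g)
}

# Run expr under a seed without relying on package internals.
with_seed_helper <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
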