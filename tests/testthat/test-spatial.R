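test_that("inverse-distance weights reproduce reciprocal distances", {
  pts <- cbind(c(0, 1, 2), c(0, 0, 0))
  rownames(pts) <- c("a", "b", "c")
  W <- spatial_weights(pts, cutoff = Inf)
  expect_equal(W$matrix[1, 2], 1)
  expect_equal(W$matrix[1, 3], 0.5)
  expect_equal(W$matrix[2, 3], 1)
  expect_true(isSymmetric(W$matrix))
  expect_equal(diag(W$matrix), rep(0, 3))

  Wr <- spatial_weights(pts, cutoff = Inf, row_standardize = TRUE)
  expect_equal(Wr$matrix[1, ], c(0, 2 / 3, 1 / 3))
  expect_equal(rowSums(Wr$matrix), rep(1, 3))
})

test_that("s0 equals the brute-force double sum on a random cloud", {
  set.seed(20)
  pts <- matrix(runif(20), 10, 2)
  W <- spatial_weights(pts, cutoff = Inf)
  expect_equal(W$s0, sum(W$matrix), tolerance = 1e-12)
  d <- as.matrix(dist(pts))
  acc <- 0
  for (i in 1:10) for (j in 1:10) if (i != j) acc <- acc + 1 / d[i, j]
  expect_equal(W$s0, acc, tolerance = 1e-12)
})

test_that("default cutoff guarantees every region a neighbor; coincident points error", {
  set.seed(21)
  pts <- matrix(runif(16), 8, 2)
  W <- spatial_weights(pts)
  expect_true(all(rowSums(W$matrix) > 0))
  dup <- rbind(c(0, 0), c(0, 0), c(1, 1))
  expect_error(spatial_weights(dup), "coincident")
})

test_that("global and local Moran match brute-force double sums (n <= 8)", {
  set.seed(22)
  for (rep in 1:10) {
    n <- sample(4:8, 1)
    pts <- matrix(runif(2 * n), n, 2)
    W <- spatial_weights(pts, cutoff = Inf,
                         row_standardize = rep %% 2 == 0)
    x <- rnorm(n)
    g <- global_moran(x, W)
    expect_equal(g$I, brute_global_moran(x, W$matrix), tolerance = 1e-12)
    l <- local_moran(x, W, n_perm = 0)
    expect_equal(l$table$I_i, brute_local_moran(x, W$matrix), tolerance = 1e-12)
    # additivity identity: sum I_i = s0 * I
    expect_equal(sum(l$table$I_i), W$s0 * g$I, tolerance = 1e-9)
    # z recomputes from stored fields
    expect_equal(g$z, (g$I - g$expected) / sqrt(g$variance), tolerance = 1e-12)
    # affine invariance of I
    g2 <- global_moran(3 * x + 7, W)
    expect_equal(g2$I, g$I, tolerance = 1e-12)
  }
})

test_that("checkerboard on a rook 2x2 lattice matches the hand evaluation", {
  w <- rbind(c(0, 1, 1, 0), c(1, 0, 0, 1), c(1, 0, 0, 1), c(0, 1, 1, 0))
  w <- w / rowSums(w)
  x <- c(1, -1, -1, 1)
  g <- global_moran(x, w)
  expect_equal(g$I, brute_global_moran(x, w), tolerance = 1e-12)
  expect_equal(g$I, -1)                  # perfect checkerboard dissimilarity
})

test_that("Moran expectation is -1/(n-1) and agrees with ape on observed I", {
  skip_if_not_installed("ape")
  set.seed(23)
  n <- 17
  pts <- matrix(runif(2 * n), n, 2)
  # ape::Moran.I row-standardizes internally, so hand it a matrix that
  # already is, making the two conventions coincide
  W <- spatial_weights(pts, cutoff = Inf, row_standardize = TRUE)
  x <- rnorm(n)
  g <- global_moran(x, W)
  expect_equal(g$expected, -1 / 16)
  a <- ape::Moran.I(x, W$matrix)
  expect_equal(g$I, a$observed, tolerance = 1e-10)
  expect_equal(g$expected, a$expected, tolerance = 1e-12)
  # ape's sd is the randomization-null standard deviation
  expect_equal(sqrt(moran_variance(x, W, "randomization")), a$sd,
               tolerance = 1e-10)
})

test_that("variance formulas match the independent moment oracle", {
  set.seed(24)
  pts <- matrix(runif(10), 5, 2)
  W <- spatial_weights(pts, cutoff = Inf)
  x <- rnorm(5)
  expect_equal(moran_variance(x, W, "normality"),
               brute_moran_variance_normality(W$matrix), tolerance = 1e-12)
  expect_gt(moran_variance(x, W, "randomization"), 0)
  # at Gaussian kurtosis (b2 = 3) the randomization and normality variances
  # agree asymptotically; their gap shrinks with n (it is O(1/n^2))
  gaps <- vapply(c(8L, 16L, 32L, 64L), function(n) {
    xk <- kurtosis3_vector(n)
    set.seed(n)
    Wk <- spatial_weights(matrix(runif(2 * n), n, 2), cutoff = Inf)
    abs(moran_variance(xk, Wk, "randomization") -
          moran_variance(xk, Wk, "normality"))
  }, 0)
  expect_true(all(diff(gaps) < 0))
  expect_lt(gaps[4], 1e-4)
})

test_that("permutation test is seed-deterministic and detects a planted signal", {
  pts <- grid_coords(7)
  W <- spatial_weights(pts, "distance_band", cutoff = 1, row_standardize = TRUE)
  x <- make_spatial_field(pts, rho = 0.8, seed = 31, W = W)
  p1 <- moran_permutation_test(x, W, n_perm = 999, seed = 5)
  p2 <- moran_permutation_test(x, W, n_perm = 999, seed = 5)
  expect_identical(p1, p2)
  expect_lte(p1$pseudo_p, 0.01)
})

test_that("LISA quadrants follow the deviation/lag sign rule", {
  # a high point among low neighbors is HL ("strong-weak")
  pts <- cbind(c(0, 1, 2, 1), c(0, 0, 0, 1))
  rownames(pts) <- c("lo1", "hi", "lo2", "lo3")
  W <- spatial_weights(pts, cutoff = Inf)
  x <- c(1, 10, 1, 1)
  l <- local_moran(x, W, n_perm = 99, seed = 1)
  tab <- l$table
  expect_equal(tab$quadrant[tab$label == "hi"], "HL")
  expect_true(all(tab$quadrant[tab$label != "hi"] == "LH"))
  expect_true(all(tab$pseudo_p > 0 & tab$pseudo_p <= 1))
  agree <- with(tab, ifelse(deviation >= 0 & lag >= 0, "HH",
                     ifelse(deviation < 0 & lag < 0, "LL",
                     ifelse(deviation >= 0, "HL", "LH"))))
  expect_identical(tab$quadrant, agree)
})

test_that("subset analysis: identity subset reproduces the full global I", {
  set.seed(25)
  pts <- matrix(runif(24), 12, 2)
  rownames(pts) <- sprintf("r%02d", 1:12)
  W <- spatial_weights(pts, cutoff = Inf)
  x <- rnorm(12)
  names(x) <- rownames(pts)
  full <- global_moran(x, W)
  sub <- subset_moran(x, W, rownames(pts))
  expect_equal(sub$global_I, full$I, tolerance = 1e-12)
  expect_error(subset_moran(x, W, c("r01", "r02")), "at least 3")
  expect_error(subset_moran(x, W, c("r01", "r02", "zzz")), "unknown")
})

test_that("an alternating high/low cluster has negative subset global I", {
  pts <- cbind(seq(0, 5), rep(0, 6))
  rownames(pts) <- sprintf("e%d", 1:6)
  W <- spatial_weights(pts, cutoff = 1.5)
  x <- rep(c(10, 1), 3)
  names(x) <- rownames(pts)
  sub <- subset_moran(x, W, rownames(pts))
  expect_lt(sub$global_I, 0)
  expect_lt(sub$mean_local_I, 0)
})

test_that("exact Moran bounds come from the spectral range, not [-1, 1]", {
  set.seed(26)
  pts <- matrix(runif(14), 7, 2)
  W <- spatial_weights(pts, cutoff = Inf)
  b <- moran_bounds(W)
  expect_lt(b[1], 0)
  expect_gt(b[2], 0)
  # every achievable I must fall inside the bounds
  for (k in 1:20) {
    x <- rnorm(7)
    I <- global_moran(x, W)$I
    expect_gte(I, b[1] - 1e-9)
    expect_lte(I, b[2] + 1e-9)
  }
})
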