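test_that("default spec echoes the emulated panel shape", {
  sp <- make_panel(synthetic_spec(seed = 2))
  p <- sp$panel
  expect_equal(nrow(p$values), 17L)
  expect_equal(ncol(p$values), 27L)
  expect_equal(as.vector(table(factor(p$scheme$dimension,
                                      levels = resilience_dimensions()))),
               c(7L, 8L, 6L, 6L))
  expect_equal(p$scheme$code[p$scheme$attribute == "negative"],
               c("V11", "V12", "V14"))
  expect_length(validate_panel(p), 0L)
  # at most one missing cell per column at the default rate
  expect_true(all(colSums(p$missing_mask) <= 1L))
  expect_equal(nrow(sp$coords), 17L)
})

test_that("generation is seed-deterministic and missing_rate 0 gives a complete panel", {
  a <- make_panel(synthetic_spec(seed = 7))
  b <- make_panel(synthetic_spec(seed = 7))
  expect_identical(a$panel$values, b$panel$values)
  expect_identical(a$coords, b$coords)
  c <- make_panel(synthetic_spec(seed = 8))
  expect_false(identical(a$panel$values, c$panel$values))
  full <- make_panel(synthetic_spec(missing_rate = 0, seed = 7))
  expect_false(any(full$panel$missing_mask))
})

test_that("zero latent strength leaves indicators essentially uncorrelated", {
  mean_abs_r <- vapply(1:20, function(s) {
    sp <- make_panel(synthetic_spec(latent_dimension_strength = 0,
                                    missing_rate = 0, seed = s))
    cm <- stats::cor(sp$panel$values)
    mean(abs(cm[upper.tri(cm)]))
  }, 0)
  expect_lt(mean(mean_abs_r), 0.25)
})

test_that("positive latent strength induces within-dimension correlation", {
  sp <- make_panel(synthetic_spec(latent_dimension_strength = 3,
                                  missing_rate = 0, seed = 3))
  cm <- abs(stats::cor(sp$panel$values))
  same_dim <- outer(sp$scheme$dimension, sp$scheme$dimension, "==")
  diag(same_dim) <- NA
  expect_gt(mean(cm[same_dim & upper.tri(cm)], na.rm = TRUE),
            mean(cm[!same_dim & upper.tri(cm)], na.rm = TRUE))
})

test_that("SAR fields span the Moran regimes with rho", {
  pts <- grid_coords(7)
  W <- spatial_weights(pts, "distance_band", cutoff = 1, row_standardize = TRUE)
  I_pos <- vapply(1:30, function(s)
    global_moran(make_spatial_field(pts, 0.8, seed = s, W = W), W)$I, 0)
  I_null <- vapply(1:30, function(s)
    global_moran(make_spatial_field(pts, 0, seed = s, W = W), W)$I, 0)
  expect_gt(mean(I_pos), mean(I_null) + 0.1)
  # rho = 0 is plain white noise through the identity transform
  f0 <- make_spatial_field(pts, 0, seed = 5, W = W)
  expect_equal(f0, with_seed_helper(5, rnorm(49)), tolerance = 1e-12)
})

test_that("known-optimum bundles certify themselves", {
  q <- known_optimum_problem("quadratic_1d")
  expect_equal(q$objective(q$certificate), 0)
  s <- known_optimum_problem("sphere_nd", centre = c(0.2, 0.7))
  expect_equal(s$objective(s$certificate), 0)
  d <- known_optimum_problem("dominant_indicator_panel", seed = 9)
  # planted indicator maximizes the univariate spread x density criterion
  crit <- apply(d$standardized$values, 2, function(col) {
    S <- projection_spread(col)
    S * local_density(col, R = 0.1 * S)
  })
  expect_equal(unname(which.max(crit)), d$planted)
})
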