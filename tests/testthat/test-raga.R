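test_that("decode maps unit genes linearly into bounds", {
  b <- rbind(c(-1, 1))
  expect_equal(raga_decode(0, b), -1)
  expect_equal(raga_decode(1, b), 1)
  expect_equal(raga_decode(0.25, rbind(c(2, 6))), 3)
  expect_error(raga_decode(1.2, b), "outside")
})

test_that("rank fitness is the geometric series over best-first ranks", {
  f <- rank_fitness(c(10, 3, 7), alpha = 0.05)
  expect_equal(f[1], 0.05)              # best
  expect_equal(f[3], 0.05 * 0.95)       # second best
  expect_equal(f[2], 0.05 * 0.95^2)
  expect_true(all(diff(sort(f, decreasing = TRUE)) < 0))
})

test_that("roulette selection is proportional to fitness", {
  expect_true(all(roulette_select(c(1, 0), 50, seed = 1) == 1L))
  freq <- tabulate(roulette_select(c(1, 1), 1e5, seed = 2), 2) / 1e5
  expect_equal(freq, c(0.5, 0.5), tolerance = 0.02)
  freq2 <- tabulate(roulette_select(c(3, 1), 1e5, seed = 3), 2) / 1e5
  expect_equal(freq2, c(0.75, 0.25), tolerance = 0.02)
})

test_that("mutation keeps genes in the unit box and is offset-symmetric", {
  set.seed(4)
  genes <- matrix(0.5, 2000, 3)
  muts <- resilpp:::raga_mutate(genes, pm = 1)
  expect_true(all(muts >= 0 & muts <= 1))
  expect_equal(mean(muts - 0.5), 0, tolerance = 0.02)
})

test_that("crossover blends stay in the box and preserve identical parents", {
  set.seed(5)
  genes <- matrix(runif(40), 10, 4)
  kids <- resilpp:::raga_crossover(genes, pc = 1)
  expect_true(all(kids >= 0 & kids <= 1))
  same <- matrix(0.3, 6, 2)
  kids2 <- resilpp:::raga_crossover(same, pc = 1)
  expect_true(all(kids2 == 0.3))
})

test_that("acceleration shrinks to the elite envelope and handles collapse", {
  b <- rbind(c(0, 1), c(0, 1))
  e <- rbind(c(0.2, 0.5), c(0.4, 0.3))
  nb <- unname(raga_accelerate(e, b))
  expect_equal(nb[1, ], c(0.2, 0.4))
  expect_equal(nb[2, ], c(0.3, 0.5))
  expect_true(all(nb[, 2] - nb[, 1] <= b[, 2] - b[, 1]))
  nc <- unname(raga_accelerate(cbind(c(0.7, 0.7)), rbind(c(0, 1))))
  expect_equal(nc[1, 2] - nc[1, 1], 2e-6, tolerance = 1e-9)
})

test_that("optimizer recovers known optima with a monotone trace over seeds", {
  for (s in 1:10) {
    q <- known_optimum_problem("quadratic_1d")
    r <- raga_optimize(q$objective, q$n_vars,
                       ga_config(seed = s, max_iterations = 100))
    expect_lt(abs(r$best_x - q$certificate), 1e-3)
    expect_gte(r$best_objective, -1e-6)
    expect_true(all(diff(r$trace) >= 0))
  }
  sph <- known_optimum_problem("sphere_nd")
  for (s in 1:10) {
    r <- raga_optimize(sph$objective, sph$n_vars,
                       ga_config(seed = s, max_iterations = 200))
    expect_true(all(abs(r$best_x - sph$certificate) < 1e-2))
  }
})

test_that("optimizer is deterministic under a fixed seed", {
  f <- function(x) -sum((x - 0.4)^2)
  a <- raga_optimize(f, 2, ga_config(seed = 42, max_iterations = 50))
  b <- raga_optimize(f, 2, ga_config(seed = 42, max_iterations = 50))
  expect_identical(a, b)
  expect_true(all(a$best_x >= a$final_bounds[, 1] - 1e-12 &
                    a$best_x <= a$final_bounds[, 2] + 1e-12))
})
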