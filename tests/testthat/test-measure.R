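std_from <- function(values, attribute = "positive") {
  standardize(toy_panel(values, attribute))
}

test_that("duplicated indicators get equal projection values; output is deterministic", {
  set.seed(10)
  v <- cbind(a = runif(8), b = runif(8))
  v <- cbind(v, v[, 1])                 # third column copies the first
  std <- std_from(v)
  cfg <- ga_config(seed = 3, max_iterations = 60)
  w1 <- index_weights(std, cfg)
  w2 <- index_weights(std, cfg)
  expect_identical(w1$projection_values, w2$projection_values)
  expect_equal(unname(w1$projection_values[1]), unname(w1$projection_values[3]),
               tolerance = 1e-6)
  expect_equal(sum(w1$weights), 1, tolerance = 1e-9)
  expect_true(all(w1$weights >= 0))
})

test_that("a planted bimodal indicator attains the extreme projection value", {
  prob <- known_optimum_problem("dominant_indicator_panel", seed = 4)
  w <- index_weights(prob$standardized, ga_config(seed = 1, max_iterations = 80))
  pv <- w$projection_values
  extreme <- which.max(abs(pv - stats::median(pv)))
  expect_equal(names(pv)[extreme], prob$certificate)
})

test_that("identical regions score identically and dominant regions score highest", {
  set.seed(12)
  v <- matrix(runif(24), 6, 4)
  v[2, ] <- v[5, ]                      # two identical regions
  std <- std_from(v)
  s <- resilience_scores(std, ga_config(seed = 2, max_iterations = 60))
  expect_equal(unname(s$scores[2]), unname(s$scores[5]), tolerance = 1e-6)

  # a region at every column maximum dominates under nonnegative directions
  v2 <- matrix(runif(20, 0, 0.8), 5, 4)
  v2[3, ] <- 1
  std2 <- std_from(v2)
  s2 <- resilience_scores(std2, ga_config(seed = 2, max_iterations = 60))
  expect_true(all(s2$scores[3] >= s2$scores - 1e-9))
})

test_that("dimension runs use only their own columns and expose non-additivity", {
  set.seed(13)
  sp <- make_panel(synthetic_spec(missing_rate = 0, seed = 21))
  std <- standardize(sp$panel)
  cfg <- ga_config(seed = 5)
  it <- c(resistance = 15L, restore = 40L, adaptability = 40L,
          collaborative = 30L)
  d1 <- dimension_scores(std, "resistance", cfg, iterations = it)
  expect_length(d1$scores, 17L)
  expect_length(d1$direction, 7L)       # resistance owns 7 indicators
  expect_error(dimension_scores(std, "nope"), "arg")

  one_ind <- std
  keep <- c(which(std$scheme$dimension == "resistance")[1],
            which(std$scheme$dimension == "restore"))
  one_ind$values <- std$values[, keep]
  one_ind$scheme <- std$scheme[keep, ]
  one_ind$missing_mask <- std$missing_mask[, keep]
  expect_error(dimension_scores(one_ind, "resistance"), "at least 2")
})

test_that("degenerate dimension input yields a zero objective", {
  v <- cbind(rep(0.5, 5), rep(0.2, 5), runif(5))
  sch <- indicator_scheme(c("A", "B", "C"),
                          c("resistance", "resistance", "restore"), "positive")
  p <- indicator_panel(v, sprintf("r%d", 1:5), sch)
  std <- list(values = v, region_labels = p$region_labels, scheme = sch,
              missing_mask = matrix(FALSE, 5, 3))
  class(std) <- c("standardized_panel", "indicator_panel")
  d <- dimension_scores(std, "resistance", ga_config(seed = 1),
                        iterations = c(resistance = 10L))
  expect_equal(d$objective, 0)
})

test_that("jenks breaks equal the exhaustive-partition optimum", {
  r <- jenks_breaks(c(1, 1.1, 9, 9.1), k = 2)
  expect_equal(r$breaks, 9)
  expect_gt(r$gvf, 0.99)
  expect_equal(sort(unlist(r$classes[1])), c(1, 1.1))

  x <- c(4, 1, 7, 7, 2, 9)
  expect_equal(jenks_breaks(x, k = length(unique(x)))$gvf, 1)

  set.seed(14)
  for (rep in 1:25) {
    m <- sample(6:12, 1)
    x <- round(runif(m, 0, 10), 2)
    for (k in 2:min(5, length(unique(x)))) {
      got <- jenks_breaks(x, k)
      expect_equal(got$sse_within, brute_jenks_sse(x, k), tolerance = 1e-10)
    }
  }
  expect_error(jenks_breaks(c(1, 1, 2), k = 3), "distinct")
})

test_that("level assignment follows the published threshold convention", {
  breaks <- c(0.034, 0.051, 0.081, 0.131)
  expect_equal(assign_levels(0.14, breaks), 1L)
  expect_equal(assign_levels(0.05, breaks), 4L)
  expect_equal(assign_levels(0.02, breaks), 5L)
  # boundaries: top break inclusive upward, interior left-closed
  expect_equal(assign_levels(c(0.131, 0.081, 0.034), breaks), c(1L, 2L, 4L))
})

test_that("entropy-TOPSIS matches a from-scratch spreadsheet computation", {
  v <- rbind(c(0.0, 1.0, 0.2),
             c(0.5, 0.4, 1.0),
             c(1.0, 0.0, 0.6),
             c(0.25, 0.8, 0.0))
  std <- std_from(v)
  got <- entropy_topsis(std)
  # independent computation, step by step
  m <- nrow(v)
  p <- sweep(v, 2, colSums(v), "/")
  e <- -colSums(ifelse(p > 0, p * log(p), 0)) / log(m)
  w <- (1 - e) / sum(1 - e)
  vw <- sweep(v, 2, w, "*")
  dpos <- sqrt(rowSums((vw - rep(apply(vw, 2, max), each = m))^2))
  dneg <- sqrt(rowSums((vw - rep(apply(vw, 2, min), each = m))^2))
  expect_equal(unname(got$weights), unname(w), tolerance = 1e-12)
  expect_equal(unname(got$closeness), unname(dneg / (dpos + dneg)),
               tolerance = 1e-12)
})

test_that("entropy endpoints: uniform column has weight 0, concentrated column dominates", {
  v <- cbind(rep(0.5, 4), c(1, 0, 0, 0), c(0.9, 0.1, 0.4, 0.6))
  sch <- indicator_scheme(c("U", "C", "X"), "resistance", "positive")
  std <- list(values = v, region_labels = sprintf("r%d", 1:4), scheme = sch,
              missing_mask = matrix(FALSE, 4, 3))
  class(std) <- c("standardized_panel", "indicator_panel")
  got <- entropy_topsis(std)
  expect_equal(unname(got$entropy["U"]), 1, tolerance = 1e-12)
  expect_equal(unname(got$weights["U"]), 0, tolerance = 1e-12)
  expect_equal(unname(got$entropy["C"]), 0, tolerance = 1e-12)
  expect_equal(unname(which.max(got$weights)), 2L)
})

test_that("scale invariance and exchangeability of the measurement", {
  set.seed(15)
  v <- matrix(runif(30), 6, 5)
  cfg <- ga_config(seed = 9, max_iterations = 40)
  base_w <- index_weights(std_from(v), cfg)
  scaled <- v
  scaled[, 2] <- v[, 2] * 37            # positive rescaling pre-standardization
  expect_equal(unname(index_weights(std_from(scaled), cfg)$weights),
               unname(base_w$weights), tolerance = 1e-12)

  perm <- c(3, 1, 2, 5, 4, 6)
  s_base <- resilience_scores(std_from(v), cfg)
  s_perm <- resilience_scores(std_from(v[perm, ]), cfg)
  expect_equal(unname(s_perm$scores), unname(s_base$scores[perm]),
               tolerance = 1e-9)
})
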