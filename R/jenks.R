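#' Jenks natural-breaks classification
#'
#' Exact optimal 1-D classification into `k` classes minimizing the
#' within-class sum of squared deviations (Fisher's dynamic programming, so
#' the optimum is global, not a heuristic).  Break values are reported as the
#' minimum of each upper class, so a value belongs to the class whose break
#' it meets or exceeds; quality is summarized by the goodness-of-variance
#' fit `GVF = 1 - SSE_within / SSE_total`.
#'
#' @param values finite numeric vector, length at least `k`.
#' @param k number of classes (at least 2, at most the number of distinct
#'   values).
#' @return A list of class `"jenks_result"`: `k`, `breaks` (k-1 ascending
#'   cut values), `levels` (per input value; level 1 is the highest class),
#'   `gvf`, and `classes` (list of sorted class members, ascending).
#' @examples
#' jenks_breaks(c(1, 1.1, 9, 9.1), k = 2)
#' @export
jenks_breaks <- function(values, k) {
  stopifnot(all(is.finite(values)), k >= 2L)
  m <- length(values)
  if (k > length(unique(values))) {
    stop_resilpp("k = %d exceeds the %d distinct values", k,
                 length(unique(values)), class = "resilpp_jenks_error")
  }
  x <- sort(values)
  # prefix sums for O(1) within-class SSE of any contiguous run
  cs <- cumsum(x); cs2 <- cumsum(x^2)
  sse <- function(i, j) { # x[i..j]
    s <- cs[j] - if (i > 1L) cs[i - 1L] else 0
    s2 <- cs2[j] - if (i > 1L) cs2[i - 1L] else 0
    s2 - s^2 / (j - i + 1L)
  }
  # dp[c, j]: minimal SSE splitting x[1..j] into c classes
  dp <- matrix(Inf, k, m)
  cut <- matrix(0L, k, m)
  for (j in seq_len(m)) dp[1L, j] <- sse(1L, j)
  for (c in 2L:k) {
    for (j in c:m) {
      for (i in c:j) { # class c is x[i..j]
        cand <- dp[c - 1L, i - 1L] + sse(i, j)
        if (cand < dp[c, j]) { dp[c, j] <- cand; cut[c, j] <- i }
      }
    }
  }
  # recover class start indices
  starts <- integer(k)
  j <- m
  for (c in k:2L) {
    starts[c] <- cut[c, j]
    j <- starts[c] - 1L
  }
  starts[1L] <- 1L
  ends <- c(starts[-1L] - 1L, m)
  classes <- lapply(seq_len(k), function(c) x[starts[c]:ends[c]])
  # breaks: minimum of each class except the lowest, ascending
  breaks <- x[starts[-1L]]
  sse_total <- sse(1L, m)
  gvf <- if (sse_total > 0) 1 - dp[k, m] / sse_total else 1
  levels <- assign_levels(values, breaks)
  structure(list(k = as.integer(k), breaks = breaks, levels = levels,
                 gvf = gvf, classes = classes, sse_within = dp[k, m]),
            class = "jenks_result")
}

#' Assign class levels from break values
#'
#' Level 1 is the highest class: a value gets level 1 when it meets or
#' exceeds the top break; interior classes are left-closed/right-open going
#' downward (`break_low <= value < break_high`), and values below the lowest
#' break get the bottom level `length(breaks) + 1`.
#'
#' @param values numeric vector.
#' @param breaks ascending cut values.
#' @return Integer levels, 1 = highest class.
#' @examples
#' assign_levels(c(0.14, 0.05, 0.02), breaks = c(0.034, 0.051, 0.081, 0.131))
#' @export
assign_levels <- function(values, breaks) {
  stopifnot(!is.unsorted(breaks, strictly = TRUE))
  k <- length(breaks) + 1L
  # number of breaks <= value, counted from below
  idx <- findInterval(values, breaks, left.open = FALSE)
  as.integer(k - idx)
}

#' @export
print.jenks_result <- function(x, ...) {
  cat(sprintf("jenks_result: %d classes, gvf = %.4f\nbreaks: %s\n",
              x$k, x$gvf, paste(signif(x$breaks, 6), collapse = ", ")))
  invisible(x)
}
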