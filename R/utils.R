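# Internal helpers shared across modules.

# Evaluate `expr` under `seed` without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Deterministic per-stage seed fan-out from one root seed; stays < 2^31.
derive_seed <- function(root, stage) {
  stopifnot(is.numeric(root), length(root) == 1L)
  offs <- sum(utf8ToInt(as.character(stage)) * seq_along(utf8ToInt(as.character(stage))))
  as.integer((as.double(root) * 48271 + offs) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_resilpp <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "resilpp_error")))
}
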