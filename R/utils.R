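# Internal helpers shared across modules.

# Derive a reproducible sub-stream seed from a master seed and a stage label.
# Keeps every source of randomness behind one integer seed while giving each
# simulation stage (founders, meiosis, traits, folds, ...) its own stream.
derive_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 131 + ch) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h * 69621 + index * 7919) %% 2147483563) + 1L
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Moment-based sample skewness (biased form, as used for transform selection).
sample_skewness <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 3L) return(NA_real_)
  s <- sd(x)
  if (s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) {
  if (!isTRUE(cond)) stop(msg, call. = FALSE)
}
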