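# internal helpers: argument checking and deterministic seed streams

stop_if_not_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0 (got %g)", name, x), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be >= 0 (got %g)", name, x), call. = FALSE)
  invisible(x)
}

# Deterministic child seed for stream `index` under `master`.
# Affine map modulo a Mersenne prime keeps streams distinct and < 2^31.
child_seed <- function(master, index) {
  m <- 2147483647
  as.integer((as.numeric(master) %% m * 48271 + as.numeric(index) * 16807) %% m)
}

# Run `expr` under a local RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}
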