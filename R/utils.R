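# internal helpers shared across the package

# Deterministically derive a child seed from a master seed and a stage label.
# Keeps every derived seed in [1, 2^31 - 2] so it is a valid R integer seed.
derive_seed <- function(seed, salt) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(as.character(salt)) * seq_along(utf8ToInt(as.character(salt))))
  as.integer((abs(seed) * 48271 + h * 16807) %% (2^31 - 1) + 1)
}

# Evaluate an expression with a local RNG state so callers' streams are
# untouched (the idiom used throughout for reproducible sub-steps).
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Half-away-from-zero rounding at `digits` decimals (report convention;
# base round() is half-to-even).
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# k folds of n indices, sizes differing by at most one, order randomized
make_folds <- function(n, k, seed) {
  stopifnot(k >= 2, n >= k)
  with_seed(seed, sample(rep_len(seq_len(k), n)))
}

stop_gapdml <- function(...) stop(sprintf(...), call. = FALSE)
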