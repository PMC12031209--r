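# internal helpers shared across modules

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never clobbers user RNG.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a child seed below 2^31 from a base seed and a stream index.
child_seed <- function(seed, index) {
  (as.numeric(seed) * 7919 + index * 104729) %% 2147483629
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_square <- function(w) {
  n <- round(sqrt(w))
  n * n == w
}
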