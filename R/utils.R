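# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is untouched. All exported stochastic functions route through
# this so a seed argument gives byte-identical output regardless of context.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
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

# Derive a child seed from a run seed and a cell index, kept inside 32-bit
# integer range so set.seed() accepts it on any platform.
derive_seed <- function(seed, i) {
  as.integer((as.double(seed) * 2654435761 + as.double(i) * 40503) %% 2147483647)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x >= 1 && x == floor(x)
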