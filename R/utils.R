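# internal helpers shared across modules

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Derive independent 31-bit sub-seeds from a master seed.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

stop_invalid <- function(...) stop(..., call. = FALSE)

# index range of a half-open time window [from, to) on a ms time axis
window_index <- function(times, from, to) {
  idx <- which(times >= from & times < to)
  if (length(idx) == 0L)
    stop_invalid("empty time window [", from, ", ", to, ") for this epoch")
  idx
}

is_meg_epochs <- function(x) inherits(x, "meg_epochs")

assert_epochs <- function(x) {
  if (!is_meg_epochs(x)) stop_invalid("expected a 'meg_epochs' object")
  invisible(x)
}
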