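# Small internal helpers shared across modules.

# Round half away from zero (behavioural-data coding convention; base round()
# rounds half to even, which would bias Likert discretisation).
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

clip <- function(x, lo, hi) {
  pmin(pmax(x, lo), hi)
}

# Derive a stream of child seeds from one master seed without disturbing the
# caller's RNG state. Values stay within the 32-bit integer range set.seed()
# accepts.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      suppressWarnings(rm(".Random.seed", envir = globalenv()))
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
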