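# Small shared helpers: presentation rounding and independent RNG streams.

#' Round half away from zero
#'
#' Presentation rounding used for report tables: exact halves round up in
#' magnitude (0.945 -> 0.95), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

# An RNG stream is a private, resumable random state, independent of the
# global stream.  Used by the simulated expert oracle so that oracle draws
# are reproducible from the oracle seed regardless of what other code draws
# from .Random.seed in between.
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$seed <- as.integer(seed)
  e$state <- NULL
  class(e) <- "rng_stream"
  e
}

# Evaluate fn() with the stream's state swapped into .Random.seed, then
# save the advanced state back and restore the caller's RNG untouched.
stream_eval <- function(stream, fn) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  if (is.null(stream$state)) {
    set.seed(stream$seed)
  } else {
    assign(".Random.seed", stream$state, envir = globalenv())
  }
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else {
      rm(".Random.seed", envir = globalenv())
    }
  })
  fn()
}

# Stable fingerprint of a character id set (order-insensitive).
id_fingerprint <- function(ids) {
  paste(sort(ids), collapse = "\x1f")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
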