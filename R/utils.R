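# Internal helpers.

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
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
  set.seed(seed)
  force(expr)
}

stop_waveclass <- function(msg, class) {
  rlang::abort(msg, class = c(class, "waveclass_error"))
}

assert_that <- function(ok, msg, class = "waveclass_invalid") {
  if (!isTRUE(ok)) stop_waveclass(msg, class)
  invisible(TRUE)
}

# Trapezoidal integral of y over x (both numeric, x ascending).
trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) / 2 * diff(x))
}
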