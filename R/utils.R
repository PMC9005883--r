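# Internal validation helpers. All user-facing errors go through stop() with
# call. = FALSE so messages name the offending quantity, not the frame.

check_number <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite and numeric", name), call. = FALSE)
  }
  invisible(x)
}

check_positive <- function(x, name) {
  check_number(x, name)
  if (any(x <= 0)) {
    bad <- x[x <= 0][1L]
    stop(sprintf("`%s` must be > 0 (got %g)", name, bad), call. = FALSE)
  }
  invisible(x)
}

check_non_negative <- function(x, name) {
  check_number(x, name)
  if (any(x < 0)) {
    bad <- x[x < 0][1L]
    stop(sprintf("`%s` must be >= 0 (got %g)", name, bad), call. = FALSE)
  }
  invisible(x)
}

check_probability <- function(x, name) {
  check_number(x, name)
  if (any(x < 0 | x > 1)) {
    bad <- x[x < 0 | x > 1][1L]
    stop(sprintf("`%s` must lie in [0, 1] (got %g)", name, bad), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
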