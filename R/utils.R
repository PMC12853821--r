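# Internal helpers shared across modules.

# Round half away from zero (printed-proportion convention); base round()
# uses banker's rounding, which disagrees at e.g. 93.75.
round_half_up <- function(x, digits = 1) {
  f <- 10^digits
  # small eps guards binary representations of exact halves (e.g. 1875/2)
  sign(x) * floor(abs(x) * f + 0.5 + 1e-9) / f
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# argmax with deterministic lexicographic tie-break over names
which_max_lex <- function(scores, tol = 1e-12) {
  stopifnot(!is.null(names(scores)), length(scores) >= 1L)
  m <- max(scores)
  sort(names(scores)[scores >= m - tol])[1L]
}

stop_if_not_scalar_flag <- function(x, what) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be TRUE or FALSE", what), call. = FALSE)
  }
}
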