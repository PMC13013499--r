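#' Round half away from zero
#'
#' Commercial ("half-up") rounding to a given number of digits. Unlike
#' [base::round()], which rounds halves to even, `round_half_up(24.5)` is 25.
#' All displayed benefit-risk values in this package use this convention;
#' internal arithmetic is never rounded.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector of the same length as `x`.
#' @export
#' @examples
#' round_half_up(c(24.5, 45.71, -0.5))
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# internal: stop with a consistent error class so callers can test on it
bra_abort <- function(msg, class = "bramcda_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# internal: check a scalar is a single finite number
assert_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    bra_abort(sprintf("`%s` must be a single finite number", name))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
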