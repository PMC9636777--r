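#' Round half away from zero
#'
#' Reports in this field print percentages rounded half-up (5.25 -> 5.3),
#' unlike [base::round()]'s banker's rounding.
#'
#' @param x numeric vector
#' @param digits integer number of decimal places
#' @return numeric vector rounded half-up
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Percentage with report rounding
#'
#' @param n numerator count
#' @param d denominator count
#' @param digits decimal places (default 1, the printing convention)
#' @return `100 * n / d`, rounded half-up
#' @export
pct <- function(n, d, digits = 1) {
  stopifnot(d > 0)
  round_half_up(100 * n / d, digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_uticost <- function(...) stop(..., call. = FALSE)

assert_cols <- function(dt, cols, name = deparse(substitute(dt))) {
  miss <- setdiff(cols, names(dt))
  if (length(miss)) {
    stop_uticost(sprintf("table '%s' is missing columns: %s",
                         name, paste(miss, collapse = ", ")))
  }
  invisible(dt)
}

## probability map: named numeric, nonnegative, sums to 1 within 1e-9
check_prob_map <- function(p, what) {
  if (is.null(names(p)) || any(!nzchar(names(p)))) {
    stop_uticost(sprintf("%s must be a named probability vector", what))
  }
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    stop_uticost(sprintf("%s must be nonnegative and sum to 1 (got %.12f)",
                         what, sum(p)))
  }
  invisible(p)
}

check_prob <- function(p, what) {
  if (length(p) != 1 || is.na(p) || p < 0 || p > 1) {
    stop_uticost(sprintf("%s must be a probability in [0, 1]", what))
  }
  invisible(p)
}
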