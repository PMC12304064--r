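#' Round half away from zero
#'
#' Rounds to `digits` decimal places with ties going away from zero
#' (so 0.5 -> 1 and -0.5 -> -1), matching how clinical tables are
#' conventionally rounded. Base `round()` rounds half to even, which
#' would turn a limit of agreement of 42.4 - 29.4 = ... differently at
#' exact halves.
#'
#' @param x numeric vector.
#' @param digits integer number of decimal places (default 0).
#' @return numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_away(c(0.5, 1.5, -0.5, 2.4))
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stop() with the caller's frame so messages name the user-facing function
abort <- function(...) stop(..., call. = FALSE)

check_number <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number", name))
  }
  if (positive && x <= 0) abort(sprintf("`%s` must be > 0 (got %g)", name, x))
  if (nonneg && x < 0) abort(sprintf("`%s` must be >= 0 (got %g)", name, x))
  invisible(x)
}
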