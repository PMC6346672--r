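#' Round half away from zero
#'
#' Commercial rounding used for all reported counts and percentages
#' (base \code{round()} rounds half to even, which does not reproduce
#' published fishery tables).
#'
#' @param x numeric vector.
#' @return numeric vector rounded to the nearest integer, ties away from zero.
#' @export
round_half_up <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert_fraction <- function(x, name, open_left = FALSE, open_right = FALSE) {
  if (!is.numeric(x) || anyNA(x)) stop(name, " must be numeric and non-missing", call. = FALSE)
  lo_ok <- if (open_left) all(x > 0) else all(x >= 0)
  hi_ok <- if (open_right) all(x < 1) else all(x <= 1)
  if (!lo_ok || !hi_ok) stop(name, " must lie in the unit interval", call. = FALSE)
  invisible(x)
}

.set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}
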