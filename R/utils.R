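#' Round half away from zero
#'
#' Report tables print weights and performance to a fixed number of decimals
#' using the "round half up" convention (0.00005 -> 0.0001), unlike base
#' [round()], which rounds half to even.  Full precision is always retained
#' internally; this is applied only at serialization time.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half away from zero to `digits` decimals.
#' @export
#' @examples
#' round_half_up(0.04925, 4)  # 0.0493
#' round(0.04925, 4)          # 0.0492 (banker's rounding)
round_half_up <- function(x, digits = 4) {
  p <- 10^digits
  sign(x) * trunc(abs(x) * p + 0.5) / p
}

# fixed-width decimal formatting for report files
fmt_dec <- function(x, digits = 4) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

check_numeric <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop_input(what, " must be finite numeric values")
  }
  invisible(x)
}
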