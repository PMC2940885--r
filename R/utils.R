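#' Round half away from zero
#'
#' Fixed-rule decimal rounding used for report rendering. Base R's `round()`
#' rounds half to even; report columns (similarity percentages, coefficients of
#' variation) use the conventional half-up rule so printed values are
#' reproducible digit for digit.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(97.0297)       # 97.0
#' round_half_up(85.15, 1)      # 85.2
round_half_up <- function(x, digits = 1) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# format with a fixed number of decimals after half-up rounding
render_num <- function(x, digits = 1) {
  formatC(round_half_up(x, digits), format = "f", digits = digits)
}

# internal condition helpers: all package errors carry a class so callers and
# the CLI can dispatch on them
hs_stop <- function(class, msg, ...) {
  stop(structure(
    class = c(class, "habsim_error", "error", "condition"),
    list(message = sprintf(msg, ...), call = sys.call(-1))
  ))
}

hs_warn <- function(msg, ...) warning(sprintf(msg, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a
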