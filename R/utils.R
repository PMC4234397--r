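#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round half away from zero
#'
#' Commercial ("half-up") rounding, used only at the presentation layer:
#' internal state is kept at full precision and rounded when rendered.
#' `round()` in R rounds half to even, which does not reproduce published
#' percentage tables.
#'
#' @param x numeric vector.
#' @param digits number of decimal places (default 0).
#' @return `x` rounded half away from zero to `digits` places.
#' @examples
#' round_half_up(22.217, 1) # 22.2
#' round_half_up(2.5)      # 3, where round(2.5) gives 2
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  # tiny epsilon absorbs binary representation error in values such as 8.235
  # that are exactly representable halves in decimal but not in binary
  sign(x) * floor(abs(x) * scale + 0.5 + 1e-9) / scale
}

# validation helpers: every user-facing constructor funnels through these so
# error messages always name the offending field
check_fraction <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x > 1)) {
    stop(sprintf("'%s' must be a fraction in [0, 1], got %s",
                 field, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  as.numeric(x)
}

check_nonneg <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop(sprintf("'%s' must be non-negative, got %s",
                 field, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  as.numeric(x)
}

check_positive <- function(x, field) {
  if (!is.numeric(x) || anyNA(x) || any(x <= 0)) {
    stop(sprintf("'%s' must be positive, got %s",
                 field, paste(format(x), collapse = ", ")), call. = FALSE)
  }
  as.numeric(x)
}

check_string <- function(x, field) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop(sprintf("'%s' must be a non-empty string", field), call. = FALSE)
  }
  x
}
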