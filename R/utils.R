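#' Round half away from zero
#'
#' Reported scores use commercial ("half-up") rounding rather than the IEEE
#' round-half-even rule, so that e.g. 22.625 prints as 22.63.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @keywords internal
round_half_up <- function(x, digits = 2) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5 + sqrt(.Machine$double.eps)) / scale
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_r2p <- function(..., class) {
  stop(errorCondition(paste0(...), class = c(class, "r2play_error")))
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)
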