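#' Round half away from zero
#'
#' Conventional "half-up" rounding as used when reporting measured or
#' derived chemical quantities, where 0.5 always rounds away from zero.
#' Base R's [round()] and [signif()] round half to even, which disagrees
#' with reported values exactly at the midpoint.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (`round_half_up`) or significant
#'   figures (`signif_half_up`).
#' @return Rounded numeric vector.
#' @examples
#' round_half_up(2.5)       # 3, where round(2.5) is 2
#' signif_half_up(3.85e-5, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + sqrt(.Machine$double.eps)) / p
}

#' @rdname round_half_up
#' @export
signif_half_up <- function(x, digits = 1) {
  out <- x
  nz <- is.finite(x) & x != 0
  e <- floor(log10(abs(x[nz])))
  out[nz] <- round_half_up(x[nz] / 10^e, digits - 1) * 10^e
  out
}

# stop() with call.=FALSE, classed for testing
.np_abort <- function(msg, class = "nanoprecip_error") {
  rlang::abort(msg, class = class)
}

.assert_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    .np_abort(sprintf("`%s` must be a single finite number.", name),
              class = "nanoprecip_input_error")
  }
  if (positive && x <= 0) {
    .np_abort(sprintf("`%s` must be > 0.", name),
              class = "nanoprecip_input_error")
  }
  invisible(x)
}
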