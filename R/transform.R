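#' Log-adjust a testosterone concentration
#'
#' The modelling scale for total testosterone (TT) is `log10(tt + 1)`. The
#' unit offset makes the transform defined at zero and maps a zero
#' concentration to a zero log-adjusted value, so the conception anchor
#' (TT = 0) stays at the origin on both scales. Working in log space
#' stabilises the variance, which grows with the hormone level.
#'
#' @param tt Numeric vector of TT concentrations in nmol/L; must be >= 0.
#' @return Numeric vector of log-adjusted values.
#' @seealso [inv_log_adjust()]
#' @export
#' @examples
#' log_adjust(c(0, 9))    # 0 and 1
log_adjust <- function(tt) {
  if (any(!is.finite(tt) | tt < 0)) {
    stop("log_adjust() requires finite non-negative concentrations")
  }
  log10(tt + 1)
}

#' Invert the log-adjustment
#'
#' @param y Numeric vector of log-adjusted values.
#' @return TT concentrations in nmol/L (`10^y - 1`).
#' @export
#' @examples
#' inv_log_adjust(log_adjust(13))   # 13
inv_log_adjust <- function(y) {
  10^y - 1
}
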