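# Internal helpers shared across modules.

# Round half away from zero (reproducible across float dialects, unlike
# base round()'s round-half-even).
round_hu <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

#' Apply CT rescale calibration and the lower HU clip
#'
#' Converts stored CT values to Hounsfield units via the affine rescale
#' (`value * slope + intercept`) and clips the result at the universal
#' lower bound of -1024 HU. Clipping is idempotent.
#'
#' @param values numeric vector or array of stored values.
#' @param slope,intercept rescale slope and intercept (defaults 1, 0).
#' @return numeric of the same shape, in HU, with no value below -1024.
#' @examples
#' hu_calibrate(0, slope = 1, intercept = -1024)  # -1024
#' hu_calibrate(-2000)                            # clipped to -1024
#' @export
hu_calibrate <- function(values, slope = 1, intercept = 0) {
  pmax(values * slope + intercept, -1024)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
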