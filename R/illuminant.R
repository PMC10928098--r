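#' Planckian-locus RGB approximation for a colour temperature
#'
#' Standard piecewise blackbody approximation mapping a correlated colour
#' temperature in Kelvin to an RGB direction, normalized to unit maximum.
#' Used both for the scene light and for the camera's white-balance
#' reference.
#'
#' @param kelvin Colour temperature, 1000-15000 K.
#' @return Numeric length-3 RGB vector with `max == 1`.
#' @examples
#' planckian_rgb(2000)  # warm: red-heavy
#' planckian_rgb(8000)  # cool: blue-heavy
#' @export
planckian_rgb <- function(kelvin) {
  stopifnot(is.finite(kelvin), kelvin >= 1000, kelvin <= 15000)
  t <- kelvin / 100
  r <- if (t <= 66) 255 else 329.698727446 * (t - 60)^-0.1332047592
  g <- if (t <= 66) 99.4708025861 * log(t) - 161.1195681661 else
    288.1221695283 * (t - 60)^-0.0755148492
  b <- if (t >= 66) 255 else if (t <= 19) 0 else
    138.5177312231 * log(t - 10) - 305.0447927307
  v <- pmin(pmax(c(r, g, b), 0), 255)
  v / max(v)
}

#' Residual colour cast of a camera white-balance mismatch
#'
#' A camera set to white-balance temperature `wb_k` divides the sensor
#' response by the Planckian RGB of that temperature; under a scene light
#' of `illuminant_k` the rendered image therefore carries the residual
#' per-channel tint `planckian_rgb(illuminant_k) / planckian_rgb(wb_k)`.
#' The tint is returned blue-referenced (blue component forced to 1), the
#' exposure convention used throughout the renderer so that blue-channel
#' calibration is invariant to the WB setting.
#'
#' @param illuminant_k Scene light colour temperature (K).
#' @param wb_k Camera white-balance setting (K).
#' @return Length-3 tint vector with `[3] == 1`.
#' @examples
#' camera_tint(5600, 5600)  # matched: c(1, 1, 1)
#' camera_tint(5600, 3000)  # camera expects warm light: blue cast
#' @export
camera_tint <- function(illuminant_k, wb_k) {
  t <- planckian_rgb(illuminant_k) / planckian_rgb(wb_k)
  if (!all(is.finite(t)))
    stop("degenerate illuminant at the requested temperatures")
  t / t[3]
}
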