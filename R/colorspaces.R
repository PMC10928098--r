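# Colour-space conversions used for feature extraction. All functions are
# vectorized over equal-length numeric vectors of 8-bit device values
# (0-255). CMYK/HSV/YCbCr operate directly on device values; CIELAB and
# CIELUV linearize through the sRGB EOTF and use the D65 white point.

check_rgb <- function(r, g, b) {
  if (length(r) != length(g) || length(g) != length(b))
    stop("r, g, b must have equal length")
  if (any(c(r, g, b) < 0 | c(r, g, b) > 255))
    stop("channel values must lie in [0, 255]")
}

#' RGB to CMY(K)
#'
#' Subtractive representation: `C' = 1 - R/255` (and likewise M', Y'),
#' `K = min(C', M', Y')`, chromatic components renormalized by `1 - K`.
#' Pure black (K = 1) yields C = M = Y = 0 by convention.
#'
#' @param r,g,b Numeric vectors of 8-bit channel values.
#' @return Data.frame with columns `c`, `m`, `y`, `k` in `[0, 1]`.
#' @examples
#' rgb_to_cmyk(255, 255, 0)  # pure yellow: y = 1
#' @export
rgb_to_cmyk <- function(r, g, b) {
  check_rgb(r, g, b)
  cp <- 1 - r / 255; mp <- 1 - g / 255; yp <- 1 - b / 255
  k <- pmin(cp, mp, yp)
  d <- 1 - k
  safe <- function(x) ifelse(d > 0, (x - k) / ifelse(d > 0, d, 1), 0)
  data.frame(c = safe(cp), m = safe(mp), y = safe(yp), k = k)
}

#' CMY(K) back to RGB
#'
#' Exact inverse of [rgb_to_cmyk()] for 8-bit inputs.
#'
#' @param c,m,y,k Numeric vectors in `[0, 1]`.
#' @return Data.frame with columns `r`, `g`, `b`.
#' @export
cmyk_to_rgb <- function(c, m, y, k) {
  data.frame(r = 255 * (1 - (c * (1 - k) + k)),
             g = 255 * (1 - (m * (1 - k) + k)),
             b = 255 * (1 - (y * (1 - k) + k)))
}

#' RGB to HSV
#'
#' Hue by the max-channel sector formulas (0 degrees when max = min),
#' saturation `1 - min/max` (0 when max = 0) and value `V = max` on the
#' 8-bit scale.
#'
#' @inheritParams rgb_to_cmyk
#' @return Data.frame with `h` in degrees `[0, 360)`, `s` in `[0, 1]`,
#'   `v` in `[0, 255]`.
#' @export
rgb_to_hsv <- function(r, g, b) {
  check_rgb(r, g, b)
  mx <- pmax(r, g, b); mn <- pmin(r, g, b)
  d <- mx - mn
  h <- numeric(length(r))
  i <- d > 0 & mx == r & g >= b
  h[i] <- 60 * (g[i] - b[i]) / d[i]
  i <- d > 0 & mx == r & g < b
  h[i] <- 60 * (g[i] - b[i]) / d[i] + 360
  i <- d > 0 & mx == g & mx != r
  h[i] <- 60 * (b[i] - r[i]) / d[i] + 120
  i <- d > 0 & mx == b & mx != r & mx != g
  h[i] <- 60 * (r[i] - g[i]) / d[i] + 240
  s <- ifelse(mx > 0, 1 - mn / ifelse(mx > 0, mx, 1), 0)
  data.frame(h = h, s = s, v = mx)
}

#' HSV back to RGB
#'
#' Inverse of [rgb_to_hsv()].
#'
#' @param h Hue in degrees `[0, 360)`.
#' @param s Saturation in `[0, 1]`.
#' @param v Value in `[0, 255]`.
#' @return Data.frame with columns `r`, `g`, `b`.
#' @export
hsv_to_rgb <- function(h, s, v) {
  hh <- (h %% 360) / 60
  i <- floor(hh)
  f <- hh - i
  p <- v * (1 - s)
  q <- v * (1 - s * f)
  t <- v * (1 - s * (1 - f))
  r <- g <- b <- numeric(length(h))
  for (sector in 0:5) {
    sel <- i == sector
    if (!any(sel)) next
    vals <- switch(as.character(sector),
                   "0" = list(v, t, p), "1" = list(q, v, p),
                   "2" = list(p, v, t), "3" = list(p, q, v),
                   "4" = list(t, p, v), "5" = list(v, p, q))
    r[sel] <- vals[[1]][sel]; g[sel] <- vals[[2]][sel]
    b[sel] <- vals[[3]][sel]
  }
  data.frame(r = r, g = g, b = b)
}

# sRGB (8-bit) -> CIEXYZ, D65 white, Y normalized to 1
srgb_to_xyz <- function(r, g, b) {
  lin <- function(v) {
    u <- v / 255
    ifelse(u <= 0.04045, u / 12.92, ((u + 0.055) / 1.055)^2.4)
  }
  rl <- lin(r); gl <- lin(g); bl <- lin(b)
  cbind(x = 0.4124564 * rl + 0.3575761 * gl + 0.1804375 * bl,
        y = 0.2126729 * rl + 0.7151522 * gl + 0.0721750 * bl,
        z = 0.0193339 * rl + 0.1191920 * gl + 0.9503041 * bl)
}

d65_white <- c(x = 0.4124564 + 0.3575761 + 0.1804375,
               y = 0.2126729 + 0.7151522 + 0.0721750,
               z = 0.0193339 + 0.1191920 + 0.9503041)

lab_f <- function(t) {
  d <- 6 / 29
  ifelse(t > d^3, t^(1 / 3), t / (3 * d^2) + 4 / 29)
}

#' RGB to CIELAB
#'
#' Forward transform sRGB -> XYZ (D65) -> L*a*b*.
#'
#' @inheritParams rgb_to_cmyk
#' @return Data.frame with `l` in `[0, 100]`, `a`, `b`.
#' @export
rgb_to_lab <- function(r, g, b) {
  check_rgb(r, g, b)
  xyz <- srgb_to_xyz(r, g, b)
  fx <- lab_f(xyz[, "x"] / d65_white["x"])
  fy <- lab_f(xyz[, "y"] / d65_white["y"])
  fz <- lab_f(xyz[, "z"] / d65_white["z"])
  data.frame(l = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

#' Chroma, hue angle and colour difference from CIELAB components
#'
#' `C* = sqrt(a*^2 + b*^2)`, hue `h = atan2(b*, a*)` in degrees
#' `[0, 360)`, and the composite difference
#' `dE*ab = sqrt(dL*^2 + da*^2 + db*^2)` when deltas are supplied.
#'
#' @param a,b CIELAB chromatic components.
#' @param dl,da,db Optional component differences for `delta_e`.
#' @return Data.frame with `chroma`, `hue` and (when deltas are given)
#'   `delta_e`.
#' @export
lab_derived <- function(a, b, dl = NULL, da = NULL, db = NULL) {
  out <- data.frame(chroma = sqrt(a^2 + b^2),
                    hue = (atan2(b, a) * 180 / pi) %% 360)
  if (!is.null(dl)) out$delta_e <- sqrt(dl^2 + da^2 + db^2)
  out
}

#' RGB to YCbCr (digital, 8-bit offsets)
#'
#' Luma/chroma transform with coefficients 0.299/0.587/0.114 and digital
#' scaling `Y = 219 Y' + 16`, `Cb = 224 Pb + 128`, `Cr = 224 Pr + 128`.
#'
#' @inheritParams rgb_to_cmyk
#' @return Data.frame with `y` in `[16, 235]`, `cb`, `cr` in `[16, 240]`.
#' @export
rgb_to_ycbcr <- function(r, g, b) {
  check_rgb(r, g, b)
  rp <- r / 255; gp <- g / 255; bp <- b / 255
  yp <- 0.299 * rp + 0.587 * gp + 0.114 * bp
  pb <- -0.1687 * rp - 0.3313 * gp + 0.500 * bp
  pr <- 0.500 * rp - 0.4187 * gp - 0.0813 * bp
  data.frame(y = 219 * yp + 16, cb = 224 * pb + 128, cr = 224 * pr + 128)
}

#' RGB to CIELUV
#'
#' Two-branch lightness formula with D65 white, and
#' `u* = 13 L* (u' - u'n)`, `v* = 13 L* (v' - v'n)` with chromaticities
#' `u' = 4X / (X + 15Y + 3Z)`, `v' = 9Y / (X + 15Y + 3Z)`. Black maps to
#' `L* = u* = v* = 0`.
#'
#' @inheritParams rgb_to_cmyk
#' @return Data.frame with `l`, `u`, `v`.
#' @export
rgb_to_luv <- function(r, g, b) {
  check_rgb(r, g, b)
  xyz <- srgb_to_xyz(r, g, b)
  yr <- xyz[, "y"] / d65_white["y"]
  l <- ifelse(yr <= (6 / 29)^3, (29 / 3)^3 * yr, 116 * yr^(1 / 3) - 16)
  den <- xyz[, "x"] + 15 * xyz[, "y"] + 3 * xyz[, "z"]
  up <- ifelse(den > 0, 4 * xyz[, "x"] / ifelse(den > 0, den, 1), 0)
  vp <- ifelse(den > 0, 9 * xyz[, "y"] / ifelse(den > 0, den, 1), 0)
  dn <- d65_white["x"] + 15 * d65_white["y"] + 3 * d65_white["z"]
  upn <- 4 * d65_white["x"] / dn
  vpn <- 9 * d65_white["y"] / dn
  data.frame(l = unname(l),
             u = unname(ifelse(den > 0, 13 * l * (up - upn), 0)),
             v = unname(ifelse(den > 0, 13 * l * (vp - vpn), 0)))
}
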