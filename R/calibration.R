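#' Calibration table for the synthetic phantom renderer
#'
#' Bundles the printed channel-versus-concentration relationships that the
#' renderer reproduces in expectation: for every one-at-a-time study factor
#' and level, the blue-channel sensitivity (pixel value per mg/dl of
#' bilirubin in the 50x50 px bilirubin ROI) and the coefficient of
#' determination that the linear fit of ROI mean against concentration
#' attains, plus per-channel baseline intercepts and the relative
#' green/red channel sensitivities.
#'
#' The baseline condition (2 mm phantom, TiO2 ratio 0.01, camera WB 5000 K
#' under a 5600 K light, ISO 500, moderate intensity, white tone) carries
#' slope -1.995 and R^2 0.958. Distance is a deliberate null factor: all
#' its levels reuse the baseline relationship.
#'
#' @param concentrations Bilirubin design points in mg/dl used to calibrate
#'   the noise level (population variance of these points enters the R^2
#'   closed form). Default: DI-water control plus the six prepared
#'   dilutions.
#' @param intercepts Named numeric vector, expected ROI pixel value of the
#'   bilirubin-free phantom at the baseline exposure, per channel.
#' @param background Scalar, expected pixel value of the white-paper
#'   background at baseline exposure (neutral).
#' @param channel_ratio Green and red sensitivities relative to blue
#'   (absorbance slopes 0.017/0.198 and 0.002/0.198).
#' @param sigma_px Per-pixel read-noise standard deviation (pixel values).
#' @return An object of class `phantom_calibration`: a list with the
#'   factor-level table (`table`), baseline row (`baseline`), intercepts,
#'   background level, channel ratios, design concentrations, exposure
#'   multipliers for ISO/intensity/tone, and `sigma_px`.
#' @examples
#' calib <- phantom_calibration()
#' subset(calib$table, study == "thickness")
#' @export
phantom_calibration <- function(concentrations = c(0, 10, 12, 14, 16, 18, 20),
                                intercepts = c(r = 180, g = 184, b = 190),
                                background = 195,
                                channel_ratio = c(g = 0.017 / 0.198,
                                                  r = 0.002 / 0.198),
                                sigma_px = 2) {
  tab <- data.frame(
    study = c("baseline",
              rep("thickness", 3), rep("tio2_ratio", 3), rep("wb", 3),
              rep("iso", 3), rep("intensity", 3), rep("tone", 3),
              rep("distance", 3)),
    level = c("baseline",
              "1", "2", "3",
              "0.01", "0.015", "0.02",
              "2000", "5000", "8000",
              "100", "500", "1000",
              "low", "moderate", "high",
              "white", "off-white", "yellow",
              "1", "2", "3"),
    slope = c(-1.995,
              -2.775, -2.630, -2.033,
              -2.630, -2.359, -1.065,
              -0.425, -1.940, -2.097,
              -1.944, -2.630, -2.022,
              -3.678, -2.531, -1.793,
              -2.106, -1.953, -2.000,
              -1.995, -1.995, -1.995),
    r2 = c(0.958,
           0.722, 0.921, 0.972,
           0.921, 0.936, 0.482,
           0.774, 0.963, 0.848,
           0.898, 0.921, 0.868,
           0.717, 0.934, 0.942,
           0.894, 0.860, 0.878,
           0.958, 0.958, 0.958),
    stringsAsFactors = FALSE
  )
  stopifnot(all(tab$r2 > 0 & tab$r2 < 1), length(intercepts) == 3)
  structure(list(
    table = tab,
    baseline = tab[tab$study == "baseline", ],
    intercepts = intercepts,
    background = background,
    channel_ratio = channel_ratio,
    concentrations = concentrations,
    # multiplicative exposure model: ISO gain (unity at ISO 500),
    # illuminance scale per intensity level, per-channel tone tint
    # (blue-referenced; warmer tones carry less blue light)
    iso_gain = function(iso) (iso / 500)^0.25,
    intensity_scale = c(low = 0.85, moderate = 1, high = 1.08),
    tone_tint = list(white = c(1, 1, 1),
                     `off-white` = c(1, 0.985, 0.94),
                     yellow = c(1, 0.97, 0.85)),
    sigma_px = sigma_px
  ), class = "phantom_calibration")
}

#' @export
print.phantom_calibration <- function(x, ...) {
  cat("Phantom calibration:", nrow(x$table), "study/level entries\n")
  cat("  baseline blue slope", x$baseline$slope, "px per mg/dl, R^2",
      x$baseline$r2, "\n")
  cat("  channel sensitivity ratios g =", signif(x$channel_ratio[["g"]], 3),
      ", r =", signif(x$channel_ratio[["r"]], 3), "(relative to blue)\n")
  invisible(x)
}

#' Noise level that makes a linear fit attain a target R-squared
#'
#' Closed form for the standard deviation of additive Gaussian noise on the
#' ROI mean such that ordinary least squares of ROI mean against
#' concentration has expected coefficient of determination `r2_target`:
#' `sigma^2 = slope^2 * Var(c) * (1 - R^2) / R^2`, with `Var(c)` the
#' population variance of the design points.
#'
#' @param slope True sensitivity, pixel value per mg/dl.
#' @param concentrations Design points (each assumed equally replicated).
#' @param r2_target Target coefficient of determination in (0, 1).
#' @return Noise standard deviation in pixel-value units.
#' @examples
#' noise_sigma_for_r2(-1.995, c(0, 10, 12, 14, 16, 18, 20), 0.958)
#' @export
noise_sigma_for_r2 <- function(slope, concentrations, r2_target) {
  if (!is.finite(r2_target) || r2_target <= 0 || r2_target >= 1)
    stop("r2_target must lie strictly between 0 and 1")
  if (length(unique(concentrations)) < 2)
    stop("need at least two distinct concentration levels")
  if (!is.finite(slope) || slope == 0)
    stop("slope of zero cannot attain a positive r2_target")
  v <- mean(concentrations^2) - mean(concentrations)^2
  abs(slope) * sqrt(v * (1 - r2_target) / r2_target)
}

# Resolve (slope, r2) for a condition from the calibration table.
# A condition tagged with a study uses that study's level entry; otherwise
# the single off-baseline factor is detected, and multi-factor conditions
# compose slopes multiplicatively relative to each factor's baseline level
# (r2 taken as the minimum over the involved studies).
calibration_lookup <- function(calib, condition) {
  tab <- calib$table
  fetch <- function(study, level) {
    row <- tab[tab$study == study & tab$level == as.character(level), ]
    if (nrow(row) == 1) return(row)
    # numeric factors (WB temperature, ISO) are continuous settings:
    # interpolate slope and r2 linearly between tabulated levels
    sub <- tab[tab$study == study, ]
    lv <- suppressWarnings(as.numeric(sub$level))
    lev_n <- suppressWarnings(as.numeric(level))
    if (nrow(sub) == 0 || any(is.na(lv)) || is.na(lev_n) ||
        lev_n < min(lv) || lev_n > max(lv))
      stop("no calibration entry for ", study, " = ", level)
    data.frame(study = study, level = as.character(level),
               slope = stats::approx(lv, sub$slope, lev_n)$y,
               r2 = stats::approx(lv, sub$r2, lev_n)$y,
               stringsAsFactors = FALSE)
  }
  study <- condition$study
  if (!is.null(study) && !is.na(study) && study != "auto") {
    lev <- if (study == "baseline") "baseline" else
      as.character(condition[[study_field(study)]])
    if (study == "baseline") return(calib$baseline)
    return(fetch(study, lev))
  }
  base <- list(thickness = "2", tio2_ratio = "0.01", wb = "5000",
               iso = "500", intensity = "moderate", tone = "white")
  off <- character(0)
  for (st in names(base)) {
    lev <- as.character(condition[[study_field(st)]])
    if (lev != base[[st]]) off <- c(off, st)
  }
  if (length(off) == 0) return(calib$baseline)
  if (length(off) == 1)
    return(fetch(off, condition[[study_field(off)]]))
  slope <- calib$baseline$slope
  r2 <- calib$baseline$r2
  for (st in off) {
    row <- fetch(st, condition[[study_field(st)]])
    ref <- fetch(st, base[[st]])
    slope <- slope * row$slope / ref$slope
    r2 <- min(r2, row$r2)
  }
  data.frame(study = paste(off, collapse = "+"), level = "composed",
             slope = slope, r2 = r2, stringsAsFactors = FALSE)
}

# map a study name to the SceneCondition field that carries its level
study_field <- function(study) {
  switch(study,
         thickness = "thickness", tio2_ratio = "tio2_ratio",
         wb = "wb_k", iso = "iso", intensity = "intensity",
         tone = "tone", distance = "distance",
         stop("unknown study: ", study))
}
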