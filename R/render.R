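roi_layout <- function(h, w) {
  if (w < 140 || h < 50)
    stop("image must be at least 140x50 px to hold two 50x50 ROIs")
  y <- (h - 50L) %/% 2L
  xa <- floor(w * 0.19)
  xb <- xa + 50L + floor(w * 0.09375)
  if (xb + 50L > w) stop("image too narrow for disjoint ROIs")
  list(roi_a = c(x = xa, y = y, w = 50L, h = 50L),
       roi_b = c(x = xb, y = y, w = 50L, h = 50L))
}

#' Noise-free expectation of a rendered scene
#'
#' Returns the per-channel expected pixel values of the bilirubin ROI (A),
#' the bilirubin-free phantom ROI (B) and the paper background for a
#' condition, together with the blue-channel slope, the scene noise level
#' and the camera tint used by [render_phantom()].
#'
#' @param condition A [scene_condition()] (or design row).
#' @param calib A [phantom_calibration()].
#' @return List with elements `roi_a`, `roi_b`, `background` (length-3 RGB
#'   expectations before quantization), `slope`, `r2`, `sigma_scene`,
#'   `tint`, `saturated`.
#' @export
phantom_expectation <- function(condition, calib = phantom_calibration()) {
  condition <- as_scene_condition(condition)
  cal <- calibration_lookup(calib, condition)
  slope_b <- cal$slope
  slopes <- c(slope_b * calib$channel_ratio[["r"]],
              slope_b * calib$channel_ratio[["g"]],
              slope_b)
  gain <- calib$iso_gain(condition$iso) *
    calib$intensity_scale[[condition$intensity]]
  tone <- calib$tone_tint[[condition$tone]]
  tint <- camera_tint(condition$illuminant_k, condition$wb_k)
  base <- gain * tone * calib$intercepts[c("r", "g", "b")]
  bg <- tint * gain * tone * calib$background
  roi_b <- tint * base
  roi_a <- roi_b + tint * slopes * condition$concentration
  sat <- any(c(roi_a, roi_b, bg) < 0 | c(roi_a, roi_b, bg) > 255)
  list(roi_a = unname(roi_a), roi_b = unname(roi_b),
       background = unname(bg), slope = slope_b, r2 = cal$r2,
       sigma_scene = noise_sigma_for_r2(slope_b, calib$concentrations,
                                        cal$r2),
       tint = tint, saturated = sat)
}

#' Render a synthetic PDMS-TiO2 phantom image
#'
#' Draws an 8-bit RGB scene: white-paper background, a 50x50 px
#' bilirubin-containing ROI (A) whose expected blue mean declines linearly
#' with concentration at the calibrated slope, and a 50x50 px
#' bilirubin-free phantom ROI (B). ISO acts as a multiplicative gain,
#' light intensity as an illuminance scale, illumination tone and the
#' scene-vs-WB temperature mismatch tint the channels via a
#' Planckian-locus model (blue-referenced). Noise has two parts: a
#' scene-level Gaussian offset per channel whose standard deviation is
#' calibrated so an OLS fit of ROI-A mean against concentration attains
#' the condition's printed R-squared, and i.i.d. per-pixel read noise.
#' Both are pinned by `replicate_seed`, and the realization depends only
#' on the scene (not the WB setting), so renders of the same seed at two
#' WB settings are captures of the same physical scene.
#'
#' @param condition A [scene_condition()] or design row.
#' @param calib A [phantom_calibration()].
#' @param size Image height and width in px, `c(h, w)`.
#' @param roi_only If `TRUE`, only the two ROI patches are materialized
#'   (fast path for feature/sensitivity simulation); the background is
#'   skipped and `pixels` is `NULL`.
#' @param noise Include the stochastic components (`FALSE` renders the
#'   noiseless expectation).
#' @param quantize Round to integer 8-bit values (`FALSE` keeps real
#'   values; useful for exactness checks).
#' @return Object of class `phantom_image`: `pixels` (h x w x 3 array in
#'   0-255, RGB), `roi_a_px`/`roi_b_px` (50 x 50 x 3 patches), `roi_a`/
#'   `roi_b` rectangles (x, y, w, h; 0-based, half-open),
#'   `truth_illuminant` (unit-norm residual cast), `condition`,
#'   `saturated` flag and the calibration row used.
#' @examples
#' img <- render_phantom(scene_condition(20, replicate_seed = 7))
#' range(img$pixels)
#' @export
render_phantom <- function(condition, calib = phantom_calibration(),
                           size = c(100, 160), roi_only = FALSE,
                           noise = TRUE, quantize = TRUE) {
  condition <- as_scene_condition(condition)
  h <- as.integer(size[1]); w <- as.integer(size[2])
  lay <- roi_layout(h, w)
  exp_ <- phantom_expectation(condition, calib)
  sigma_scene <- if (noise) exp_$sigma_scene else 0
  sigma_px <- if (noise) calib$sigma_px else 0
  tint <- exp_$tint

  n_roi <- 50L * 50L
  set.seed(condition$replicate_seed)
  z_scene <- rnorm(3)
  za <- matrix(rnorm(n_roi * 3), n_roi, 3)
  zb <- matrix(rnorm(n_roi * 3), n_roi, 3)

  # scene-referred values; camera tint multiplies everything so that a
  # WB change re-renders the identical scene under another cast
  patch <- function(expect, z) {
    v <- t(tint * (t(matrix(expect, n_roi, 3, byrow = TRUE)) +
                     sigma_scene * z_scene) + t(sigma_px * z))
    v <- pmin(pmax(v, 0), 255)
    if (quantize) v <- round(v)
    array(v, dim = c(50L, 50L, 3L))
  }
  # undo the outer tint on expectations already tinted in phantom_expectation
  roi_a_px <- patch(exp_$roi_a / tint, za)
  roi_b_px <- patch(exp_$roi_b / tint, zb)

  pixels <- NULL
  if (!roi_only) {
    n_bg <- h * w - 2L * n_roi
    zg <- matrix(rnorm(n_bg * 3), n_bg, 3)
    bgv <- t(tint * (exp_$background / tint + sigma_scene * z_scene) +
               t(sigma_px * zg))
    bgv <- pmin(pmax(bgv, 0), 255)
    if (quantize) bgv <- round(bgv)
    pixels <- array(0, dim = c(h, w, 3L))
    mask <- matrix(TRUE, h, w)
    put <- function(px, rect) {
      rows <- (rect["y"] + 1L):(rect["y"] + rect["h"])
      cols <- (rect["x"] + 1L):(rect["x"] + rect["w"])
      for (k in 1:3) pixels[rows, cols, k] <<- matrix(px[, , k], 50L, 50L)
      mask[rows, cols] <<- FALSE
    }
    put(roi_a_px, lay$roi_a)
    put(roi_b_px, lay$roi_b)
    for (k in 1:3) {
      plane <- pixels[, , k]
      plane[mask] <- bgv[, k]
      pixels[, , k] <- plane
    }
  }
  structure(list(pixels = pixels, roi_a_px = roi_a_px, roi_b_px = roi_b_px,
                 roi_a = lay$roi_a, roi_b = lay$roi_b,
                 truth_illuminant = tint / sqrt(sum(tint^2)),
                 condition = condition, saturated = exp_$saturated,
                 slope = exp_$slope, sigma_scene = exp_$sigma_scene,
                 quantized = quantize),
            class = "phantom_image")
}

#' @export
print.phantom_image <- function(x, ...) {
  dims <- if (is.null(x$pixels)) "ROI-only" else
    paste(dim(x$pixels)[1:2], collapse = "x")
  cat(sprintf("Phantom image (%s), %g mg/dl, blue slope %.3f%s\n",
              dims, x$condition$concentration, x$slope,
              if (x$saturated) " [saturated]" else ""))
  invisible(x)
}

#' Write a rendered dataset to disk
#'
#' Renders every design row as an 8-bit RGB PNG and writes a CSV manifest
#' with the condition, ROI rectangles (`x,y,w,h`, 0-based) and saturation
#' flag per image.
#'
#' @param design Data.frame of scene conditions, e.g. [phantom_design()].
#' @param calib A [phantom_calibration()].
#' @param out_dir Output directory (created if missing).
#' @param size Image size `c(h, w)`.
#' @return The manifest data.frame (also written to
#'   `file.path(out_dir, "manifest.csv")`), invisibly.
#' @export
generate_phantom_dataset <- function(design, calib = phantom_calibration(),
                                     out_dir, size = c(100, 160)) {
  if (nrow(design) == 0) stop("empty design")
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    img <- render_phantom(design[i, ], calib, size = size)
    path <- file.path(out_dir, sprintf("phantom_%05d.png", i))
    png::writePNG(img$pixels / 255, path)
    cnd <- img$condition
    rows[[i]] <- data.frame(
      image_path = path, concentration_mg_dl = cnd$concentration,
      thickness_mm = cnd$thickness, tio2_ratio = cnd$tio2_ratio,
      wb_K = cnd$wb_k, illuminant_K = cnd$illuminant_k, iso = cnd$iso,
      intensity = cnd$intensity, tone = cnd$tone, distance = cnd$distance,
      seed = cnd$replicate_seed, study = cnd$study,
      roi_a = paste(img$roi_a, collapse = ","),
      roi_b = paste(img$roi_b, collapse = ","),
      saturated = img$saturated, stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}
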