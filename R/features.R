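# the fixed, versioned feature header: 11 colour features then 6
# parameter features; `concentration` is the label column
FEATURE_COLS <- c("roi_r", "roi_g", "roi_b", "roi_s", "roi_a_star",
                  "roi_b_star", "roi_u_star", "roi_v_star",
                  "d_r", "d_g", "d_b",
                  "thickness_mm", "tio2_ratio", "wb_k", "iso",
                  "intensity_code", "tone_code")
COLOUR_FEATURES <- FEATURE_COLS[1:11]
PARAM_FEATURES <- FEATURE_COLS[12:17]
REDUCED_COLS <- c("roi_r", "roi_g", "roi_b", "d_r", "d_g", "d_b")

intensity_code <- c(low = 1, moderate = 2, high = 3)
tone_code <- c(white = 1, `off-white` = 2, yellow = 3)

roi_patch <- function(image, roi) {
  if (inherits(image, "phantom_image")) {
    if (identical(unname(roi), unname(image$roi_a))) return(image$roi_a_px)
    if (identical(unname(roi), unname(image$roi_b))) return(image$roi_b_px)
    px <- image$pixels
    if (is.null(px))
      stop("ROI-only image: only its own ROI rectangles are available")
  } else px <- as_pixel_array(image)
  if (roi["w"] < 50 || roi["h"] < 50)
    stop("ROI must be at least 50x50 px")
  if (roi["x"] < 0 || roi["y"] < 0 ||
      roi["x"] + roi["w"] > dim(px)[2] || roi["y"] + roi["h"] > dim(px)[1])
    stop("ROI outside image bounds")
  px[(roi["y"] + 1):(roi["y"] + roi["h"]),
     (roi["x"] + 1):(roi["x"] + roi["w"]), , drop = FALSE]
}

#' Mean channel values over a region of interest
#'
#' Arithmetic mean of each RGB channel over a rectangular ROI (`x, y, w,
#' h`; 0-based, half-open), the quantity regressed against concentration
#' throughout the sensitivity analysis.
#'
#' @param image A `phantom_image` or h x w x 3 array.
#' @param roi ROI rectangle; defaults to the image's bilirubin ROI.
#' @return Named numeric vector `c(r, g, b)`.
#' @export
extract_roi_means <- function(image, roi = image$roi_a) {
  p <- roi_patch(image, roi)
  c(r = mean(p[, , 1]), g = mean(p[, , 2]), b = mean(p[, , 3]))
}

# the 8 colour-space means of one ROI patch (per-pixel conversion, then
# spatial mean)
roi_colour_means <- function(patch) {
  r <- c(patch[, , 1]); g <- c(patch[, , 2]); b <- c(patch[, , 3])
  hsv <- rgb_to_hsv(r, g, b)
  lab <- rgb_to_lab(r, g, b)
  luv <- rgb_to_luv(r, g, b)
  c(roi_r = mean(r), roi_g = mean(g), roi_b = mean(b),
    roi_s = mean(hsv$s), roi_a_star = mean(lab$a),
    roi_b_star = mean(lab$b), roi_u_star = mean(luv$u),
    roi_v_star = mean(luv$v))
}

feature_row <- function(image) {
  cnd <- image$condition
  cf <- roi_colour_means(image$roi_a_px)
  mb <- c(mean(image$roi_b_px[, , 1]), mean(image$roi_b_px[, , 2]),
          mean(image$roi_b_px[, , 3]))
  as.data.frame(as.list(c(
    cf,
    d_r = cf[["roi_r"]] - mb[1], d_g = cf[["roi_g"]] - mb[2],
    d_b = cf[["roi_b"]] - mb[3],
    thickness_mm = cnd$thickness, tio2_ratio = cnd$tio2_ratio,
    wb_k = cnd$wb_k, iso = cnd$iso,
    intensity_code = intensity_code[[cnd$intensity]],
    tone_code = tone_code[[cnd$tone]],
    concentration = cnd$concentration)))
}

#' Simulate the model-ready feature table for a design
#'
#' Renders every design row and extracts one feature row per image: 11
#' colour features (ROI-A mean R, G, B; mean HSV saturation; mean CIELAB
#' a*, b*; mean CIELUV u*, v*; and the A-minus-B RGB differences) plus 6
#' parameter features (thickness, TiO2 ratio, WB setting, ISO, intensity
#' and tone codes) and the concentration label.
#'
#' @param design Data.frame of conditions, e.g. [phantom_design()].
#' @param calib A [phantom_calibration()].
#' @param wb_correct "gw" applies Gray World white-balance correction to
#'   each image before feature extraction (requires full-frame rendering);
#'   "none" extracts from the raw render (ROI fast path).
#' @param size Image size `c(h, w)` when full frames are rendered.
#' @return Data.frame with the 17 feature columns and `concentration`.
#' @export
simulate_feature_table <- function(design, calib = phantom_calibration(),
                                   wb_correct = c("gw", "none"),
                                   size = c(100, 160)) {
  wb_correct <- match.arg(wb_correct)
  if (nrow(design) == 0) stop("empty design")
  rows <- vector("list", nrow(design))
  for (i in seq_len(nrow(design))) {
    img <- render_phantom(design[i, ], calib, size = size,
                          roi_only = wb_correct == "none")
    if (wb_correct == "gw")
      img <- apply_wb_correction(img, estimate_gray_world(img))
    rows[[i]] <- feature_row(img)
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  tab
}

#' Build the feature table from a rendered dataset on disk
#'
#' Reads each manifest row's PNG, optionally applies Gray World
#' correction, and extracts the same 17-feature row as
#' [simulate_feature_table()]. Rows whose image is missing or whose ROIs
#' do not fit are skipped with a warning and counted.
#'
#' @param manifest Manifest data.frame from [generate_phantom_dataset()]
#'   (or the path to `manifest.csv`).
#' @param wb_correct "gw" or "none".
#' @return Feature data.frame; the number of skipped rows is attached as
#'   attribute `skipped`.
#' @export
build_feature_table <- function(manifest, wb_correct = c("gw", "none")) {
  wb_correct <- match.arg(wb_correct)
  if (is.character(manifest))
    manifest <- utils::read.csv(manifest, stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$image_path), , drop = FALSE]
  parse_roi <- function(s) {
    v <- as.integer(strsplit(s, ",")[[1]])
    c(x = v[1], y = v[2], w = v[3], h = v[4])
  }
  rows <- list(); skipped <- 0L
  for (i in seq_len(nrow(manifest))) {
    m <- manifest[i, ]
    if (!file.exists(m$image_path)) {
      warning("missing image skipped: ", m$image_path)
      skipped <- skipped + 1L
      next
    }
    px <- png::readPNG(m$image_path) * 255
    roi_a <- parse_roi(m$roi_a); roi_b <- parse_roi(m$roi_b)
    ok <- tryCatch({
      img <- structure(list(
        pixels = px, roi_a_px = roi_patch(px, roi_a),
        roi_b_px = roi_patch(px, roi_b), roi_a = roi_a, roi_b = roi_b,
        truth_illuminant = c(1, 1, 1) / sqrt(3), quantized = TRUE,
        condition = scene_condition(m$concentration_mg_dl, m$thickness_mm,
                                    m$tio2_ratio, m$wb_K, m$illuminant_K,
                                    m$iso, m$intensity, m$tone, m$distance,
                                    m$seed, m$study)),
        class = "phantom_image")
      if (wb_correct == "gw")
        img <- apply_wb_correction(img, estimate_gray_world(img))
      rows[[length(rows) + 1L]] <- feature_row(img)
      TRUE
    }, error = function(e) {
      warning("row ", i, " skipped: ", conditionMessage(e))
      FALSE
    })
    if (!ok) skipped <- skipped + 1L
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  attr(tab, "skipped") <- skipped
  tab
}

#' Reduced six-feature view of a feature table
#'
#' Keeps only the RGB means and A-minus-B RGB differences (the colour-
#' space-free feature set the model comparison is run against), plus the
#' label.
#'
#' @param table Full feature table.
#' @return Data.frame with `roi_r`, `roi_g`, `roi_b`, `d_r`, `d_g`,
#'   `d_b` and `concentration`.
#' @export
reduced_feature_view <- function(table) {
  stopifnot(all(REDUCED_COLS %in% names(table)))
  table[, c(REDUCED_COLS, "concentration")]
}
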