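test_that("CMYK follows the subtractive formulas and edge conventions", {
  expect_equal(unlist(rgb_to_cmyk(255, 255, 255)),
               c(c = 0, m = 0, y = 0, k = 0))
  expect_equal(unlist(rgb_to_cmyk(255, 255, 0)),
               c(c = 0, m = 0, y = 1, k = 0))
  # hand arithmetic at (128, 64, 32)
  cp <- 1 - 128 / 255; mp <- 1 - 64 / 255; yp <- 1 - 32 / 255
  k <- cp
  got <- rgb_to_cmyk(128, 64, 32)
  expect_equal(got$k, k)
  expect_equal(got$c, 0)
  expect_equal(got$m, (mp - k) / (1 - k))
  expect_equal(got$y, (yp - k) / (1 - k))
  # pure black: C = M = Y defined as 0
  expect_equal(unlist(rgb_to_cmyk(0, 0, 0)), c(c = 0, m = 0, y = 0, k = 1))
})

test_that("HSV follows the sector formulas", {
  expect_equal(unlist(rgb_to_hsv(255, 0, 0)), c(h = 0, s = 1, v = 255))
  expect_equal(rgb_to_hsv(0, 0, 255)$h, 240)
  expect_equal(rgb_to_hsv(0, 255, 0)$h, 120)
  gray <- rgb_to_hsv(77, 77, 77)
  expect_equal(c(gray$h, gray$s), c(0, 0))
  expect_equal(rgb_to_hsv(0, 0, 0)$s, 0)
})

test_that("CMYK and HSV round-trip exactly on an 8-bit lattice", {
  v <- seq(0, 255, by = 17)  # 16^3 lattice
  g <- expand.grid(r = v, g = v, b = v)
  cm <- rgb_to_cmyk(g$r, g$g, g$b)
  back <- cmyk_to_rgb(cm$c, cm$m, cm$y, cm$k)
  expect_equal(back$r, g$r, tolerance = 1e-9)
  expect_equal(back$g, g$g, tolerance = 1e-9)
  expect_equal(back$b, g$b, tolerance = 1e-9)
  hs <- rgb_to_hsv(g$r, g$g, g$b)
  expect_true(all(hs$h >= 0 & hs$h < 360))
  expect_true(all(hs$s >= 0 & hs$s <= 1))
  back2 <- hsv_to_rgb(hs$h, hs$s, hs$v)
  expect_equal(back2$r, g$r, tolerance = 1e-6)
  expect_equal(back2$g, g$g, tolerance = 1e-6)
  expect_equal(back2$b, g$b, tolerance = 1e-6)
})

test_that("YCbCr uses the printed coefficients and digital offsets", {
  w <- rgb_to_ycbcr(255, 255, 255)
  expect_equal(unlist(w), c(y = 235, cb = 128, cr = 128), tolerance = 0.1)
  gr <- rgb_to_ycbcr(100, 100, 100)
  expect_equal(c(gr$cb, gr$cr), c(128, 128), tolerance = 0.05)
  # hand evaluation at (128, 64, 200)
  rp <- 128 / 255; gp <- 64 / 255; bp <- 200 / 255
  yp <- 0.299 * rp + 0.587 * gp + 0.114 * bp
  got <- rgb_to_ycbcr(128, 64, 200)
  expect_equal(got$y, 219 * yp + 16)
  expect_equal(got$cb, 224 * (-0.1687 * rp - 0.3313 * gp + 0.5 * bp) + 128)
  expect_equal(got$cr, 224 * (0.5 * rp - 0.4187 * gp - 0.0813 * bp) + 128)
  # digital range over the lattice
  v <- seq(0, 255, by = 17)
  g <- expand.grid(r = v, g = v, b = v)
  yy <- rgb_to_ycbcr(g$r, g$g, g$b)
  expect_true(all(yy$y >= 16 - 1e-9 & yy$y <= 235 + 1e-9))
  expect_true(all(yy$cb >= 16 - 1e-9 & yy$cb <= 240 + 1e-9))
  expect_true(all(yy$cr >= 16 - 1e-9 & yy$cr <= 240 + 1e-9))
})

test_that("Lab and Luv agree with the reference converter and each other", {
  set.seed(5)
  r <- sample(0:255, 40); g <- sample(0:255, 40); b <- sample(0:255, 40)
  lab <- rgb_to_lab(r, g, b)
  ref <- grDevices::convertColor(cbind(r, g, b) / 255, from = "sRGB",
                                 to = "Lab")
  expect_equal(lab$l, unname(ref[, 1]), tolerance = 0.02)
  expect_equal(lab$a, unname(ref[, 2]), tolerance = 0.05)
  expect_equal(lab$b, unname(ref[, 3]), tolerance = 0.05)
  luv <- rgb_to_luv(r, g, b)
  refl <- grDevices::convertColor(cbind(r, g, b) / 255, from = "sRGB",
                                  to = "Luv")
  expect_equal(luv$u, unname(refl[, 2]), tolerance = 0.05)
  expect_equal(luv$v, unname(refl[, 3]), tolerance = 0.05)
  # shared lightness definition
  expect_equal(luv$l, lab$l, tolerance = 1e-9)
})

test_that("achromatic axis behaves canonically in Lab/Luv", {
  gr <- seq(0, 255, by = 15)
  lab <- rgb_to_lab(gr, gr, gr)
  luv <- rgb_to_luv(gr, gr, gr)
  expect_true(all(abs(lab$a) < 1e-6 & abs(lab$b) < 1e-6))
  expect_true(all(abs(luv$u) < 1e-6 & abs(luv$v) < 1e-6))
  expect_true(all(diff(lab$l) > 0))  # strictly increasing lightness
  expect_equal(rgb_to_lab(255, 255, 255)$l, 100, tolerance = 1e-6)
  expect_equal(rgb_to_luv(0, 0, 0)$l, 0)
  w <- rgb_to_luv(255, 255, 255)
  expect_equal(c(w$l, w$u, w$v), c(100, 0, 0), tolerance = 1e-6)
})

test_that("derived Lab quantities follow their definitions", {
  d <- lab_derived(a = 3, b = 4, dl = 3, da = 4, db = 0)
  expect_equal(d$chroma, 5)
  expect_equal(d$delta_e, 5)
  expect_equal(lab_derived(0, 0)$chroma, 0)
  expect_equal(lab_derived(a = -1, b = 0)$hue, 180)
  expect_equal(lab_derived(a = 0, b = -2)$hue, 270)
  expect_equal(lab_derived(1, 1, 0, 0, 0)$delta_e, 0)
})

test_that("channel slopes on a concentration ramp carry the expected signs", {
  # controlled environment: camera WB matched to the 5600 K scene light
  conc <- c(0, 10, 12, 14, 16, 18, 20)
  m <- sapply(conc, function(cc) {
    img <- render_phantom(scene_condition(cc, wb_k = 5600,
                                          study = "baseline"),
                          noise = FALSE, quantize = FALSE,
                          roi_only = TRUE)
    extract_roi_means(img, img$roi_a)
  })
  slope_of <- function(vals) fit_channel_regression(vals, conc)$slope
  b_slope <- slope_of(m["b", ])
  y_slope <- slope_of(rgb_to_cmyk(m["r", ], m["g", ], m["b", ])$y)
  bstar <- slope_of(rgb_to_lab(m["r", ], m["g", ], m["b", ])$b)
  s_slope <- slope_of(rgb_to_hsv(m["r", ], m["g", ], m["b", ])$s)
  cb_slope <- slope_of(rgb_to_ycbcr(m["r", ], m["g", ], m["b", ])$cb)
  v_slope <- slope_of(rgb_to_luv(m["r", ], m["g", ], m["b", ])$v)
  expect_lt(b_slope, 0)   # B down
  expect_gt(y_slope, 0)   # CMYK yellow up
  expect_gt(bstar, 0)     # b* up
  expect_gt(s_slope, 0)   # saturation up
  expect_lt(cb_slope, 0)  # Cb down
  expect_gt(v_slope, 0)   # v* up
})
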