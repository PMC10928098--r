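test_that("angular error has the metric identities", {
  expect_equal(angular_error(c(1, 1, 1), c(2, 2, 2)), 0)
  expect_equal(angular_error(c(1, 0, 0), c(0, 1, 0)), 90)
  expect_equal(angular_error(c(1, 1, 0), c(1, 0, 0)), 45)
  # symmetric and scale-invariant
  set.seed(31)
  for (i in 1:20) {
    a <- runif(3, 0.1, 1); b <- runif(3, 0.1, 1); k <- runif(1, 0.01, 50)
    expect_equal(angular_error(a, b), angular_error(b, a))
    expect_equal(angular_error(a, k * b), angular_error(a, b))
    expect_gte(angular_error(a, b), 0)
  }
  # zero iff positively proportional
  expect_equal(angular_error(c(1, 2, 3), c(2, 4, 6)), 0)
  expect_gt(angular_error(c(1, 2, 3), c(2, 4, 6.01)), 0)
  expect_error(angular_error(c(0, 0, 0), c(1, 1, 1)), "zero")
})

test_that("estimators agree with their closed-form oracles", {
  gray <- array(128, dim = c(8, 8, 3))
  for (m in c("gw", "wp", "msgp", "ch")) {
    est <- suppressWarnings(estimate_illuminant(gray, m))
    expect_equal(est$rho, rep(1, 3) / sqrt(3), tolerance = 1e-9)
  }
  # gray world is the per-channel mean direction
  img <- array(0, dim = c(4, 4, 3))
  img[, , 1] <- 100; img[, , 2] <- 50; img[, , 3] <- 25
  want <- c(100, 50, 25) / sqrt(sum(c(100, 50, 25)^2))
  expect_equal(estimate_gray_world(img)$rho, want, tolerance = 1e-12)
  # white patch is the per-channel max direction
  img[1, 1, ] <- c(255, 10, 60)
  mx <- c(255, 50, 60)
  expect_equal(estimate_white_patch(img)$rho, mx / sqrt(sum(mx^2)),
               tolerance = 1e-12)
  # scale invariance of the white-patch direction
  expect_equal(estimate_white_patch(img * 0.5)$rho,
               estimate_white_patch(img)$rho, tolerance = 1e-12)
})

test_that("grey-pixel estimator finds a neutral textured region", {
  # scene: chromatic flat background + textured *gray* patch under an
  # illuminant L; only the gray texture is a low grey-index candidate
  set.seed(40)
  L <- c(1.0, 0.8, 0.6)
  img <- array(0, dim = c(30, 30, 3))
  for (k in 1:3) img[, , k] <- c(60, 30, 160)[k] * L[k]
  tex <- 120 + matrix(rnorm(100, sd = 12), 10, 10)  # achromatic texture
  for (k in 1:3) img[11:20, 11:20, k] <- tex * L[k]
  est <- estimate_grey_pixels(img, top_fraction = 0.05)
  expect_lt(angular_error(L, est$rho), 2)
  # no spatial variation: falls back to gray world with a warning
  flat <- array(100, dim = c(6, 6, 3))
  expect_warning(est2 <- estimate_grey_pixels(flat), "Gray World")
  expect_equal(est2$rho, rep(1, 3) / sqrt(3), tolerance = 1e-9)
})

test_that("PCA estimator matches a brute-force eigen decomposition", {
  # rank-1 data: all pixels on one chromatic ray
  d <- c(0.9, 0.5, 0.2)
  ray <- array(0, dim = c(5, 5, 3))
  set.seed(8)
  amp <- matrix(runif(25, 10, 250), 5, 5)
  for (k in 1:3) ray[, , k] <- amp * d[k]
  expect_lt(angular_error(d, estimate_cheng_pca(ray, 0.4)$rho), 1e-6)
  # 3-pixel toy image against a hand-rolled scatter eigenvector of the
  # retained extremes (select_fraction 0.3 keeps one pixel per end)
  px <- rbind(c(200, 120, 40), c(100, 90, 80), c(20, 60, 100))
  toy <- array(0, dim = c(1, 3, 3))
  for (k in 1:3) toy[1, , k] <- px[, k]
  got <- estimate_cheng_pca(toy, 0.3)$rho
  mu <- colMeans(px)
  proj <- px %*% (mu / sqrt(sum(mu^2)))
  sel <- px[c(which.min(proj), which.max(proj)), ]
  ev <- eigen(t(sel) %*% sel)$vectors[, 1]
  if (sum(ev) < 0) ev <- -ev
  expect_equal(got, ev / sqrt(sum(ev^2)), tolerance = 1e-9)
})

test_that("von Kries correction neutralizes a known cast", {
  img <- array(0, dim = c(4, 4, 3))
  img[, , 1] <- 200; img[, , 2] <- 100; img[, , 3] <- 100
  out <- apply_wb_correction(img, c(2, 1, 1))
  expect_equal(out[, , 1], out[, , 2], tolerance = 1e-9)
  expect_equal(out[, , 2], out[, , 3], tolerance = 1e-9)
  # neutral estimate leaves the image unchanged
  expect_equal(apply_wb_correction(img, c(1, 1, 1)), img)
  # gray-world fixed point: correcting by GW makes GW neutral
  set.seed(9)
  noisy <- array(runif(300, 20, 230), dim = c(10, 10, 3))
  corr <- apply_wb_correction(noisy, estimate_gray_world(noisy))
  expect_lt(angular_error(c(1, 1, 1), estimate_gray_world(corr)$rho), 1e-6)
  expect_error(apply_wb_correction(img, c(0, 1, 1)), "positive")
})

test_that("synthetic renders are estimated close to their true cast", {
  img <- render_phantom(scene_condition(10, wb_k = 3000,
                                        replicate_seed = 12))
  expect_lt(angular_error(img$truth_illuminant,
                          estimate_gray_world(img)$rho), 3)
  expect_lt(angular_error(img$truth_illuminant,
                          estimate_cheng_pca(img)$rho), 5)
})

test_that("paired benchmark scores methods against the true cast", {
  pairs <- render_wb_pairs(6, wb_k = 3000, seed = 21)
  # identical pairs: every method scores zero
  same <- benchmark_wb_methods(pairs$references, pairs$references)
  expect_true(all(same$summary$mean < 1e-9))
  bm <- benchmark_wb_methods(pairs$images, pairs$references)
  expect_setequal(bm$summary$method, c("gw", "wp", "msgp", "ch"))
  expect_true(all(bm$summary$mean >= 0))
  expect_equal(dim(bm$errors), c(6, 4))
  # correcting with the *true* illuminant re-scores at quantization level
  err <- sapply(seq_along(pairs$images), function(i) {
    corr <- apply_wb_correction(pairs$images[[i]],
                                pairs$images[[i]]$truth_illuminant)
    angular_error(estimate_gray_world(pairs$references[[i]])$rho,
                  estimate_gray_world(corr)$rho)
  })
  expect_lt(max(err), 0.2)
  # unpaired inputs are rejected
  expect_error(benchmark_wb_methods(pairs$images[1:2],
                                    rev(pairs$references[1:2])),
               "unpaired")
})

test_that("gray world stays accurate across the WB temperature range", {
  for (k in c(2000, 4500, 7000)) {
    p <- render_wb_pairs(5, wb_k = k, seed = 33)
    b <- benchmark_wb_methods(p$images, p$references, methods = "gw")
    expect_lt(b$summary$mean, 0.5)
  }
})
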