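# pixel accessors ---------------------------------------------------------

as_pixel_array <- function(image) {
  if (inherits(image, "phantom_image")) {
    if (is.null(image$pixels))
      stop("ROI-only phantom image: full pixels required here")
    return(image$pixels)
  }
  if (is.array(image) && length(dim(image)) == 3 && dim(image)[3] == 3)
    return(image)
  stop("expected a phantom_image or an h x w x 3 array")
}

as_pixel_matrix <- function(image) {
  px <- as_pixel_array(image)
  cbind(c(px[, , 1]), c(px[, , 2]), c(px[, , 3]))
}

# angular error ------------------------------------------------------------

#' Angular error between two illuminant RGB vectors
#'
#' Arccosine of the cosine similarity between the ground-truth and
#' estimated illuminant vectors, in degrees. Scale-invariant in both
#' arguments; zero exactly when the vectors are positively proportional.
#'
#' @param rho_true,rho_est Length-3 non-zero RGB vectors.
#' @return Angle in degrees, in `[0, 180]`.
#' @examples
#' angular_error(c(1, 1, 1), c(2, 2, 2))  # 0
#' angular_error(c(1, 0, 0), c(0, 1, 0))  # 90
#' @export
angular_error <- function(rho_true, rho_est) {
  if (length(rho_true) != 3 || length(rho_est) != 3)
    stop("illuminants must be length-3 RGB vectors")
  na <- sqrt(sum(rho_true^2)); nb <- sqrt(sum(rho_est^2))
  if (na == 0 || nb == 0) stop("zero illuminant vector")
  cs <- sum(rho_true * rho_est) / (na * nb)
  acos(pmin(pmax(cs, -1), 1)) * 180 / pi
}

# estimators ---------------------------------------------------------------

new_illuminant <- function(rho, method) {
  rho <- as.numeric(rho)
  if (all(rho == 0)) stop("estimated illuminant is the zero vector")
  structure(list(rho = rho / sqrt(sum(rho^2)), method = method),
            class = "illuminant_estimate")
}

#' @export
print.illuminant_estimate <- function(x, ...) {
  cat(sprintf("Illuminant estimate [%s]: (%.4f, %.4f, %.4f)\n",
              x$method, x$rho[1], x$rho[2], x$rho[3]))
  invisible(x)
}

#' Gray World illuminant estimate
#'
#' Assumes the average reflectance of the scene is achromatic, so the
#' per-channel spatial mean is proportional to the illuminant.
#'
#' @param image A `phantom_image` or h x w x 3 array.
#' @return An `illuminant_estimate`.
#' @export
estimate_gray_world <- function(image) {
  new_illuminant(colMeans(as_pixel_matrix(image)), "gw")
}

#' White Patch (MaxRGB) illuminant estimate
#'
#' Takes the brightest response per channel (or a robust upper percentile)
#' as the white point.
#'
#' @inheritParams estimate_gray_world
#' @param percentile Per-channel upper percentile in (0, 100]; 100 is the
#'   classic per-channel maximum.
#' @return An `illuminant_estimate`.
#' @export
estimate_white_patch <- function(image, percentile = 100) {
  m <- as_pixel_matrix(image)
  rho <- if (percentile >= 100) apply(m, 2, max) else
    apply(m, 2, stats::quantile, probs = percentile / 100, names = FALSE)
  new_illuminant(rho, "wp")
}

# 3x3 box mean with edge replication, for local log-contrast
box_mean3 <- function(m) {
  pad <- rbind(m[1, , drop = FALSE], m, m[nrow(m), , drop = FALSE])
  pad <- cbind(pad[, 1, drop = FALSE], pad, pad[, ncol(pad), drop = FALSE])
  r <- nrow(m); cc <- ncol(m)
  acc <- matrix(0, r, cc)
  for (di in 0:2) for (dj in 0:2)
    acc <- acc + pad[di + seq_len(r), dj + seq_len(cc)]
  acc / 9
}

#' Grey-pixel illuminant estimate (MSGP core)
#'
#' Computes a per-pixel grey index from local log-channel contrast: pixels
#' whose contrast is equal across channels behave like grey surfaces and
#' reflect the illuminant directly. The most-grey `top_fraction` of
#' textured pixels is averaged to form the estimate. On an image with no
#' spatial variation the method is undefined and falls back to Gray World
#' with a warning. This is the grey-index core of the mean-shifted
#' grey-pixel method; the full mean-shift refinement is not implemented.
#'
#' @inheritParams estimate_gray_world
#' @param top_fraction Fraction of candidate pixels kept (default 0.1%).
#' @return An `illuminant_estimate`.
#' @export
estimate_grey_pixels <- function(image, top_fraction = 0.001) {
  stopifnot(top_fraction > 0, top_fraction <= 1)
  px <- as_pixel_array(image)
  lg <- log(px + 1)
  ctr <- array(0, dim = dim(px))
  for (k in 1:3) ctr[, , k] <- abs(lg[, , k] - box_mean3(lg[, , k]))
  mc <- (ctr[, , 1] + ctr[, , 2] + ctr[, , 3]) / 3
  valid <- mc > 1e-4
  if (!any(valid)) {
    warning("no spatial variation: falling back to Gray World")
    est <- estimate_gray_world(image)
    return(new_illuminant(est$rho, "msgp"))
  }
  dev <- sqrt(((ctr[, , 1] - mc)^2 + (ctr[, , 2] - mc)^2 +
                 (ctr[, , 3] - mc)^2) / 3)
  gi <- dev / (mc + 1e-6)
  gi[!valid] <- Inf
  n_keep <- max(1L, ceiling(sum(valid) * top_fraction))
  keep <- order(gi)[seq_len(n_keep)]
  m <- as_pixel_matrix(px)
  new_illuminant(colMeans(m[keep, , drop = FALSE]), "msgp")
}

#' Bright-and-dark-pixel PCA illuminant estimate (Cheng's method)
#'
#' Projects all pixel RGB vectors onto the mean-vector direction, retains
#' the top and bottom `select_fraction` of projections, and returns the
#' first principal direction (uncentred scatter) of the retained pixels,
#' sign-fixed to non-negative components.
#'
#' @inheritParams estimate_gray_world
#' @param select_fraction Fraction retained at each extreme (0, 0.5).
#' @return An `illuminant_estimate`.
#' @export
estimate_cheng_pca <- function(image, select_fraction = 0.035) {
  stopifnot(select_fraction > 0, select_fraction < 0.5)
  m <- as_pixel_matrix(image)
  mu <- colMeans(m)
  if (all(mu == 0)) stop("black image: illuminant undefined")
  proj <- as.numeric(m %*% (mu / sqrt(sum(mu^2))))
  n <- nrow(m)
  k <- max(1L, ceiling(n * select_fraction))
  ord <- order(proj)
  sel <- m[c(ord[seq_len(k)], ord[(n - k + 1L):n]), , drop = FALSE]
  sc <- crossprod(sel)
  if (all(sc == 0)) {
    warning("degenerate retained set: falling back to mean vector")
    return(new_illuminant(mu, "ch"))
  }
  e <- eigen(sc, symmetric = TRUE)$vectors[, 1]
  if (sum(e) < 0) e <- -e
  new_illuminant(e, "ch")
}

#' Estimate the scene illuminant of an image
#'
#' Front end to the four colour-constancy estimators.
#'
#' @inheritParams estimate_gray_world
#' @param method "gw" (Gray World), "wp" (White Patch / MaxRGB), "msgp"
#'   (grey pixels) or "ch" (Cheng's PCA).
#' @param ... Passed to the chosen estimator.
#' @return An `illuminant_estimate`.
#' @export
estimate_illuminant <- function(image, method = c("gw", "wp", "msgp", "ch"),
                                ...) {
  method <- match.arg(method)
  switch(method,
         gw = estimate_gray_world(image),
         wp = estimate_white_patch(image, ...),
         msgp = estimate_grey_pixels(image, ...),
         ch = estimate_cheng_pca(image, ...))
}

# correction ---------------------------------------------------------------

#' Von Kries white-balance correction
#'
#' Divides each channel by the corresponding component of the estimated
#' illuminant and rescales by the estimate's mean so overall luminance is
#' preserved, then clips to `[0, 255]` (and re-quantizes when the input
#' was 8-bit).
#'
#' @param image A `phantom_image` or h x w x 3 array.
#' @param est An `illuminant_estimate` or length-3 vector.
#' @return Same type as `image`, corrected.
#' @export
apply_wb_correction <- function(image, est) {
  rho <- if (inherits(est, "illuminant_estimate")) est$rho else as.numeric(est)
  if (length(rho) != 3 || any(rho <= 0))
    stop("illuminant must have three positive components")
  g <- mean(rho) / rho
  fix <- function(a, quantize) {
    for (k in 1:3) a[, , k] <- a[, , k] * g[k]
    a <- pmin(pmax(a, 0), 255)
    if (quantize) a <- round(a)
    a
  }
  if (inherits(image, "phantom_image")) {
    q <- isTRUE(image$quantized)
    if (!is.null(image$pixels)) image$pixels <- fix(image$pixels, q)
    image$roi_a_px <- fix(image$roi_a_px, q)
    image$roi_b_px <- fix(image$roi_b_px, q)
    tr <- image$truth_illuminant * g
    image$truth_illuminant <- tr / sqrt(sum(tr^2))
    return(image)
  }
  fix(as_pixel_array(image), FALSE)
}

# benchmarking -------------------------------------------------------------

#' Benchmark colour-constancy methods against reference captures
#'
#' Each observed image is paired with a reference render of the same scene
#' captured at the balanced colour temperature. For a method M, the
#' estimated cast is `M(observed) / M(reference)` component-wise (the
#' reference cancels M's scene-content bias), the true cast is the ratio
#' of the renders' ground-truth illuminants, and the score is the angular
#' error between the two. Returns the per-method mean and standard
#' deviation across pairs.
#'
#' @param images List of observed `phantom_image`s.
#' @param references List of matched reference `phantom_image`s (same
#'   scenes, balanced WB).
#' @param methods Character vector of estimator names.
#' @param ... Passed to the estimators.
#' @return List with `summary` (data.frame: method, mean, sd, n) and
#'   `errors` (pair x method matrix of angular errors in degrees).
#' @export
benchmark_wb_methods <- function(images, references,
                                 methods = c("gw", "wp", "msgp", "ch"),
                                 ...) {
  if (length(images) != length(references) || length(images) == 0)
    stop("images and references must be non-empty and paired")
  for (i in seq_along(images)) {
    ci <- images[[i]]$condition; cr <- references[[i]]$condition
    if (!is.null(ci) && !is.null(cr) &&
        (ci$replicate_seed != cr$replicate_seed ||
         ci$concentration != cr$concentration))
      stop("unpaired inputs: pair ", i, " is not the same scene")
  }
  errs <- matrix(NA_real_, length(images), length(methods),
                 dimnames = list(NULL, methods))
  for (i in seq_along(images)) {
    truth <- images[[i]]$truth_illuminant / references[[i]]$truth_illuminant
    for (m in methods) {
      e_obs <- estimate_illuminant(images[[i]], m, ...)$rho
      e_ref <- estimate_illuminant(references[[i]], m, ...)$rho
      errs[i, m] <- angular_error(truth, e_obs / e_ref)
    }
  }
  summary <- data.frame(method = methods,
                        mean = colMeans(errs),
                        sd = apply(errs, 2, stats::sd),
                        n = nrow(errs), row.names = NULL)
  list(summary = summary, errors = errs)
}

#' Render matched observed/reference scene pairs
#'
#' Convenience generator for WB benchmarking: for each scene it renders
#' one capture at `wb_k` and one reference capture at the balanced
#' temperature (camera WB equal to the scene light), sharing the
#' replicate seed so both are the same physical scene.
#'
#' @param n_scenes Number of scene pairs.
#' @param wb_k Off-balance camera WB of the observed captures (K).
#' @param illuminant_k Scene light temperature (K); the reference is
#'   captured with `wb_k = illuminant_k`.
#' @param calib A [phantom_calibration()].
#' @param seed Base seed; scene i uses `replicate_seed = seed + i`.
#' @param size Image size `c(h, w)`.
#' @return List with `images` and `references`.
#' @export
render_wb_pairs <- function(n_scenes = 50, wb_k = 3000,
                            illuminant_k = 5600,
                            calib = phantom_calibration(), seed = 1L,
                            size = c(100, 160)) {
  concs <- calib$concentrations
  imgs <- vector("list", n_scenes); refs <- vector("list", n_scenes)
  for (i in seq_len(n_scenes)) {
    conc <- concs[(i - 1L) %% length(concs) + 1L]
    obs_c <- scene_condition(conc, wb_k = wb_k, illuminant_k = illuminant_k,
                             replicate_seed = seed + i, study = "baseline")
    ref_c <- scene_condition(conc, wb_k = illuminant_k,
                             illuminant_k = illuminant_k,
                             replicate_seed = seed + i, study = "baseline")
    imgs[[i]] <- render_phantom(obs_c, calib, size = size)
    refs[[i]] <- render_phantom(ref_c, calib, size = size)
  }
  list(images = imgs, references = refs)
}
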