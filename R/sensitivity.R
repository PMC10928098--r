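#' Linear fit of channel value against concentration
#'
#' Ordinary least squares of a channel statistic (typically the ROI-A
#' blue mean) on bilirubin concentration, with the coefficient of
#' determination, the slope standard error and the overall regression
#' F-test that the sensitivity analysis reports.
#'
#' @param values Channel means (one per image).
#' @param concentrations Matching concentrations, mg/dl.
#' @return Object of class `channel_fit`: slope, intercept, r2, slope_se,
#'   f_stat, f_p, n.
#' @examples
#' fit <- fit_channel_regression(c(10, 7, 4, 1), c(0, 1, 2, 3))
#' fit$slope  # -3
#' @export
fit_channel_regression <- function(values, concentrations) {
  if (length(values) != length(concentrations))
    stop("values and concentrations must have equal length")
  n <- length(values)
  if (n < 3) stop("need at least 3 points")
  if (length(unique(concentrations)) < 2)
    stop("need at least 2 distinct concentrations")
  x <- concentrations; y <- values
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  sse <- sum(res^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sse / sst else NA_real_
  mse <- sse / (n - 2)
  slope_se <- sqrt(mse / sxx)
  ssr <- sst - sse
  f_stat <- if (mse > 0) ssr / mse else Inf
  f_p <- stats::pf(f_stat, 1, n - 2, lower.tail = FALSE)
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 slope_se = slope_se, f_stat = f_stat, f_p = f_p, n = n),
            class = "channel_fit")
}

#' @export
print.channel_fit <- function(x, ...) {
  cat(sprintf(
    "Channel fit (n = %d): slope %.4f (SE %.4f), R^2 %.4f, F p %.3g\n",
    x$n, x$slope, x$slope_se, x$r2, x$f_p))
  invisible(x)
}

#' Compare the slopes of two independent regressions
#'
#' Two-sample slope t-test: `t = (b1 - b2) / sqrt(SE1^2 + SE2^2)` with
#' Welch-Satterthwaite degrees of freedom built from each fit's residual
#' degrees of freedom; two-sided p.
#'
#' @param fit1,fit2 `channel_fit` objects from independent datasets.
#' @return List with `t_stat`, `df`, `p`.
#' @export
compare_slopes <- function(fit1, fit2) {
  s1 <- fit1$slope_se^2; s2 <- fit2$slope_se^2
  if (s1 + s2 == 0) stop("zero pooled standard error")
  t_stat <- (fit1$slope - fit2$slope) / sqrt(s1 + s2)
  df <- (s1 + s2)^2 / (s1^2 / (fit1$n - 2) + s2^2 / (fit2$n - 2))
  p <- 2 * stats::pt(-abs(t_stat), df)
  list(t_stat = t_stat, df = df, p = p)
}

#' Kruskal-Wallis test with Dunn's post-hoc pairwise comparisons
#'
#' Kruskal-Wallis H test (tie-corrected) across groups, followed by
#' Dunn's pairwise z-tests on mean ranks with tie correction and Holm
#' multiplicity adjustment.
#'
#' @param groups Named list of numeric vectors.
#' @param p_adjust Multiplicity adjustment method (see
#'   [stats::p.adjust()]).
#' @return List with `h`, `p`, and `pairwise` (data.frame: group1,
#'   group2, z, p, p_adj).
#' @export
kruskal_dunn <- function(groups, p_adjust = "holm") {
  if (length(groups) < 2 || any(lengths(groups) == 0))
    stop("need at least 2 non-empty groups")
  if (is.null(names(groups)))
    names(groups) <- paste0("g", seq_along(groups))
  pooled <- unlist(groups, use.names = FALSE)
  if (length(unique(pooled)) == 1) {
    pairs <- utils::combn(names(groups), 2)
    return(list(h = 0, p = 1,
                pairwise = data.frame(group1 = pairs[1, ],
                                      group2 = pairs[2, ],
                                      z = 0, p = 1, p_adj = 1)))
  }
  kw <- stats::kruskal.test(groups)
  rk <- rank(pooled)
  idx <- rep(names(groups), lengths(groups))
  n <- length(pooled)
  mean_rank <- tapply(rk, idx, mean)
  sizes <- tapply(rk, idx, length)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(names(groups), 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_term) *
                 (1 / sizes[[a]] + 1 / sizes[[b]]))
    z[j] <- (mean_rank[[a]] - mean_rank[[b]]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  list(h = unname(kw$statistic), p = kw$p.value,
       pairwise = data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                             z = z, p = p,
                             p_adj = stats::p.adjust(p, p_adjust)))
}

#' Paired Wilcoxon signed-rank test
#'
#' Compares paired model-performance vectors before and after a
#' modification. All-zero differences are a degenerate case and are
#' flagged rather than tested.
#'
#' @param before,after Equal-length paired numeric vectors.
#' @return List with `w` (signed-rank statistic), `p` and `degenerate`.
#' @export
wilcoxon_paired <- function(before, after) {
  if (length(before) != length(after))
    stop("before and after must be paired (equal length)")
  d <- after - before
  if (all(d == 0))
    return(list(w = NA_real_, p = NA_real_, degenerate = TRUE))
  wt <- suppressWarnings(stats::wilcox.test(after, before, paired = TRUE))
  list(w = unname(wt$statistic), p = wt$p.value, degenerate = FALSE)
}

#' One-at-a-time sensitivity study on the synthetic generator
#'
#' Renders `n_per_level` replicates per concentration for every level of
#' one study factor, fits the blue-channel (or another channel's)
#' regression per level, and compares all level pairs by the slope
#' t-test — the per-factor analysis of the parametric study.
#'
#' @param factor_name One of "thickness", "tio2_ratio", "wb", "iso",
#'   "intensity", "tone", "distance", or "baseline" (single condition).
#' @param calib A [phantom_calibration()].
#' @param n_per_level Images per concentration level.
#' @param channel "r", "g" or "b".
#' @param seed Base seed for the replicate seeds.
#' @return List with `fits` (data.frame of per-level slope, SE, r2, F p
#'   and the calibrated truth) and `pairwise` (slope-comparison table).
#' @export
sensitivity_study <- function(factor_name, calib = phantom_calibration(),
                              n_per_level = 30, channel = "b", seed = 1L) {
  levels <- calib$table[calib$table$study == factor_name, "level"]
  if (length(levels) == 0) stop("unknown factor: ", factor_name)
  chan <- match(channel, c("r", "g", "b"))
  fits <- list()
  off <- 0L
  for (lev in levels) {
    conc <- rep(calib$concentrations, each = n_per_level)
    vals <- numeric(length(conc))
    for (i in seq_along(conc)) {
      args <- list(concentration = conc[i],
                   replicate_seed = seed + off + i, study = factor_name)
      if (factor_name != "baseline") {
        fld <- study_field(factor_name)
        args[[fld]] <- if (fld %in% c("intensity", "tone")) lev else
          as.numeric(lev)
      }
      img <- render_phantom(do.call(scene_condition, args), calib,
                            roi_only = TRUE)
      vals[i] <- mean(img$roi_a_px[, , chan])
    }
    off <- off + length(conc)
    fit <- fit_channel_regression(vals, conc)
    truth <- calib$table[calib$table$study == factor_name &
                           calib$table$level == lev, ]
    fits[[lev]] <- list(fit = fit, truth = truth)
  }
  fit_df <- do.call(rbind, lapply(names(fits), function(lev) {
    f <- fits[[lev]]$fit; tr <- fits[[lev]]$truth
    data.frame(level = lev, slope = f$slope, slope_se = f$slope_se,
               r2 = f$r2, f_p = f$f_p, n = f$n,
               slope_true = tr$slope, r2_true = tr$r2)
  }))
  pairs <- if (length(levels) > 1) {
    cmb <- utils::combn(names(fits), 2)
    do.call(rbind, lapply(seq_len(ncol(cmb)), function(j) {
      cmp <- compare_slopes(fits[[cmb[1, j]]]$fit, fits[[cmb[2, j]]]$fit)
      data.frame(level1 = cmb[1, j], level2 = cmb[2, j],
                 t_stat = cmp$t_stat, df = cmp$df, p = cmp$p)
    }))
  } else NULL
  list(fits = fit_df, pairwise = pairs)
}
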