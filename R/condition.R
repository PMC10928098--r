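#' Construct one experimental scene condition
#'
#' A scene condition is one combination of bilirubin concentration, the six
#' confounder factors studied in the parametric analysis (phantom
#' thickness, TiO2 scattering ratio, camera white balance, ISO, light
#' intensity, illumination tone), the null factor distance, the scene
#' illuminant, and a replicate seed that pins the stochastic realization
#' of the scene (two renders of the same condition and seed are
#' bit-identical; renders differing only in `wb_k` share the same scene
#' fluctuation, emulating re-photographing one scene at another camera
#' setting).
#'
#' @param concentration Bilirubin concentration, mg/dl; one of
#'   0, 10, 12, 14, 16, 18, 20 (DI-water control plus six dilutions).
#' @param thickness Phantom thickness, mm (1, 2 or 3).
#' @param tio2_ratio TiO2 scattering-agent mass ratio (0.01, 0.015, 0.02).
#' @param wb_k Camera white-balance setting, Kelvin (2000-8000).
#' @param illuminant_k Scene light colour temperature, Kelvin.
#' @param iso Camera sensor gain setting (100-1000).
#' @param intensity Ambient light intensity: "low", "moderate" or "high".
#' @param tone Illumination tone: "white", "off-white" or "yellow".
#' @param distance Capture distance, ordinal 1-3 (no effect by design).
#' @param replicate_seed Integer seed identifying the scene replicate.
#' @param study Which one-at-a-time study the condition belongs to
#'   ("baseline", "thickness", "tio2_ratio", "wb", "iso", "intensity",
#'   "tone", "distance"), or "auto" to detect the single off-baseline
#'   factor.
#' @return A list of class `scene_condition`.
#' @export
scene_condition <- function(concentration,
                            thickness = 2,
                            tio2_ratio = 0.01,
                            wb_k = 5000,
                            illuminant_k = 5600,
                            iso = 500,
                            intensity = "moderate",
                            tone = "white",
                            distance = 2,
                            replicate_seed = 1L,
                            study = "auto") {
  if (!concentration %in% c(0, 10, 12, 14, 16, 18, 20))
    stop("concentration must be one of 0, 10, 12, 14, 16, 18, 20 mg/dl")
  if (!thickness %in% c(1, 2, 3)) stop("thickness must be 1, 2 or 3 mm")
  if (!tio2_ratio %in% c(0.01, 0.015, 0.02))
    stop("tio2_ratio must be 0.01, 0.015 or 0.02")
  if (wb_k < 2000 || wb_k > 8000) stop("wb_k must lie in 2000-8000 K")
  if (iso < 100 || iso > 1000) stop("iso must lie in 100-1000")
  intensity <- match.arg(intensity, c("low", "moderate", "high"))
  tone <- match.arg(tone, c("white", "off-white", "yellow"))
  structure(list(concentration = concentration, thickness = thickness,
                 tio2_ratio = tio2_ratio, wb_k = wb_k,
                 illuminant_k = illuminant_k, iso = iso,
                 intensity = intensity, tone = tone, distance = distance,
                 replicate_seed = as.integer(replicate_seed),
                 study = study),
            class = "scene_condition")
}

#' @export
print.scene_condition <- function(x, ...) {
  cat(sprintf(paste0("Scene: %g mg/dl | %g mm, ratio %g | WB %g K ",
                     "(light %g K) | ISO %g, %s, %s | seed %d [%s]\n"),
              x$concentration, x$thickness, x$tio2_ratio, x$wb_k,
              x$illuminant_k, x$iso, x$intensity, x$tone,
              x$replicate_seed, x$study))
  invisible(x)
}

#' Default full experimental design
#'
#' Reconstructs the 3465-image design as 33 condition settings x 7
#' concentrations x `n_replicates` replicates. The 33 settings are the
#' seven one-at-a-time studies of the parametric analysis (3 levels each
#' for thickness, TiO2 ratio, WB, ISO, intensity, tone and distance = 21
#' settings) plus 12 replicated baseline settings, so that
#' 33 x 7 x 15 = 3465.
#'
#' @param n_replicates Replicates per condition setting and concentration.
#' @param concentrations Concentration levels, mg/dl.
#' @param seed Base seed; row i receives `replicate_seed = seed + i`.
#' @return A data.frame with one row per image: the scene-condition fields
#'   plus `study`.
#' @examples
#' nrow(phantom_design())  # 3465
#' @export
phantom_design <- function(n_replicates = 15,
                           concentrations = c(0, 10, 12, 14, 16, 18, 20),
                           seed = 1L) {
  base <- data.frame(thickness = 2, tio2_ratio = 0.01, wb_k = 5000,
                     iso = 500, intensity = "moderate", tone = "white",
                     distance = 2, stringsAsFactors = FALSE)
  settings <- base[rep(1, 12), ]
  settings$study <- "baseline"
  vary <- list(
    thickness = list(field = "thickness", levels = c(1, 2, 3)),
    tio2_ratio = list(field = "tio2_ratio", levels = c(0.01, 0.015, 0.02)),
    wb = list(field = "wb_k", levels = c(2000, 5000, 8000)),
    iso = list(field = "iso", levels = c(100, 500, 1000)),
    intensity = list(field = "intensity",
                     levels = c("low", "moderate", "high")),
    tone = list(field = "tone", levels = c("white", "off-white", "yellow")),
    distance = list(field = "distance", levels = c(1, 2, 3))
  )
  for (st in names(vary)) {
    blk <- base[rep(1, length(vary[[st]]$levels)), ]
    blk[[vary[[st]]$field]] <- vary[[st]]$levels
    blk$study <- st
    settings <- rbind(settings, blk)
  }
  rownames(settings) <- NULL
  n_set <- nrow(settings)  # 33
  idx <- expand.grid(rep = seq_len(n_replicates),
                     concentration = concentrations,
                     setting = seq_len(n_set))
  design <- settings[idx$setting, ]
  design$concentration <- idx$concentration
  design$illuminant_k <- 5600
  design$replicate_seed <- as.integer(seed) + seq_len(nrow(design))
  rownames(design) <- NULL
  design[, c("study", "concentration", "thickness", "tio2_ratio", "wb_k",
             "illuminant_k", "iso", "intensity", "tone", "distance",
             "replicate_seed")]
}

# coerce a design row (data.frame or list) to a scene_condition
as_scene_condition <- function(x) {
  if (inherits(x, "scene_condition")) return(x)
  x <- as.list(x)
  scene_condition(concentration = x$concentration,
                  thickness = x$thickness, tio2_ratio = x$tio2_ratio,
                  wb_k = x$wb_k,
                  illuminant_k = if (is.null(x$illuminant_k)) 5600 else x$illuminant_k,
                  iso = x$iso, intensity = as.character(x$intensity),
                  tone = as.character(x$tone), distance = x$distance,
                  replicate_seed = x$replicate_seed,
                  study = if (is.null(x$study)) "auto" else as.character(x$study))
}
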