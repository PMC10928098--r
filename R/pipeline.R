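#' Default run configuration
#'
#' Assembles the configuration of a full pipeline run: design and
#' calibration, white-balance method, feature set, model list, per-stage
#' seeds and the output directory. All fields can be overridden via
#' `...` or supplied from a YAML/JSON file with [read_run_config()].
#'
#' @param out_dir Output directory for stage artifacts.
#' @param ... Overrides of the defaults.
#' @return A named list (class `run_config`).
#' @export
run_config <- function(out_dir = tempfile("bilphantom_run_"), ...) {
  cfg <- list(
    out_dir = out_dir,
    n_replicates = 15,
    concentrations = c(0, 10, 12, 14, 16, 18, 20),
    wb_method = "gw",
    feature_set = 17,          # 17 or 6
    models = MODEL_NAMES,
    tasks = c("classification", "regression"),
    write_images = FALSE,      # in-memory feature simulation by default
    wb_benchmark_scenes = 50,
    wb_benchmark_k = 3000,
    cv_repeats = 10,
    cv_folds = 10,
    seeds = list(generator = 1L, split = 1L, cv = 1L, permutation = 1L)
  )
  override <- list(...)
  cfg[names(override)] <- override
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML or JSON
#'
#' @param path File path; format chosen by extension.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path) else
    jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(run_config, raw)
}

#' Run the full pipeline
#'
#' Executes generate -> white-balance benchmark -> features ->
#' sensitivity -> models as one reproducible run. Per-stage artifacts
#' (feature CSV, WB report CSV, sensitivity CSV, model report JSON) are
#' written under `config$out_dir`, the configuration is serialized
#' alongside them, and a manifest of stage outputs with checksums and
#' wall times is returned.
#'
#' @param config A [run_config()].
#' @return The run manifest (data.frame: stage, artifact, md5, seconds),
#'   invisibly; stage results are attached as attribute `results`.
#' @export
run_pipeline <- function(config = run_config()) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  calib <- phantom_calibration(concentrations = config$concentrations)
  manifest <- list(); results <- list()
  log_stage <- function(stage, artifact, t0) {
    secs <- as.numeric(Sys.time()) - t0
    message(sprintf("[%s] wrote %s (%.1fs, seed generator=%d)",
                    stage, artifact, secs, config$seeds$generator))
    manifest[[length(manifest) + 1L]] <<- data.frame(
      stage = stage, artifact = artifact,
      md5 = as.character(tools::md5sum(artifact)), seconds = secs)
  }

  cfg_path <- file.path(config$out_dir, "run_config.json")
  jsonlite::write_json(unclass(config), cfg_path, auto_unbox = TRUE,
                       pretty = TRUE)

  # stage 1: design (+ optional image rendering)
  t0 <- as.numeric(Sys.time())
  design <- phantom_design(n_replicates = config$n_replicates,
                           concentrations = config$concentrations,
                           seed = config$seeds$generator)
  if (isTRUE(config$write_images)) {
    img_dir <- file.path(config$out_dir, "images")
    generate_phantom_dataset(design, calib, img_dir)
  }
  dpath <- file.path(config$out_dir, "design.csv")
  utils::write.csv(design, dpath, row.names = FALSE)
  log_stage("generate", dpath, t0)
  results$design <- design

  # stage 2: WB benchmark
  t0 <- as.numeric(Sys.time())
  pairs <- render_wb_pairs(config$wb_benchmark_scenes,
                           wb_k = config$wb_benchmark_k, calib = calib,
                           seed = config$seeds$generator + 100000L)
  wb <- benchmark_wb_methods(pairs$images, pairs$references)
  wpath <- file.path(config$out_dir, "wb_angular_errors.csv")
  utils::write.csv(wb$summary, wpath, row.names = FALSE)
  log_stage("wb", wpath, t0)
  results$wb <- wb

  # stage 3: features
  t0 <- as.numeric(Sys.time())
  feats <- simulate_feature_table(design, calib,
                                  wb_correct = config$wb_method)
  if (config$feature_set == 6) {
    model_tab <- reduced_feature_view(feats)
    feat_cols <- REDUCED_COLS
  } else {
    model_tab <- feats
    feat_cols <- FEATURE_COLS
  }
  fpath <- file.path(config$out_dir, "features.csv")
  utils::write.csv(feats, fpath, row.names = FALSE)
  log_stage("features", fpath, t0)
  results$features <- feats

  # stage 4: sensitivity
  t0 <- as.numeric(Sys.time())
  sens <- do.call(rbind, lapply(
    c("baseline", "thickness", "tio2_ratio", "wb", "iso", "intensity",
      "tone", "distance"),
    function(f) {
      s <- sensitivity_study(f, calib, n_per_level = 30,
                             seed = config$seeds$generator + 200000L)
      cbind(factor = f, s$fits)
    }))
  spath <- file.path(config$out_dir, "sensitivity.csv")
  utils::write.csv(sens, spath, row.names = FALSE)
  log_stage("sensitivity", spath, t0)
  results$sensitivity <- sens

  # stage 5: models
  t0 <- as.numeric(Sys.time())
  parts <- split_dataset(model_tab, seed = config$seeds$split)
  reports <- list()
  for (task in config$tasks) {
    for (m in config$models) {
      reports[[paste(task, m, sep = "_")]] <-
        train_eval(parts$train, parts$test, m, task,
                   features = feat_cols,
                   cv_repeats = config$cv_repeats,
                   cv_folds = config$cv_folds, seed = config$seeds$cv)
    }
  }
  mpath <- file.path(config$out_dir, "model_reports.json")
  jsonlite::write_json(lapply(reports, function(r)
    r[setdiff(names(r), c("predict", "roc_points", "grid"))]),
    mpath, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  log_stage("models", mpath, t0)
  results$reports <- reports

  out <- do.call(rbind, manifest)
  mf <- file.path(config$out_dir, "run_manifest.csv")
  utils::write.csv(out, mf, row.names = FALSE)
  attr(out, "results") <- results
  invisible(out)
}
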