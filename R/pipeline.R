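#' Write a table atomically, with a provenance stamp
#'
#' Writes to a temporary file in the destination directory and renames it
#' into place, so readers never observe a partial file; a `<path>.meta.json`
#' sidecar records the seed and a hash of the configuration used.
#'
#' @param table data.frame to write.
#' @param path destination CSV path.
#' @param seed,config optional provenance to stamp in the sidecar.
#' @return `path`, invisibly.
#' @export
write_table_atomic <- function(table, path, seed = NULL, config = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  data.table::fwrite(table, tmp)
  file.rename(tmp, path)
  stamp <- list(
    written = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = seed,
    config_hash = if (!is.null(config)) {
      sum(utf8ToInt(paste(deparse(config), collapse = ""))) # cheap stable digest
    }
  )
  jsonlite::write_json(stamp, paste0(path, ".meta.json"), auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Run the full synthetic study end to end
#'
#' Convenience driver used by the analysis scripts: simulate the study,
#' extract per-video features, fit the internal and external mixed models,
#' compute their Wald term tests, and run the rating validation.
#'
#' @param seed integer master seed; stage seeds are derived from it so each
#'   stage is independently reproducible.
#' @param config a [synthetic_config()].
#' @param feature_cfg a [feature_config()].
#' @param level simulation level passed to [generate_study()];
#'   `"keypoints"` runs the genuine keypoint pipeline, `"summary"` skips
#'   rendering.
#' @param anova_type `"II"` or `"III"`.
#' @return list with `study`, `features`, `fits` (internal, external),
#'   `anovas`, `agreement`.
#' @export
run_study <- function(seed = 1L, config = synthetic_config(),
                      feature_cfg = feature_config(),
                      level = c("keypoints", "summary"), anova_type = "II") {
  level <- match.arg(level)
  study <- generate_study(config, seed = seed, level = level)
  features <- if (level == "keypoints") {
    extract_features(study$videos, feature_cfg)
  } else {
    study$summaries
  }
  fits <- list(
    internal = fit_mixed_model(features, "internal"),
    external = fit_mixed_model(features, "external")
  )
  anovas <- lapply(fits, anova_wald, type = anova_type)
  ratings <- generate_ratings(seed = seed + 1L)
  list(
    study = study, features = features, fits = fits, anovas = anovas,
    agreement = agreement_report(ratings)
  )
}
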