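# File I/O: 8-bit grayscale PNG images, labels.csv, masks, manifest and
# configuration snapshots, and the batch generate / evaluate runners behind
# the command-line interface.

#' Write an image as 8-bit grayscale PNG
#'
#' @param image Matrix with values in `[0, 1]`.
#' @param path Output path.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(unclass(image), path)
}

#' Read an 8-bit grayscale PNG as an image matrix
#'
#' Multi-channel files are collapsed to their first channel.
#'
#' @param path PNG path.
#' @return Matrix with values in `[0, 1]`.
#' @export
read_image_png <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}

#' Serialize a pipeline configuration to YAML
#'
#' @param cfg A pipeline configuration.
#' @param path Optional file path; when omitted the YAML string is returned.
#' @return The YAML string, invisibly when written to a file.
#' @export
config_to_yaml <- function(cfg, path = NULL) {
  lst <- unclass(cfg)
  lst$.class <- class(cfg)[1]
  txt <- yaml::as.yaml(lst)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Look up a pipeline configuration by id
#'
#' Pipeline ids: `cr500`, `cr1000`, `pupil500`, `pupil1000`, `eds2019`,
#' `chugh`, `eds2020`.
#'
#' @param pipeline Pipeline id string.
#' @param stage Training stage, 1 or 2.
#' @param ... Overrides passed to the configuration constructor.
#' @return A configuration object.
#' @export
pipeline_config <- function(pipeline, stage = 1, ...) {
  switch(pipeline,
    cr500 = highres_cr_config(rate = "500", stage = stage, ...),
    cr1000 = highres_cr_config(rate = "1000", stage = stage, ...),
    pupil500 = highres_pupil_config(rate = "500", stage = stage, ...),
    pupil1000 = highres_pupil_config(rate = "1000", stage = stage, ...),
    eds2019 = eds2019_config(...),
    chugh = chugh_config(stage = stage, ...),
    eds2020 = eds2020_config(stage = stage, ...),
    rlang::abort(paste0("unknown pipeline: ", pipeline),
                 class = "eyeforge_error_usage")
  )
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n` PNG images (plus mask PNGs where the pipeline produces
#' masks), a `labels.csv` (columns `filename`, `feature`, `id`, `x`, `y`,
#' `absent`; full-resolution 0-based pixel-center coordinates), a resolved
#' configuration snapshot (`config.yaml`) and a `manifest.json` recording
#' the seed and counts. Identical seeds yield identical files.
#'
#' @param cfg A pipeline configuration (see [pipeline_config()]).
#' @param n Number of images.
#' @param seed Root seed.
#' @param out_dir Output directory (created if missing).
#' @return The manifest, invisibly.
#' @export
run_generate <- function(cfg, n, seed, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    rlang::abort(paste0("cannot create output directory: ", out_dir),
                 class = "eyeforge_error_usage")
  }
  scenes <- generate_scenes(cfg, n, seed = seed)
  filenames <- sprintf("img_%06d.png", seq_len(n) - 1L)
  for (i in seq_len(n)) {
    write_image_png(scenes[[i]]$image, file.path(out_dir, filenames[i]))
    for (mn in names(scenes[[i]]$masks)) {
      write_image_png(scenes[[i]]$masks[[mn]] * 1,
                      file.path(out_dir, sub("\\.png$",
                                             paste0("_", mn, ".png"),
                                             filenames[i])))
    }
  }
  labels <- labels_tibble(scenes, filenames)
  utils::write.csv(labels, file.path(out_dir, "labels.csv"),
                   row.names = FALSE)
  config_to_yaml(cfg, file.path(out_dir, "config.yaml"))
  manifest <- list(seed = seed, n = n, pipeline = class(cfg)[1],
                   n_label_rows = nrow(labels))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

#' Compare predicted and true feature centers
#'
#' Joins two label tables on `filename`, `feature` and `id` and reports the
#' mean pixel error plus cumulative detection rates.
#'
#' @param pred,truth Data frames (or CSV paths) with columns `filename`,
#'   `feature`, `id`, `x`, `y`.
#' @param thresholds Detection-rate thresholds, px.
#' @param scale Upscaling factor applied to predictions (to undo image
#'   downscaling).
#' @return List with `mean_error`, `detection` and the joined per-feature
#'   `errors` tibble.
#' @export
run_eval <- function(pred, truth, thresholds = c(2, 5), scale = 1) {
  read_any <- function(x) {
    if (is.character(x)) {
      tibble::as_tibble(utils::read.csv(x, stringsAsFactors = FALSE))
    } else tibble::as_tibble(x)
  }
  pred <- read_any(pred)
  truth <- read_any(truth)
  joined <- dplyr::inner_join(pred, truth,
                              by = c("filename", "feature", "id"),
                              suffix = c("_pred", "_true"))
  if (nrow(joined) == 0) {
    rlang::abort("no matching keys between prediction and truth tables",
                 class = "eyeforge_error_usage")
  }
  joined$error_px <- sqrt((joined$x_pred * scale - joined$x_true)^2 +
                            (joined$y_pred * scale - joined$y_true)^2)
  list(mean_error = mean(joined$error_px),
       detection = cumulative_detection_rate(joined$error_px, thresholds),
       errors = joined)
}
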