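#' Configuration for an end-to-end run
#'
#' Bundles stain profiles, denoising parameters, tiling and calibration.
#' Precedence when the CLI is used: command-line flag > config file >
#' these defaults. The resolved configuration is serialized into the
#' output directory for provenance.
#'
#' @param profiles stain profiles ([default_profiles()] by default).
#' @param params a [denoise_params] list.
#' @param tile_size tile side length in px.
#' @param pixel_size_um physical pixel size in micrometres.
#' @param log_level `"quiet"`, `"info"` or `"debug"`.
#' @return A `run_config` list.
#' @export
run_config <- function(profiles = default_profiles(), params = denoise_params(),
                       tile_size = 2000, pixel_size_um = 0.23,
                       log_level = c("info", "quiet", "debug")) {
  structure(list(profiles = profiles, params = params,
                 tile_size = as.integer(tile_size),
                 pixel_size_um = pixel_size_um,
                 log_level = match.arg(log_level)),
            class = "run_config")
}

mito_log <- function(config, ...) {
  if (!identical(config$log_level, "quiet")) message(sprintf(...))
}

config_as_list <- function(config) {
  list(tile_size = config$tile_size,
       pixel_size_um = config$pixel_size_um,
       log_level = config$log_level,
       params = unclass(config$params),
       profiles = lapply(config$profiles, function(p)
         list(hue_windows = p$hue_windows, sat_window = p$sat_window,
              val_window = p$val_window)))
}

#' Read a run configuration from a YAML file
#'
#' Any field absent from the file keeps its [run_config()] default.
#'
#' @param path YAML file with any of the fields `tile_size`,
#'   `pixel_size_um`, `log_level`, `params` (denoise parameter fields) and
#'   `profiles`.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("config file not found: %s", path))
  raw <- tryCatch(yaml::read_yaml(path),
                  error = function(e) stop_parse(sprintf("cannot parse %s: %s",
                                                         path, conditionMessage(e))))
  base <- run_config()
  if (!is.null(raw$params)) {
    pa <- unclass(base$params)
    pa[names(raw$params)] <- raw$params
    base$params <- do.call(denoise_params, pa)
  }
  if (!is.null(raw$profiles))
    base$profiles <- lapply(stats::setNames(names(raw$profiles), names(raw$profiles)),
                            function(nm) {
                              p <- raw$profiles[[nm]]
                              channel_profile(nm, lapply(p$hue_windows, unlist),
                                              unlist(p$sat_window), unlist(p$val_window))
                            })
  for (f in c("tile_size", "pixel_size_um", "log_level"))
    if (!is.null(raw[[f]])) base[[f]] <- raw[[f]]
  run_config(base$profiles, base$params, base$tile_size, base$pixel_size_um,
             base$log_level)
}

#' Run the full Mito-score pipeline on one image
#'
#' Computes the DAB and hematoxylin masks, counts nuclei, scores either
#' the annotated regions (when given) or every tile, and writes the
#' results bundle into `out_dir`: `scores.csv`, `heatmap.png` +
#' `heatmap_grid.csv`, QC overlays (apex circles, binary mask previews)
#' and the resolved `config.yaml`. All inputs are read and validated
#' before the first output file is written, and each file is written
#' atomically, so a failing run leaves no partial outputs. Outputs are
#' deterministic: re-running with the same inputs reproduces them
#' byte-identically.
#'
#' CSV coordinates are 0-based with half-open rectangles.
#'
#' @param image an [rgb_image] or a path to a PNG/TIFF file.
#' @param out_dir output directory (created if missing).
#' @param annotations optional: a path to a Labelme-style JSON file or a
#'   list of `annotation_region` objects. When given, `scores.csv` holds
#'   one row per region; otherwise one row per tile.
#' @param config a [run_config].
#' @return Invisibly, a list with the written `paths`, the region or tile
#'   `scores` data.frame, the whole-image `nuclei` count object and the
#'   `granules` table.
#' @export
mito_run <- function(image, out_dir, annotations = NULL, config = run_config()) {
  # ingest + validate everything up front (atomicity: fail before writing)
  if (is.character(image)) image <- read_rgb_image(image, config$pixel_size_um)
  if (!inherits(image, "rgb_image")) stop_validation("'image' must be an rgb_image or a file path")
  regions <- NULL
  if (!is.null(annotations)) {
    regions <- if (is.character(annotations)) read_annotations(annotations) else annotations
    for (r in regions) as_polygon(r, dim(image)[1], dim(image)[2])
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)

  mito_log(config, "image: %d x %d px", dim(image)[1], dim(image)[2])
  hsv <- rgb_to_hsv(image)
  ihc_mask <- extract_mask(hsv, config$profiles$ihc)
  nuc_mask <- extract_mask(hsv, config$profiles$nucleus)
  nuclei <- suppressWarnings(
    count_nuclei(hsv$val, nucleus_mask = nuc_mask, params = config$params))
  mito_log(config, "whole image: %d IHC px, %d nuclei", sum(ihc_mask), nuclei$count)
  granules <- extract_granules(ihc_mask, attr(image, "pixel_size_um"))

  if (!is.null(regions)) {
    rows <- lapply(regions, function(r) {
      s <- score_region(image, r, profiles = config$profiles,
                        params = config$params, nuclei = nuclei)
      as.data.frame(s)
    })
    scores_df <- do.call(rbind, rows)
  }
  ts <- score_tiles(image, config$tile_size, config$profiles, config$params)
  if (is.null(regions)) scores_df <- tile_scores_csv(ts)

  paths <- list(
    scores = file.path(out_dir, "scores.csv"),
    heatmap = file.path(out_dir, "heatmap.png"),
    heatmap_grid = file.path(out_dir, "heatmap_grid.csv"),
    granules = file.path(out_dir, "granules.csv"),
    qc_apexes = file.path(out_dir, "qc_apexes.png"),
    qc_ihc_mask = file.path(out_dir, "qc_ihc_mask.png"),
    qc_nucleus_mask = file.path(out_dir, "qc_nucleus_mask.png"),
    config = file.path(out_dir, "config.yaml"))

  atomic_write_csv(scores_df, paths$scores)
  render_heatmap(ts, paths$heatmap, paths$heatmap_grid)
  gr <- granules
  gr$centroid_row <- gr$centroid_row - 1  # file convention: 0-based
  gr$centroid_col <- gr$centroid_col - 1
  atomic_write_csv(gr, paths$granules)
  write_image(draw_apex_overlay(image, nuclei), paths$qc_apexes)
  write_image(unclass(ihc_mask), paths$qc_ihc_mask)
  write_image(unclass(nuc_mask), paths$qc_nucleus_mask)
  atomic_write(paths$config, function(p) yaml::write_yaml(config_as_list(config), p))
  mito_log(config, "results written to %s", out_dir)

  invisible(list(paths = paths, scores = scores_df, tiles = ts,
                 nuclei = nuclei, granules = granules))
}
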