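#' The Mito-score: IHC-positive pixels per nucleus
#'
#' The per-cell mitochondrial abundance statistic: the number of DAB
#' (mitochondrial IHC) positive pixels divided by the number of nuclei.
#' With zero nuclei the score is undefined and flagged rather than
#' dropped, since pure-background tiles are common in whole sections.
#'
#' @param ihc_pixels non-negative integer count of IHC-positive pixels.
#' @param nuclei non-negative integer nucleus count.
#' @param region_label optional label ("carcinoma", "stroma", a tile id...).
#' @param fallback_used whether the crowded-cell fallback fired upstream.
#' @return A `mito_score` object: list with `ihc_pixels`, `nuclei`,
#'   `score` (`NaN` when undefined), `undefined`, `region_label`,
#'   `fallback_used`.
#' @examples
#' mito_score(1000, 10)$score
#' @export
mito_score <- function(ihc_pixels, nuclei, region_label = NA_character_,
                       fallback_used = NA) {
  if (!is.numeric(ihc_pixels) || length(ihc_pixels) != 1L || is.na(ihc_pixels) || ihc_pixels < 0)
    stop_validation("'ihc_pixels' must be a single non-negative number")
  if (!is.numeric(nuclei) || length(nuclei) != 1L || is.na(nuclei) || nuclei < 0)
    stop_validation("'nuclei' must be a single non-negative number")
  undef <- nuclei == 0
  structure(list(ihc_pixels = as.numeric(ihc_pixels),
                 nuclei = as.numeric(nuclei),
                 score = if (undef) NaN else ihc_pixels / nuclei,
                 undefined = undef,
                 region_label = region_label,
                 fallback_used = fallback_used),
            class = "mito_score")
}

#' @export
print.mito_score <- function(x, ...) {
  lab <- if (is.na(x$region_label)) "" else sprintf(" [%s]", x$region_label)
  if (x$undefined)
    cat(sprintf("<mito_score>%s undefined (%.0f IHC px, 0 nuclei)\n", lab, x$ihc_pixels))
  else
    cat(sprintf("<mito_score>%s %.4g  (%.0f IHC px / %.0f nuclei)\n",
                lab, x$score, x$ihc_pixels, x$nuclei))
  invisible(x)
}

#' @export
as.data.frame.mito_score <- function(x, ...) {
  data.frame(region_label = x$region_label, ihc_pixels = x$ihc_pixels,
             nuclei = x$nuclei, score = x$score,
             fallback_used = x$fallback_used, stringsAsFactors = FALSE)
}

#' Extract stained granules from an IHC mask
#'
#' Connected components (8-connectivity) of the IHC-positive mask with
#' per-granule area and physical circular-equivalent diameter
#' `2 * sqrt(area / pi) * pixel_size_um`, for comparison with the 1-2 um
#' size of a mitochondrion.
#'
#' @param ihc_mask logical matrix / `binary_mask` of IHC-positive pixels.
#' @param pixel_size_um physical pixel size in micrometres (0.23 at 40x).
#' @return A data.frame with one row per granule: `area_px`,
#'   `equivalent_diameter_um`, `centroid_row`, `centroid_col` (1-based).
#' @export
extract_granules <- function(ihc_mask, pixel_size_um = 0.23) {
  if (!is.logical(ihc_mask) || is.null(dim(ihc_mask)))
    stop_validation("'ihc_mask' must be a logical matrix")
  if (!is.numeric(pixel_size_um) || pixel_size_um <= 0)
    stop_validation("'pixel_size_um' must be positive")
  lab <- label_components(ihc_mask)
  areas <- component_areas(lab)
  if (!length(areas))
    return(data.frame(area_px = integer(0), equivalent_diameter_um = numeric(0),
                      centroid_row = numeric(0), centroid_col = numeric(0)))
  cents <- component_centroids(lab)
  data.frame(area_px = areas,
             equivalent_diameter_um = 2 * sqrt(areas / pi) * pixel_size_um,
             centroid_row = cents[, "row"], centroid_col = cents[, "col"])
}

#' Mito-score of an annotated region
#'
#' Stain masks are computed on the full image (all mask operations are
#' pixelwise, so this equals per-region computation); IHC pixels are then
#' counted inside the polygon, and nuclei are counted as apexes falling
#' inside the polygon (apex membership, not component overlap, assigns a
#' nucleus to a region).
#'
#' @param image an [rgb_image].
#' @param region an `annotation_region` or `n x 2` `(row, col)` vertex
#'   matrix (1-based pixel coordinates).
#' @param profiles stain profiles, see [default_profiles()].
#' @param params a [denoise_params] list.
#' @param label region label; defaults to the annotation's label.
#' @param nuclei optional precomputed whole-image `nucleus_count` (to
#'   avoid recounting when scoring several regions of one image).
#' @return A `mito_score` object.
#' @export
score_region <- function(image, region, profiles = default_profiles(),
                         params = denoise_params(), label = NULL,
                         nuclei = NULL) {
  poly <- as_polygon(region, dim(image)[1], dim(image)[2])
  if (is.null(label))
    label <- if (inherits(region, "annotation_region")) region$label else NA_character_
  hsv <- rgb_to_hsv(image)
  ihc <- extract_mask(hsv, profiles$ihc)
  if (is.null(nuclei)) {
    nmask <- extract_mask(hsv, profiles$nucleus)
    nuclei <- count_nuclei(hsv$val, nucleus_mask = nmask, params = params)
  }
  n_in <- if (nuclei$count)
    sum(points_in_polygon(nuclei$apexes[, 1], nuclei$apexes[, 2], poly))
  else 0L
  mito_score(count_positive_pixels(ihc, poly), n_in,
             region_label = label, fallback_used = nuclei$fallback_used)
}
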