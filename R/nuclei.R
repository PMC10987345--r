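#' Denoising and apex-detection parameters for nucleus counting
#'
#' Controls the morphological cleanup of the thresholded nucleus mask and
#' the apex (local-maximum) detection on the distance map. The defaults
#' are the smallest structuring elements that visibly smooth edges and
#' close stain holes on 40x (0.23 um/px) imagery.
#'
#' @param dilation_radius disc radius (px) used to smooth nucleus edges.
#' @param dilation_iters number of dilation passes.
#' @param closing_radius disc radius (px) of the closing that fills holes
#'   left by unstained chromatin.
#' @param erosion_iters erosions (disc radius 1 each) of the mask support
#'   before apex detection, peeling boundary pixels off.
#' @param min_apex_separation minimum pairwise Euclidean distance (px)
#'   between counted apexes; closer maxima are consolidated into the
#'   stronger one.
#' @param min_nucleus_area connected components smaller than this (px^2)
#'   are discarded as specks.
#' @param crowding_area_factor the crowded-cell fallback triggers when the
#'   mean component area exceeds this multiple of the median area of
#'   single-apex components.
#' @return A `denoise_params` list.
#' @export
denoise_params <- function(dilation_radius = 1, dilation_iters = 1,
                           closing_radius = 2, erosion_iters = 1,
                           min_apex_separation = 7, min_nucleus_area = 20,
                           crowding_area_factor = 3) {
  p <- list(dilation_radius = dilation_radius, dilation_iters = dilation_iters,
            closing_radius = closing_radius, erosion_iters = erosion_iters,
            min_apex_separation = min_apex_separation,
            min_nucleus_area = min_nucleus_area,
            crowding_area_factor = crowding_area_factor)
  if (any(vapply(p, function(v) !is.numeric(v) || length(v) != 1L || v < 0, logical(1))))
    stop_validation("all denoise parameters must be single non-negative numbers")
  if (p$min_apex_separation < 1) stop_validation("min_apex_separation must be >= 1")
  structure(p, class = "denoise_params")
}

#' Morphologically denoise a nucleus mask
#'
#' Dilation (disc of `dilation_radius`, `dilation_iters` times) smooths
#' ragged nucleus edges; closing (disc of `closing_radius`) fills interior
#' holes smaller than the element; components below `min_nucleus_area`
#' are removed (8-connectivity).
#'
#' @param mask logical matrix / `binary_mask`.
#' @param params a [denoise_params] list.
#' @return A `binary_mask`.
#' @export
denoise <- function(mask, params = denoise_params()) {
  if (!is.logical(mask) || is.null(dim(mask)))
    stop_validation("'mask' must be a logical matrix")
  m <- unclass(mask)
  if (params$dilation_radius > 0 && params$dilation_iters > 0)
    for (k in seq_len(params$dilation_iters)) m <- mt_dilate(m, params$dilation_radius)
  m <- mt_close(m, params$closing_radius)
  if (params$min_nucleus_area > 0 && any(m)) {
    lab <- label_components(m)
    areas <- component_areas(lab)
    small <- which(areas < params$min_nucleus_area)
    if (length(small)) m <- m & !(lab %in% small & lab > 0L)
    dim(m) <- dim(mask)
  }
  as_binary_mask(m, attr(mask, "source_profile"))
}

# Local maxima of `dist` (8-neighborhood, >= all neighbours) grouped into
# equal-value plateaus; one representative pixel per plateau (the plateau
# pixel nearest its centroid, ties broken by row then col).
plateau_maxima <- function(dist, support) {
  mx <- max_filter3(dist)
  cand <- support & dist > 0 & (dist >= mx - 1e-9)
  if (!any(cand)) return(matrix(numeric(0), 0, 3, dimnames = list(NULL, c("row", "col", "value"))))
  lab <- label_components(cand)
  idx <- which(cand, arr.ind = TRUE)
  l <- lab[cand]
  reps <- t(vapply(split(seq_along(l), l), function(ii) {
    rr <- idx[ii, 1]; cc <- idx[ii, 2]
    cy <- mean(rr); cx <- mean(cc)
    d2 <- (rr - cy)^2 + (cc - cx)^2
    best <- ii[order(d2, rr, cc)][1]
    c(idx[best, 1], idx[best, 2], dist[idx[best, 1], idx[best, 2]])
  }, numeric(3)))
  colnames(reps) <- c("row", "col", "value")
  reps
}

#' Count nucleus apexes on a distance map
#'
#' Apexes are the local maxima (8-neighborhood) of the distance map,
#' restricted to the support after `erosion_iters` boundary-peeling
#' erosions, consolidated so that plateaus of equal maximal value yield
#' one apex and so that kept apexes are pairwise at least
#' `min_apex_separation` pixels apart (closer maxima are absorbed by the
#' stronger peak; ties are resolved deterministically by position). For
#' each apex the center of gravity of its connected component is returned.
#'
#' @param dist numeric distance-map matrix from [distance_map()].
#' @param params a [denoise_params] list.
#' @return A `nucleus_count` object: list with `count`, `apexes` (n x 2,
#'   1-based `(row, col)`), `centroids` (n x 2), `distance_map`,
#'   `fallback_used`.
#' @export
count_apexes <- function(dist, params = denoise_params()) {
  if (!is.numeric(dist) || is.null(dim(dist)))
    stop_validation("'dist' must be a numeric matrix")
  if (min(dist) < 0) stop_validation("a distance map cannot be negative")
  support <- dist > 0
  er <- support
  if (params$erosion_iters > 0)
    for (k in seq_len(params$erosion_iters)) er <- mt_erode(er, 1)
  reps <- plateau_maxima(dist, er)
  # greedy separation: strongest peak first
  if (nrow(reps) > 1) {
    ord <- order(-reps[, "value"], reps[, "row"], reps[, "col"])
    reps <- reps[ord, , drop = FALSE]
    keep <- logical(nrow(reps))
    for (i in seq_len(nrow(reps))) {
      if (!any(keep)) { keep[i] <- TRUE; next }
      d <- sqrt((reps[keep, "row"] - reps[i, "row"])^2 +
                (reps[keep, "col"] - reps[i, "col"])^2)
      keep[i] <- all(d >= params$min_apex_separation)
    }
    reps <- reps[keep, , drop = FALSE]
    reps <- reps[order(reps[, "row"], reps[, "col"]), , drop = FALSE]
  }
  apexes <- reps[, c("row", "col"), drop = FALSE]
  lab <- label_components(support)
  cents <- component_centroids(lab)
  centroids <- if (nrow(apexes)) cents[lab[apexes], , drop = FALSE]
               else matrix(numeric(0), 0, 2, dimnames = list(NULL, c("row", "col")))
  structure(list(count = nrow(apexes), apexes = apexes, centroids = centroids,
                 distance_map = dist, fallback_used = FALSE,
                 params = params),
            class = "nucleus_count")
}

#' Count nuclei in an image or nucleus mask
#'
#' The full counting pipeline: Otsu binarization of the brightness (HSV
#' value) plane restricted to the hematoxylin HSV mask (nuclei are the
#' dark side), morphological denoising, Euclidean distance map, and apex
#' counting. If the field is crowded -- mean component area above
#' `crowding_area_factor` times the median area of components holding a
#' single apex -- the apex detection is rerun once with one extra erosion
#' and a smaller apex separation (floor 3), and `fallback_used` is set.
#'
#' @param x an [rgb_image] (the HSV conversion, nucleus mask and value
#'   plane are computed internally), or a numeric intensity matrix in
#'   `[0, 255]` (then `nucleus_mask` is required).
#' @param nucleus_mask logical matrix marking hematoxylin-colored pixels;
#'   computed from `profiles$nucleus` when `x` is an image.
#' @param params a [denoise_params] list.
#' @param profiles stain profiles (used only when `x` is an image).
#' @return A `nucleus_count` object (see [count_apexes()]) with the
#'   denoised mask in `$mask`.
#' @examples
#' scene <- generate_synthetic(synthetic_spec(n_nuclei = 4, n_granules = 0,
#'                                            image_size = c(128, 128), seed = 7))
#' suppressWarnings(count_nuclei(scene$image))$count
#' @export
count_nuclei <- function(x, nucleus_mask = NULL, params = denoise_params(),
                         profiles = default_profiles()) {
  if (inherits(x, "rgb_image")) {
    hsv <- rgb_to_hsv(x)
    if (is.null(nucleus_mask)) nucleus_mask <- extract_mask(hsv, profiles$nucleus)
    intensity <- hsv$val
  } else {
    if (is.null(nucleus_mask)) stop_validation("'nucleus_mask' is required when 'x' is an intensity matrix")
    intensity <- x
  }
  if (!all(dim(intensity) == dim(nucleus_mask)))
    stop_validation("intensity and nucleus mask shapes differ")
  binarized <- otsu_binarize(intensity, nucleus_mask, foreground = "low")
  cleaned <- denoise(binarized, params)
  dm <- distance_map(cleaned)
  res <- count_apexes(dm, params)

  # crowded-cell fallback: one deterministic retry with stronger peeling
  lab <- label_components(cleaned)
  areas <- component_areas(lab)
  if (length(areas) && res$count > 0) {
    apex_comp <- lab[res$apexes]
    n_apex <- tabulate(apex_comp, length(areas))
    singles <- areas[n_apex == 1L]
    if (length(singles) &&
        mean(areas) > params$crowding_area_factor * median(singles)) {
      p2 <- params
      p2$erosion_iters <- params$erosion_iters + 1
      p2$min_apex_separation <- max(3, params$min_apex_separation - 2)
      res <- count_apexes(dm, p2)
      res$fallback_used <- TRUE
    }
  }
  res$mask <- cleaned
  res
}

#' @export
print.nucleus_count <- function(x, ...) {
  cat(sprintf("<nucleus_count> %d nuclei%s\n", x$count,
              if (isTRUE(x$fallback_used)) " (crowded-cell fallback used)" else ""))
  if (x$count) {
    show <- utils::head(cbind(round(x$apexes, 1), round(x$centroids, 2)), 5)
    colnames(show) <- c("apex_row", "apex_col", "centroid_row", "centroid_col")
    print(show)
    if (x$count > 5) cat(sprintf("... and %d more\n", x$count - 5))
  }
  invisible(x)
}

#' Draw a QC overlay circling each counted apex
#'
#' Reproduces the validation overlay a pathologist reviews: a red circle
#' of fixed radius around every apex, drawn into a copy of the image.
#'
#' @param image an [rgb_image].
#' @param result a `nucleus_count` object.
#' @param radius circle radius in px.
#' @param color length-3 RGB vector in 0-255.
#' @return An [rgb_image] with circles burned in.
#' @export
draw_apex_overlay <- function(image, result, radius = 9, color = c(255, 0, 0)) {
  px <- unclass(image)
  h <- dim(px)[1]; w <- dim(px)[2]
  if (result$count) for (i in seq_len(result$count)) {
    cy <- result$apexes[i, 1]; cx <- result$apexes[i, 2]
    th <- seq(0, 2 * pi, length.out = ceiling(2 * pi * radius) * 2)
    rr <- pmin(pmax(round(cy + radius * sin(th)), 1), h)
    cc <- pmin(pmax(round(cx + radius * cos(th)), 1), w)
    for (ch in 1:3) px[cbind(rr, cc, ch)] <- color[ch]
  }
  rgb_image(px, pixel_size_um = attr(image, "pixel_size_um"))
}
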