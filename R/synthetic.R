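#' Specification for a synthetic brightfield IHC scene
#'
#' Describes a hard-edged (no anti-aliasing) rendering of
#' hematoxylin-blue nuclei (ellipses) and DAB-brown granules (disks) on a
#' near-white background, with exact painted-pixel ground truth. The
#' defaults emulate one 40x field of view at 0.23 um/px: 25 nuclei of
#' 6-10 px mean radius (aspect ratio up to 1.2), and granules whose radii
#' (2.25-4.2 px) correspond to the 1-2 um physical size of a
#' mitochondrion at that resolution.
#'
#' @param image_size `c(height, width)` in px.
#' @param n_nuclei number of nuclei.
#' @param nucleus_radius_range `c(lo, hi)` mean radius range in px.
#' @param nucleus_color RGB triple inside the hematoxylin HSV windows
#'   (hue 200-320 after conversion).
#' @param n_granules number of granules.
#' @param granule_radius_range `c(lo, hi)` disk radius range in px.
#' @param granule_color RGB triple inside the DAB HSV windows (hue 0-60).
#' @param background_color near-white RGB triple (value > 220, so it is
#'   excluded by both stain profiles).
#' @param overlap_fraction fraction of nuclei placed as touching pairs
#'   (boundaries overlap slightly); the rest are isolated.
#' @param allow_overlap may granules sit on nuclei? Default `FALSE`,
#'   which keeps per-class painted-pixel counts exact.
#' @param seed RNG seed; a fixed seed gives a byte-identical image.
#' @param pixel_size_um physical pixel size recorded on the image.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(image_size = c(512, 512), n_nuclei = 25,
                           nucleus_radius_range = c(6, 10),
                           nucleus_color = c(60, 70, 150),
                           n_granules = 80,
                           granule_radius_range = c(2.25, 4.2),
                           granule_color = c(130, 80, 40),
                           background_color = c(245, 242, 238),
                           overlap_fraction = 0, allow_overlap = FALSE,
                           seed = 1L, pixel_size_um = 0.23) {
  spec <- list(image_size = as.integer(image_size), n_nuclei = as.integer(n_nuclei),
               nucleus_radius_range = nucleus_radius_range,
               nucleus_color = nucleus_color, n_granules = as.integer(n_granules),
               granule_radius_range = granule_radius_range,
               granule_color = granule_color, background_color = background_color,
               overlap_fraction = overlap_fraction, allow_overlap = isTRUE(allow_overlap),
               seed = as.integer(seed), pixel_size_um = pixel_size_um)
  if (length(spec$image_size) != 2L || any(spec$image_size < 1L))
    stop_validation("image_size must be c(height, width) >= 1")
  if (spec$n_nuclei < 0L || spec$n_granules < 0L)
    stop_validation("counts must be non-negative")
  if (spec$overlap_fraction < 0 || spec$overlap_fraction > 1)
    stop_validation("overlap_fraction must lie in [0, 1]")
  structure(spec, class = "synthetic_spec")
}

#' @export
print.synthetic_spec <- function(x, ...) {
  cat(sprintf("<synthetic_spec> %dx%d px, %d nuclei (%.0f%% touching), %d granules, seed %d\n",
              x$image_size[1], x$image_size[2], x$n_nuclei,
              100 * x$overlap_fraction, x$n_granules, x$seed))
  invisible(x)
}

#' Do the spec's colors land in their intended HSV windows?
#'
#' @param spec a [synthetic_spec].
#' @param profiles stain profiles to check against.
#' @return `TRUE` iff `nucleus_color` maps into the nucleus profile and
#'   `granule_color` into the IHC profile.
#' @export
validate_spec_colors <- function(spec, profiles = default_profiles()) {
  in_profile <- function(rgb, profile) {
    hsv <- rgb_to_hsv(array(rgb, dim = c(1, 1, 3)))
    m <- extract_mask(hsv, profile)
    m[1, 1]
  }
  in_profile(spec$nucleus_color, profiles$nucleus) &&
    in_profile(spec$granule_color, profiles$ihc)
}

# Run fn with a private RNG stream; the caller's .Random.seed is untouched.
with_seed <- function(seed, fn) {
  has <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", globalenv()) else NULL
  on.exit(if (has) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  set.seed(seed)
  fn()
}

# Pixels (1-based rows/cols) of a hard-edged ellipse: center (cy, cx), semi
# axes a, b, rotation th. Returns an n x 2 index matrix.
ellipse_pixels <- function(cy, cx, a, b, th, h, w) {
  rr <- max(a, b)
  r0 <- max(1L, floor(cy - rr)); r1 <- min(h, ceiling(cy + rr))
  c0 <- max(1L, floor(cx - rr)); c1 <- min(w, ceiling(cx + rr))
  if (r0 > r1 || c0 > c1) return(matrix(integer(0), 0, 2))
  g <- expand.grid(r = r0:r1, c = c0:c1)
  dy <- g$r - cy; dx <- g$c - cx
  u <- (dx * cos(th) + dy * sin(th)) / a
  v <- (-dx * sin(th) + dy * cos(th)) / b
  as.matrix(g[u * u + v * v <= 1, , drop = FALSE])
}

#' Render a synthetic IHC scene with exact ground truth
#'
#' Paints the background, then non-overlapping hard-edged nucleus
#' ellipses (optionally a fraction as touching pairs), then granule
#' disks kept off the nuclei and off each other (default), tracking every
#' painted pixel. Rendering is deterministic for a fixed spec.
#'
#' @param spec a [synthetic_spec].
#' @return A `synthetic_scene`: list with `image` (an [rgb_image]) and
#'   `truth` (list: `nucleus_centers`, `nucleus_count`,
#'   `nucleus_pixel_count`, `ihc_pixel_count`, `granule_records`).
#' @examples
#' scene <- generate_synthetic(synthetic_spec(n_nuclei = 3, n_granules = 5,
#'                                            image_size = c(96, 96)))
#' scene$truth$nucleus_count
#' @export
generate_synthetic <- function(spec) {
  if (!inherits(spec, "synthetic_spec")) spec <- do.call(synthetic_spec, spec)
  if ((spec$n_nuclei > 0 || spec$n_granules > 0) && !validate_spec_colors(spec))
    stop_validation("spec colors do not fall in their intended HSV windows")
  h <- spec$image_size[1]; w <- spec$image_size[2]
  with_seed(spec$seed, function() {
    cls <- matrix(0L, h, w)          # 0 bg, 1 nucleus, 2 granule
    gadj <- matrix(FALSE, h, w)      # granule pixels grown by 1 (keeps granules apart)

    # --- nuclei ---------------------------------------------------------
    n <- spec$n_nuclei
    n_pair_members <- 2L * ((round(spec$overlap_fraction * n)) %/% 2L)
    centers <- matrix(numeric(0), 0, 2)
    radii <- numeric(0)
    margin_gap <- 8   # free space between isolated nuclei (apexes stay apart)
    sample_shape <- function(aspect_max) {
      rho <- runif(1, spec$nucleus_radius_range[1], spec$nucleus_radius_range[2])
      q <- sqrt(runif(1, 1, aspect_max))
      list(a = rho * q, b = rho / q, th = runif(1, 0, pi), rho = rho)
    }
    place <- function(shape, near = NULL, tries = 500L) {
      rr <- max(shape$a, shape$b)
      for (t in seq_len(tries)) {
        if (is.null(near)) {
          cy <- runif(1, rr + 2, h - rr - 2)
          cx <- runif(1, rr + 2, w - rr - 2)
        } else {
          phi <- runif(1, 0, 2 * pi)
          d <- 0.92 * (near$rho + shape$rho)
          cy <- near$cy + d * sin(phi); cx <- near$cx + d * cos(phi)
          if (cy < rr + 2 || cy > h - rr - 2 || cx < rr + 2 || cx > w - rr - 2) next
        }
        if (nrow(centers)) {
          dmin <- sqrt((centers[, 1] - cy)^2 + (centers[, 2] - cx)^2)
          lim <- radii + rr + margin_gap
          if (!is.null(near)) {
            # the partner may (must) be close; everyone else keeps distance
            ok <- dmin >= lim
            ok[nrow(centers)] <- TRUE  # partner placed last
            if (!all(ok)) next
          } else if (!all(dmin >= lim)) next
        }
        return(list(cy = cy, cx = cx))
      }
      stop(errorCondition(
        sprintf("cannot pack %d nuclei of radius %g-%g into %d x %d px", n,
                spec$nucleus_radius_range[1], spec$nucleus_radius_range[2], h, w),
        class = c("mitoscore_packing_error", "mitoscore_validation_error", "error")))
    }
    paint_nucleus <- function(shape, pos) {
      px <- ellipse_pixels(pos$cy, pos$cx, shape$a, shape$b, shape$th, h, w)
      cls[px] <<- 1L
      centers <<- rbind(centers, c(pos$cy, pos$cx))
      radii <<- c(radii, max(shape$a, shape$b))
    }
    i <- 0L
    while (i < n_pair_members) {
      s1 <- sample_shape(1.1); s2 <- sample_shape(1.1)
      p1 <- place(s1)
      paint_nucleus(s1, p1)
      p2 <- place(s2, near = list(cy = p1$cy, cx = p1$cx, rho = s1$rho))
      paint_nucleus(s2, p2)
      i <- i + 2L
    }
    while (i < n) {
      s <- sample_shape(1.2)
      paint_nucleus(s, place(s))
      i <- i + 1L
    }
    nucleus_px <- sum(cls == 1L)

    # --- granules -------------------------------------------------------
    grec <- vector("list", spec$n_granules)
    for (gi in seq_len(spec$n_granules)) {
      placed <- FALSE
      for (t in 1:500) {
        r <- runif(1, spec$granule_radius_range[1], spec$granule_radius_range[2])
        cy <- runif(1, r + 2, h - r - 2); cx <- runif(1, r + 2, w - r - 2)
        px <- ellipse_pixels(cy, cx, r, r, 0, h, w)
        if (!nrow(px)) next
        if (any(gadj[px])) next
        if (!spec$allow_overlap && any(cls[px] != 0L)) next
        cls[px] <- 2L
        grow <- ellipse_pixels(cy, cx, r + 1.6, r + 1.6, 0, h, w)
        gadj[grow] <- TRUE
        grec[[gi]] <- data.frame(
          area_px = nrow(px),
          equivalent_diameter_um = 2 * sqrt(nrow(px) / pi) * spec$pixel_size_um,
          centroid_row = mean(px[, 1]), centroid_col = mean(px[, 2]),
          radius_px = r)
        placed <- TRUE
        break
      }
      if (!placed)
        stop(errorCondition(
          sprintf("cannot pack %d granules into %d x %d px", spec$n_granules, h, w),
          class = c("mitoscore_packing_error", "mitoscore_validation_error", "error")))
    }
    granule_records <- if (spec$n_granules)
      do.call(rbind, grec)
    else data.frame(area_px = integer(0), equivalent_diameter_um = numeric(0),
                    centroid_row = numeric(0), centroid_col = numeric(0),
                    radius_px = numeric(0))

    # --- assemble RGB ---------------------------------------------------
    px <- array(0L, dim = c(h, w, 3))
    for (k in 1:3) {
      plane <- matrix(spec$background_color[k], h, w)
      plane[cls == 1L] <- spec$nucleus_color[k]
      plane[cls == 2L] <- spec$granule_color[k]
      px[, , k] <- plane
    }
    colnames(centers) <- c("row", "col")
    structure(list(
      image = rgb_image(px, pixel_size_um = spec$pixel_size_um),
      truth = list(nucleus_centers = centers,
                   nucleus_count = nrow(centers),
                   nucleus_pixel_count = nucleus_px,
                   ihc_pixel_count = sum(cls == 2L),
                   granule_records = granule_records),
      class_map = cls,
      spec = spec), class = "synthetic_scene")
  })
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat(sprintf("<synthetic_scene> %dx%d px: %d nuclei (%d px), %d granules (%d IHC px)\n",
              dim(x$image)[1], dim(x$image)[2], x$truth$nucleus_count,
              x$truth$nucleus_pixel_count, nrow(x$truth$granule_records),
              x$truth$ihc_pixel_count))
  invisible(x)
}
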