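new_annotation_region <- function(label, polygon, source_file = NA_character_) {
  colnames(polygon) <- c("row", "col")
  structure(list(label = label, polygon = polygon, source_file = source_file),
            class = "annotation_region")
}

#' @export
print.annotation_region <- function(x, ...) {
  cat(sprintf("<annotation_region '%s'> %d vertices, area %.1f px^2\n",
              x$label, nrow(x$polygon), polygon_area(x$polygon)))
  invisible(x)
}

#' Area of an annotation polygon (shoelace formula)
#'
#' @param region an `annotation_region` or `n x 2` vertex matrix.
#' @return Area in px^2.
#' @export
region_area <- function(region) {
  if (inherits(region, "annotation_region")) region <- region$polygon
  polygon_area(as.matrix(region))
}

# TRUE if any two non-adjacent edges properly cross (shared endpoints of
# adjacent edges are fine).
polygon_self_intersects <- function(poly) {
  n <- nrow(poly)
  seg <- cbind(poly, poly[c(2:n, 1), ])
  cross2 <- function(ox, oy, ax, ay, bx, by) (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      p <- seg[i, ]; q <- seg[j, ]
      d1 <- cross2(p[1], p[2], p[3], p[4], q[1], q[2])
      d2 <- cross2(p[1], p[2], p[3], p[4], q[3], q[4])
      d3 <- cross2(q[1], q[2], q[3], q[4], p[1], p[2])
      d4 <- cross2(q[1], q[2], q[3], q[4], p[3], p[4])
      if (((d1 > 0 & d2 < 0) | (d1 < 0 & d2 > 0)) &&
          ((d3 > 0 & d4 < 0) | (d3 < 0 & d4 > 0))) return(TRUE)
    }
  }
  FALSE
}

#' Read Labelme-style polygon annotations
#'
#' Reads the minimal Labelme JSON dialect: a top-level `shapes` list whose
#' entries carry a `label` and a `points` list of `[x, y]` vertices in
#' 0-based pixel coordinates (x = column, y = row). Points are converted
#' to the package's in-R convention of 1-based `(row, col)`. Unknown
#' labels are preserved verbatim. Self-intersecting polygons are rejected.
#'
#' @param path path to the JSON file.
#' @return A list of `annotation_region` objects.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_io(sprintf("annotation file not found: %s", path))
  doc <- tryCatch(jsonlite::fromJSON(path, simplifyVector = FALSE),
                  error = function(e)
                    stop_parse(sprintf("malformed JSON in %s: %s", path, conditionMessage(e))))
  shapes <- doc$shapes
  if (is.null(shapes)) stop_parse(sprintf("no 'shapes' list in %s", path))
  out <- lapply(seq_along(shapes), function(i) {
    s <- shapes[[i]]
    if (is.null(s$points) || length(s$points) < 3)
      stop_validation(sprintf("shape %d ('%s') in %s needs >= 3 vertices",
                              i, s$label %||% "?", path))
    pts <- do.call(rbind, lapply(s$points, function(p) as.numeric(unlist(p))))
    poly <- cbind(row = pts[, 2] + 1, col = pts[, 1] + 1)  # [x, y] 0-based -> (row, col) 1-based
    if (polygon_self_intersects(poly))
      stop_validation(sprintf("shape %d ('%s') in %s is self-intersecting",
                              i, s$label %||% "?", path))
    new_annotation_region(s$label %||% NA_character_, poly, source_file = path)
  })
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write annotations as Labelme-style JSON
#'
#' Counterpart of [read_annotations()]; handy for building fixtures.
#'
#' @param regions list of `annotation_region` objects (or named list with
#'   `label` and an `n x 2` 1-based `(row, col)` polygon matrix).
#' @param path output path.
#' @param image_size optional `c(height, width)` recorded in the file.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(regions, path, image_size = NULL) {
  shapes <- lapply(regions, function(r) {
    poly <- if (inherits(r, "annotation_region")) r$polygon else as.matrix(r$polygon)
    list(label = if (is.na(r$label)) "region" else r$label,
         points = lapply(seq_len(nrow(poly)),
                         function(i) c(poly[i, 2] - 1, poly[i, 1] - 1)),  # (row,col) -> [x,y]
         shape_type = "polygon")
  })
  doc <- list(version = "5.0.1", shapes = shapes)
  if (!is.null(image_size))
    doc <- c(doc, list(imageHeight = image_size[1], imageWidth = image_size[2]))
  atomic_write(path, function(p)
    jsonlite::write_json(doc, p, auto_unbox = TRUE, digits = NA, pretty = TRUE))
  invisible(path)
}
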