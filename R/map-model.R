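# Domain types for the annotated landscape and the annotation-file dialect.
#
# Internal coordinates are always metres with the origin at the lower-left of
# the map extent and y increasing upward.  The annotation file may use any
# planar unit (e.g. image pixels); `scale` converts file units to metres at
# load time and back at write time.

ROAD_CLASSES <- c("highway", "railroad", "country")
C1_SET <- c(0.2, 0.4, 0.6, 0.8, 1.0)
C2_SET <- c(-1.0, -0.5, 0.0)
C4_BY_CLASS <- c(highway = -0.5, railroad = -0.3, country = -0.1)
BUFFER_BY_CLASS <- c(highway = 500, railroad = 300, country = 100)
MAIN_CLASSES <- c("highway", "railroad")

in_set <- function(v, set, tol = 1e-9) !is.na(v) & vapply(v, function(x) any(abs(set - x) < tol), logical(1L))

#' Map extent
#'
#' @param width,height extent in metres
#' @param scale metres per annotation-file coordinate unit (e.g. 10000 / image
#'   width in pixels for a pixel-annotated 10 km map)
#' @return a `map_extent` object
#' @export
map_extent <- function(width, height, scale = 1) {
  stopifnot(is.numeric(width), is.numeric(height), is.numeric(scale))
  if (width <= 0 || height <= 0 || scale <= 0) {
    stop("map_extent: width, height and scale must all be positive")
  }
  structure(list(width = as.numeric(width), height = as.numeric(height),
                 scale = as.numeric(scale)),
            class = "map_extent")
}

#' Forage field polygon
#'
#' @param id unique identifier
#' @param vertices two-column matrix of planar coordinates in metres,
#'   implicitly closed
#' @param c1 nectar-productivity coefficient in \{0.2, 0.4, 0.6, 0.8, 1.0\},
#'   or `NA` if not yet assigned
#' @param c2 pesticide-contamination coefficient in \{-1, -0.5, 0\}, or `NA`
#' @return a `field_polygon` object
#' @export
field_polygon <- function(id, vertices, c1 = NA_real_, c2 = NA_real_) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  f <- structure(list(id = as.character(id), vertices = vertices,
                      c1 = as.numeric(c1), c2 = as.numeric(c2)),
                 class = "field_polygon")
  validate_field(f)
  f
}

validate_field <- function(f, c1_set = C1_SET, c2_set = C2_SET) {
  v <- f$vertices
  if (nrow(v) < 3L) stop("field '", f$id, "': polygon needs at least 3 vertices")
  if (!polygon_is_simple(v)) stop("field '", f$id, "': polygon is degenerate or self-intersecting")
  if (polygon_area(v) <= 0) stop("field '", f$id, "': polygon has no area")
  if (!is.na(f$c1) && !in_set(f$c1, c1_set)) {
    stop("field '", f$id, "': c1 = ", f$c1, " not in {", paste(c1_set, collapse = ", "), "}")
  }
  if (!is.na(f$c2) && !in_set(f$c2, c2_set)) {
    stop("field '", f$id, "': c2 = ", f$c2, " not in {", paste(c2_set, collapse = ", "), "}")
  }
  invisible(f)
}

#' Classified road polyline
#'
#' The pollution coefficient `c4` and the proximity-loss corridor half-width
#' `buffer_width` derive from the class: highway -0.5 / 500 m, railroad
#' -0.3 / 300 m, country -0.1 / 100 m.  Highways and railroads count as main
#' roads for the crossing penalty.
#'
#' @param id unique identifier
#' @param points two-column matrix of polyline coordinates in metres
#' @param road_class one of `"highway"`, `"railroad"`, `"country"`
#' @return a `road` object
#' @export
road <- function(id, points, road_class) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  road_class <- match.arg(road_class, ROAD_CLASSES)
  r <- structure(list(id = as.character(id), points = points,
                      road_class = road_class,
                      c4 = unname(C4_BY_CLASS[road_class]),
                      buffer_width = unname(BUFFER_BY_CLASS[road_class]),
                      crossing_main = road_class %in% MAIN_CLASSES),
                 class = "road")
  validate_road(r)
  r
}

validate_road <- function(r) {
  p <- r$points
  if (nrow(p) < 2L) stop("road '", r$id, "': polyline needs at least 2 points")
  if (sum(sqrt(diff(p[, 1L])^2 + diff(p[, 2L])^2)) <= 0) {
    stop("road '", r$id, "': polyline has zero length")
  }
  if (!in_set(r$c4, C4_BY_CLASS)) {
    stop("road '", r$id, "': c4 = ", r$c4, " not in {", paste(C4_BY_CLASS, collapse = ", "), "}")
  }
  invisible(r)
}

#' Semantically annotated map
#'
#' @param extent a [map_extent()]
#' @param fields list of [field_polygon()] objects (unique ids)
#' @param roads list of [road()] objects (unique ids)
#' @return a `semantic_map` object
#' @export
semantic_map <- function(extent, fields = list(), roads = list()) {
  stopifnot(inherits(extent, "map_extent"))
  m <- structure(list(extent = extent, fields = fields, roads = roads),
                 class = "semantic_map")
  validate_map(m)
  m
}

validate_map <- function(m, c1_set = C1_SET, c2_set = C2_SET) {
  fid <- vapply(m$fields, `[[`, character(1L), "id")
  rid <- vapply(m$roads, `[[`, character(1L), "id")
  if (anyDuplicated(fid)) stop("duplicate field ids: ", paste(fid[duplicated(fid)], collapse = ", "))
  if (anyDuplicated(rid)) stop("duplicate road ids: ", paste(rid[duplicated(rid)], collapse = ", "))
  tol <- 1e-6
  for (f in m$fields) {
    validate_field(f, c1_set, c2_set)
    v <- f$vertices
    if (min(v[, 1L]) < -tol || max(v[, 1L]) > m$extent$width + tol ||
        min(v[, 2L]) < -tol || max(v[, 2L]) > m$extent$height + tol) {
      stop("field '", f$id, "': vertices fall outside the map extent")
    }
  }
  for (r in m$roads) {
    validate_road(r)
    p <- r$points
    if (min(p[, 1L]) < -tol || max(p[, 1L]) > m$extent$width + tol ||
        min(p[, 2L]) < -tol || max(p[, 2L]) > m$extent$height + tol) {
      stop("road '", r$id, "': points fall outside the map extent")
    }
  }
  invisible(m)
}

#' @export
print.semantic_map <- function(x, ...) {
  cat(sprintf("semantic_map: %.0f x %.0f m (scale %g m/unit), %d fields, %d roads\n",
              x$extent$width, x$extent$height, x$extent$scale,
              length(x$fields), length(x$roads)))
  invisible(x)
}

# ---- annotation-file dialect ------------------------------------------------
# A GeoJSON FeatureCollection.  Top-level "properties" carries the extent;
# polygon features are fields ({kind:"field", id, c1, c2}), line-string
# features are roads ({kind:"road", id, road_class}).  Coordinates are stored
# in file units (metres / extent$scale).

#' Write a semantic map to an annotation file
#'
#' The format is a GeoJSON-compatible FeatureCollection; see [read_map()].
#' The round trip `read_map(write_map(m))` preserves ids and attributes
#' exactly and coordinates to well below 1e-9 m.
#'
#' @param map a [semantic_map()]
#' @param path output file path
#' @return `invisible(path)`
#' @export
write_map <- function(map, path) {
  validate_map(map)
  s <- map$extent$scale
  feat_field <- lapply(map$fields, function(f) {
    ring <- rbind(f$vertices, f$vertices[1L, , drop = FALSE]) / s
    list(type = "Feature",
         properties = list(kind = "field", id = f$id,
                           c1 = if (is.na(f$c1)) NULL else f$c1,
                           c2 = if (is.na(f$c2)) NULL else f$c2),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) ring[i, ]))))
  })
  feat_road <- lapply(map$roads, function(r) {
    pts <- r$points / s
    list(type = "Feature",
         properties = list(kind = "road", id = r$id, road_class = r$road_class),
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(pts)), function(i) pts[i, ])))
  })
  doc <- list(type = "FeatureCollection",
              properties = list(extent = list(width = map$extent$width,
                                              height = map$extent$height,
                                              scale = map$extent$scale)),
              features = c(feat_field, feat_road))
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null", pretty = FALSE)
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

#' Read a semantic map from an annotation file
#'
#' The file is a GeoJSON FeatureCollection whose top-level `properties.extent`
#' gives `width` and `height` in metres and `scale` in metres per coordinate
#' unit.  Polygon features with `properties.kind == "field"` become forage
#' fields (optional `c1`, `c2` coefficients); LineString features with
#' `kind == "road"` become classified roads, whose pollution coefficient and
#' corridor width derive from `road_class`.  Coordinates are multiplied by
#' `scale`, so pixel-annotated maps load directly.
#'
#' Malformed geometry and out-of-set coefficients are rejected with an error
#' naming the offending feature; degenerate polygons are never silently
#' repaired, because repairs change areas and hence the honey estimate.
#'
#' @param path file path
#' @return a [semantic_map()]
#' @export
read_map <- function(path) {
  if (!file.exists(path)) stop("read_map: no such file: ", path)
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(doc$type, "FeatureCollection")) {
    stop("read_map: not a FeatureCollection: ", path)
  }
  ext <- doc$properties$extent
  if (is.null(ext)) stop("read_map: missing properties.extent")
  extent <- map_extent(ext$width, ext$height, if (is.null(ext$scale)) 1 else ext$scale)
  s <- extent$scale
  fields <- list(); roads <- list()
  for (ft in doc$features) {
    pr <- ft$properties
    id <- if (is.null(pr$id)) "<missing id>" else as.character(pr$id)
    kind <- pr$kind
    if (identical(kind, "field")) {
      if (!identical(ft$geometry$type, "Polygon")) {
        stop("feature '", id, "': kind 'field' requires Polygon geometry")
      }
      ring <- ft$geometry$coordinates[[1L]]
      xy <- do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]]))) * s
      n <- nrow(xy)
      if (n >= 2L && all(abs(xy[1L, ] - xy[n, ]) < 1e-12)) xy <- xy[-n, , drop = FALSE]
      fields[[length(fields) + 1L]] <- field_polygon(
        id, xy,
        c1 = if (is.null(pr$c1)) NA_real_ else pr$c1,
        c2 = if (is.null(pr$c2)) NA_real_ else pr$c2)
    } else if (identical(kind, "road")) {
      if (!identical(ft$geometry$type, "LineString")) {
        stop("feature '", id, "': kind 'road' requires LineString geometry")
      }
      xy <- do.call(rbind, lapply(ft$geometry$coordinates,
                                  function(p) c(p[[1L]], p[[2L]]))) * s
      if (is.null(pr$road_class)) stop("road '", id, "': missing road_class")
      roads[[length(roads) + 1L]] <- road(id, xy, pr$road_class)
    } else {
      stop("feature '", id, "': unknown kind '", kind, "'")
    }
  }
  semantic_map(extent, fields, roads)
}
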