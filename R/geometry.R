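# Flight-area clipping, road buffer overlap, and road-crossing classification.

#' Colony flight area
#'
#' The disc a colony forages over, modelled as a uniform circle around the
#' hive.  For clipping it is represented as a regular 720-gon (relative area
#' error ~1.3e-5).
#'
#' @param center hive location `c(x, y)` in metres
#' @param radius flight radius in metres (default 3 km)
#' @return a `flight_area` object
#' @export
flight_area <- function(center, radius = 3000) {
  center <- as.numeric(center)
  if (length(center) != 2L || anyNA(center)) stop("flight_area: center must be c(x, y)")
  if (!is.numeric(radius) || radius <= 0) stop("flight_area: radius must be positive")
  structure(list(center = center, radius = as.numeric(radius)),
            class = "flight_area")
}

#' Clip a field to the flight area
#'
#' Returns the part of the field a colony at the flight-area's centre can
#' reach, and its area `S_pot`.  Disjoint field and circle give an empty
#' geometry with `s_pot = 0`.
#'
#' @param field a [field_polygon()]
#' @param area a [flight_area()]
#' @param circle optional precomputed circle polygon (internal reuse)
#' @return list with `geometry` (coordinate matrix, possibly 0 rows) and
#'   `s_pot` (square metres)
#' @export
clip_to_flight_area <- function(field, area, circle = NULL) {
  stopifnot(inherits(field, "field_polygon"), inherits(area, "flight_area"))
  v <- field$vertices
  cx <- area$center[1L]; cy <- area$center[2L]
  # cheap reject on bounding boxes
  ddx <- pmax(0, pmax(min(v[, 1L]) - cx, cx - max(v[, 1L])))
  ddy <- pmax(0, pmax(min(v[, 2L]) - cy, cy - max(v[, 2L])))
  if (ddx * ddx + ddy * ddy > area$radius^2) {
    return(list(geometry = v[0L, , drop = FALSE], s_pot = 0))
  }
  if (is.null(circle)) circle <- circle_polygon(cx, cy, area$radius)
  g <- clip_polygon_convex(v, circle)
  list(geometry = g, s_pot = polygon_area(g))
}

# flat-capped corridor rectangles of half-width w around each polyline edge
road_buffer_pieces <- function(points, w) {
  n <- nrow(points)
  pieces <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    a <- points[k, ]; b <- points[k + 1L, ]
    d <- b - a
    len <- sqrt(sum(d * d))
    if (len <= 0) next
    nx <- -d[2L] / len * w; ny <- d[1L] / len * w
    pieces[[k]] <- cbind(c(a[1L] + nx, b[1L] + nx, b[1L] - nx, a[1L] - nx),
                         c(a[2L] + ny, b[2L] + ny, b[2L] - ny, a[2L] - ny))
  }
  Filter(Negate(is.null), pieces)
}

#' Area of a field segment lying inside a road's pollution corridor
#'
#' The corridor is a flat-capped band of half-width `buffer_width` on both
#' sides of the polyline (per-edge rectangles; their union, so joint overlaps
#' are not double-counted).  `S2` is the area of the clipped field segment
#' falling inside that band; it is bounded by the segment area `S_pot`.
#'
#' @param segment clipped geometry from [clip_to_flight_area()] (the
#'   `geometry` matrix, or the whole returned list)
#' @param road a [road()]
#' @return `S2` in square metres
#' @export
road_proximity_area <- function(segment, road) {
  if (is.list(segment) && !is.null(segment$geometry)) segment <- segment$geometry
  stopifnot(inherits(road, "road"))
  if (is.null(nrow(segment)) || nrow(segment) < 3L) return(0)
  w <- road$buffer_width
  # bbox reject against the corridor's bbox
  p <- road$points
  if (min(segment[, 1L]) > max(p[, 1L]) + w || max(segment[, 1L]) < min(p[, 1L]) - w ||
      min(segment[, 2L]) > max(p[, 2L]) + w || max(segment[, 2L]) < min(p[, 2L]) - w) {
    return(0)
  }
  area_intersect_union(segment, road_buffer_pieces(p, w))
}

#' Road-crossing availability coefficient C3
#'
#' Classifies the straight flight line from the apiary to a field segment's
#' representative point: 1.0 if it crosses no road, 0.5 if it crosses at
#' least one main road (highway or railroad), 0.7 if it crosses only country
#' roads.  Crossings are strict: grazing an endpoint does not count.
#'
#' @param site apiary location `c(x, y)` in metres
#' @param representative representative point of the field segment, metres
#' @param roads list of [road()] objects
#' @return 1.0, 0.7 or 0.5
#' @export
crossing_class <- function(site, representative, roads) {
  any_cross <- main_cross <- FALSE
  ax <- site[1L]; ay <- site[2L]
  bx <- representative[1L]; by <- representative[2L]
  for (r in roads) {
    p <- r$points
    n <- nrow(p)
    hit <- segments_cross(ax, ay, bx, by,
                          p[-n, 1L], p[-n, 2L], p[-1L, 1L], p[-1L, 2L])
    if (any(hit)) {
      any_cross <- TRUE
      if (r$crossing_main) { main_cross <- TRUE; break }
    }
  }
  if (main_cross) 0.5 else if (any_cross) 0.7 else 1.0
}
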