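# Planar partition of the map extent by road polylines.
#
# Roads are extended past the extent along their terminal directions, every
# pair of segments (roads + the extent boundary) is intersected, segments are
# split at shared intersection points, and the faces of the resulting planar
# graph are extracted with a half-edge walk.  Because split points are
# computed once and shared by both segments, node identification needs no
# tolerance in the generic position the generator produces.

# prepend/append far collinear points so terminal edges reach past the extent
extend_polyline <- function(pts, extent) {
  big <- 2 * sqrt(extent$width^2 + extent$height^2)
  first_dir <- function(p) {
    for (i in 2:nrow(p)) {
      d <- p[i, ] - p[1L, ]
      if (sum(d * d) > 0) return(d / sqrt(sum(d * d)))
    }
    c(1, 0)
  }
  u <- first_dir(pts)
  v <- first_dir(pts[rev(seq_len(nrow(pts))), , drop = FALSE])
  rbind(pts[1L, ] - u * big, pts, pts[nrow(pts), ] - v * big)
}

# segments as a matrix (x1, y1, x2, y2) from a polyline
polyline_edges <- function(pts) {
  n <- nrow(pts)
  cbind(pts[-n, 1L], pts[-n, 2L], pts[-1L, 1L], pts[-1L, 2L])
}

#' Partition the map extent by its roads
#'
#' Splits the extent into the disjoint regions bounded by road polylines
#' (extended to the boundary along their terminal directions, so every road
#' separates).  The region containing the apiary is the "active" region;
#' fields in any other region can only be reached by crossing a road.
#'
#' A site lying on a road (within 1e-6 m) is flagged `on_road` and assigned
#' deterministically to the region on the left of the road's direction.
#'
#' @param map a [semantic_map()]
#' @param site apiary location `c(x, y)` in metres
#' @param main_only partition by main roads (highway, railroad) only
#' @return a `region_partition`: list with `regions` (list of polygon
#'   matrices), `areas`, `active_region_id` (index into `regions`),
#'   `main_only`, `on_road`
#' @export
partition_by_roads <- function(map, site, main_only = FALSE) {
  stopifnot(inherits(map, "semantic_map"))
  W <- map$extent$width; H <- map$extent$height
  site <- as.numeric(site)
  if (site[1L] < 0 || site[1L] > W || site[2L] < 0 || site[2L] > H) {
    stop("partition_by_roads: site outside the map extent")
  }
  roads <- map$roads
  if (main_only) roads <- Filter(function(r) r$crossing_main, roads)

  boundary <- cbind(c(0, W, W, 0), c(0, 0, H, H))
  segs <- polyline_edges(rbind(boundary, boundary[1L, , drop = FALSE]))
  for (r in roads) segs <- rbind(segs, polyline_edges(extend_polyline(r$points, map$extent)))

  ns <- nrow(segs)
  splits <- vector("list", ns)          # interior split points per segment
  eps <- 1e-12                          # strict-interior parameter tolerance
  snap <- 1e-9                          # endpoint-snap parameter tolerance
  if (ns > 1L) {
    for (i in seq_len(ns - 1L)) {
      js <- (i + 1L):ns
      p <- segment_intersection_params(segs[i, 1L], segs[i, 2L], segs[i, 3L], segs[i, 4L],
                                       segs[js, 1L], segs[js, 2L], segs[js, 3L], segs[js, 4L])
      on_i <- p$ok & !is.na(p$t) & p$t > -snap & p$t < 1 + snap
      on_j <- p$ok & !is.na(p$u) & p$u > -snap & p$u < 1 + snap
      touch <- on_i & on_j
      if (!any(touch)) next
      for (q in which(touch)) {
        t <- p$t[q]; u <- p$u[q]; jj <- js[q]
        # shared point: an endpoint's exact coordinates when the crossing
        # grazes one (T-junctions), else the computed intersection
        pt <- if (t < snap) segs[i, 1:2] else if (t > 1 - snap) segs[i, 3:4]
          else if (u < snap) segs[jj, 1:2] else if (u > 1 - snap) segs[jj, 3:4]
          else c(segs[i, 1L] + t * (segs[i, 3L] - segs[i, 1L]),
                 segs[i, 2L] + t * (segs[i, 4L] - segs[i, 2L]))
        if (t > eps && t < 1 - eps) splits[[i]] <- rbind(splits[[i]], c(pt, t))
        if (u > eps && u < 1 - eps) splits[[jj]] <- rbind(splits[[jj]], c(pt, u))
      }
    }
  }

  # split each segment at its recorded points (shared coordinates, so node
  # identification is exact) and drop pieces outside the extent
  piece_a <- piece_b <- NULL
  tol <- 1e-9
  for (i in seq_len(ns)) {
    a <- segs[i, 1:2]; b <- segs[i, 3:4]
    sp <- splits[[i]]
    chain <- rbind(a, if (!is.null(sp)) sp[order(sp[, 3L]), 1:2, drop = FALSE], b)
    for (k in seq_len(nrow(chain) - 1L)) {
      p1 <- chain[k, ]; p2 <- chain[k + 1L, ]
      if (sum((p2 - p1)^2) < tol^2) next
      mx <- (p1[1L] + p2[1L]) / 2; my <- (p1[2L] + p2[2L]) / 2
      if (mx < -tol || mx > W + tol || my < -tol || my > H + tol) next
      piece_a <- rbind(piece_a, p1)
      piece_b <- rbind(piece_b, p2)
    }
  }

  regions <- extract_faces(piece_a, piece_b)
  areas <- vapply(regions, polygon_area_signed, numeric(1L))
  keep <- areas > 1e-6
  regions <- regions[keep]
  areas <- areas[keep]

  loc <- locate_site(site, regions, roads)
  structure(list(regions = regions, areas = areas,
                 active_region_id = loc$region, main_only = main_only,
                 on_road = loc$on_road),
            class = "region_partition")
}

# faces of the planar graph given by undirected segments (a[i,] -- b[i,]);
# returns vertex cycles; bounded faces come out counter-clockwise
extract_faces <- function(a, b) {
  if (is.null(a)) return(list())
  key <- function(x, y) paste(format(x, digits = 15L), format(y, digits = 15L))
  ka <- key(a[, 1L], a[, 2L]); kb <- key(b[, 1L], b[, 2L])
  nodes_key <- unique(c(ka, kb))
  idx <- seq_along(nodes_key); names(idx) <- nodes_key
  na <- idx[ka]; nb <- idx[kb]
  coords <- matrix(0, length(nodes_key), 2L)
  coords[na, 1L] <- a[, 1L]; coords[na, 2L] <- a[, 2L]
  coords[nb, 1L] <- b[, 1L]; coords[nb, 2L] <- b[, 2L]

  dup <- na == nb
  na <- na[!dup]; nb <- nb[!dup]
  ne <- length(na)
  # half-edges 1..2ne: h and h+ne are twins
  hfrom <- c(na, nb); hto <- c(nb, na)
  twin <- c(seq_len(ne) + ne, seq_len(ne))
  ang <- atan2(coords[hto, 2L] - coords[hfrom, 2L],
               coords[hto, 1L] - coords[hfrom, 1L])

  nxt <- integer(2L * ne)
  out_by_node <- split(seq_len(2L * ne), hfrom)
  for (v in names(out_by_node)) {
    hs <- out_by_node[[v]]
    hs <- hs[order(ang[hs])]            # ccw order of out-edges at node v
    m <- length(hs)
    # next(h) for each half-edge h ending at v: the out-edge one position
    # clockwise of twin(h) in the ccw order — faces keep their interior left
    incoming <- twin[hs]
    p <- seq_len(m)
    nxt[incoming] <- hs[ifelse(p - 1L >= 1L, p - 1L, m)]
  }

  visited <- logical(2L * ne)
  faces <- list()
  for (h0 in seq_len(2L * ne)) {
    if (visited[h0]) next
    h <- h0
    cyc <- integer(0)
    repeat {
      visited[h] <- TRUE
      cyc <- c(cyc, hfrom[h])
      h <- nxt[h]
      if (h == h0 || h == 0L || length(cyc) > 2L * ne) break
    }
    if (length(cyc) >= 3L) {
      faces[[length(faces) + 1L]] <- coords[cyc, , drop = FALSE]
    }
  }
  faces
}

# find the region containing the site; nudge left of the nearest road when on one
locate_site <- function(site, regions, roads) {
  on_road <- FALSE
  probe <- site
  if (length(roads)) {
    dmin <- Inf; nearest <- NULL
    for (r in roads) {
      d <- dist_points_polyline(site[1L], site[2L], r$points)
      if (d < dmin) { dmin <- d; nearest <- r }
    }
    if (dmin <= 1e-6) {
      on_road <- TRUE
      p <- nearest$points
      # nearest edge's left normal
      k <- which.min(vapply(seq_len(nrow(p) - 1L), function(i) {
        dist_points_polyline(site[1L], site[2L], p[i:(i + 1L), , drop = FALSE])
      }, numeric(1L)))
      d <- p[k + 1L, ] - p[k, ]
      d <- d / sqrt(sum(d * d))
      probe <- site + c(-d[2L], d[1L]) * 1e-3
    }
  }
  hit <- which(vapply(regions, function(rg) {
    points_in_polygon(probe[1L], probe[2L], rg)
  }, logical(1L)))
  if (!length(hit)) {
    # numerical edge graze: fall back to nearest region centroid-distance
    hit <- which.min(vapply(regions, function(rg) {
      min(dist_points_polyline(probe[1L], probe[2L], rbind(rg, rg[1L, ])))
    }, numeric(1L)))
  }
  list(region = hit[1L], on_road = on_road)
}
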