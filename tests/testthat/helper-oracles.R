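# Independent oracles: Monte-Carlo area estimates and a sequential-split
# region partition.  Deliberately written against the geometric definitions,
# not the package's kernel, so they can arbitrate it.

# crossing-count point-in-polygon, vectorised over query points
oracle_in_poly <- function(px, py, poly) {
  n <- nrow(poly)
  cnt <- integer(length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1L else i + 1L
    y1 <- poly[i, 2L]; y2 <- poly[j, 2L]
    if (y1 == y2) next
    x1 <- poly[i, 1L]; x2 <- poly[j, 1L]
    hit <- ((y1 <= py) != (y2 <= py))
    xi <- x1 + (py - y1) / (y2 - y1) * (x2 - x1)
    cnt <- cnt + as.integer(hit & xi > px)
  }
  cnt %% 2L == 1L
}

# Monte-Carlo area of polygon ∩ disc
mc_poly_circle_area <- function(poly, cx, cy, r, n = 1e6, seed = 42) {
  set.seed(seed)
  bx <- range(poly[, 1L]); by <- range(poly[, 2L])
  px <- stats::runif(n, bx[1L], bx[2L]); py <- stats::runif(n, by[1L], by[2L])
  inside <- oracle_in_poly(px, py, poly) & ((px - cx)^2 + (py - cy)^2 <= r^2)
  A <- diff(bx) * diff(by); p <- mean(inside)
  list(area = A * p, se = A * sqrt(p * (1 - p) / n))
}

# is a point inside the flat-capped corridor (union of per-edge rectangles)?
oracle_in_corridor <- function(px, py, road_pts, w) {
  inside <- logical(length(px))
  for (k in seq_len(nrow(road_pts) - 1L)) {
    a <- road_pts[k, ]; b <- road_pts[k + 1L, ]
    d <- b - a; len <- sqrt(sum(d * d))
    if (len == 0) next
    along <- ((px - a[1L]) * d[1L] + (py - a[2L]) * d[2L]) / len
    perp <- ((px - a[1L]) * -d[2L] + (py - a[2L]) * d[1L]) / len
    inside <- inside | (along >= 0 & along <= len & abs(perp) <= w)
  }
  inside
}

# Monte-Carlo area of polygon ∩ corridor
mc_poly_corridor_area <- function(poly, road_pts, w, n = 1e6, seed = 42) {
  set.seed(seed)
  bx <- range(poly[, 1L]); by <- range(poly[, 2L])
  px <- stats::runif(n, bx[1L], bx[2L]); py <- stats::runif(n, by[1L], by[2L])
  inside <- oracle_in_poly(px, py, poly) & oracle_in_corridor(px, py, road_pts, w)
  A <- diff(bx) * diff(by); p <- mean(inside)
  list(area = A * p, se = A * sqrt(p * (1 - p) / n))
}

# independent half-plane clip (keeps the side left of a->b)
oracle_clip_left <- function(poly, a, b) {
  n <- nrow(poly)
  out <- NULL
  d <- (b[1L] - a[1L]) * (poly[, 2L] - a[2L]) - (b[2L] - a[2L]) * (poly[, 1L] - a[1L])
  for (i in seq_len(n)) {
    j <- if (i == 1L) n else i - 1L
    if (d[j] >= 0 && d[i] >= 0) {
      out <- rbind(out, poly[i, ])
    } else if (d[j] >= 0 || d[i] >= 0) {
      t <- d[j] / (d[j] - d[i])
      cross <- poly[j, ] + t * (poly[i, ] - poly[j, ])
      out <- if (d[j] >= 0) rbind(out, cross) else rbind(out, cross, poly[i, ])
    }
  }
  if (is.null(out)) matrix(numeric(0), 0L, 2L) else out
}

oracle_area <- function(poly) {
  n <- nrow(poly)
  if (n < 3L) return(0)
  i <- seq_len(n); j <- c(n, i[-n])
  abs(sum(poly[j, 1L] * poly[i, 2L] - poly[i, 1L] * poly[j, 2L])) / 2
}

# sequential-split partition of a rectangle extent by infinite straight lines
# (each line given by two points); returns region areas
oracle_split_partition <- function(W, H, lines) {
  regions <- list(cbind(c(0, W, W, 0), c(0, 0, H, H)))
  for (ln in lines) {
    nxt <- list()
    for (rg in regions) {
      left <- oracle_clip_left(rg, ln[1L, ], ln[2L, ])
      right <- oracle_clip_left(rg, ln[2L, ], ln[1L, ])
      if (oracle_area(left) > 1e-9) nxt[[length(nxt) + 1L]] <- left
      if (oracle_area(right) > 1e-9) nxt[[length(nxt) + 1L]] <- right
    }
    regions <- nxt
  }
  vapply(regions, oracle_area, numeric(1L))
}

# random convex test polygon: hull of points scattered around a centre
oracle_random_convex <- function(cx, cy, rmin, rmax) {
  repeat {
    k <- sample(6:10, 1L)
    ang <- stats::runif(k, 0, 2 * pi)
    rad <- stats::runif(k, rmin, rmax)
    pts <- cbind(cx + rad * cos(ang), cy + rad * sin(ang))
    hull <- pts[rev(grDevices::chull(pts)), , drop = FALSE]
    if (nrow(hull) >= 4L) return(hull)
  }
}

# small ready-made maps for tests
tiny_map <- function(n_fields = 5, n_roads = 2, seed = 1) {
  generate_map(fixture_spec(n_fields = n_fields, n_roads = n_roads, seed = seed))
}
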