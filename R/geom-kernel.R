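# Planar geometry kernel.
#
# Polygons are plain two-column matrices (x, y) in metres, implicitly closed
# (first vertex not repeated).  Everything here is pure R; hot paths are
# vectorised over vertices/edges so the per-call loops stay short.

#' Signed polygon area (shoelace)
#'
#' Positive for counter-clockwise vertex order.
#' @param xy two-column coordinate matrix, implicitly closed
#' @return signed area in square units of the input
#' @keywords internal
polygon_area_signed <- function(xy) {
  n <- nrow(xy)
  if (is.null(n) || n < 3L) return(0)
  x <- xy[, 1L]; y <- xy[, 2L]
  j <- c(n, seq_len(n - 1L))
  sum(x[j] * y - x * y[j]) / 2
}

#' Absolute polygon area
#' @inheritParams polygon_area_signed
#' @keywords internal
polygon_area <- function(xy) abs(polygon_area_signed(xy))

# reorder vertices counter-clockwise
ensure_ccw <- function(xy) {
  if (polygon_area_signed(xy) < 0) xy[rev(seq_len(nrow(xy))), , drop = FALSE] else xy
}

#' Even-odd point-in-polygon test, vectorised over query points
#' @param px,py query coordinates
#' @param xy polygon
#' @return logical vector
#' @keywords internal
points_in_polygon <- function(px, py, xy) {
  n <- nrow(xy)
  inside <- logical(length(px))
  x <- xy[, 1L]; y <- xy[, 2L]
  j <- n
  for (i in seq_len(n)) {
    yi <- y[i]; yj <- y[j]
    if (yi != yj) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < (x[j] - x[i]) * (py - yi) / (yj - yi) + x[i])
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

# orientation of c relative to directed line a->b (>0 left)
orient2d <- function(ax, ay, bx, by, cx, cy) {
  (bx - ax) * (cy - ay) - (by - ay) * (cx - ax)
}

#' Do segments (a,b) and (c,d) properly cross?
#'
#' Strict crossing only: shared endpoints or tangential touches do not count.
#' Vectorised over the (c,d) segments.
#' @keywords internal
segments_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  d1 <- orient2d(cx, cy, dx, dy, ax, ay)
  d2 <- orient2d(cx, cy, dx, dy, bx, by)
  d3 <- orient2d(ax, ay, bx, by, cx, cy)
  d4 <- orient2d(ax, ay, bx, by, dx, dy)
  (d1 * d2 < 0) & (d3 * d4 < 0)
}

# intersection parameters of segment (a,b) with segments (c,d); returns list of
# t (along a->b), u (along c->d) and validity mask, NA where parallel
segment_intersection_params <- function(ax, ay, bx, by, cx, cy, dx, dy, tol = 1e-12) {
  rx <- bx - ax; ry <- by - ay
  sx <- dx - cx; sy <- dy - cy
  den <- rx * sy - ry * sx
  ok <- abs(den) > tol * pmax(abs(rx * sy), abs(ry * sx), 1)
  t <- u <- rep(NA_real_, length(cx))
  if (any(ok)) {
    qpx <- cx[ok] - ax; qpy <- cy[ok] - ay
    t[ok] <- (qpx * sy[ok] - qpy * sx[ok]) / den[ok]
    u[ok] <- (qpx * ry - qpy * rx) / den[ok]
  }
  list(t = t, u = u, ok = ok)
}

#' Is a polygon simple (no self-intersection, no repeated vertices)?
#' @keywords internal
polygon_is_simple <- function(xy, tol = 1e-9) {
  n <- nrow(xy)
  if (is.null(n) || n < 3L) return(FALSE)
  nxt <- c(seq_len(n)[-1L], 1L)
  ex1 <- xy[, 1L]; ey1 <- xy[, 2L]
  ex2 <- xy[nxt, 1L]; ey2 <- xy[nxt, 2L]
  len <- sqrt((ex2 - ex1)^2 + (ey2 - ey1)^2)
  if (any(len < tol)) return(FALSE)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    # skip edges adjacent to i (share a vertex)
    js <- js[js != i + 1L & !(i == 1L & js == n)]
    if (!length(js)) next
    if (any(segments_cross(ex1[i], ey1[i], ex2[i], ey2[i],
                           ex1[js], ey1[js], ex2[js], ey2[js]))) {
      return(FALSE)
    }
  }
  TRUE
}

#' Clip a polygon against the half-plane left of directed line a->b
#'
#' One Sutherland–Hodgman stage; output follows the subject's orientation.
#' @keywords internal
clip_halfplane <- function(xy, ax, ay, bx, by) {
  n <- nrow(xy)
  if (n == 0L) return(xy)
  d <- orient2d(ax, ay, bx, by, xy[, 1L], xy[, 2L])
  if (all(d >= 0)) return(xy)
  if (all(d < 0)) return(xy[0L, , drop = FALSE])
  outx <- numeric(2L * n); outy <- numeric(2L * n); m <- 0L
  j <- n
  for (i in seq_len(n)) {
    di <- d[i]; dj <- d[j]
    if (dj >= 0) {
      if (di >= 0) {                       # in -> in
        m <- m + 1L; outx[m] <- xy[i, 1L]; outy[m] <- xy[i, 2L]
      } else {                             # in -> out
        t <- dj / (dj - di)
        m <- m + 1L
        outx[m] <- xy[j, 1L] + t * (xy[i, 1L] - xy[j, 1L])
        outy[m] <- xy[j, 2L] + t * (xy[i, 2L] - xy[j, 2L])
      }
    } else if (di >= 0) {                  # out -> in
      t <- dj / (dj - di)
      m <- m + 1L
      outx[m] <- xy[j, 1L] + t * (xy[i, 1L] - xy[j, 1L])
      outy[m] <- xy[j, 2L] + t * (xy[i, 2L] - xy[j, 2L])
      m <- m + 1L; outx[m] <- xy[i, 1L]; outy[m] <- xy[i, 2L]
    }
    j <- i
  }
  cbind(outx[seq_len(m)], outy[seq_len(m)])
}

#' Clip a simple polygon against a convex polygon
#'
#' Sutherland–Hodgman over the convex clip's edges.  Half-planes that do not
#' cut the subject's bounding box are skipped, so clipping a small field
#' against a 720-gon flight circle touches only the nearby arc edges.  A
#' concave subject may come back with degenerate connecting edges when the
#' true intersection is disconnected; the area is still correct.
#' @param subject simple polygon (any orientation)
#' @param clip convex polygon
#' @return clipped polygon matrix (possibly 0 rows)
#' @keywords internal
clip_polygon_convex <- function(subject, clip) {
  empty <- subject[0L, , drop = FALSE]
  if (nrow(subject) < 3L || nrow(clip) < 3L) return(empty)
  clip <- ensure_ccw(clip)
  m <- nrow(clip)
  ax <- clip[, 1L]; ay <- clip[, 2L]
  k <- c(seq_len(m)[-1L], 1L)
  bx <- clip[k, 1L]; by <- clip[k, 2L]
  xr <- range(subject[, 1L]); yr <- range(subject[, 2L])
  # signed position of the 4 bbox corners w.r.t. every clip edge
  ex <- bx - ax; ey <- by - ay
  dmin <- dmax <- NULL
  for (cx in xr) for (cy in yr) {
    d <- ex * (cy - ay) - ey * (cx - ax)
    dmin <- if (is.null(dmin)) d else pmin(dmin, d)
    dmax <- if (is.null(dmax)) d else pmax(dmax, d)
  }
  if (any(dmax < 0)) return(empty)         # bbox fully outside one half-plane
  out <- subject
  for (i in which(dmin < 0)) {             # only half-planes that can cut
    out <- clip_halfplane(out, ax[i], ay[i], bx[i], by[i])
    if (nrow(out) < 3L) return(empty)
  }
  out
}

#' Regular polygon approximating a circle
#'
#' 720 vertices leave a relative area deficit of about 1.3e-5 against the true
#' disc — far below the model's precision.
#' @keywords internal
circle_polygon <- function(cx, cy, r, n = 720L) {
  t <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(cx + r * cos(t), cy + r * sin(t))
}

#' Distance from points to a polyline, vectorised over points
#' @keywords internal
dist_points_polyline <- function(px, py, pts) {
  best <- rep(Inf, length(px))
  for (k in seq_len(nrow(pts) - 1L)) {
    ax <- pts[k, 1L]; ay <- pts[k, 2L]
    dx <- pts[k + 1L, 1L] - ax; dy <- pts[k + 1L, 2L] - ay
    l2 <- dx * dx + dy * dy
    t <- if (l2 > 0) pmin(1, pmax(0, ((px - ax) * dx + (py - ay) * dy) / l2)) else 0
    best <- pmin(best, (ax + t * dx - px)^2 + (ay + t * dy - py)^2)
  }
  sqrt(best)
}

# y-intervals of the polygon's interior on the vertical line x = x0
# (even-odd rule; x0 must avoid vertex abscissae — callers use slab midpoints)
poly_y_intervals <- function(xy, x0) {
  n <- nrow(xy)
  x <- xy[, 1L]; y <- xy[, 2L]
  k <- c(seq_len(n)[-1L], 1L)
  x2 <- x[k]; y2 <- y[k]
  cr <- (x < x0) != (x2 < x0)
  if (!any(cr)) return(NULL)
  t <- (x0 - x[cr]) / (x2[cr] - x[cr])
  ys <- sort(y[cr] + t * (y2[cr] - y[cr]))
  if (length(ys) %% 2L == 1L) ys <- ys[-length(ys)]  # numerical vertex graze
  if (!length(ys)) return(NULL)
  matrix(ys, ncol = 2L, byrow = TRUE)
}

# merge possibly overlapping [start, end] rows into disjoint intervals
merge_intervals <- function(iv) {
  if (is.null(iv) || nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv[, 1L]), , drop = FALSE]
  s <- iv[, 1L]; e <- iv[, 2L]
  os <- s[1L]; oe <- e[1L]
  rs <- re <- numeric(nrow(iv)); m <- 0L
  for (i in seq_len(nrow(iv))[-1L]) {
    if (s[i] <= oe) {
      oe <- max(oe, e[i])
    } else {
      m <- m + 1L; rs[m] <- os; re[m] <- oe
      os <- s[i]; oe <- e[i]
    }
  }
  m <- m + 1L; rs[m] <- os; re[m] <- oe
  cbind(rs[seq_len(m)], re[seq_len(m)])
}

# total length of the intersection of two disjoint-interval sets
intersect_intervals_length <- function(a, b) {
  tot <- 0
  for (i in seq_len(nrow(a))) {
    lo <- pmax(a[i, 1L], b[, 1L])
    hi <- pmin(a[i, 2L], b[, 2L])
    tot <- tot + sum(pmax(0, hi - lo))
  }
  tot
}

#' Area of subject ∩ (union of pieces) by vertical slab sweep
#'
#' Exact up to float: slab boundaries are placed at every vertex abscissa and
#' every pairwise edge crossing, so within a slab all cross-sections are
#' linear in x and a midpoint evaluation integrates them exactly.
#' @param subject simple polygon
#' @param pieces list of simple polygons (typically buffer rectangles)
#' @return area in squared input units
#' @keywords internal
area_intersect_union <- function(subject, pieces) {
  pieces <- Filter(function(p) nrow(p) >= 3L, pieces)
  if (nrow(subject) < 3L || !length(pieces)) return(0)
  sxr <- range(subject[, 1L]); syr <- range(subject[, 2L])
  keep <- vapply(pieces, function(p) {
    min(p[, 1L]) <= sxr[2L] && max(p[, 1L]) >= sxr[1L] &&
      min(p[, 2L]) <= syr[2L] && max(p[, 2L]) >= syr[1L]
  }, logical(1L))
  pieces <- pieces[keep]
  if (!length(pieces)) return(0)

  polys <- c(list(subject), pieces)
  e1 <- do.call(rbind, lapply(polys, function(p) p))
  e2 <- do.call(rbind, lapply(polys, function(p) p[c(seq_len(nrow(p))[-1L], 1L), , drop = FALSE]))
  ne <- nrow(e1)
  lo <- max(sxr[1L], min(vapply(pieces, function(p) min(p[, 1L]), 0)))
  hi <- min(sxr[2L], max(vapply(pieces, function(p) max(p[, 1L]), 0)))
  if (hi <= lo) return(0)

  xs <- c(e1[, 1L], e2[, 1L])
  for (i in seq_len(ne - 1L)) {
    js <- (i + 1L):ne
    p <- segment_intersection_params(e1[i, 1L], e1[i, 2L], e2[i, 1L], e2[i, 2L],
                                     e1[js, 1L], e1[js, 2L], e2[js, 1L], e2[js, 2L])
    hit <- p$ok & !is.na(p$t) & p$t > 0 & p$t < 1 & p$u > 0 & p$u < 1
    if (any(hit)) {
      xs <- c(xs, e1[i, 1L] + p$t[hit] * (e2[i, 1L] - e1[i, 1L]))
    }
  }
  xs <- sort(unique(c(lo, hi, xs[xs > lo & xs < hi])))
  if (length(xs) > 1L) xs <- xs[c(TRUE, diff(xs) > 1e-9)]

  area <- 0
  for (i in seq_len(length(xs) - 1L)) {
    w <- xs[i + 1L] - xs[i]
    if (w <= 0) next
    xm <- (xs[i] + xs[i + 1L]) / 2
    sub <- poly_y_intervals(subject, xm)
    if (is.null(sub)) next
    un <- do.call(rbind, lapply(pieces, poly_y_intervals, x0 = xm))
    if (is.null(un) || nrow(un) == 0L) next
    area <- area + w * intersect_intervals_length(sub, merge_intervals(un))
  }
  area
}

#' Interior representative point of a polygon
#'
#' Approximate pole of inaccessibility: horizontal scanlines across the
#' polygon's interior; the candidate with the best clearance (scan-interval
#' half-width capped by true boundary distance) wins.  Always returns a point
#' strictly inside a valid simple polygon.
#' @keywords internal
representative_point <- function(xy, nlevels = 13L) {
  yr <- range(xy[, 2L])
  levels <- seq(yr[1L], yr[2L], length.out = nlevels + 2L)[-c(1L, nlevels + 2L)]
  bump <- (yr[2L] - yr[1L]) * 1e-7
  vy <- unique(xy[, 2L])
  levels <- vapply(levels, function(l) {
    if (any(abs(vy - l) < bump)) l + 17 * bump else l
  }, numeric(1L))
  swapped <- xy[, c(2L, 1L), drop = FALSE]
  closed <- rbind(xy, xy[1L, , drop = FALSE])
  best <- NULL; best_clear <- -Inf
  for (l in levels) {
    iv <- poly_y_intervals(swapped, l)   # x-intervals at y = l
    if (is.null(iv)) next
    for (r in seq_len(nrow(iv))) {
      half <- (iv[r, 2L] - iv[r, 1L]) / 2
      if (half <= 0) next
      cx <- (iv[r, 1L] + iv[r, 2L]) / 2
      clear <- min(half, dist_points_polyline(cx, l, closed))
      if (clear > best_clear) { best_clear <- clear; best <- c(cx, l) }
    }
  }
  if (is.null(best)) best <- colMeans(xy)   # degenerate fallback
  best
}
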