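# Seeded synthetic landscape generator.
#
# Emulates the reference region: a 10 x 10 km rectangle, ~200 convex field
# parcels of at least one hectare, ~28 roads of three classes crossing the
# full extent as noisy straight polylines.  Everything is deterministic per
# seed; coefficients are drawn from the standard sets.

#' Synthetic landscape specification
#'
#' @param extent_m `c(width, height)` in metres
#' @param n_fields number of field parcels
#' @param n_roads number of roads
#' @param road_class_mix named proportions over highway/railroad/country
#' @param seed integer RNG seed
#' @param scale metres per file coordinate unit for the generated map
#' @return a `fixture_spec` object
#' @export
fixture_spec <- function(extent_m = c(10000, 10000), n_fields = 200L,
                         n_roads = 28L,
                         road_class_mix = c(highway = 4, railroad = 3, country = 21) / 28,
                         seed = 1L, scale = 1) {
  if (n_fields < 0 || n_roads < 0) stop("fixture_spec: counts must be non-negative")
  if (!all(names(road_class_mix) %in% ROAD_CLASSES)) {
    stop("fixture_spec: road_class_mix names must be road classes")
  }
  structure(list(extent_m = as.numeric(extent_m), n_fields = as.integer(n_fields),
                 n_roads = as.integer(n_roads),
                 road_class_mix = road_class_mix / sum(road_class_mix),
                 seed = as.integer(seed), scale = as.numeric(scale)),
            class = "fixture_spec")
}

# one random convex parcel: sorted-angle star polygon around a centre
random_convex_parcel <- function(W, H, min_area = 1e4) {
  rmax <- min(280, W / 2 - 1, H / 2 - 1)
  if (rmax <= 100) return(NULL)          # extent too small for a 1-ha parcel
  for (try in seq_len(200L)) {
    R <- stats::runif(1L, 100, rmax)
    cx <- stats::runif(1L, R, W - R)
    cy <- stats::runif(1L, R, H - R)
    k <- sample(5:9, 1L)
    ang <- sort(stats::runif(k, 0, 2 * pi))
    rad <- stats::runif(k, 0.6, 1) * R
    v <- cbind(cx + rad * cos(ang), cy + rad * sin(ang))
    v <- v[rev(grDevices::chull(v)), , drop = FALSE]       # convex, ccw
    if (nrow(v) >= 4L && polygon_area(v) >= min_area) return(v)
  }
  NULL
}

# noisy straight polyline spanning the full extent; endpoints exactly on the
# boundary so the partition always separates
random_spanning_road <- function(W, H) {
  theta <- stats::runif(1L, 0, pi)
  q <- c(stats::runif(1L, 0.2 * W, 0.8 * W), stats::runif(1L, 0.2 * H, 0.8 * H))
  u <- c(cos(theta), sin(theta))
  # clip the infinite line q + t u to the extent rectangle
  ts <- c()
  if (abs(u[1L]) > 1e-12) ts <- c(ts, (0 - q[1L]) / u[1L], (W - q[1L]) / u[1L])
  if (abs(u[2L]) > 1e-12) ts <- c(ts, (0 - q[2L]) / u[2L], (H - q[2L]) / u[2L])
  pts_on <- lapply(ts, function(t) q + t * u)
  keep <- vapply(pts_on, function(p) {
    p[1L] >= -1e-9 && p[1L] <= W + 1e-9 && p[2L] >= -1e-9 && p[2L] <= H + 1e-9
  }, logical(1L))
  ends <- do.call(rbind, pts_on[keep])
  ends <- ends[c(which.min(ends %*% u), which.max(ends %*% u)), , drop = FALSE]
  ends[, 1L] <- pmin(W, pmax(0, ends[, 1L]))
  ends[, 2L] <- pmin(H, pmax(0, ends[, 2L]))
  len <- sqrt(sum((ends[2L, ] - ends[1L, ])^2))
  nseg <- max(2L, ceiling(len / 900))
  t <- seq(0, 1, length.out = nseg + 1L)
  base <- cbind(ends[1L, 1L] + t * (ends[2L, 1L] - ends[1L, 1L]),
                ends[1L, 2L] + t * (ends[2L, 2L] - ends[1L, 2L]))
  nrm <- c(-(ends[2L, 2L] - ends[1L, 2L]), ends[2L, 1L] - ends[1L, 1L]) / len
  jit <- c(0, stats::rnorm(nseg - 1L, 0, 60), 0)   # endpoints stay on the boundary
  pts <- base + outer(jit, nrm)
  pts[, 1L] <- pmin(W - 1e-9, pmax(1e-9, pts[, 1L]))
  pts[, 2L] <- pmin(H - 1e-9, pmax(1e-9, pts[, 2L]))
  pts[1L, ] <- base[1L, ]; pts[nrow(pts), ] <- base[nrow(base), ]
  pts
}

#' Generate a synthetic semantic map
#'
#' Deterministic per `spec$seed`.  Parcels are convex (4–8 vertices, >= 1 ha,
#' rejection-sampled inside the extent; overlap between parcels is allowed).
#' Roads are noisy straight polylines spanning the extent.  Field and road
#' coefficients are assigned from the standard sets under the same seed.
#'
#' @param spec a [fixture_spec()]
#' @return a [semantic_map()]
#' @export
generate_map <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  W <- spec$extent_m[1L]; H <- spec$extent_m[2L]
  extent <- map_extent(W, H, spec$scale)
  gen <- with_rng(spec$seed, {
    fields <- vector("list", spec$n_fields)
    for (i in seq_len(spec$n_fields)) {
      v <- random_convex_parcel(W, H)
      if (is.null(v)) stop("generate_map: could not place field ", i, " (infeasible packing)")
      fields[[i]] <- field_polygon(sprintf("f%03d", i), v)
    }
    classes <- if (spec$n_roads > 0L) {
      sample(names(spec$road_class_mix), spec$n_roads, replace = TRUE,
             prob = spec$road_class_mix)
    } else character(0)
    roads <- vector("list", spec$n_roads)
    for (i in seq_len(spec$n_roads)) {
      roads[[i]] <- road(sprintf("r%02d", i), random_spanning_road(W, H), classes[i])
    }
    list(fields = fields, roads = roads)
  })
  m <- semantic_map(extent, gen$fields, gen$roads)
  m <- assign_field_coefficients(m, coefficient_sets(), seed = spec$seed)
  assign_road_coefficients(m, coefficient_sets())
}
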