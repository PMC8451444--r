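# The yield model: coefficient combination, per-segment honey, road-proximity
# losses, total honey and supportable colony count.
#
# Unit convention: S_pot and S2 are carried in square metres and converted to
# hectares inside the yield formulas; base_productivity is the nectar mass
# (kg) one hectare of a fully productive field (c1 = 1) offers, and
# delta = h * k converts offered nectar to collectible honey.

#' Model parameters
#'
#' Defaults reproduce the reference configuration: a colony turns 5 kg of
#' nectar into 2 kg of honey (h = 0.4), forages 35% of what a field offers
#' (k = 0.35), needs 90 kg of honey for its own survival and is expected to
#' yield 60 kg of surplus; a fully productive hectare offers 100 kg of
#' nectar; the flight radius is 3 km.
#'
#' @param h nectar-to-honey production rate, in (0, 1]
#' @param k foraging efficiency, in (0, 1]
#' @param H_colony kg of honey a colony needs for self-consumption
#' @param H_average kg of surplus honey targeted per colony
#' @param base_productivity kg nectar per hectare at c1 = 1
#' @param radius flight radius in metres
#' @return a `model_params` object with `delta = h * k`
#' @export
model_params <- function(h = 0.4, k = 0.35, H_colony = 90, H_average = 60,
                         base_productivity = 100, radius = 3000) {
  if (!(h > 0 && h <= 1)) stop("model_params: h must be in (0, 1]")
  if (!(k > 0 && k <= 1)) stop("model_params: k must be in (0, 1]")
  if (H_colony < 0 || H_average < 0) stop("model_params: honey targets must be non-negative")
  if (base_productivity <= 0) stop("model_params: base_productivity must be positive")
  if (radius <= 0) stop("model_params: radius must be positive")
  structure(list(h = h, k = k, delta = h * k,
                 H_colony = H_colony, H_average = H_average,
                 base_productivity = base_productivity, radius = radius),
            class = "model_params")
}

#' Combined field coefficient
#'
#' Combines nectar productivity and pesticide contamination:
#' `c_f = c1 + c2` clamped below at zero, so a heavily contaminated field
#' contributes nothing however productive it is.
#'
#' @param c1 nectar-productivity coefficient(s)
#' @param c2 pesticide-contamination coefficient(s)
#' @return `c_f` in `[0, 1]`, vectorised
#' @export
field_coefficient <- function(c1, c2) {
  if (anyNA(c1) || anyNA(c2)) stop("field_coefficient: c1/c2 not assigned")
  pmax(0, c1 + c2)
}

#' Honey yield of a field segment
#'
#' `H(i) = c_f * c3 * S_pot[ha] * base_productivity * delta`.
#'
#' @param segment list (or one-row data.frame) with `c_f`, `c3`, `s_pot` (m2)
#' @param params a [model_params()]
#' @return yield in kg of honey
#' @export
segment_yield <- function(segment, params = model_params()) {
  segment$c_f * segment$c3 * (segment$s_pot / 1e4) *
    params$base_productivity * params$delta
}

#' Road-proximity honey losses of a field segment
#'
#' `H_losses = sum_r c_f * c3 * (-c4_r) * S2_r[ha] * base_productivity *
#' delta`, summed over the roads whose pollution corridor overlaps the
#' segment, then clamped at the segment's own yield so the net contribution
#' is never negative (several overlapping corridors would otherwise be able
#' to overshoot).
#'
#' @param segment list with `c_f`, `c3`, `s_pot` and `s2_by_road` (named
#'   numeric vector of S2 areas in m2)
#' @param roads list of [road()] objects covering the names of `s2_by_road`
#' @param params a [model_params()]
#' @return losses in kg of honey, `0 <= losses <= segment_yield`
#' @export
segment_losses <- function(segment, roads, params = model_params()) {
  s2 <- segment$s2_by_road
  if (is.null(s2) || !length(s2)) return(0)
  c4 <- vapply(roads, `[[`, numeric(1L), "c4")
  names(c4) <- vapply(roads, `[[`, character(1L), "id")
  missing <- setdiff(names(s2), names(c4))
  if (length(missing)) stop("segment_losses: unknown road id(s): ", paste(missing, collapse = ", "))
  raw <- sum(segment$c_f * segment$c3 * (-c4[names(s2)]) * (s2 / 1e4) *
               params$base_productivity * params$delta)
  min(raw, segment_yield(segment, params))
}

#' Total honey over all field segments
#'
#' @param segments data.frame with columns `h_i` and `h_losses` (as built by
#'   [evaluate_location()]), or a list of segment lists with those elements
#' @return total collectible honey `H = sum(h_i) - sum(h_losses)`, kg
#' @export
total_honey <- function(segments) {
  if (is.data.frame(segments)) {
    h <- sum(segments$h_i) - sum(segments$h_losses)
  } else {
    h <- sum(vapply(segments, `[[`, numeric(1L), "h_i")) -
      sum(vapply(segments, `[[`, numeric(1L), "h_losses"))
  }
  max(0, h)
}

#' Supportable colony count
#'
#' `N = floor(H / (H_colony + H_average))`, with the survival gate: when the
#' location cannot even feed one colony (`H < H_colony`) no colony should be
#' placed at all.
#'
#' @param H total collectible honey, kg
#' @param params a [model_params()]
#' @return integer colony count
#' @export
colony_count <- function(H, params = model_params()) {
  if (!is.numeric(H) || anyNA(H) || H < 0) stop("colony_count: H must be a non-negative number")
  if (H < params$H_colony) return(0L)
  as.integer(floor(H / (params$H_colony + params$H_average)))
}

#' Evaluate a candidate apiary location
#'
#' Runs the full model at a site: every field is clipped to the flight
#' circle; each non-empty segment gets its availability coefficient `C3` from
#' the straight flight line to its representative point (1 / 0.7 / 0.5 for
#' no / country-only / main-road crossings), its road-proximity areas `S2`,
#' its yield and its losses; totals give the honey estimate `H` and colony
#' count `N`.
#'
#' @param map a [semantic_map()] whose fields all carry c1/c2 coefficients
#' @param site apiary location `c(x, y)` in the map's input units (multiplied
#'   by `extent$scale` internally)
#' @param params a [model_params()]
#' @param include_segments keep the per-segment audit table in the result
#' @return a `site_result`: list with `x`, `y` (input units), `on_road`,
#'   `honey` (kg), `hives` (integer) and optionally `segments`
#' @export
evaluate_location <- function(map, site, params = model_params(),
                              include_segments = FALSE) {
  stopifnot(inherits(map, "semantic_map"), inherits(params, "model_params"))
  site <- as.numeric(site)
  if (length(site) != 2L || anyNA(site)) stop("evaluate_location: site must be c(x, y)")
  s <- map$extent$scale
  site_m <- site * s
  W <- map$extent$width; H <- map$extent$height
  if (site_m[1L] < 0 || site_m[1L] > W || site_m[2L] < 0 || site_m[2L] > H) {
    stop("evaluate_location: site outside the map extent")
  }
  on_road <- FALSE
  for (r in map$roads) {
    if (dist_points_polyline(site_m[1L], site_m[2L], r$points) <= 1e-6) {
      on_road <- TRUE
      break
    }
  }

  area <- flight_area(site_m, params$radius)
  circle <- circle_polygon(site_m[1L], site_m[2L], params$radius)
  rows <- list()
  for (f in map$fields) {
    if (is.na(f$c1) || is.na(f$c2)) {
      stop("evaluate_location: field '", f$id, "' has unassigned coefficients; ",
           "run assign_field_coefficients() first")
    }
    clip <- clip_to_flight_area(f, area, circle = circle)
    if (clip$s_pot <= 1e-9) next
    rep_pt <- representative_point(clip$geometry)
    c3 <- crossing_class(site_m, rep_pt, map$roads)
    c_f <- field_coefficient(f$c1, f$c2)
    s2 <- numeric(0)
    if (c_f > 0) {
      for (r in map$roads) {
        a <- road_proximity_area(clip$geometry, r)
        if (a > 0) s2[r$id] <- a
      }
    }
    seg <- list(field_id = f$id, s_pot = clip$s_pot, c_f = c_f, c3 = c3,
                s2_by_road = s2)
    seg$h_i <- segment_yield(seg, params)
    seg$h_losses <- if (length(s2)) segment_losses(seg, map$roads, params) else 0
    rows[[length(rows) + 1L]] <- seg
  }

  honey <- total_honey(rows)
  res <- list(x = site[1L], y = site[2L], on_road = on_road,
              honey = honey, hives = colony_count(honey, params))
  if (include_segments) {
    res$segments <- data.frame(
      field_id = vapply(rows, `[[`, character(1L), "field_id"),
      s_pot = vapply(rows, `[[`, numeric(1L), "s_pot"),
      c_f = vapply(rows, `[[`, numeric(1L), "c_f"),
      c3 = vapply(rows, `[[`, numeric(1L), "c3"),
      s2 = vapply(rows, function(x) sum(x$s2_by_road), numeric(1L)),
      h_i = vapply(rows, `[[`, numeric(1L), "h_i"),
      h_losses = vapply(rows, `[[`, numeric(1L), "h_losses"))
  }
  structure(res, class = "site_result")
}

#' @export
print.site_result <- function(x, ...) {
  cat(site_result_json(x), "\n")
  invisible(x)
}

#' Serialize a site result as JSON
#'
#' Produces the interchange object with exactly the keys
#' `{"x", "y", "onRoad", "honey", "hives"}`; honey is rounded to two
#' decimals in the output (full precision is kept internally).
#'
#' @param result a `site_result` from [evaluate_location()]
#' @return a JSON string
#' @export
site_result_json <- function(result) {
  stopifnot(inherits(result, "site_result"))
  as.character(jsonlite::toJSON(
    list(x = result$x, y = result$y, onRoad = result$on_road,
         honey = round(result$honey, 2), hives = as.integer(result$hives)),
    auto_unbox = TRUE, digits = NA))
}
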