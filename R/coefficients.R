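# Coefficient layers: seeded random assignment of field coefficients and the
# deterministic road-class mapping.

#' Coefficient sets
#'
#' The enumerated sets the layer coefficients are drawn from, and the road
#' class mappings.  Defaults: c1 in \{0.2, 0.4, 0.6, 0.8, 1.0\} (nectar
#' productivity per hectare, 20–100 kg), c2 in \{-1, -0.5, 0\} (pesticide
#' contamination), c4 and corridor half-width by class (highway -0.5 / 500 m,
#' railroad -0.3 / 300 m, country -0.1 / 100 m).
#'
#' @param c1_set,c2_set numeric value sets for the field coefficients
#' @param c4_by_class,buffer_by_class named vectors over the road classes
#' @return a `coefficient_sets` object
#' @export
coefficient_sets <- function(c1_set = C1_SET, c2_set = C2_SET,
                             c4_by_class = C4_BY_CLASS,
                             buffer_by_class = BUFFER_BY_CLASS) {
  stopifnot(is.numeric(c1_set), is.numeric(c2_set))
  if (!all(ROAD_CLASSES %in% names(c4_by_class)) ||
      !all(ROAD_CLASSES %in% names(buffer_by_class))) {
    stop("coefficient_sets: c4_by_class and buffer_by_class must cover ",
         paste(ROAD_CLASSES, collapse = ", "))
  }
  structure(list(c1_set = c1_set, c2_set = c2_set,
                 c4_by_class = c4_by_class, buffer_by_class = buffer_by_class),
            class = "coefficient_sets")
}

# run code under a fixed, portable RNG state and restore the caller's state
with_rng <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  force(code)
}

#' Assign field coefficients by seeded uniform draws
#'
#' Draws c1 and c2 independently and uniformly from their sets
#' (Mersenne-Twister, explicit seed).  Draws are consumed in field-id sort
#' order, so the insertion order of fields never changes the outcome.  By
#' default only missing (`NA`) coefficients are filled — real coefficients
#' supplied in the annotation file are kept.
#'
#' @param map a [semantic_map()]
#' @param sets a [coefficient_sets()]
#' @param seed integer RNG seed
#' @param overwrite replace already-assigned coefficients too
#' @return the map with coefficients assigned
#' @export
assign_field_coefficients <- function(map, sets = coefficient_sets(), seed,
                                      overwrite = FALSE) {
  stopifnot(inherits(map, "semantic_map"), inherits(sets, "coefficient_sets"))
  n <- length(map$fields)
  if (!n) return(map)
  ids <- vapply(map$fields, `[[`, character(1L), "id")
  ord <- order(ids)
  draws <- with_rng(seed, list(
    c1 = sample(sets$c1_set, n, replace = TRUE),
    c2 = sample(sets$c2_set, n, replace = TRUE)))
  for (k in seq_len(n)) {
    i <- ord[k]
    if (overwrite || is.na(map$fields[[i]]$c1)) map$fields[[i]]$c1 <- draws$c1[k]
    if (overwrite || is.na(map$fields[[i]]$c2)) map$fields[[i]]$c2 <- draws$c2[k]
  }
  validate_map(map, c1_set = unique(c(sets$c1_set, C1_SET)),
               c2_set = unique(c(sets$c2_set, C2_SET)))
  map
}

#' Assign road coefficients from road class
#'
#' Pure function of `road_class`: sets `c4`, `buffer_width` and
#' `crossing_main` from the class mappings.
#'
#' @param map a [semantic_map()]
#' @param sets a [coefficient_sets()]
#' @return the map with road coefficients set
#' @export
assign_road_coefficients <- function(map, sets = coefficient_sets()) {
  stopifnot(inherits(map, "semantic_map"), inherits(sets, "coefficient_sets"))
  for (i in seq_along(map$roads)) {
    cls <- map$roads[[i]]$road_class
    if (!cls %in% names(sets$c4_by_class)) {
      stop("assign_road_coefficients: unknown road_class '", cls, "'")
    }
    map$roads[[i]]$c4 <- unname(sets$c4_by_class[cls])
    map$roads[[i]]$buffer_width <- unname(sets$buffer_by_class[cls])
    map$roads[[i]]$crossing_main <- cls %in% MAIN_CLASSES
  }
  map
}
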