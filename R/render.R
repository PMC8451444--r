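# Colour-encoded layer renderer (red -> green ramps, class-dependent road
# widths), matching the model's visual audit layers.

layer_names <- c("fields", "productivity", "pesticides", "roads", "partition", "flight")

ramp_colour <- function(v, lo, hi) {
  pal <- grDevices::colorRamp(c("#ff0000", "#00cc00"))
  t <- if (hi > lo) pmin(1, pmax(0, (v - lo) / (hi - lo))) else rep(1, length(v))
  rgb <- pal(t)
  grDevices::rgb(rgb[, 1L], rgb[, 2L], rgb[, 3L], maxColorValue = 255)
}

#' Render a map layer to a PNG image
#'
#' Layers: `fields` (uniform parcels), `productivity` (c1 ramp, bright green
#' at the highest value), `pesticides` (c2 ramp, bright green at zero
#' contamination), `roads` (class-dependent colour and width), `partition`
#' (regions between roads, active region highlighted when `site` is given),
#' `flight` (flight circle at `site`).
#'
#' @param map a [semantic_map()]
#' @param layer one of `r paste0('"', layer_names, '"', collapse = ", ")`
#' @param site optional apiary location `c(x, y)` in map input units
#' @param path output PNG path
#' @param radius flight radius in metres (for the `flight` layer)
#' @param width_px image width in pixels
#' @return `invisible(path)`
#' @export
render_layers <- function(map, layer, site = NULL, path, radius = 3000,
                          width_px = 800L) {
  stopifnot(inherits(map, "semantic_map"))
  if (!layer %in% layer_names) {
    stop("render_layers: unknown layer '", layer, "'; use one of ",
         paste(layer_names, collapse = ", "))
  }
  W <- map$extent$width; H <- map$extent$height
  site_m <- if (!is.null(site)) as.numeric(site) * map$extent$scale
  grDevices::png(path, width = width_px, height = round(width_px * H / W))
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(0, 0, 0, 0))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, W), ylim = c(0, H), asp = 1)
  graphics::rect(0, 0, W, H, col = "white", border = "grey40")

  if (layer %in% c("fields", "productivity", "pesticides", "flight")) {
    for (f in map$fields) {
      col <- switch(layer,
        fields = "#d9c87c",
        productivity = if (is.na(f$c1)) "grey80" else ramp_colour(f$c1, min(C1_SET), max(C1_SET)),
        pesticides = if (is.na(f$c2)) "grey80" else ramp_colour(f$c2, min(C2_SET), max(C2_SET)),
        flight = "#d9c87c")
      graphics::polygon(f$vertices[, 1L], f$vertices[, 2L], col = col, border = "grey30")
    }
  }
  if (layer %in% c("roads", "flight", "partition")) {
    for (r in map$roads) {
      col <- ramp_colour(r$c4, min(C4_BY_CLASS), max(C4_BY_CLASS))
      lwd <- c(highway = 4, railroad = 3, country = 1.5)[r$road_class]
      graphics::lines(r$points[, 1L], r$points[, 2L], col = col, lwd = lwd)
    }
  }
  if (layer == "partition") {
    part <- partition_by_roads(map, if (is.null(site_m)) c(W, H) / 2 else site_m)
    shade <- grDevices::hcl.colors(max(2L, length(part$regions)), "Pastel 1")
    for (i in seq_along(part$regions)) {
      col <- if (i == part$active_region_id) "#80d080" else shade[i]
      graphics::polygon(part$regions[[i]][, 1L], part$regions[[i]][, 2L],
                        col = grDevices::adjustcolor(col, 0.5), border = "grey40")
    }
  }
  if (layer == "flight" && !is.null(site_m)) {
    cp <- circle_polygon(site_m[1L], site_m[2L], radius, n = 360L)
    graphics::polygon(cp[, 1L], cp[, 2L],
                      col = grDevices::adjustcolor("#3050ff", 0.2), border = "#3050ff")
    graphics::points(site_m[1L], site_m[2L], pch = 19, col = "#3050ff")
  }
  invisible(path)
}
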