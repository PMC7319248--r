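#' Point-in-polygon test (ray casting)
#'
#' Vectorized even-odd rule; points exactly on an edge count as inside.
#'
#' @param lon,lat Point coordinates.
#' @param polygon Two-column matrix of polygon vertices (lon, lat); the ring
#'   need not be explicitly closed.
#' @return Logical vector.
#' @export
point_in_polygon <- function(lon, lat, polygon) {
  polygon <- as.matrix(polygon)
  if (nrow(polygon) < 3 || any(!is.finite(polygon)))
    stop("polygon must have at least 3 finite vertices")
  px <- polygon[, 1]; py <- polygon[, 2]
  if (px[1] != px[length(px)] || py[1] != py[length(py)]) {
    px <- c(px, px[1]); py <- c(py, py[1])
  }
  n <- length(px) - 1L
  inside <- rep(FALSE, length(lon))
  on_edge <- rep(FALSE, length(lon))
  for (i in seq_len(n)) {
    x1 <- px[i]; y1 <- py[i]; x2 <- px[i + 1L]; y2 <- py[i + 1L]
    crosses <- ((y1 > lat) != (y2 > lat))
    if (any(crosses)) {
      xint <- x1 + (lat - y1) / (y2 - y1) * (x2 - x1)
      flip <- crosses & (lon < xint)
      inside[flip] <- !inside[flip]
    }
    # on-segment check
    d <- abs((x2 - x1) * (lat - y1) - (y2 - y1) * (lon - x1))
    within <- lon >= pmin(x1, x2) - 1e-12 & lon <= pmax(x1, x2) + 1e-12 &
      lat >= pmin(y1, y2) - 1e-12 & lat <= pmax(y1, y2) + 1e-12
    on_edge <- on_edge | (d < 1e-9 & within)
  }
  inside | on_edge
}

#' Read / write a polygon as GeoJSON
#'
#' Minimal GeoJSON support for a single Polygon geometry (outer ring only),
#' optionally wrapped in a Feature / FeatureCollection.
#'
#' @param path File path.
#' @return Two-column matrix (lon, lat) of the outer ring.
#' @export
read_geojson_polygon <- function(path) {
  g <- jsonlite::read_json(path, simplifyVector = TRUE)
  geom <- g
  if (identical(g$type, "FeatureCollection")) geom <- g$features$geometry
  if (!is.null(geom$type) && identical(unlist(geom$type)[1], "Feature"))
    geom <- geom$geometry
  coords <- geom$coordinates
  if (is.list(coords)) coords <- coords[[1]]
  if (is.array(coords) && length(dim(coords)) == 3) coords <- coords[1, , ]
  m <- matrix(as.numeric(coords), ncol = 2)
  colnames(m) <- c("lon", "lat")
  m
}

#' @rdname read_geojson_polygon
#' @param polygon Two-column matrix (lon, lat).
#' @param properties Named list of Feature properties (e.g. name, area_km2).
#' @export
write_geojson_polygon <- function(polygon, path, properties = list()) {
  polygon <- as.matrix(polygon)
  if (polygon[1, 1] != polygon[nrow(polygon), 1] ||
      polygon[1, 2] != polygon[nrow(polygon), 2])
    polygon <- rbind(polygon, polygon[1, ])
  ring <- lapply(seq_len(nrow(polygon)), function(i) c(polygon[i, 1], polygon[i, 2]))
  feat <- list(type = "Feature",
               properties = properties,
               geometry = list(type = "Polygon", coordinates = list(ring)))
  jsonlite::write_json(list(type = "FeatureCollection", features = list(feat)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# great-circle-free planar km sizes of a 0.1 degree cell at given latitude
KM_PER_DEG <- 111.32

#' Area of grid cells (km^2), cos-latitude weighted
#'
#' @param lat Cell-center latitudes (degrees).
#' @param spacing Grid spacing in degrees (default 0.1).
#' @return Cell areas in km^2 for each latitude.
#' @export
cell_area_km2 <- function(lat, spacing = 0.1) {
  (KM_PER_DEG * spacing)^2 * cos(lat * pi / 180)
}
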