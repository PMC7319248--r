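#' Detection table: effective strip width and trackline detection by Beaufort
#'
#' Builds a per-species table of effective strip half-width (ESW, km) and
#' trackline detection probability g(0) indexed by Beaufort sea state.
#' Published coefficient models exist for the California Current species;
#' this package ships a synthetic fixture with plausible monotone values
#' (see [detection_fixture()]) and users supply real tables as CSV via
#' [read_detection_csv()].
#'
#' @param species Character vector.
#' @param beaufort Integer Beaufort states.
#' @param esw_km ESW in km, 0 < esw <= truncation.
#' @param g0 Trackline detection probability in (0, 1].
#' @param truncation_km Perpendicular truncation distance w (km).
#' @return A `data.frame` of class `detection_table`.
#' @export
detection_table <- function(species, beaufort, esw_km, g0, truncation_km = 5.5) {
  tab <- data.frame(species = as.character(species),
                    beaufort = as.integer(beaufort),
                    esw_km = as.numeric(esw_km),
                    g0 = as.numeric(g0))
  if (any(tab$esw_km <= 0 | tab$esw_km > truncation_km))
    stop("ESW must satisfy 0 < ESW <= truncation distance")
  if (any(tab$g0 <= 0 | tab$g0 > 1)) stop("g(0) must be in (0, 1]")
  for (sp in unique(tab$species)) {
    sub <- tab[tab$species == sp, ]
    sub <- sub[order(sub$beaufort), ]
    if (is.unsorted(rev(sub$esw_km)) && any(diff(sub$esw_km) > 1e-12))
      stop("ESW must be non-increasing in Beaufort for species ", sp)
    if (any(diff(sub$g0) > 1e-12))
      stop("g(0) must be non-increasing in Beaufort for species ", sp)
  }
  attr(tab, "truncation_km") <- truncation_km
  class(tab) <- c("detection_table", "data.frame")
  tab
}

#' Synthetic single-species detection fixture
#'
#' Plausible monotone ESW / g(0) values over Beaufort 0-6 for a generic
#' delphinid-like species. These are synthetic placeholders, not published
#' coefficient values.
#'
#' @param species Species name used in the table.
#' @param truncation_km Truncation distance (km).
#' @return A [detection_table()].
#' @export
detection_fixture <- function(species = "sim_delphinid", truncation_km = 5.5) {
  detection_table(
    species = species,
    beaufort = 0:6,
    esw_km = c(3.0, 2.8, 2.5, 2.1, 1.7, 1.3, 0.9),
    g0 = c(0.95, 0.92, 0.88, 0.82, 0.74, 0.65, 0.50),
    truncation_km = truncation_km
  )
}

#' Read / write detection tables as CSV
#'
#' CSV columns: species, beaufort, esw_km, g0.
#'
#' @param path File path.
#' @param truncation_km Truncation distance for validation.
#' @return [detection_table()] (reader) or `path` invisibly (writer).
#' @export
read_detection_csv <- function(path, truncation_km = 5.5) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "beaufort", "esw_km", "g0")
  if (!all(need %in% names(d)))
    stop("detection CSV must have columns: ", paste(need, collapse = ", "))
  detection_table(d$species, d$beaufort, d$esw_km, d$g0, truncation_km)
}

#' @rdname read_detection_csv
#' @param table A `detection_table`.
#' @export
write_detection_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Effective area searched of an effort segment
#'
#' A = 2 * L * ESW * g(0): the detection-corrected area sampled by a
#' segment of length L with effective strip half-width ESW and trackline
#' detection probability g(0). Vectorized.
#'
#' @param L_km Segment length (km), >= 0.
#' @param esw_km Effective strip half-width (km), > 0.
#' @param g0 Trackline detection probability in (0, 1].
#' @return Effective area in km^2.
#' @export
effective_area <- function(L_km, esw_km, g0) {
  if (any(L_km < 0)) stop("segment length must be non-negative")
  if (any(esw_km <= 0)) stop("ESW must be positive")
  if (any(g0 <= 0 | g0 > 1)) stop("g(0) must be in (0, 1]")
  2 * L_km * esw_km * g0
}

#' Line-transect density on a segment
#'
#' D = n * s / A: animals per km^2 from the number of sightings n, mean
#' group size s and effective area searched A. Returns 0 where n = 0.
#'
#' @param n Number of sightings (groups) on the segment.
#' @param s Mean group size (ignored where n = 0).
#' @param A Effective area searched (km^2), > 0.
#' @return Density in animals per km^2.
#' @export
segment_density <- function(n, s, A) {
  if (any(n < 0)) stop("sighting count must be non-negative")
  if (any(A <= 0)) stop("effective area must be positive")
  s <- ifelse(n > 0, s, 0)
  if (any(n > 0 & s < 1)) stop("mean group size must be >= 1 where n > 0")
  n * s / A
}

#' Attach detection parameters and effective areas to segments
#'
#' Looks up ESW and g(0) for each segment's Beaufort state and populates
#' `esw`, `g0` and `area_km2 = 2 * length_km * esw * g0`.
#'
#' @param segments Segment data frame (see [segment_effort()]).
#' @param table A [detection_table()].
#' @param species Species whose rows of `table` to use; defaults to the
#'   single species present in the table.
#' @return `segments` with `esw`, `g0`, `area_km2` populated.
#' @export
apply_detection <- function(segments, table, species = NULL) {
  if (is.null(species)) {
    species <- unique(table$species)
    if (length(species) != 1L)
      stop("table has several species; supply `species`")
  }
  tab <- table[table$species == species, ]
  if (nrow(tab) == 0L) stop("species not found in detection table: ", species)
  idx <- match(segments$beaufort, tab$beaufort)
  if (anyNA(idx))
    stop("detection table is missing Beaufort state(s): ",
         paste(sort(unique(segments$beaufort[is.na(idx)])), collapse = ", "))
  segments$esw <- tab$esw_km[idx]
  segments$g0 <- tab$g0[idx]
  segments$area_km2 <- effective_area(segments$length_km, segments$esw, segments$g0)
  segments
}
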