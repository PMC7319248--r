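#' Construct a gridded prediction surface
#'
#' @param lon,lat Cell-center coordinate vectors.
#' @param values Matrix \[lat, lon\] of cell values (density in animals per
#'   km^2 or presence probability); masked cells are NA.
#' @param units `"animals_km2"` or `"probability"`.
#' @param date A `Date` or the string `"average"`.
#' @param depth Optional depth matrix \[lat, lon\] (positive m downward),
#'   used for isobath-based strata.
#' @param spacing Grid spacing (degrees).
#' @return Object of class `prediction_surface` carrying cos-latitude
#'   weighted cell areas.
#' @export
prediction_surface <- function(lon, lat, values, units = "animals_km2",
                               date = "average", depth = NULL,
                               spacing = 0.1) {
  values <- as.matrix(values)
  if (nrow(values) != length(lat) || ncol(values) != length(lon))
    stop("values must be a [lat, lon] matrix")
  if (any(values < 0, na.rm = TRUE)) stop("surface values must be >= 0")
  if (units == "probability" && any(values > 1, na.rm = TRUE))
    stop("probability surfaces must be <= 1")
  area <- matrix(cell_area_km2(lat, spacing), length(lat), length(lon))
  structure(list(lon = lon, lat = lat, values = values, units = units,
                 date = date, depth = depth, area_km2 = area,
                 spacing = spacing),
            class = "prediction_surface")
}

surface_grid_df <- function(env, day_index) {
  g <- expand.grid(lat = env$lat, lon = env$lon, KEEP.OUT.ATTRS = FALSE)
  d <- day_index
  g$sst <- as.vector(env$sst[, , d]); g$sst_sd <- as.vector(env$sst_sd[, , d])
  ssh <- as.vector(env$ssh[, , d])
  if (env$ssh_source[d] == "nrt") ssh <- ssh + env$ssh_offset_m
  g$ssh <- ssh
  g$ssh_sd <- as.vector(env$ssh_sd[, , d]); g$mld <- as.vector(env$mld[, , d])
  g$depth <- as.vector(env$depth)
  g$year <- env$year[d]
  g
}

#' Daily prediction composite
#'
#' Evaluates a fitted model cell-wise on one day's covariates. Density
#' models use a 1-km^2 reference effective area so the value is animals
#' per km^2; presence models yield probabilities. Two-stage density uses
#' `group_fit`.
#'
#' @param fit A `cetsdm_fit` or `brt_fit`.
#' @param env An `env_grid`.
#' @param date Day to predict (must be present in `env`).
#' @param group_fit Optional group-size `cetsdm_fit` for encounter-rate
#'   models.
#' @return A [prediction_surface()].
#' @export
predict_daily <- function(fit, env, date, group_fit = NULL) {
  d <- match(as.Date(date), env$dates)
  if (is.na(d)) stop("date absent from environmental grid: ", date)
  g <- surface_grid_df(env, d)
  vals <- if (inherits(fit, "brt_fit")) {
    predict(fit, g)
  } else if (fit$spec$response %in% c("individuals", "encounter_rate")) {
    predict_density(fit, group_fit, g)
  } else {
    predict(fit, g)
  }
  units <- if (inherits(fit, "brt_fit") ||
               (inherits(fit, "cetsdm_fit") && fit$spec$response == "presence"))
    "probability" else "animals_km2"
  prediction_surface(env$lon, env$lat,
                     matrix(vals, length(env$lat), length(env$lon)),
                     units = units, date = env$dates[d], depth = env$depth,
                     spacing = env$spacing)
}

check_same_grid <- function(surfaces) {
  ref <- surfaces[[1]]
  for (s in surfaces[-1]) {
    if (!identical(s$lon, ref$lon) || !identical(s$lat, ref$lat))
      stop("surfaces are on different grids")
  }
  ref
}

#' Multiyear (multi-day) average surface
#'
#' Cell-wise arithmetic mean of daily composites, the long-term expected
#' pattern over the conditions sampled.
#'
#' @param surfaces List of [prediction_surface()]s on one grid.
#' @return A [prediction_surface()] with date `"average"`.
#' @export
multiyear_average <- function(surfaces) {
  if (length(surfaces) < 1) stop("need at least one surface")
  ref <- check_same_grid(surfaces)
  stack <- simplify2array(lapply(surfaces, `[[`, "values"))
  avg <- apply(stack, c(1, 2), mean)
  prediction_surface(ref$lon, ref$lat, avg, units = ref$units,
                     date = "average", depth = ref$depth,
                     spacing = ref$spacing)
}

#' Lognormal confidence surfaces from daily composites
#'
#' Per cell, the CV of the multi-day mean is computed from the temporal
#' variability of the daily surfaces (`sd / (sqrt(n) * mean)`, the
#' distance-sampling convention for the CV of an estimate; set
#' `cv = "daily"` for the raw temporal CV `sd / mean`). The interval is
#' `mean / C` to `mean * C` with `C = exp(z * sqrt(log(1 + CV^2)))` and `z`
#' the two-sided normal quantile of the level (1.645 at 0.90). Cells with
#' zero mean get a degenerate (0, 0) interval.
#'
#' @param surfaces List of >= 2 daily [prediction_surface()]s.
#' @param level Confidence level (default 0.90).
#' @param cv `"mean"` (default) or `"daily"`.
#' @return List with `mean`, `low`, `high` surfaces and the `factor` matrix
#'   C.
#' @export
lognormal_ci <- function(surfaces, level = 0.90, cv = c("mean", "daily")) {
  cv <- match.arg(cv)
  if (length(surfaces) < 2) stop("need at least two daily surfaces")
  ref <- check_same_grid(surfaces)
  stack <- simplify2array(lapply(surfaces, `[[`, "values"))
  n <- length(surfaces)
  m <- apply(stack, c(1, 2), mean)
  s <- apply(stack, c(1, 2), stats::sd)
  cv_val <- ifelse(m > 0, s / m, 0)
  if (cv == "mean") cv_val <- cv_val / sqrt(n)
  z <- stats::qnorm(1 - (1 - level) / 2)
  C <- exp(z * sqrt(log(1 + cv_val^2)))
  low <- ifelse(m > 0, m / C, 0)
  high <- ifelse(m > 0, m * C, 0)
  units <- ref$units
  mk <- function(v) prediction_surface(ref$lon, ref$lat, v, units = units,
                                       date = "average", depth = ref$depth,
                                       spacing = ref$spacing)
  list(mean = mk(m), low = mk(low), high = mk(pmin(high, if (units == "probability") 1 else Inf)),
       factor = C)
}

#' Lognormal interval factor for a given CV
#'
#' `C = exp(z * sqrt(log(1 + CV^2)))`; the interval is mean/C to mean*C.
#'
#' @param cv Coefficient of variation.
#' @param level Confidence level.
#' @return The multiplicative factor C.
#' @export
lognormal_ci_factor <- function(cv, level = 0.90) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  exp(z * sqrt(log(1 + cv^2)))
}

#' Clip a surface to the study area
#'
#' Masks (sets to NA) every cell whose center falls outside the polygon,
#' so predictions are never extrapolated outside the modeled region.
#'
#' @param surface A [prediction_surface()].
#' @param polygon Two-column (lon, lat) matrix, or a GeoJSON path.
#' @return The clipped surface.
#' @export
clip_to_study_area <- function(surface, polygon) {
  if (is.character(polygon)) polygon <- read_geojson_polygon(polygon)
  grid <- expand.grid(lat = surface$lat, lon = surface$lon,
                      KEEP.OUT.ATTRS = FALSE)
  inside <- point_in_polygon(grid$lon, grid$lat, polygon)
  if (!any(inside)) stop("polygon does not intersect the surface grid")
  mask <- matrix(inside, length(surface$lat), length(surface$lon))
  surface$values[!mask] <- NA
  surface
}

#' Equal-numbered (quantile) binning of a surface
#'
#' Classifies unmasked cells into `n_bins` classes of near-equal cell
#' counts based on value quantiles, the display convention used to compare
#' surfaces across model types. Monotone transforms of the values leave
#' the binning unchanged.
#'
#' @param surface A [prediction_surface()].
#' @param n_bins Number of bins (default 8).
#' @return List with `bins` (integer matrix, NA where masked) and `edges`.
#' @export
equal_numbered_bins <- function(surface, n_bins = 8) {
  v <- surface$values
  ok <- !is.na(v)
  u <- unique(v[ok])
  if (length(u) < n_bins) {
    warning("fewer distinct values than bins; using ", max(1, length(u)), " bin(s)")
    n_bins <- max(1, length(u))
  }
  edges <- unique(stats::quantile(v[ok], probs = seq(0, 1, length.out = n_bins + 1),
                                  names = FALSE, type = 7))
  bins <- matrix(NA_integer_, nrow(v), ncol(v))
  if (length(edges) < 2) {
    bins[ok] <- 1L
  } else {
    bins[ok] <- as.integer(cut(v[ok], breaks = edges, include.lowest = TRUE))
  }
  list(bins = bins, edges = edges)
}

#' Total abundance of a density surface over a stratum
#'
#' Sums density times cos-latitude-weighted cell area over the cells whose
#' centers fall in the stratum (a latitude band with an inshore/offshore
#' side of the isobath split; see [make_strata()]).
#'
#' @param surface A density [prediction_surface()] with a depth field.
#' @param stratum One row of a [make_strata()] table, or NULL for the whole
#'   surface.
#' @return Abundance in animals.
#' @export
stratum_abundance <- function(surface, stratum = NULL) {
  v <- surface$values
  keep <- !is.na(v)
  if (!is.null(stratum)) {
    if (is.null(surface$depth)) stop("surface carries no depth field")
    latm <- matrix(surface$lat, length(surface$lat), length(surface$lon))
    memb <- latm >= stratum$lat_min & latm < stratum$lat_max &
      stratum_depth_side(surface$depth, stratum)
    keep <- keep & memb
    if (!any(keep)) {
      warning("stratum has no unmasked cells: ", stratum$name)
      return(0)
    }
  }
  sum(v[keep] * surface$area_km2[keep])
}

#' Write a prediction surface as long-format CSV
#'
#' Columns: time, lat, lon, value (NA rows for masked cells retained).
#'
#' @param surface A [prediction_surface()].
#' @param path Output path.
#' @export
write_surface_csv <- function(surface, path) {
  g <- expand.grid(lat = surface$lat, lon = surface$lon,
                   KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(time = as.character(surface$date), lat = g$lat,
                    lon = g$lon, value = as.vector(surface$values),
                    units = surface$units)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
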