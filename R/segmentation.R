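#' Cut continuous effort into approximate target-length segments
#'
#' Each continuous effort run of length L is split into
#' `k = max(1, round(L / target_length_km))` equal-length segments, so
#' segment lengths within a run are identical and total effort length is
#' conserved exactly. Segment midpoint position, date and modal Beaufort
#' (ties resolved to the higher, detection-conservative state) are carried
#' from the track steps.
#'
#' @param track Track data.frame from [simulate_survey()] (columns run_id,
#'   step, along_km, lon, lat, date, year, beaufort, step_km).
#' @param target_length_km Target segment length (km, default 5).
#' @return data.frame of segment skeletons: id, run_id, date, year, lat,
#'   lon, length_km, beaufort, along_start, along_end.
#' @export
segment_effort <- function(track, target_length_km = 5) {
  if (target_length_km <= 0) stop("target length must be positive")
  out <- list(); id <- 0L
  for (rid in unique(track$run_id)) {
    run <- track[track$run_id == rid, ]
    run <- run[order(run$step), ]
    L <- sum(run$step_km)
    if (L <= 0) { warning("zero-length run skipped: ", rid); next }
    k <- max(1L, round(L / target_length_km))
    seg_len <- L / k
    bounds <- seq(0, L, length.out = k + 1L)
    for (j in seq_len(k)) {
      id <- id + 1L
      mid <- (bounds[j] + bounds[j + 1L]) / 2
      inseg <- run$along_km > bounds[j] & run$along_km <= bounds[j + 1L] + 1e-9
      stepmid <- run[which.min(abs(run$along_km - mid)), ]
      bft <- modal_beaufort(run$beaufort[inseg])
      out[[id]] <- data.frame(
        id = id, run_id = rid, date = stepmid$date, year = stepmid$year,
        lat = stepmid$lat, lon = stepmid$lon, length_km = seg_len,
        beaufort = bft, along_start = bounds[j], along_end = bounds[j + 1L])
    }
  }
  if (length(out) == 0) stop("no usable effort runs")
  segs <- do.call(rbind, out)
  rownames(segs) <- NULL
  segs
}

# modal state; ties broken towards the higher (worse-detection) state
modal_beaufort <- function(b) {
  if (length(b) == 0) return(NA_integer_)
  tb <- table(b)
  as.integer(max(as.integer(names(tb)[tb == max(tb)])))
}

#' Retain segments at or below a maximum Beaufort state
#'
#' Sea states above the cutoff carry too little detection power; the
#' standard filter keeps Beaufort <= 5.
#'
#' @param segments Segment data.frame.
#' @param max_state Highest retained modal Beaufort (default 5).
#' @return Filtered segments.
#' @export
filter_beaufort <- function(segments, max_state = 5) {
  keep <- segments$beaufort <= max_state
  if (!any(keep)) warning("no segments remain after the Beaufort filter")
  segments[keep, , drop = FALSE]
}

#' Assign sightings to segments with perpendicular truncation
#'
#' Sightings beyond the truncation distance are discarded. Each surviving
#' sighting is assigned to exactly one segment: by along-track containment
#' when the sightings carry `run_id`/`along_km`, otherwise to the nearest
#' segment midpoint on the same date. Populates the sighting count `n_sight`
#' and mean recorded group size `mean_group` (NA where `n_sight` = 0).
#'
#' @param segments Segment data.frame (skeletons from [segment_effort()]).
#' @param sightings Sighting data.frame with `perp_km` and `size_best`.
#' @param truncation_km Perpendicular truncation distance (km, default 5.5).
#' @return Segments with `n_sight` and `mean_group` columns.
#' @export
assign_sightings <- function(segments, sightings, truncation_km = 5.5) {
  segments$n_sight <- 0L
  segments$mean_group <- NA_real_
  if (nrow(sightings) == 0) return(segments)
  keep <- sightings$perp_km <= truncation_km & sightings$perp_km >= 0
  sightings <- sightings[keep, , drop = FALSE]
  if (nrow(sightings) == 0) return(segments)

  by_run <- !is.null(sightings$run_id) && !is.null(sightings$along_km) &&
    !is.null(segments$run_id)
  sizes <- vector("list", nrow(segments))
  dropped <- 0L
  for (i in seq_len(nrow(sightings))) {
    s <- sightings[i, ]
    if (by_run) {
      cand <- which(segments$run_id == s$run_id &
                      s$along_km > segments$along_start - 1e-9 &
                      s$along_km <= segments$along_end + 1e-9)
    } else {
      cand <- which(segments$date == s$date)
      if (length(cand)) {
        dd <- (segments$lat[cand] - s$lat)^2 + (segments$lon[cand] - s$lon)^2
        cand <- cand[which.min(dd)]
      }
    }
    if (length(cand) == 0) { dropped <- dropped + 1L; next }
    j <- cand[1]
    segments$n_sight[j] <- segments$n_sight[j] + 1L
    sizes[[j]] <- c(sizes[[j]], s$size_best)
  }
  if (dropped > 0)
    warning(dropped, " sighting(s) had no eligible segment and were dropped")
  has <- segments$n_sight > 0
  segments$mean_group[has] <- vapply(sizes[has], mean, numeric(1))
  segments
}

#' Attach midpoint environmental covariates to segments
#'
#' Covariates are read from the grid cell containing each segment midpoint
#' on the segment's date (nearest cell center, no interpolation). SSH from
#' days flagged as the near-real-time source receives `+ssh_offset_m` to
#' harmonize it with the reanalysis reference level.
#'
#' @param segments Segment data.frame with lat, lon, date.
#' @param env An `env_grid`.
#' @param ssh_offset_m Harmonization offset added to near-real-time SSH
#'   (m, default +0.035).
#' @return Segments with sst, sst_sd, ssh, ssh_sd, mld, depth columns.
#' @export
sample_covariates <- function(segments, env, ssh_offset_m = 0.035) {
  cov <- tryCatch(
    env_lookup(env, segments$lon, segments$lat, segments$date),
    error = function(e) stop("covariate sampling failed: ", conditionMessage(e)))
  cov$ssh <- cov$ssh + ifelse(cov$ssh_source == "nrt", ssh_offset_m, 0)
  for (v in c("sst", "sst_sd", "ssh", "ssh_sd", "mld", "depth"))
    segments[[v]] <- cov[[v]]
  segments
}

#' Read / write the segment table as CSV
#'
#' One row per modeling segment with columns id, date, year, lat, lon,
#' length_km, beaufort, sst, sst_sd, ssh, ssh_sd, mld, depth, n_sight,
#' mean_group, esw, g0, area_km2 (ISO-8601 dates).
#'
#' @param segments Segment data.frame.
#' @param path File path.
#' @export
write_segments_csv <- function(segments, path) {
  cols <- c("id", "date", "year", "lat", "lon", "length_km", "beaufort",
            "sst", "sst_sd", "ssh", "ssh_sd", "mld", "depth",
            "n_sight", "mean_group", "esw", "g0", "area_km2")
  out <- segments[, intersect(cols, names(segments)), drop = FALSE]
  out$date <- format(as.Date(out$date))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_segments_csv
#' @export
read_segments_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$date <- as.Date(d$date)
  d
}
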