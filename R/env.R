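#' Generate daily gridded environmental fields
#'
#' Builds a regular 0.1-degree grid of daily dynamic ocean covariates with
#' the statistical structure the downstream models assume: sea surface
#' temperature (SST) with a latitudinal gradient plus seeded smooth spatial
#' noise, its 3 x 3-box standard deviation (sdSST), sea surface height (SSH)
#' and sdSSH, a smooth positive mixed-layer depth (MLD), and a static depth
#' field increasing offshore (positive metres downward). Optional "heatwave"
#' days receive a uniform positive SST anomaly plus a poleward shift of the
#' isotherms (so the warm anomaly is at least `anomaly_c` everywhere).
#'
#' Two SSH sources are emulated: days whose year is in `nrt_years` are
#' flagged as coming from a near-real-time system whose reference level sits
#' `ssh_offset_m` below the reanalysis; [sample_covariates()] harmonizes
#' them by adding the offset back.
#'
#' @param extent Numeric `c(lon_min, lon_max, lat_min, lat_max)` in degrees;
#'   must span at least 5 x 5 cells (3 x 3 sd boxes need >= 3 x 3).
#' @param n_days Number of days (ignored when `dates` is given).
#' @param heatwave_days Integer indices into the dates, or a `Date` vector,
#'   marking heatwave days.
#' @param seed Integer seed; fields are bit-identical for a fixed seed.
#' @param dates Optional `Date` vector (possibly spanning several years).
#' @param start_date First day when `dates` is not supplied.
#' @param anomaly_c Heatwave SST anomaly (degrees C, default +2).
#' @param shift_deg Poleward isotherm displacement on heatwave days (degrees
#'   latitude).
#' @param sst_south SST at the southern edge (degrees C).
#' @param sst_gradient SST decrease per degree latitude northward.
#' @param nrt_years Integer years whose SSH comes from the near-real-time
#'   source.
#' @param ssh_offset_m Reference-level discrepancy between the two SSH
#'   sources (m).
#' @param spacing Grid spacing in degrees.
#' @return An object of class `env_grid`: cell-center `lon`/`lat` vectors,
#'   `dates`, `year`, `ssh_source`, `heatwave` per day, static `depth`
#'   matrix \[lat, lon\] and daily arrays \[lat, lon, day\] `sst`, `sst_sd`,
#'   `ssh`, `ssh_sd`, `mld`.
#' @export
make_env_fields <- function(extent, n_days = 1, heatwave_days = integer(0),
                            seed = 1, dates = NULL,
                            start_date = as.Date("1996-08-01"),
                            anomaly_c = 2, shift_deg = 1,
                            sst_south = 21, sst_gradient = 0.5,
                            nrt_years = integer(0), ssh_offset_m = 0.035,
                            spacing = 0.1) {
  if (length(extent) != 4) stop("extent must be c(lon_min, lon_max, lat_min, lat_max)")
  lon <- seq(extent[1] + spacing / 2, extent[2] - spacing / 2, by = spacing)
  lat <- seq(extent[3] + spacing / 2, extent[4] - spacing / 2, by = spacing)
  if (length(lon) < 3 || length(lat) < 3)
    stop("extent smaller than 3 x 3 cells: 3 x 3 sd boxes undefined")
  if (length(lon) < 5 || length(lat) < 5)
    stop("extent must span at least 5 x 5 cells")
  if (is.null(dates)) {
    if (n_days < 1) stop("n_days must be >= 1")
    dates <- start_date + seq_len(n_days) - 1
  }
  nd <- length(dates)
  hw <- rep(FALSE, nd)
  if (inherits(heatwave_days, "Date")) {
    hw[dates %in% heatwave_days] <- TRUE
  } else if (length(heatwave_days)) {
    hw[as.integer(heatwave_days)] <- TRUE
  }
  ny <- length(lat); nx <- length(lon)
  year <- as.integer(format(dates, "%Y"))

  set.seed(seed)
  # static depth: shallow at the eastern (coastal) edge, deep offshore
  dist_coast <- outer(rep(1, ny), (extent[2] - lon)) # degrees west of coast
  depth <- 15 + 4200 * (1 - exp(-dist_coast / 1.1)) +
    400 * smooth_field(ny, nx)
  depth <- pmax(depth, 5)

  sst <- sst_sd <- ssh <- ssh_sd <- mld <- array(0, c(ny, nx, nd))
  lat_m <- matrix(lat, ny, nx)
  # draw all noise first so heatwave flags never perturb the RNG stream
  noise_sst <- lapply(seq_len(nd), function(d) smooth_field(ny, nx))
  noise_ssh <- lapply(seq_len(nd), function(d) smooth_field(ny, nx))
  noise_mld <- lapply(seq_len(nd), function(d) smooth_field(ny, nx))
  ssh_source <- ifelse(year %in% nrt_years, "nrt", "reanalysis")
  for (d in seq_len(nd)) {
    shift <- if (hw[d]) shift_deg else 0
    base <- sst_south - sst_gradient * (lat_m - shift - extent[3]) +
      if (hw[d]) anomaly_c else 0
    sst[, , d] <- base + 0.9 * noise_sst[[d]]
    ssh_true <- 0.05 * (lat_m - mean(lat)) / max(1, diff(range(lat))) +
      0.06 * noise_ssh[[d]]
    ssh[, , d] <- ssh_true - if (ssh_source[d] == "nrt") ssh_offset_m else 0
    mld[, , d] <- pmax(exp(log(30) + 0.04 * (lat_m - extent[3]) +
                             0.35 * noise_mld[[d]]), 1)
    sst_sd[, , d] <- neighborhood_sd(sst[, , d])
    ssh_sd[, , d] <- neighborhood_sd(ssh[, , d])
  }
  structure(list(lon = lon, lat = lat, dates = dates, year = year,
                 ssh_source = ssh_source, heatwave = hw, depth = depth,
                 sst = sst, sst_sd = sst_sd, ssh = ssh, ssh_sd = ssh_sd,
                 mld = mld, spacing = spacing,
                 ssh_offset_m = ssh_offset_m),
            class = "env_grid")
}

# seeded smooth spatial noise: white noise blurred by a separable
# moving-average kernel, rescaled to unit sd
smooth_field <- function(ny, nx, passes = 3) {
  z <- matrix(stats::rnorm(ny * nx), ny, nx)
  k <- rep(1 / 5, 5)
  for (p in seq_len(passes)) {
    z <- apply(z, 2, blur1d, k = k)
    z <- t(apply(z, 1, blur1d, k = k))
  }
  s <- stats::sd(as.vector(z))
  if (s > 0) z / s else z
}

blur1d <- function(v, k) {
  half <- (length(k) - 1) / 2
  vp <- c(rev(v[seq_len(half)]), v, rev(v[length(v) - seq_len(half) + 1]))
  as.numeric(stats::filter(vp, k, sides = 2))[half + seq_along(v)]
}

# per-cell sample sd over the 3x3 neighborhood (truncated at edges)
neighborhood_sd <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  s <- s2 <- cnt <- matrix(0, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    yi <- seq_len(ny) + dy
    xi <- seq_len(nx) + dx
    yok <- yi >= 1 & yi <= ny
    xok <- xi >= 1 & xi <= nx
    s[yok, xok] <- s[yok, xok] + m[yi[yok], xi[xok]]
    s2[yok, xok] <- s2[yok, xok] + m[yi[yok], xi[xok]]^2
    cnt[yok, xok] <- cnt[yok, xok] + 1
  }
  v <- (s2 - s^2 / cnt) / (cnt - 1)
  sqrt(pmax(v, 0))
}

#' Look up environmental covariates at points
#'
#' Nearest-cell-center lookup (no interpolation, matching the grid's native
#' resolution). SSH is returned as stored, i.e. without inter-source
#' harmonization; see [sample_covariates()].
#'
#' @param env An `env_grid`.
#' @param lon,lat Point coordinates (degrees).
#' @param date A single `Date` or vector matching `lon`.
#' @return data.frame with sst, sst_sd, ssh, ssh_sd, mld, depth, lat, lon,
#'   year and the day's ssh_source.
#' @export
env_lookup <- function(env, lon, lat, date) {
  n <- length(lon)
  date <- rep(as.Date(date), length.out = n)
  di <- match(date, env$dates)
  if (anyNA(di)) stop("date(s) absent from environmental grid: ",
                      paste(unique(date[is.na(di)]), collapse = ", "))
  half <- env$spacing / 2 + 1e-9
  xi <- vapply(lon, function(p) which.min(abs(env$lon - p)), integer(1))
  yi <- vapply(lat, function(p) which.min(abs(env$lat - p)), integer(1))
  bad <- abs(env$lon[xi] - lon) > half | abs(env$lat[yi] - lat) > half
  if (any(bad))
    stop("point(s) outside environmental grid: index ",
         paste(which(bad), collapse = ", "))
  idx <- cbind(yi, xi, di)
  out <- data.frame(
    sst = env$sst[idx], sst_sd = env$sst_sd[idx], ssh = env$ssh[idx],
    ssh_sd = env$ssh_sd[idx], mld = env$mld[idx],
    depth = env$depth[cbind(yi, xi)],
    lat = env$lat[yi], lon = env$lon[xi],
    year = env$year[di], ssh_source = env$ssh_source[di],
    stringsAsFactors = FALSE
  )
  if (anyNA(out$depth)) stop("point(s) on land-masked cell: index ",
                             paste(which(is.na(out$depth)), collapse = ", "))
  out
}

#' Write an environmental grid as long-format CSV
#'
#' Columns follow CF-style naming: time (ISO-8601), lat, lon, then one
#' column per variable (sst, sst_sd, ssh, ssh_sd, mld, depth).
#'
#' @param env An `env_grid`.
#' @param path Output path.
#' @export
write_env_csv <- function(env, path) {
  nd <- length(env$dates)
  grid <- expand.grid(lat = env$lat, lon = env$lon, time = env$dates,
                      KEEP.OUT.ATTRS = FALSE)
  out <- data.frame(time = format(grid$time), lat = grid$lat, lon = grid$lon,
                    sst = as.vector(env$sst), sst_sd = as.vector(env$sst_sd),
                    ssh = as.vector(env$ssh), ssh_sd = as.vector(env$ssh_sd),
                    mld = as.vector(env$mld),
                    depth = rep(as.vector(env$depth), nd))
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}
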