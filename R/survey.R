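#' Define a line-transect survey design
#'
#' @param waypoints List of transects, each a two-column matrix of
#'   (lon, lat) waypoints traversed in order.
#' @param speed_kmh Ship speed (km/hr; systematic cetacean surveys run
#'   near 18 km/hr).
#' @param hours_per_day Daily effort hours.
#' @param beaufort_init Initial Beaufort state.
#' @param beaufort_transition 7 x 7 row-stochastic matrix over states 0-6
#'   (first-order Markov chain along the track); states 6+ are produced and
#'   filtered downstream by [filter_beaufort()].
#' @param n_observers Number of independent group-size estimators.
#' @param truncation_km Perpendicular truncation distance w (km).
#' @param target_segment_km Target modeling segment length (km).
#' @param step_km Track discretization step (km).
#' @param start_date First survey day.
#' @return Object of class `survey_design`.
#' @export
survey_design <- function(waypoints, speed_kmh = 18, hours_per_day = 10,
                          beaufort_init = 2,
                          beaufort_transition = default_beaufort_transition(),
                          n_observers = 3, truncation_km = 5.5,
                          target_segment_km = 5, step_km = 1,
                          start_date = as.Date("1996-08-01")) {
  if (truncation_km <= 0) stop("truncation distance must be positive")
  if (target_segment_km <= 0) stop("target segment length must be positive")
  stopifnot(is.list(waypoints), length(waypoints) >= 1)
  structure(list(waypoints = waypoints, speed_kmh = speed_kmh,
                 hours_per_day = hours_per_day,
                 beaufort_init = beaufort_init,
                 beaufort_transition = beaufort_transition,
                 n_observers = n_observers, truncation_km = truncation_km,
                 target_segment_km = target_segment_km, step_km = step_km,
                 start_date = start_date),
            class = "survey_design")
}

#' Default Beaufort transition matrix
#'
#' Sticky tridiagonal chain over states 0-6: stay with probability 0.8,
#' move one state up/down with 0.1 each (reflected at the ends).
#'
#' @return 7 x 7 row-stochastic matrix.
#' @export
default_beaufort_transition <- function() {
  P <- matrix(0, 7, 7, dimnames = list(0:6, 0:6))
  for (i in 1:7) {
    P[i, i] <- 0.8
    if (i > 1) P[i, i - 1] <- 0.1 else P[i, i] <- P[i, i] + 0.1
    if (i < 7) P[i, i + 1] <- 0.1 else P[i, i] <- P[i, i] + 0.1
  }
  P
}

#' Parallel zig-zag transect waypoints over an extent
#'
#' Convenience generator of north-south-stacked east-west transect lines,
#' the systematic-grid layout of shipboard cetacean surveys.
#'
#' @param extent `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param n_transects Number of east-west lines.
#' @param inset Degrees to keep clear of the extent edge.
#' @return List of two-row waypoint matrices.
#' @export
grid_transects <- function(extent, n_transects = 10, inset = 0.15) {
  lats <- seq(extent[3] + inset, extent[4] - inset, length.out = n_transects)
  lapply(seq_along(lats), function(i) {
    lo <- c(extent[1] + inset, extent[2] - inset)
    if (i %% 2 == 0) lo <- rev(lo)
    cbind(lon = lo, lat = c(lats[i], lats[i]))
  })
}

#' Simulate a line-transect survey over an environmental grid
#'
#' Discretizes the design's transects into `step_km` steps, evolves
#' Beaufort as a Markov chain along the track, and generates detected
#' sightings from the species' inhomogeneous Poisson group process thinned
#' by Beaufort-dependent detection: the expected number of groups detected
#' within the truncation distance on a step of length dL is
#' `lambda * 2 * ESW(bft) * g0(bft) * dL`. Perpendicular distances are
#' drawn from a half-normal detection curve whose scale is solved so its
#' integral to the truncation distance equals the tabulated ESW; a tail of
#' beyond-truncation detections (out to 1.5 w) is also generated so the
#' truncation filter is exercised.
#'
#' @param env An `env_grid`.
#' @param truth A [species_truth()].
#' @param design A [survey_design()].
#' @param detection A [detection_table()] covering every Beaufort state the
#'   design can produce.
#' @param seed Integer seed (reproducible for fixed seed).
#' @param group_noise_sd Absolute sd of a single observer's group-size
#'   estimate (the magnitude of multi-observer estimation error is a free
#'   simulation parameter).
#' @return List with `track` (one row per step: run_id, step, lon, lat,
#'   date, year, beaufort, step_km) and `sightings` (one row per detected
#'   group).
#' @export
simulate_survey <- function(env, truth, design, detection, seed = 1,
                            group_noise_sd = 1) {
  set.seed(seed)
  track <- build_track(design, env)
  if (nrow(track) == 0) stop("empty survey track")
  track$beaufort <- simulate_beaufort(nrow(track), design$beaufort_init,
                                      design$beaufort_transition)
  cov <- env_lookup(env, track$lon, track$lat, track$date)
  lambda <- truth_intensity(truth, cov)

  sp <- unique(detection$species)[1]
  tab <- detection[detection$species == sp, ]
  need <- sort(unique(track$beaufort))
  if (!all(need %in% tab$beaufort))
    stop("detection table must cover Beaufort states: ",
         paste(setdiff(need, tab$beaufort), collapse = ", "))
  w <- design$truncation_km
  sigma <- vapply(tab$esw_km, halfnormal_scale, numeric(1), w = w)
  names(sigma) <- tab$beaufort

  di <- match(track$beaufort, tab$beaufort)
  esw <- tab$esw_km[di]; g0 <- tab$g0[di]; sig <- sigma[di]
  # within-truncation and tail expectations per step
  mu_in <- lambda * 2 * esw * g0 * track$step_km
  p_tail <- (stats::pnorm(1.5 * w / sig) - stats::pnorm(w / sig)) *
    sqrt(2 * pi) * sig
  mu_out <- lambda * 2 * p_tail * g0 * track$step_km

  n_in <- stats::rpois(nrow(track), mu_in)
  n_out <- stats::rpois(nrow(track), mu_out)
  rows <- rep(seq_len(nrow(track)), n_in + n_out)
  if (length(rows) == 0) {
    sightings <- empty_sightings(sp)
  } else {
    in_trunc <- rep(rep(c(TRUE, FALSE), nrow(track)),
                    as.vector(rbind(n_in, n_out)))
    s_sig <- sig[rows]
    lo <- ifelse(in_trunc, 0, w)
    hi <- ifelse(in_trunc, w, 1.5 * w)
    u <- stats::runif(length(rows), stats::pnorm(lo / s_sig),
                      stats::pnorm(hi / s_sig))
    perp <- stats::qnorm(u) * s_sig
    tlat <- track$lat[rows]
    true_size <- pmax(1, round(stats::rlnorm(length(rows),
                                             truth_group_meanlog(truth, tlat,
                                               track$year[rows]),
                                             truth$group_sdlog)))
    size_best <- vapply(true_size, observe_group_size, numeric(1),
                        n_observers = design$n_observers,
                        noise_sd = group_noise_sd)
    sightings <- data.frame(
      species = sp, run_id = track$run_id[rows],
      along_km = track$along_km[rows],
      lon = track$lon[rows], lat = tlat,
      date = track$date[rows], year = track$year[rows],
      perp_km = perp, true_size = true_size, size_best = size_best,
      beaufort = track$beaufort[rows], stringsAsFactors = FALSE)
  }
  list(track = track, sightings = sightings)
}

empty_sightings <- function(sp) {
  data.frame(species = character(0), run_id = integer(0),
             along_km = numeric(0), lon = numeric(0), lat = numeric(0),
             date = as.Date(character(0)), year = integer(0),
             perp_km = numeric(0), true_size = numeric(0),
             size_best = numeric(0), beaufort = integer(0),
             stringsAsFactors = FALSE)
}

# half-normal scale sigma such that integral_0^w exp(-x^2 / 2 sigma^2) = esw
halfnormal_scale <- function(esw, w) {
  if (esw >= w) return(1e6) # effectively uniform detection to w
  f <- function(s) sqrt(2 * pi) * s * (stats::pnorm(w / s) - 0.5) - esw
  stats::uniroot(f, c(1e-3, 100 * w), tol = 1e-10)$root
}

# discretize transects into steps; a run = one transect traversed within
# one calendar day (runs break at transect ends and at day boundaries)
build_track <- function(design, env) {
  km_day <- design$speed_kmh * design$hours_per_day
  step <- design$step_km
  out <- list(); run <- 0L; day_i <- 1L; km_today <- 0
  nd <- length(env$dates)
  for (tr in design$waypoints) {
    pts <- transect_steps(tr, step)
    if (nrow(pts) == 0) next
    i <- 1L
    while (i <= nrow(pts)) {
      if (km_today >= km_day) { # next survey day
        day_i <- day_i + 1L
        km_today <- 0
        if (day_i > nd) break
      }
      take <- min(nrow(pts) - i + 1L, floor((km_day - km_today) / step))
      if (take <= 0) { km_today <- km_day; next }
      run <- run + 1L
      blk <- pts[i:(i + take - 1L), , drop = FALSE]
      out[[run]] <- data.frame(
        run_id = run, step = seq_len(take),
        along_km = (seq_len(take) - 0.5) * step,
        lon = blk[, 1], lat = blk[, 2],
        date = env$dates[day_i], year = env$year[day_i],
        step_km = step)
      km_today <- km_today + take * step
      i <- i + take
    }
    if (day_i > nd) break
  }
  if (length(out) == 0) return(data.frame())
  do.call(rbind, out)
}

# midpoints of step_km-long steps along a waypoint polyline (planar degrees)
transect_steps <- function(waypoints, step_km) {
  pts <- list()
  for (i in seq_len(nrow(waypoints) - 1)) {
    p1 <- waypoints[i, ]; p2 <- waypoints[i + 1, ]
    mid_lat <- (p1[2] + p2[2]) / 2
    dx <- (p2[1] - p1[1]) * KM_PER_DEG * cos(mid_lat * pi / 180)
    dy <- (p2[2] - p1[2]) * KM_PER_DEG
    len <- sqrt(dx^2 + dy^2)
    n <- floor(len / step_km)
    if (n < 1) next
    f <- (seq_len(n) - 0.5) * step_km / len
    pts[[i]] <- cbind(p1[1] + f * (p2[1] - p1[1]), p1[2] + f * (p2[2] - p1[2]))
  }
  if (length(pts) == 0) return(matrix(numeric(0), 0, 2))
  do.call(rbind, pts)
}

simulate_beaufort <- function(n, init, P) {
  states <- 0:6
  s <- integer(n)
  cur <- match(init, states)
  for (i in seq_len(n)) {
    cur <- sample.int(7, 1, prob = P[cur, ])
    s[i] <- states[cur]
  }
  s
}

#' Write simulated effort and sightings as CSV
#'
#' Effort columns: run_id, step, along_km, lon, lat, date (ISO-8601),
#' year, beaufort, step_km. Sighting columns: species, run_id, along_km,
#' lon, lat, date, year, perp_km, true_size, size_best, beaufort.
#'
#' @param track,sightings Components of a [simulate_survey()] result.
#' @param path Output path.
#' @export
write_effort_csv <- function(track, path) {
  track$date <- format(as.Date(track$date))
  utils::write.csv(track, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_effort_csv
#' @export
write_sightings_csv <- function(sightings, path) {
  sightings$date <- format(as.Date(sightings$date))
  utils::write.csv(sightings, path, row.names = FALSE)
  invisible(path)
}

#' Multi-observer group-size estimate
#'
#' Averages `n_observers` independent noisy "best" estimates of the true
#' group size; the recorded value is floored at 1.
#'
#' @param true_size True group size (>= 1).
#' @param n_observers Number of observers (>= 1).
#' @param noise_sd Absolute sd of a single observer's estimate (>= 0).
#' @param seed Optional seed for a standalone reproducible draw.
#' @return Recorded (averaged) group size.
#' @export
observe_group_size <- function(true_size, n_observers = 3, noise_sd = 1,
                               seed = NULL) {
  if (true_size < 1) stop("true group size must be >= 1")
  if (n_observers < 1) stop("need at least one observer")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  est <- true_size + stats::rnorm(n_observers, 0, noise_sd)
  max(1, mean(est))
}
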