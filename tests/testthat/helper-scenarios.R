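# Shared simulation scenarios built in code (no stored fixtures).

# detection table with identical ESW / g(0) at every Beaufort state
flat_detection <- function(esw = 2, g0 = 0.8, species = "sp",
                           truncation_km = 5.5) {
  detection_table(species, 0:6, rep(esw, 7), rep(g0, 7),
                  truncation_km = truncation_km)
}

august_dates <- function(years, days_per_year) {
  as.Date(unlist(lapply(years, function(y)
    as.character(as.Date(sprintf("%d-08-01", y)) + seq_len(days_per_year) - 1))))
}

# multiyear survey over a coastal domain; returns env, truth and the full
# segment table (segmented, filtered, truncated, covariate-sampled,
# detection-corrected)
sim_case <- function(seed, years = c(1996, 2001), days_per_year = 10,
                     extent = c(-126, -122, 34, 40), lambda0 = 0.01,
                     sst_slope = 0.25, sst_ref = 18, group_meanlog = log(8),
                     group_sdlog = 0.6, n_transects = 10,
                     heatwave_years = NULL, anomaly_c = 2,
                     year_trend = NULL, group_size_trend = NULL,
                     det = detection_fixture("sp")) {
  dates <- august_dates(years, days_per_year)
  hw <- as.Date(character(0))
  for (y in heatwave_years)
    hw <- c(hw, dates[format(dates, "%Y") == as.character(y)])
  env <- make_env_fields(extent, dates = dates, heatwave_days = hw,
                         seed = seed, anomaly_c = anomaly_c)
  terms <- if (sst_slope != 0)
    list(resp_monotone("sst", sst_slope, ref = sst_ref)) else list()
  truth <- species_truth("sp", lambda0, terms = terms,
                         group_meanlog = group_meanlog,
                         group_sdlog = group_sdlog,
                         year_trend = year_trend,
                         group_size_trend = group_size_trend)
  segs <- suppressWarnings(simulate_survey_years(
    env, truth, det, list(n_transects = n_transects, step_km = 1,
                          target_segment_km = 5), years, seed = seed + 7))
  list(env = env, truth = truth, det = det, segments = segs)
}

# synthetic segment table without the survey machinery (fast model tests)
synthetic_segments <- function(n, seed, lambda = 0.02, area = NULL,
                               meansize = 8) {
  set.seed(seed)
  area <- if (is.null(area)) runif(n, 10, 24) else rep(area, length.out = n)
  segs <- data.frame(
    id = seq_len(n), year = 1996L,
    lat = runif(n, 34, 40), lon = runif(n, -126, -122),
    length_km = 5, beaufort = sample(0:5, n, TRUE),
    sst = runif(n, 12, 22), sst_sd = abs(rnorm(n, 0.4, 0.1)),
    ssh = rnorm(n, 0, 0.05), ssh_sd = abs(rnorm(n, 0.02, 0.01)),
    mld = exp(rnorm(n, log(30), 0.3)), depth = runif(n, 50, 4500),
    area_km2 = area)
  segs$n_sight <- rpois(n, lambda * segs$area_km2)
  segs$mean_group <- ifelse(segs$n_sight > 0,
                            pmax(1, round(rlnorm(n, log(meansize), 0.4))), NA)
  segs
}

# track made of synthetic continuous runs with given lengths (1-km steps,
# fractional remainder as a shorter final step is avoided by using the
# exact step length)
synthetic_track <- function(run_lengths_km, beaufort = 2,
                            date = as.Date("1996-08-01")) {
  out <- list()
  for (i in seq_along(run_lengths_km)) {
    L <- run_lengths_km[i]
    n <- max(1, round(L))
    step <- L / n
    out[[i]] <- data.frame(
      run_id = i, step = seq_len(n), along_km = (seq_len(n) - 0.5) * step,
      lon = -124 + (seq_len(n) - 0.5) * step / 111.32, lat = 36,
      date = date, year = 1996L, step_km = step,
      beaufort = rep(beaufort, length.out = n))
  }
  do.call(rbind, out)
}

surface_grid_df_test <- function(env, d) cetsdm:::surface_grid_df(env, d)
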