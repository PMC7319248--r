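test_that("multi-observer group sizes average and floor correctly", {
  expect_equal(observe_group_size(15, n_observers = 4, noise_sd = 0), 15)
  expect_equal(observe_group_size(1, noise_sd = 0), 1)
  set.seed(1)
  rec <- replicate(50, observe_group_size(1, n_observers = 2, noise_sd = 10))
  expect_true(all(rec >= 1)) # floored at 1 despite large negative noise
  expect_error(observe_group_size(10, noise_sd = -1), "non-negative")
  expect_error(observe_group_size(0.5), ">= 1")
  expect_error(observe_group_size(10, n_observers = 0), "observer")
})

test_that("segment group counts are Poisson with mean lambda * A", {
  # constant intensity 0.1 groups/km2, flat detection ESW 2 km, g0 0.8:
  # a 5-km segment searches A = 16 km2, so counts ~ Poisson(1.6)
  ext <- c(-126, -121, 34, 40)
  env <- make_env_fields(ext, n_days = 1, seed = 21)
  truth <- species_truth("sp", 0.1)
  det <- flat_detection(esw = 2, g0 = 0.8)
  # one long survey day covering a dense transect grid
  des <- survey_design(grid_transects(ext, 60), hours_per_day = 1e5,
                       start_date = env$dates[1])
  sim <- simulate_survey(env, truth, des, det, seed = 22)
  segs <- segment_effort(sim$track, 5)
  segs <- assign_sightings(segs, sim$sightings, 5.5)
  n_seg <- nrow(segs)
  expect_gt(n_seg, 4000)
  se <- sqrt(1.6 / n_seg)
  expect_lt(abs(mean(segs$n_sight) - 1.6), 3 * se)
  expect_gt(var(segs$n_sight) / mean(segs$n_sight), 0.9) # Poisson-like
})

test_that("detected totals match the line-integral thinning oracle", {
  ext <- c(-126, -122, 34, 40)
  env <- make_env_fields(ext, n_days = 2, seed = 31)
  truth <- species_truth("sp", 0.05,
                         terms = list(resp_monotone("sst", 0.2, ref = 18)))
  det <- detection_fixture("sp")
  des <- survey_design(grid_transects(ext, 12), start_date = env$dates[1])
  sim <- simulate_survey(env, truth, des, det, seed = 32)
  # oracle: numerical line integral of lambda * 2 * ESW(bft) * g0(bft) dL
  cov <- env_lookup(env, sim$track$lon, sim$track$lat, sim$track$date)
  lam <- truth_intensity(truth, cov)
  i <- match(sim$track$beaufort, det$beaufort)
  expected <- sum(lam * 2 * det$esw_km[i] * det$g0[i] * sim$track$step_km)
  observed <- sum(sim$sightings$perp_km <= 5.5)
  expect_lt(abs(observed - expected), 3 * sqrt(expected))
})

test_that("zero intensity yields zero sightings; empty tracks error", {
  ext <- c(-126, -122, 34, 40)
  env <- make_env_fields(ext, n_days = 1, seed = 41)
  des <- survey_design(grid_transects(ext, 3), start_date = env$dates[1])
  sim <- simulate_survey(env, species_truth("sp", 0), des,
                         detection_fixture("sp"), seed = 42)
  expect_equal(nrow(sim$sightings), 0)
  # waypoints shorter than one step -> no track
  tiny <- survey_design(list(cbind(c(-124, -124.001), c(36, 36))),
                        start_date = env$dates[1])
  expect_error(simulate_survey(env, species_truth("sp", 0.1), tiny,
                               detection_fixture("sp")), "empty")
})

test_that("survey simulation is reproducible for a fixed seed", {
  ext <- c(-126, -122, 34, 40)
  env <- make_env_fields(ext, n_days = 1, seed = 51)
  des <- survey_design(grid_transects(ext, 5), start_date = env$dates[1])
  truth <- species_truth("sp", 0.05)
  s1 <- simulate_survey(env, truth, des, detection_fixture("sp"), seed = 52)
  s2 <- simulate_survey(env, truth, des, detection_fixture("sp"), seed = 52)
  expect_identical(s1$track, s2$track)
  expect_identical(s1$sightings, s2$sightings)
})

test_that("effort and sightings write as documented CSV", {
  ext <- c(-126, -122, 34, 40)
  env <- make_env_fields(ext, n_days = 1, seed = 81)
  des <- survey_design(grid_transects(ext, 4), start_date = env$dates[1])
  sim <- simulate_survey(env, species_truth("sp", 0.05), des,
                         detection_fixture("sp"), seed = 82)
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_effort_csv(sim$track, p1)
  write_sightings_csv(sim$sightings, p2)
  eff <- read.csv(p1); sgt <- read.csv(p2)
  expect_equal(nrow(eff), nrow(sim$track))
  expect_true(all(c("run_id", "along_km", "beaufort") %in% names(eff)))
  expect_equal(nrow(sgt), nrow(sim$sightings))
  expect_true(all(c("perp_km", "size_best") %in% names(sgt)))
})

test_that("detection table must cover the simulated Beaufort states", {
  ext <- c(-126, -122, 34, 40)
  env <- make_env_fields(ext, n_days = 1, seed = 61)
  des <- survey_design(grid_transects(ext, 5), start_date = env$dates[1])
  short_tab <- detection_table("sp", 0:3, c(3, 2.5, 2, 1.5),
                               c(0.9, 0.85, 0.8, 0.75))
  expect_error(simulate_survey(env, species_truth("sp", 0.05), des,
                               short_tab, seed = 62), "cover Beaufort")
})

test_that("a heatwave shifts warm-affinity peak intensity poleward", {
  ext <- c(-126, -122, 34, 40)
  env <- make_env_fields(ext, n_days = 2, heatwave_days = 2, seed = 71)
  truth <- species_truth("sp", 0.05,
                         terms = list(resp_unimodal("sst", opt = 19, width = 1)))
  grid1 <- surface_grid_df_test(env, 1)
  grid2 <- surface_grid_df_test(env, 2)
  lam1 <- truth_intensity(truth, grid1)
  lam2 <- truth_intensity(truth, grid2)
  peak_lat <- function(lam, g) sum(g$lat * lam) / sum(lam)
  expect_gt(peak_lat(lam2, grid2), peak_lat(lam1, grid1))
})
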