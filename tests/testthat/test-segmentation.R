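test_that("runs split into k = max(1, round(L/target)) equal segments", {
  segs5 <- segment_effort(synthetic_track(5), 5)
  expect_equal(nrow(segs5), 1)
  expect_equal(segs5$length_km, 5.0)

  segs12 <- segment_effort(synthetic_track(12), 5)
  expect_equal(nrow(segs12), 2)
  expect_equal(segs12$length_km, c(6.0, 6.0))

  segs2 <- segment_effort(synthetic_track(2), 5)
  expect_equal(nrow(segs2), 1)
  expect_equal(segs2$length_km, 2.0)
})

test_that("segmentation conserves total effort length", {
  set.seed(8)
  lens <- runif(20, 1, 30)
  track <- synthetic_track(lens)
  segs <- segment_effort(track, 5)
  expect_lt(abs(sum(segs$length_km) - sum(track$step_km)), 1e-9)
  # per run too
  for (r in unique(segs$run_id)) {
    expect_lt(abs(sum(segs$length_km[segs$run_id == r]) -
                    sum(track$step_km[track$run_id == r])), 1e-9)
  }
})

test_that("segmentation is deterministic (no hidden randomness)", {
  track <- synthetic_track(c(7, 13, 22), beaufort = 3)
  expect_identical(segment_effort(track, 5), segment_effort(track, 5))
})

test_that("modal Beaufort breaks ties towards the higher state", {
  expect_equal(cetsdm:::modal_beaufort(c(2, 2, 4, 4)), 4L)
  expect_equal(cetsdm:::modal_beaufort(c(1, 1, 1, 5)), 1L)
})

test_that("the Beaufort filter keeps only states <= 5", {
  segs <- data.frame(id = 1:3, beaufort = c(3, 5, 6))
  kept <- filter_beaufort(segs)
  expect_equal(kept$beaufort, c(3, 5))
  expect_identical(filter_beaufort(segs[1:2, ]), segs[1:2, ])
  expect_warning(out <- filter_beaufort(data.frame(beaufort = c(6, 6))),
                 "no segments")
  expect_equal(nrow(out), 0)
})

test_that("sightings are truncated at 5.5 km and averaged per segment", {
  segs <- segment_effort(synthetic_track(10), 5) # two 5-km segments
  sight <- data.frame(run_id = 1, along_km = c(2, 3, 8, 4),
                      perp_km = c(1, 4.2, 0.5, 6.0),
                      size_best = c(10, 20, 7, 99),
                      lat = 36, lon = -124, date = as.Date("1996-08-01"))
  out <- assign_sightings(segs, sight, truncation_km = 5.5)
  expect_equal(out$n_sight, c(2L, 1L)) # the 6.0-km sighting is excluded
  expect_equal(out$mean_group, c(15, 7))
  # sighting conservation: within-truncation sightings all assigned once
  expect_equal(sum(out$n_sight), sum(sight$perp_km <= 5.5))

  none <- assign_sightings(segs, sight[0, , drop = FALSE])
  expect_equal(none$n_sight, c(0L, 0L))
  expect_true(all(is.na(none$mean_group)))
})

test_that("sightings with no eligible segment are dropped with a warning", {
  segs <- segment_effort(synthetic_track(10), 5)
  orphan <- data.frame(run_id = 9, along_km = 2, perp_km = 1, size_best = 5,
                       lat = 36, lon = -124, date = as.Date("1996-08-01"))
  expect_warning(out <- assign_sightings(segs, orphan), "dropped")
  expect_equal(sum(out$n_sight), 0)
})

test_that("midpoint covariates come from the containing cell and day", {
  env <- make_env_fields(c(-126, -122, 34, 40), n_days = 1, seed = 12)
  env$sst[] <- 15 # constant field
  segs <- data.frame(id = 1, lat = 36.07, lon = -124.42,
                     date = env$dates[1])
  out <- sample_covariates(segs, env)
  expect_equal(out$sst, 15)
  expect_equal(out$depth, env$depth[which.min(abs(env$lat - 36.07)),
                                    which.min(abs(env$lon + 124.42))])
  segs$lon <- -150
  expect_error(sample_covariates(segs, env), "outside")
})

test_that("near-real-time SSH is harmonized by +0.035 m", {
  env <- make_env_fields(c(-126, -122, 34, 40),
                         dates = august_dates(2014, 1), seed = 13,
                         nrt_years = 2014)
  env$ssh[] <- 0.100 # stored near-real-time value
  segs <- data.frame(id = 1, lat = 36, lon = -124, date = env$dates[1])
  out <- sample_covariates(segs, env)
  expect_equal(out$ssh, 0.135)
  # reanalysis days are untouched
  env2 <- make_env_fields(c(-126, -122, 34, 40),
                          dates = august_dates(1996, 1), seed = 13)
  env2$ssh[] <- 0.100
  segs$date <- env2$dates[1]
  out2 <- sample_covariates(segs, env2)
  expect_equal(out2$ssh, 0.100)
})

test_that("segment CSV round-trips the documented schema", {
  case <- sim_case(3, years = 1996, days_per_year = 3, n_transects = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_segments_csv(case$segments, path)
  back <- read_segments_csv(path)
  expect_equal(back$area_km2, case$segments$area_km2)
  expect_equal(back$date, case$segments$date)
  expect_true(all(c("sst", "ssh", "mld", "depth", "n_sight", "mean_group",
                    "esw", "g0") %in% names(back)))
})
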