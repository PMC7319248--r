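test_that("the 8-stratum layout is disjoint and exhaustive", {
  strata <- make_strata(seq(34, 40, length.out = 5), isobath_m = 2000)
  expect_equal(nrow(strata), 8L)
  set.seed(1)
  lat <- runif(500, 34, 39.999)
  depth <- runif(500, 10, 4500)
  memb <- sapply(seq_len(nrow(strata)), function(i) {
    st <- strata[i, ]
    lat >= st$lat_min & lat < st$lat_max & cetsdm:::stratum_depth_side(depth, st)
  })
  expect_true(all(rowSums(memb) == 1)) # every point in exactly one stratum
  expect_error(make_strata(c(34, 34)), "strictly increasing")
})

test_that("observed stratum values follow the Horvitz-Thompson ratio", {
  strata <- make_strata(c(34, 40), isobath_m = 2000) # one band, two zones
  segs <- data.frame(lat = rep(36, 4), depth = rep(3000, 4),
                     n_sight = c(2, 1, 0, 0), mean_group = c(10, 10, NA, NA),
                     area_km2 = c(8, 8, 10, 10))
  vals <- suppressWarnings(observed_stratum_values(segs, strata, "density"))
  expect_equal(unname(vals["band1_offshore"]), 30 / 36)
  # single-stratum arithmetic: sum(n*s) = 30 over A = 16 gives 1.875
  one <- data.frame(lat = 36, depth = 3000, n_sight = 2, mean_group = 15,
                    area_km2 = 16)
  expect_equal(unname(suppressWarnings(
    observed_stratum_values(one, strata, "density"))["band1_offshore"]), 1.875)
  # presence mode: 3 occupied of 12
  p <- data.frame(lat = rep(36, 12), depth = 3000,
                  n_sight = c(rep(1, 3), rep(0, 9)), mean_group = NA,
                  area_km2 = 10)
  expect_equal(unname(suppressWarnings(
    observed_stratum_values(p, strata, "presence_rate"))["band1_offshore"]), 0.25)
  # empty stratum flagged
  expect_warning(observed_stratum_values(one, strata, "density"), "without effort")
  # no sightings anywhere: zeros
  z <- p; z$n_sight <- 0L
  expect_equal(unname(suppressWarnings(
    observed_stratum_values(z, strata, "density"))["band1_offshore"]), 0)
})

test_that("evaluation reports tie the metric battery together", {
  segs <- synthetic_segments(600, seed = 2, lambda = 0.03)
  enc <- fit_count_model(segs, make_model_spec("encounter_rate", terms = "sst",
                                               tweedie_power = 1.2))
  grp <- fit_group_size_model(segs)
  d <- predict_density(enc, grp, segs)
  strata <- make_strata(seq(34, 40, length.out = 3), isobath_m = 2000)
  rep <- suppressWarnings(eval_report(segs, d, fit = enc, strata = strata,
                                      mode = "density"))
  expect_true(rep$auc >= 0 && rep$auc <= 1)
  expect_true(rep$tss >= -1 && rep$tss <= 1)
  expect_true(abs(rep$spearman$rho) <= 1)
  expect_equal(rep$obs_pred,
               sum(segs$n_sight * ifelse(segs$n_sight > 0, segs$mean_group, 0)) /
                 sum(d * segs$area_km2))
  path <- withr::local_tempfile(fileext = ".json")
  write_eval_report(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$auc, rep$auc)
  expect_equal(back$spearman_rho, rep$spearman$rho)
})

test_that("novel-year harness never leaks holdout segments into training", {
  case <- sim_case(5, years = c(1996, 2001, 2014), days_per_year = 6,
                   n_transects = 6)
  seen_train <- NULL
  builders <- list(probe = function(train) {
    seen_train <<- train
    list(fit = NULL, mode = "presence_rate",
         predict_seg = function(segs) rep(0.5, nrow(segs)))
  })
  out <- suppressWarnings(novel_year_cv(case$segments, case$env, 2014, builders))
  expect_false(any(seen_train$year == 2014))
  expect_false(any(seen_train$id %in%
                     case$segments$id[case$segments$year == 2014]))
  expect_named(out, "probe")
  expect_error(novel_year_cv(case$segments, case$env, 1888, builders),
               "absent")
})

test_that("stationary simulations calibrate the density model on holdout", {
  case <- sim_case(6, years = c(1996, 2001, 2005, 2014), days_per_year = 10,
                   lambda0 = 0.015, sst_slope = 0.25)
  cv <- suppressWarnings(novel_year_cv(
    case$segments, case$env, 2014,
    builders = list(density = density_builder(
      make_model_spec("encounter_rate", terms = "sst", tweedie_power = 1.2)))))
  expect_gt(cv$density$report$obs_pred, 0.8)
  expect_lt(cv$density$report$obs_pred, 1.25)
})

test_that("heatwave difference surfaces are positive in the poleward third", {
  case <- sim_case(7, years = c(1996, 2001, 2005, 2014), days_per_year = 8,
                   lambda0 = 0.012, sst_slope = 0.35,
                   heatwave_years = 2014, anomaly_c = 2.5)
  cv <- suppressWarnings(novel_year_cv(
    case$segments, case$env, 2014,
    builders = list(density = density_builder(
      make_model_spec("encounter_rate", terms = "sst", tweedie_power = 1.2))),
    n_surface_days = 3))
  diff <- cv$density$difference
  expect_false(is.null(diff))
  north <- diff$lat >= quantile(diff$lat, 2 / 3)
  expect_gt(mean(diff$values[north, ]), 0)
})
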