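tiny_env <- function(seed = 1, n_days = 2, hw = integer(0))
  make_env_fields(c(-126, -124, 34, 36), n_days = n_days,
                  heatwave_days = hw, seed = seed)

flat_surface <- function(value, env = tiny_env(), date = "average")
  prediction_surface(env$lon, env$lat,
                     matrix(value, length(env$lat), length(env$lon)),
                     date = date, depth = env$depth)

test_that("daily composites evaluate models cell-wise on that day", {
  env <- tiny_env(2)
  segs <- synthetic_segments(500, seed = 2, lambda = 0.04)
  const <- fit_count_model(segs, make_model_spec("individuals",
                                                 tweedie_power = 1.2))
  s0 <- predict_daily(const, env, env$dates[1])
  expect_equal(max(s0$values) - min(s0$values), 0, tolerance = 1e-12)

  sst_fit <- fit_count_model(segs, make_model_spec("individuals",
                                                   terms = "sst",
                                                   tweedie_power = 1.2))
  s1 <- predict_daily(sst_fit, env, env$dates[1])
  s2 <- predict_daily(sst_fit, env, env$dates[2])
  expect_false(identical(s1$values, s2$values))
  expect_true(all(s1$values >= 0))
  expect_error(predict_daily(const, env, as.Date("1900-01-01")), "absent")
})

test_that("multiyear averages are cell-wise means", {
  a <- flat_surface(0); b <- flat_surface(2)
  avg <- multiyear_average(list(a, b))
  expect_true(all(avg$values == 1))
  expect_equal(multiyear_average(list(a))$values, a$values)
  other <- prediction_surface(a$lon + 10, a$lat, a$values)
  expect_error(multiyear_average(list(a, other)), "different grids")
})

test_that("lognormal intervals collapse without temporal variance", {
  surfs <- replicate(4, flat_surface(0.3), simplify = FALSE)
  ci <- lognormal_ci(surfs)
  expect_equal(ci$low$values, ci$mean$values)
  expect_equal(ci$high$values, ci$mean$values)
  # zero-mean cells get a degenerate (0, 0) interval
  surfs0 <- replicate(3, flat_surface(0), simplify = FALSE)
  ci0 <- lognormal_ci(surfs0)
  expect_true(all(ci0$low$values == 0) && all(ci0$high$values == 0))
  expect_error(lognormal_ci(surfs[1]), "two")
})

test_that("the interval factor matches the lognormal quantile", {
  # CV = 0.5: C = exp(1.645 sqrt(ln 1.25)) ~ 2.175, the 95th lognormal
  # quantile of a unit-median lognormal with that CV
  sdl <- sqrt(log(1.25))
  expect_equal(lognormal_ci_factor(0.5, 0.90), qlnorm(0.95, 0, sdl),
               tolerance = 1e-12)
  expect_equal(lognormal_ci_factor(0.5, 0.90), 2.175, tolerance = 1e-3)
})

test_that("low <= mean <= high everywhere on stochastic surfaces", {
  set.seed(3)
  env <- tiny_env(3)
  nc <- length(env$lat) * length(env$lon)
  surfs <- lapply(1:5, function(i)
    prediction_surface(env$lon, env$lat,
                       matrix(rlnorm(nc, log(0.1), 0.4),
                              length(env$lat), length(env$lon))))
  ci <- lognormal_ci(surfs)
  expect_true(all(ci$low$values <= ci$mean$values + 1e-12))
  expect_true(all(ci$mean$values <= ci$high$values + 1e-12))
})

test_that("study-area clipping matches the analytic half-plane oracle", {
  s <- flat_surface(1)
  all_poly <- cbind(c(-130, -120, -120, -130), c(30, 30, 40, 40))
  expect_equal(clip_to_study_area(s, all_poly)$values, s$values)

  cut <- -124.95
  half <- cbind(c(-130, cut, cut, -130), c(30, 30, 40, 40))
  clipped <- clip_to_study_area(s, half)
  inside_oracle <- outer(rep(TRUE, length(s$lat)), s$lon <= cut, FUN = "&")
  expect_identical(!is.na(clipped$values), inside_oracle)

  expect_error(clip_to_study_area(s, cbind(c(-90, -91, -91), c(0, 0, 1))),
               "intersect")
  expect_error(clip_to_study_area(s, cbind(-124, 35)), "3 finite vertices")
})

test_that("masking commutes with averaging", {
  set.seed(4)
  env <- tiny_env(4)
  mk <- function() prediction_surface(env$lon, env$lat,
    matrix(runif(length(env$lat) * length(env$lon)), length(env$lat)))
  surfs <- list(mk(), mk(), mk())
  half <- cbind(c(-130, -124.95, -124.95, -130), c(30, 30, 40, 40))
  a <- clip_to_study_area(multiyear_average(surfs), half)
  b <- multiyear_average(lapply(surfs, clip_to_study_area, polygon = half))
  expect_equal(a$values, b$values)
})

test_that("equal-numbered bins have near-equal counts and rank invariance", {
  set.seed(5)
  v <- matrix(runif(800), 20, 40)
  s <- prediction_surface(seq(-126, -122.1, by = 0.1), seq(34.05, 35.95, by = 0.1), v)
  bb <- equal_numbered_bins(s, 8)
  counts <- table(bb$bins)
  expect_equal(length(counts), 8L)
  expect_true(max(counts) - min(counts) <= 2)
  s2 <- s; s2$values <- s$values^2 # monotone transform
  expect_identical(equal_numbered_bins(s2, 8)$bins, bb$bins)
  sc <- s; sc$values[] <- 0.7
  expect_warning(one <- equal_numbered_bins(sc, 8), "fewer distinct")
  expect_true(all(one$bins == 1))
})

test_that("stratum abundance integrates density over cell areas", {
  env <- tiny_env(6)
  s <- flat_surface(0.01, env)
  total <- stratum_abundance(s)
  expect_equal(total, 0.01 * sum(s$area_km2))
  # doubling density doubles abundance; zero surface gives zero
  s2 <- s; s2$values <- s$values * 2
  expect_equal(stratum_abundance(s2), 2 * total)
  expect_equal(stratum_abundance(flat_surface(0, env)), 0)
  # uniform density over one stratum equals density x stratum area
  strata <- make_strata(c(34, 35, 36), isobath_m = 2000)
  st <- strata[strata$name == "band1_offshore", ]
  memb <- outer(env$lat >= 34 & env$lat < 35, rep(TRUE, length(env$lon))) &
    env$depth > 2000
  expect_equal(stratum_abundance(s, st), 0.01 * sum(s$area_km2[memb]))
})
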