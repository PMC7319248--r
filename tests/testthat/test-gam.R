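test_that("forced near-Poisson Tweedie matches an independent Poisson GLM", {
  segs <- synthetic_segments(600, seed = 1, lambda = 0.03)
  spec <- make_model_spec("encounter_rate", tweedie_power = 1.01)
  fit <- fit_count_model(segs, spec)
  ref <- glm(n_sight ~ 1 + offset(log(area_km2)), family = poisson(),
             data = segs)
  expect_equal(unname(coef(fit$model)), unname(coef(ref)), tolerance = 5e-4)
})

test_that("intercept-only count models are offset-calibrated", {
  segs <- synthetic_segments(1500, seed = 2, lambda = 0.025)
  fit <- fit_count_model(segs, make_model_spec("encounter_rate"))
  pred_total <- sum(predict(fit, segs) * segs$area_km2)
  expect_lt(abs(pred_total / sum(segs$n_sight) - 1), 0.01)
  expect_true(fit$tweedie_power > 1 && fit$tweedie_power < 2)
})

test_that("degenerate count responses are rejected", {
  segs <- synthetic_segments(100, seed = 3, lambda = 0)
  expect_error(fit_count_model(segs, make_model_spec("encounter_rate")),
               "all-zero")
  segs$area_km2[1] <- 0
  expect_error(fit_count_model(segs, make_model_spec("encounter_rate")),
               "positive effective area")
})

test_that("group-size model back-transforms exactly when variance is zero", {
  segs <- synthetic_segments(300, seed = 4, lambda = 0.05)
  segs$mean_group[segs$n_sight > 0] <- 10
  fit <- fit_group_size_model(segs)
  expect_lt(fit$sigma2, 1e-10)
  expect_equal(predict(fit, segs), rep(10, nrow(segs)), tolerance = 1e-6)
})

test_that("group-size model recovers a latitudinal size gradient", {
  set.seed(5)
  segs <- synthetic_segments(800, seed = 5, lambda = 0.2)
  pres <- segs$n_sight > 0
  meanlog <- log(4) + 0.25 * (segs$lat - 34)
  segs$mean_group[pres] <- pmax(1, round(rlnorm(sum(pres), meanlog[pres], 0.3)))
  fit <- fit_group_size_model(segs)
  pred <- predict(fit, segs)
  expect_gt(cor(pred, exp(meanlog), method = "spearman"), 0.9)
})

test_that("group-size fits demand enough presence segments and locations", {
  segs <- synthetic_segments(300, seed = 6, lambda = 0.001)
  expect_error(fit_group_size_model(segs), "pooling")
  segs2 <- synthetic_segments(300, seed = 7, lambda = 0.3)
  segs2$lat <- 36; segs2$lon <- -124 # single location
  expect_error(fit_group_size_model(segs2), "unique locations")
})

test_that("pruning removes noise terms but keeps real signal", {
  drops <- 0L
  for (s in 1:10) {
    segs <- synthetic_segments(700, seed = 100 + s, lambda = 0.0)
    lam <- 0.02 * exp(0.4 * (segs$sst - 17))
    set.seed(200 + s)
    segs$n_sight <- rpois(nrow(segs), lam * segs$area_km2)
    segs$noise_x <- rnorm(nrow(segs))
    spec <- make_model_spec("encounter_rate", terms = c("sst", "noise_x"),
                            tweedie_power = 1.1)
    fit <- prune_terms(fit_count_model(segs, spec))
    if (!"s(noise_x)" %in% fit$retained && "s(sst)" %in% fit$retained)
      drops <- drops + 1L
  }
  expect_gte(drops, 9L)
})

test_that("pruning an all-noise model yields intercept-only with warning", {
  segs <- synthetic_segments(500, seed = 8, lambda = 0.02)
  segs$noise_x <- rnorm(nrow(segs))
  spec <- make_model_spec("encounter_rate", terms = "noise_x",
                          tweedie_power = 1.2)
  fit <- fit_count_model(segs, spec)
  expect_warning(pruned <- prune_terms(fit), "intercept-only")
  expect_length(pruned$retained, 0)
})

test_that("two-stage density is the encounter x group-size product", {
  segs <- synthetic_segments(600, seed = 9, lambda = 0.05)
  enc <- fit_count_model(segs, make_model_spec("encounter_rate",
                                               tweedie_power = 1.2))
  grp <- fit_group_size_model(segs)
  d <- predict_density(enc, grp, segs)
  expect_equal(d, pmax(predict(enc, segs) * predict(grp, segs), 0))
  expect_true(all(d >= 0))
  expect_error(predict_density(enc, NULL, segs), "group-size")
})

test_that("homogeneous intercept-only densities match observed density", {
  segs <- synthetic_segments(3000, seed = 10, lambda = 0.03, meansize = 6)
  enc <- fit_count_model(segs, make_model_spec("encounter_rate"))
  grp <- fit_group_size_model(segs)
  d <- predict_density(enc, grp, segs)
  obs_density <- sum(segs$n_sight * ifelse(segs$n_sight > 0, segs$mean_group, 0)) /
    sum(segs$area_km2)
  pred_total <- sum(d * segs$area_km2)
  obs_total <- obs_density * sum(segs$area_km2)
  expect_lt(abs(pred_total / obs_total - 1), 0.03)
})

test_that("presence GAMs separate a clean signal and refuse one class", {
  set.seed(11)
  segs <- synthetic_segments(400, seed = 11, lambda = 0)
  segs$n_sight <- as.integer(segs$sst > 17) # perfectly separable
  spec <- make_model_spec("presence", terms = "sst")
  # perfect separation: mgcv warns about convergence, which is the point
  fit <- suppressWarnings(fit_presence_gam(segs, spec))
  p <- predict(fit, segs)
  expect_true(all(p >= 0 & p <= 1))
  expect_gte(auc(segs$n_sight, p), 0.99)
  segs$n_sight <- 1L
  expect_error(fit_presence_gam(segs, spec), "single-class")
})

test_that("null presence models explain almost no deviance", {
  low <- 0L
  for (s in 1:10) {
    segs <- synthetic_segments(500, seed = 300 + s, lambda = 0.02)
    set.seed(400 + s)
    segs$n_sight <- rbinom(nrow(segs), 1, 0.3) # independent of covariates
    fit <- fit_presence_gam(segs, make_model_spec("presence",
                                                  terms = c("sst", "mld")))
    if (explained_deviance(fit) <= 2) low <- low + 1L
  }
  expect_gte(low, 9L)
})

test_that("fitted SDM metadata round-trips as JSON", {
  segs <- synthetic_segments(400, seed = 12, lambda = 0.04)
  fit <- fit_count_model(segs, make_model_spec("encounter_rate", terms = "sst",
                                               tweedie_power = 1.3))
  path <- withr::local_tempfile(fileext = ".json")
  sdm_save(fit, path)
  back <- sdm_load(path)
  expect_equal(back$response, "encounter_rate")
  expect_equal(back$tweedie_power, 1.3)
  expect_equal(back$retained_terms, fit$retained)
  expect_equal(unlist(back$coefficients), coef(fit$model)[names(unlist(back$coefficients))],
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("predictions demand every model covariate", {
  segs <- synthetic_segments(400, seed = 13, lambda = 0.04)
  fit <- fit_count_model(segs, make_model_spec("encounter_rate", terms = "sst",
                                               tweedie_power = 1.3))
  expect_error(predict(fit, data.frame(mld = 1:3)), "missing covariate")
})
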