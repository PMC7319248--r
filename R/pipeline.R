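#' Default demo run configuration
#'
#' A small self-contained scenario: a coastal domain with a latitudinal
#' SST gradient, a warm-affinity delphinid-like species, several survey
#' years with one optional heatwave year, and all three model families.
#'
#' @param seed Master seed.
#' @param out_dir Output directory.
#' @return Nested configuration list (YAML-serializable).
#' @export
default_run_config <- function(seed = 1, out_dir = tempfile("cetsdm_run_")) {
  list(
    seed = seed,
    out_dir = out_dir,
    env = list(extent = c(-126, -122, 34, 40),
               days_per_year = 16,
               years = c(1996, 2001, 2005),
               heatwave_years = integer(0),
               anomaly_c = 2),
    truth = list(name = "sim_delphinid", lambda0 = 0.01,
                 sst_slope = 0.25, sst_ref = 18,
                 group_meanlog = log(8), group_sdlog = 0.6),
    design = list(n_transects = 8, step_km = 1, target_segment_km = 5,
                  truncation_km = 5.5),
    models = list(density = list(response = "encounter_rate",
                                 terms = c("sst", "depth"),
                                 interaction = "lon:lat"),
                  presence = list(terms = c("sst", "depth"),
                                  interaction = "lon:lat"),
                  brt = list(min_trees = 60, n_iterations = 2,
                             cv_folds = 5, variants = "dyn_bathy")),
    strata = list(n_bands = 4, isobath_m = 2000),
    holdout_year = NULL)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes simulate -> segment -> detect -> fit (density GAM, presence
#' GAM, BRT) -> predict -> evaluate, writing the segment table, model
#' metadata, average prediction surfaces, evaluation reports and a run
#' manifest (seed, versions, input summaries) under `config$out_dir`.
#' Deterministic for a fixed config.
#'
#' @param config A configuration list (see [default_run_config()]) or the
#'   path to a YAML file holding one.
#' @return The output directory, invisibly; stage results as attributes.
#' @export
run_pipeline <- function(config = default_run_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  validate_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed

  # --- simulate -------------------------------------------------------
  ec <- config$env
  dates <- as.Date(unlist(lapply(ec$years, function(y)
    as.character(as.Date(sprintf("%d-08-01", y)) + seq_len(ec$days_per_year) - 1))))
  hw <- as.Date(character(0))
  for (y in ec$heatwave_years)
    hw <- c(hw, dates[format(dates, "%Y") == as.character(y)])
  env <- make_env_fields(ec$extent, dates = dates, heatwave_days = hw,
                         seed = seed, anomaly_c = ec$anomaly_c %||% 2)
  tc <- config$truth
  truth <- species_truth(tc$name, tc$lambda0,
                         terms = list(resp_monotone("sst", tc$sst_slope,
                                                    ref = tc$sst_ref %||% 0)),
                         group_meanlog = tc$group_meanlog,
                         group_sdlog = tc$group_sdlog)
  det <- if (!is.null(config$detection_csv))
    read_detection_csv(config$detection_csv) else detection_fixture(tc$name)
  dc <- config$design
  segments <- simulate_survey_years(env, truth, det, dc, ec$years, seed)
  write_segments_csv(segments, file.path(config$out_dir, "segments.csv"))

  # --- fit ------------------------------------------------------------
  mc <- config$models
  dens_spec <- make_model_spec(mc$density$response %||% "encounter_rate",
                               terms = mc$density$terms,
                               interaction = mc$density$interaction,
                               tweedie_power = mc$density$tweedie_power)
  dens <- prune_terms(fit_count_model(segments, dens_spec))
  grp <- if (dens_spec$response == "encounter_rate")
    fit_group_size_model(segments) else NULL
  pres_spec <- make_model_spec("presence", terms = mc$presence$terms,
                               interaction = mc$presence$interaction)
  pres <- prune_terms(fit_presence_gam(segments, pres_spec))
  bc <- brt_config(min_trees = mc$brt$min_trees %||% 1000,
                   n_iterations = mc$brt$n_iterations %||% 10,
                   cv_folds = mc$brt$cv_folds %||% 10, seed = seed)
  brt <- select_best_brt(segments, bc,
                         variants = mc$brt$variants %||%
                           c("dyn_bathy", "dyn_bathy_lat", "dyn_bathy_lon", "all"))
  sdm_save(dens, file.path(config$out_dir, "density_gam.json"))
  sdm_save(pres, file.path(config$out_dir, "presence_gam.json"))
  write_brt_influence_csv(brt, file.path(config$out_dir, "brt_influence.csv"))
  utils::write.csv(brt$leaderboard,
                   file.path(config$out_dir, "brt_leaderboard.csv"),
                   row.names = FALSE)

  # --- predict --------------------------------------------------------
  days <- env$dates[unique(round(seq(1, length(env$dates), length.out = 8)))]
  surf_d <- multiyear_average(lapply(days, function(d)
    predict_daily(dens, env, d, group_fit = grp)))
  surf_p <- multiyear_average(lapply(days, function(d)
    predict_daily(pres, env, d)))
  write_surface_csv(surf_d, file.path(config$out_dir, "density_surface.csv"))
  write_surface_csv(surf_p, file.path(config$out_dir, "suitability_surface.csv"))

  # --- evaluate -------------------------------------------------------
  sc <- config$strata
  ext <- ec$extent
  strata <- make_strata(seq(ext[3], ext[4], length.out = (sc$n_bands %||% 4) + 1),
                        isobath_m = sc$isobath_m %||% 2000)
  reports <- list(
    density = eval_report(segments, predict_density(dens, grp, segments),
                          fit = dens, strata = strata, mode = "density"),
    presence = eval_report(segments, predict(pres, segments), fit = pres,
                           strata = strata, mode = "presence_rate"),
    brt = eval_report(segments, predict(brt, segments), strata = strata,
                      mode = "presence_rate"))
  for (nm in names(reports))
    write_eval_report(reports[[nm]],
                      file.path(config$out_dir, paste0("eval_", nm, ".json")))

  cv <- NULL
  if (!is.null(config$holdout_year)) {
    cv <- novel_year_cv(segments, env, config$holdout_year,
                        builders = list(
                          density = density_builder(dens_spec),
                          presence = presence_builder(pres_spec)),
                        strata = strata)
  }

  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("cetsdm")),
                   r_version = R.version.string,
                   n_segments = nrow(segments),
                   n_sightings = sum(segments$n_sight),
                   years = ec$years,
                   config = config[setdiff(names(config), "out_dir")])
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  res <- config$out_dir
  attr(res, "segments") <- segments
  attr(res, "reports") <- reports
  attr(res, "cv") <- cv
  invisible(res)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_config <- function(config) {
  need <- c("seed", "out_dir", "env", "truth", "design", "models", "strata")
  miss <- setdiff(need, names(config))
  if (length(miss))
    stop("config is missing field(s): ", paste(miss, collapse = ", "))
  if (!is.null(config$detection_csv) && !file.exists(config$detection_csv))
    stop("detection table not found: ", config$detection_csv)
  invisible(TRUE)
}

#' Simulate surveys over several years and build the segment table
#'
#' Runs [simulate_survey()] once per survey year (offsetting the seed per
#' year), then applies the full segmentation chain: cut effort, Beaufort
#' filter, truncation + sighting assignment, midpoint covariates and
#' detection-corrected effective areas.
#'
#' @param env An `env_grid` spanning the survey years.
#' @param truth A [species_truth()].
#' @param detection A [detection_table()].
#' @param design_cfg List with n_transects, step_km, target_segment_km,
#'   truncation_km (a full [survey_design()] is built per year), or a
#'   `survey_design` to reuse.
#' @param years Integer survey years.
#' @param seed Base seed.
#' @return Segment table ready for model fitting.
#' @export
simulate_survey_years <- function(env, truth, detection, design_cfg, years,
                                  seed = 1) {
  ext <- c(min(env$lon) - env$spacing / 2, max(env$lon) + env$spacing / 2,
           min(env$lat) - env$spacing / 2, max(env$lat) + env$spacing / 2)
  all_segs <- list()
  for (i in seq_along(years)) {
    y <- years[i]
    ydates <- env$dates[env$year == y]
    env_y <- env
    # restrict the design's calendar to this year's days
    keep <- env$year == y
    env_y$dates <- env$dates[keep]; env_y$year <- env$year[keep]
    env_y$ssh_source <- env$ssh_source[keep]
    env_y$heatwave <- env$heatwave[keep]
    for (v in c("sst", "sst_sd", "ssh", "ssh_sd", "mld"))
      env_y[[v]] <- env[[v]][, , keep, drop = FALSE]
    design <- if (inherits(design_cfg, "survey_design")) design_cfg else
      survey_design(grid_transects(ext, design_cfg$n_transects %||% 8),
                    step_km = design_cfg$step_km %||% 1,
                    target_segment_km = design_cfg$target_segment_km %||% 5,
                    truncation_km = design_cfg$truncation_km %||% 5.5,
                    start_date = ydates[1])
    sim <- simulate_survey(env_y, truth, design, detection,
                           seed = seed + 1000L * i)
    segs <- segment_effort(sim$track, design$target_segment_km)
    segs <- filter_beaufort(segs, 5)
    segs <- assign_sightings(segs, sim$sightings, design$truncation_km)
    segs <- sample_covariates(segs, env_y)
    segs <- apply_detection(segs, detection)
    all_segs[[i]] <- segs
  }
  segs <- do.call(rbind, all_segs)
  segs$id <- seq_len(nrow(segs))
  rownames(segs) <- NULL
  segs
}
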