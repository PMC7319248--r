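#' Geographic evaluation strata
#'
#' Builds the 2 x `n_bands` stratification used to validate spatial
#' pattern: north-south latitude bands crossed with an inshore/offshore
#' split at an isobath (default 2,000 m, roughly the slope-to-rise
#' transition). Membership is by segment/cell latitude and depth.
#'
#' @param lat_breaks Increasing latitude band edges (length `n_bands + 1`).
#' @param isobath_m Depth (m) of the inshore/offshore split.
#' @return data.frame with columns name, lat_min, lat_max, zone
#'   (`"inshore"`/`"offshore"`), isobath_m.
#' @export
make_strata <- function(lat_breaks, isobath_m = 2000) {
  if (is.unsorted(lat_breaks, strictly = TRUE))
    stop("lat_breaks must be strictly increasing")
  nb <- length(lat_breaks) - 1
  rows <- list()
  for (b in seq_len(nb)) for (zone in c("offshore", "inshore")) {
    rows[[length(rows) + 1L]] <- data.frame(
      name = sprintf("band%d_%s", b, zone),
      lat_min = lat_breaks[b], lat_max = lat_breaks[b + 1],
      zone = zone, isobath_m = isobath_m, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

stratum_depth_side <- function(depth, stratum) {
  if (stratum$zone == "inshore") depth <= stratum$isobath_m
  else depth > stratum$isobath_m
}

# stratum index (row of strata) for each segment; NA when outside all bands
assign_stratum <- function(lat, depth, strata) {
  out <- rep(NA_integer_, length(lat))
  for (i in seq_len(nrow(strata))) {
    st <- strata[i, ]
    memb <- lat >= st$lat_min & lat < st$lat_max &
      stratum_depth_side(depth, st)
    out[memb] <- i
  }
  out
}

#' Survey-derived values per stratum
#'
#' Density mode returns the Horvitz-Thompson-style observed density
#' `sum(n_i * s_i) / sum(A_i)` per stratum (animals per km^2); presence
#' mode returns the fraction of occupied segments. Strata with no effort
#' are NA and flagged with a warning.
#'
#' @param segments Segment table with n_sight, mean_group, area_km2, lat,
#'   depth.
#' @param strata A [make_strata()] table.
#' @param mode `"density"` or `"presence_rate"`.
#' @return Named numeric vector, one value per stratum.
#' @export
observed_stratum_values <- function(segments, strata,
                                    mode = c("density", "presence_rate")) {
  mode <- match.arg(mode)
  idx <- assign_stratum(segments$lat, segments$depth, strata)
  out <- stats::setNames(rep(NA_real_, nrow(strata)), strata$name)
  for (i in seq_len(nrow(strata))) {
    seg <- segments[which(idx == i), , drop = FALSE]
    if (nrow(seg) == 0) next
    out[i] <- if (mode == "density") {
      ind <- seg$n_sight * ifelse(seg$n_sight > 0, seg$mean_group, 0)
      sum(ind) / sum(seg$area_km2)
    } else {
      mean(seg$n_sight > 0)
    }
  }
  if (anyNA(out))
    warning("stratum/strata without effort: ",
            paste(names(out)[is.na(out)], collapse = ", "))
  out
}

#' Model-predicted values per stratum (from segments)
#'
#' Density mode: effort-weighted predicted density
#' `sum(D_hat_i * A_i) / sum(A_i)`; presence mode: mean predicted
#' probability.
#'
#' @param predicted Per-segment predictions (density in animals/km^2 or
#'   probability).
#' @param segments Matching segment table.
#' @param strata A [make_strata()] table.
#' @param mode `"density"` or `"presence_rate"`.
#' @return Named numeric vector per stratum.
#' @export
predicted_stratum_values <- function(predicted, segments, strata,
                                     mode = c("density", "presence_rate")) {
  mode <- match.arg(mode)
  idx <- assign_stratum(segments$lat, segments$depth, strata)
  out <- stats::setNames(rep(NA_real_, nrow(strata)), strata$name)
  for (i in seq_len(nrow(strata))) {
    w <- which(idx == i)
    if (length(w) == 0) next
    out[i] <- if (mode == "density") {
      sum(predicted[w] * segments$area_km2[w]) / sum(segments$area_km2[w])
    } else {
      mean(predicted[w])
    }
  }
  out
}

#' Full explanatory performance report for a fitted SDM
#'
#' Computes explained deviance, AUC and TSS at the max-SSS threshold
#' (occupancy vs. predicted score), the stratified Spearman rank
#' correlation with its exact one-tailed p, and the observed:predicted
#' calibration ratio (total individuals vs. predicted individuals for
#' density models; occupied-segment count vs. summed probability for
#' suitability models).
#'
#' @param segments Segment table with n_sight, mean_group, area_km2, lat,
#'   depth.
#' @param predicted Per-segment predictions on the response scale
#'   (density in animals/km^2 for density models, probability otherwise).
#' @param fit Optional fitted model for explained deviance.
#' @param strata Optional [make_strata()] table for the rank validation.
#' @param mode `"density"` or `"presence_rate"`.
#' @return List of class `eval_report`.
#' @export
eval_report <- function(segments, predicted, fit = NULL, strata = NULL,
                        mode = c("density", "presence_rate")) {
  mode <- match.arg(mode)
  occ <- as.integer(segments$n_sight > 0)
  a <- auc(occ, predicted)
  th <- max_sss_threshold(occ, predicted)
  t_val <- tss(occ, predicted, th)
  obs_ind <- segments$n_sight * ifelse(segments$n_sight > 0,
                                       segments$mean_group, 0)
  if (mode == "density") {
    observed_total <- sum(obs_ind)
    predicted_total <- sum(predicted * segments$area_km2)
  } else {
    observed_total <- sum(occ)
    predicted_total <- sum(predicted)
  }
  ratio <- obs_pred_ratio(observed_total, predicted_total)
  sp <- NULL; per_stratum <- NULL
  if (!is.null(strata)) {
    obs_s <- observed_stratum_values(segments, strata, mode)
    pred_s <- predicted_stratum_values(predicted, segments, strata, mode)
    keep <- !is.na(obs_s) & !is.na(pred_s)
    if (sum(keep) >= 3) {
      sp <- spearman_stratified(obs_s[keep], pred_s[keep])
    } else {
      warning("fewer than 3 strata carry effort; rank validation skipped")
    }
    per_stratum <- data.frame(stratum = strata$name[keep],
                              observed = obs_s[keep],
                              predicted = pred_s[keep])
  }
  structure(list(
    explained_deviance = if (!is.null(fit)) explained_deviance(fit) else NA,
    auc = a, tss = t_val, threshold = th,
    spearman = sp, obs_pred = ratio, per_stratum = per_stratum,
    observed_total = observed_total, predicted_total = predicted_total,
    mode = mode), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Expl.Dev. %.2f%%  AUC %.3f  TSS %.3f (thr %.3g)  Obs:Pred %.3f\n",
              x$explained_deviance, x$auc, x$tss, x$threshold, x$obs_pred))
  if (!is.null(x$spearman))
    cat(sprintf("Stratified Spearman rho %.3f (one-tailed p %.4f%s)\n",
                x$spearman$rho, x$spearman$p_value,
                if (x$spearman$significant) ", significant" else ""))
  invisible(x)
}

#' Write an evaluation report as JSON / flat CSV
#'
#' @param report An [eval_report()].
#' @param path Output path (.json or .csv).
#' @export
write_eval_report <- function(report, path) {
  if (grepl("\\.json$", path)) {
    obj <- report[c("explained_deviance", "auc", "tss", "threshold",
                    "obs_pred", "observed_total", "predicted_total", "mode")]
    obj$spearman_rho <- report$spearman$rho
    obj$spearman_p <- report$spearman$p_value
    obj$per_stratum <- report$per_stratum
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         null = "null", na = "null")
  } else {
    flat <- data.frame(metric = c("explained_deviance", "auc", "tss",
                                  "threshold", "obs_pred", "spearman_rho",
                                  "spearman_p"),
                       value = c(report$explained_deviance, report$auc,
                                 report$tss, report$threshold,
                                 report$obs_pred,
                                 if (is.null(report$spearman)) NA else report$spearman$rho,
                                 if (is.null(report$spearman)) NA else report$spearman$p_value))
    utils::write.csv(flat, path, row.names = FALSE)
  }
  invisible(path)
}

#' Novel-year cross-validation harness
#'
#' Trains every supplied model builder on all survey years except the
#' holdout, predicts on the holdout year's segments and environment, and
#' reports the holdout observed:predicted calibration per model together
#' with a difference surface (holdout-days average prediction minus
#' training-days average prediction), the anomaly view used to diagnose
#' distribution shifts.
#'
#' @param segments Full segment table (with covariates and areas).
#' @param env The `env_grid` covering all survey days.
#' @param holdout_year Year to withhold (must be present).
#' @param builders Named list of functions `function(train_segments)`
#'   returning a list with `predict_seg(segments)` (per-segment response:
#'   density or probability), `mode` (`"density"`/`"presence_rate"`), and
#'   optionally `fit` and `predict_surface(env, date)`.
#' @param strata Optional strata for per-model rank validation.
#' @param n_surface_days Cap on days used for the difference surfaces
#'   (evenly thinned); 0 disables surfaces.
#' @return Named list per builder: `report` ([eval_report()] on the
#'   holdout), `difference` (a [prediction_surface()] or NULL).
#' @export
novel_year_cv <- function(segments, env, holdout_year, builders,
                          strata = NULL, n_surface_days = 0) {
  if (!holdout_year %in% segments$year)
    stop("holdout year absent from the dataset: ", holdout_year)
  train <- segments[segments$year != holdout_year, , drop = FALSE]
  test <- segments[segments$year == holdout_year, , drop = FALSE]
  if (length(unique(train$year)) < 2)
    stop("need at least two training years")
  stopifnot(nrow(test) > 0, !any(test$id %in% train$id))
  out <- list()
  for (nm in names(builders)) {
    b <- builders[[nm]](train)
    pred <- b$predict_seg(test)
    rep <- eval_report(test, pred, fit = b$fit, strata = strata,
                       mode = b$mode)
    diff_surface <- NULL
    if (n_surface_days > 0 && !is.null(b$predict_surface)) {
      hold_days <- env$dates[env$year == holdout_year]
      train_days <- env$dates[env$year != holdout_year]
      thin <- function(d) d[unique(round(seq(1, length(d),
                                             length.out = min(n_surface_days, length(d)))))]
      s_hold <- multiyear_average(lapply(thin(hold_days),
                                         function(d) b$predict_surface(env, d)))
      s_train <- multiyear_average(lapply(thin(train_days),
                                          function(d) b$predict_surface(env, d)))
      diff_surface <- s_hold
      diff_surface$values <- s_hold$values - s_train$values
      class(diff_surface) <- "list" # difference values may be negative
    }
    out[[nm]] <- list(report = rep, difference = diff_surface)
  }
  out
}

#' Standard model builders for [novel_year_cv()]
#'
#' `density_builder` fits the count model (plus group-size stage for
#' encounter-rate specs) with pruning; `presence_builder` fits the pruned
#' binomial smoother; `brt_builder` fits and screens a BRT.
#'
#' @param spec,group_spec Model specs (see [make_model_spec()]).
#' @param config A [brt_config()] for the BRT builder.
#' @param prune Apply [prune_terms()].
#' @return A builder function for [novel_year_cv()].
#' @export
density_builder <- function(spec, group_spec = NULL, prune = TRUE) {
  force(spec); force(group_spec); force(prune)
  function(train) {
    cf <- fit_count_model(train, spec)
    if (prune) cf <- prune_terms(cf)
    gf <- NULL
    if (spec$response == "encounter_rate") {
      gs <- if (is.null(group_spec))
        make_model_spec("group_size", interaction = "lon:lat") else group_spec
      gf <- fit_group_size_model(train, gs)
    }
    list(fit = cf, mode = "density",
         predict_seg = function(segs) predict_density(cf, gf, segs),
         predict_surface = function(env, date) predict_daily(cf, env, date,
                                                             group_fit = gf))
  }
}

#' @rdname density_builder
#' @export
presence_builder <- function(spec, prune = TRUE) {
  force(spec); force(prune)
  function(train) {
    pf <- fit_presence_gam(train, spec)
    if (prune) pf <- prune_terms(pf)
    list(fit = pf, mode = "presence_rate",
         predict_seg = function(segs) predict(pf, segs),
         predict_surface = function(env, date) predict_daily(pf, env, date))
  }
}

#' @rdname density_builder
#' @export
brt_builder <- function(config = brt_config()) {
  force(config)
  function(train) {
    bf <- screen_predictors(fit_brt(train, config))
    list(fit = NULL, mode = "presence_rate",
         predict_seg = function(segs) predict(bf, segs),
         predict_surface = function(env, date) predict_daily(bf, env, date))
  }
}
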