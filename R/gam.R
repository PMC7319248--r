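#' Specify a smoother-based SDM
#'
#' Describes the response kind and candidate terms of a generalized
#' additive SDM. Univariate covariates enter as shrinkage smooths
#' (`bs = "ts"`); at most one bivariate interaction (a lon-lat tensor
#' product or a latitude-by-dynamic-variable tensor, e.g. `"lon:lat"` or
#' `"lat:sst"`) may be included per candidate model, mirroring the practice
#' of offering interactions individually.
#'
#' @param response One of `"individuals"`, `"encounter_rate"`,
#'   `"group_size"`, `"presence"`.
#' @param terms Character vector of univariate covariate names (columns of
#'   the segment table: sst, sst_sd, ssh, ssh_sd, mld, depth, lat, lon).
#' @param interaction Optional single string `"a:b"` naming one tensor
#'   interaction.
#' @param offer_year Offer year as a (continuous smooth) predictor.
#' @param tweedie_power Fix the Tweedie power instead of profiling.
#' @param tweedie_powers Profile grid for the Tweedie power.
#' @param k Basis dimension of univariate smooths.
#' @param k_tensor Marginal basis dimension of tensor smooths (total
#'   coefficients ~ k_tensor^2; default 3 gives ~10).
#' @param bias_correct Apply the lognormal mean back-transform
#'   `exp(mu + sigma^2/2)` for group-size predictions.
#' @param min_presence Minimum presence segments for a group-size fit.
#' @return Object of class `model_spec`.
#' @export
make_model_spec <- function(response = c("individuals", "encounter_rate",
                                         "group_size", "presence"),
                            terms = character(0), interaction = NULL,
                            offer_year = FALSE, tweedie_power = NULL,
                            tweedie_powers = seq(1.1, 1.9, by = 0.1),
                            k = 5, k_tensor = 3, bias_correct = TRUE,
                            min_presence = 30) {
  response <- match.arg(response)
  if (!is.null(interaction) && length(interaction) > 1)
    stop("at most one bivariate interaction per candidate model")
  structure(list(response = response, terms = terms,
                 interaction = interaction, offer_year = offer_year,
                 tweedie_power = tweedie_power,
                 tweedie_powers = tweedie_powers, k = k,
                 k_tensor = k_tensor, bias_correct = bias_correct,
                 min_presence = min_presence),
            class = "model_spec")
}

# term descriptors: label used by mgcv summary -> formula code
spec_term_list <- function(spec, data) {
  tl <- list()
  for (v in spec$terms) {
    k <- min(spec$k, length(unique(data[[v]])) - 1L)
    if (k < 3) stop("too few unique values for smooth term: ", v)
    tl[[length(tl) + 1L]] <- list(
      label = sprintf("s(%s)", v), vars = v,
      code = sprintf("s(%s, k = %d, bs = 'ts')", v, k))
  }
  if (!is.null(spec$interaction)) {
    vv <- strsplit(spec$interaction, ":", fixed = TRUE)[[1]]
    if (length(vv) != 2) stop("interaction must be of the form 'a:b'")
    tl[[length(tl) + 1L]] <- list(
      label = sprintf("te(%s,%s)", vv[1], vv[2]), vars = vv,
      code = sprintf("te(%s, %s, k = c(%d, %d), bs = 'ts')",
                     vv[1], vv[2], spec$k_tensor, spec$k_tensor))
  }
  if (isTRUE(spec$offer_year)) {
    nu <- length(unique(data$year))
    if (nu >= 4) {
      tl[[length(tl) + 1L]] <- list(
        label = "s(year)", vars = "year",
        code = sprintf("s(year, k = %d, bs = 'ts')", min(3L, nu - 1L)))
    } else if (nu >= 2) {
      # too few survey years for a smooth: linear trend term
      tl[[length(tl) + 1L]] <- list(label = "year", vars = "year",
                                    code = "year", parametric = TRUE)
    }
  }
  tl
}

build_formula <- function(response_var, term_list, offset_var = NULL) {
  rhs <- vapply(term_list, `[[`, character(1), "code")
  if (!is.null(offset_var)) rhs <- c(rhs, sprintf("offset(log(%s))", offset_var))
  if (length(rhs) == 0) rhs <- "1"
  stats::as.formula(paste(response_var, "~", paste(rhs, collapse = " + ")))
}

#' Fit a Tweedie count SDM with a log effective-area offset
#'
#' Fits a log-link count model to per-segment individuals
#' (`round(n_sight * mean_group)`, the single-response formulation used for
#' whales) or group encounters (`n_sight`, the first stage of the
#' delphinid two-stage model), with `log(area_km2)` as offset so that the
#' linear predictor is a density. Overdispersion is handled by a Tweedie
#' family whose power is estimated by profiling REML over a fixed grid
#' (default 1.1-1.9 by 0.1), falling back to 1.3 when the profile is flat
#' within tolerance. Shrinkage smooths are used throughout; follow with
#' [prune_terms()] for the p <= .05 retention loop.
#'
#' @param segments Segment table with response ingredients, covariates and
#'   positive `area_km2`.
#' @param spec A [make_model_spec()] with response `"individuals"` or
#'   `"encounter_rate"`.
#' @param flat_tol REML range below which the power profile is declared
#'   flat.
#' @return Object of class `cetsdm_fit`.
#' @export
fit_count_model <- function(segments, spec, flat_tol = 0.01) {
  if (!spec$response %in% c("individuals", "encounter_rate"))
    stop("spec response must be individuals or encounter_rate")
  if (is.null(segments$area_km2) || any(segments$area_km2 <= 0))
    stop("all segments must carry a positive effective area area_km2")
  data <- segments
  data$.resp <- if (spec$response == "individuals") {
    round(data$n_sight * ifelse(data$n_sight > 0, data$mean_group, 0))
  } else {
    data$n_sight
  }
  if (all(data$.resp == 0)) stop("all-zero response: nothing to fit")
  tl <- spec_term_list(spec, data)
  fml <- build_formula(".resp", tl, offset_var = "area_km2")

  if (!is.null(spec$tweedie_power)) {
    p_hat <- spec$tweedie_power
    fit <- fit_tweedie(fml, data, p_hat)
  } else {
    fits <- lapply(spec$tweedie_powers, function(p)
      tryCatch(fit_tweedie(fml, data, p), error = function(e) NULL))
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) stop("Tweedie profile failed for every power",
                       if (length(tl)) " (singular design?)" else "")
    scores <- vapply(fits[ok], function(f) as.numeric(f$gcv.ubre), numeric(1))
    if (diff(range(scores)) < flat_tol) {
      p_hat <- 1.3
      fit <- fit_tweedie(fml, data, p_hat)
    } else {
      p_hat <- spec$tweedie_powers[ok][which.min(scores)]
      fit <- fits[ok][[which.min(scores)]]
    }
  }
  new_cetsdm_fit(fit, spec, tl, data, tweedie_power = p_hat)
}

fit_tweedie <- function(fml, data, p) {
  mgcv::gam(fml, family = mgcv::Tweedie(p = p, link = "log"),
            data = data, method = "REML", select = FALSE)
}

new_cetsdm_fit <- function(model, spec, term_list, data,
                           tweedie_power = NULL, sigma2 = NULL) {
  structure(list(model = model, spec = spec, term_list = term_list,
                 data = data, tweedie_power = tweedie_power,
                 sigma2 = sigma2,
                 retained = vapply(term_list, `[[`, character(1), "label")),
            class = "cetsdm_fit")
}

#' @export
print.cetsdm_fit <- function(x, ...) {
  cat("cetsdm fit:", x$spec$response, "\n")
  cat("  retained terms:",
      if (length(x$retained)) paste(x$retained, collapse = " + ") else "(intercept only)", "\n")
  if (!is.null(x$tweedie_power)) cat("  Tweedie power:", x$tweedie_power, "\n")
  if (!is.null(x$sigma2)) cat("  log-scale residual variance:", signif(x$sigma2, 4), "\n")
  cat("  explained deviance:", sprintf("%.2f%%", explained_deviance(x)), "\n")
  invisible(x)
}

#' Fit the lognormal group-size SDM
#'
#' Gaussian model of `log(mean_group)` on presence segments with a
#' lon-lat tensor-product smooth capturing geographic group-size structure;
#' additional spec terms are honored. Stores the log-scale residual
#' variance; response-scale predictions apply the lognormal mean
#' correction `exp(mu + sigma^2/2)` when `spec$bias_correct` is TRUE.
#'
#' @param segments Segment table; only rows with `n_sight > 0` are used.
#' @param spec A [make_model_spec()]; defaults to the plain lon-lat tensor
#'   model.
#' @return Object of class `cetsdm_fit` with `sigma2` populated.
#' @export
fit_group_size_model <- function(segments,
                                 spec = make_model_spec("group_size",
                                                        interaction = "lon:lat")) {
  pres <- segments[segments$n_sight > 0, , drop = FALSE]
  if (nrow(pres) < spec$min_presence)
    stop("only ", nrow(pres), " presence segments (< ", spec$min_presence,
         "); consider pooling across years or species")
  if (nrow(unique(pres[, c("lon", "lat")])) < spec$k_tensor^2 + 1)
    stop("too few unique locations for the lon-lat tensor smooth")
  data <- pres
  data$.resp <- log(data$mean_group)
  if (stats::sd(data$.resp) < 1e-10) {
    # constant group size: smoothing-parameter and scale estimation are
    # degenerate, so fit the exact intercept-only model directly
    fit <- stats::glm(.resp ~ 1, data = data)
    return(new_cetsdm_fit(fit, spec, list(), data, sigma2 = 0))
  }
  tl <- spec_term_list(spec, data)
  fml <- build_formula(".resp", tl)
  fit <- mgcv::gam(fml, family = stats::gaussian(), data = data,
                   method = "REML", select = FALSE)
  new_cetsdm_fit(fit, spec, tl, data, sigma2 = fit$sig2)
}

#' Fit a binomial presence/absence SDM
#'
#' Logit-link smoother model of segment occupancy (1 where a segment
#' carries at least one sighting). Uses the same shrinkage bases and is
#' subject to the same [prune_terms()] loop as the density models;
#' predictions are probabilities in \[0, 1\].
#'
#' @inheritParams fit_count_model
#' @param spec A [make_model_spec()] with response `"presence"`.
#' @return Object of class `cetsdm_fit`.
#' @export
fit_presence_gam <- function(segments, spec) {
  if (spec$response != "presence") stop("spec response must be presence")
  data <- segments
  data$.resp <- as.integer(data$n_sight > 0)
  if (length(unique(data$.resp)) < 2)
    stop("single-class response: need both presence and absence segments")
  tl <- spec_term_list(spec, data)
  fml <- build_formula(".resp", tl)
  fit <- mgcv::gam(fml, family = stats::binomial("logit"), data = data,
                   method = "REML", select = FALSE)
  new_cetsdm_fit(fit, spec, tl, data)
}

#' Backwards term-significance pruning
#'
#' Iteratively drops the least significant term with approximate p > alpha
#' and refits (shrinkage bases throughout) until every retained term has
#' p <= alpha, per the standard overfitting guard for these SDMs. If every
#' term is dropped an intercept-only model is returned with a warning.
#'
#' @param fit A `cetsdm_fit`.
#' @param alpha Retention threshold (default 0.05).
#' @return A pruned `cetsdm_fit`.
#' @export
prune_terms <- function(fit, alpha = 0.05) {
  tl <- fit$term_list
  repeat {
    pv <- term_p_values(fit$model, tl)
    if (length(pv) == 0 || all(pv <= alpha, na.rm = TRUE)) break
    worst <- which.max(ifelse(is.na(pv), 1, pv))
    tl <- tl[-worst]
    if (length(tl) == 0)
      warning("all terms pruned; returning intercept-only model")
    fit <- refit_with_terms(fit, tl)
  }
  fit
}

term_p_values <- function(model, term_list) {
  sm <- summary(model)
  pv <- numeric(length(term_list))
  for (i in seq_along(term_list)) {
    lab <- term_list[[i]]$label
    if (isTRUE(term_list[[i]]$parametric)) {
      row <- match(lab, rownames(sm$p.table))
      pv[i] <- if (is.na(row)) NA_real_ else sm$p.table[row, ncol(sm$p.table)]
    } else {
      row <- match(lab, rownames(sm$s.table))
      pv[i] <- if (is.na(row)) NA_real_ else sm$s.table[row, ncol(sm$s.table)]
    }
  }
  pv
}

refit_with_terms <- function(fit, tl) {
  spec <- fit$spec
  data <- fit$data
  offset_var <- if (spec$response %in% c("individuals", "encounter_rate"))
    "area_km2" else NULL
  fml <- build_formula(".resp", tl, offset_var = offset_var)
  model <- switch(spec$response,
    individuals = ,
    encounter_rate = fit_tweedie(fml, data, fit$tweedie_power),
    presence = mgcv::gam(fml, family = stats::binomial("logit"), data = data,
                         method = "REML", select = FALSE),
    group_size = mgcv::gam(fml, family = stats::gaussian(), data = data,
                           method = "REML", select = FALSE))
  out <- new_cetsdm_fit(model, spec, tl, data,
                        tweedie_power = fit$tweedie_power,
                        sigma2 = if (spec$response == "group_size") model$sig2)
  out
}

#' Predict from a smoother SDM at covariate values
#'
#' @param object A `cetsdm_fit`.
#' @param newdata data.frame of covariates. Count models predict at a
#'   reference effective area of 1 km^2 (so the value is a density);
#'   group-size models apply the lognormal back-transform per the spec.
#' @param type `"response"` or `"link"`.
#' @param ... Unused.
#' @return Numeric vector of predictions.
#' @export
predict.cetsdm_fit <- function(object, newdata, type = "response", ...) {
  needed <- unique(unlist(lapply(object$term_list, `[[`, "vars")))
  miss <- setdiff(needed, names(newdata))
  if (length(miss)) stop("missing covariate(s): ", paste(miss, collapse = ", "))
  if (object$spec$response %in% c("individuals", "encounter_rate"))
    newdata$area_km2 <- 1
  eta <- if (inherits(object$model, "gam")) {
    as.numeric(mgcv::predict.gam(object$model, newdata = newdata,
                                 type = "link"))
  } else {
    as.numeric(stats::predict(object$model, newdata = newdata, type = "link"))
  }
  if (type == "link") return(eta)
  if (object$spec$response == "group_size") {
    corr <- if (isTRUE(object$spec$bias_correct)) object$sigma2 / 2 else 0
    return(exp(eta + corr))
  }
  as.numeric(object$model$family$linkinv(eta))
}

#' Compose density predictions from fitted models
#'
#' Two-stage (delphinid) composition multiplies the encounter-rate
#' prediction (groups per km^2 at unit effective area) by the predicted
#' group size; single-response (whale) models return individuals per km^2
#' directly. Densities are never negative.
#'
#' @param count_fit `cetsdm_fit` with response individuals or
#'   encounter_rate.
#' @param group_fit Optional `cetsdm_fit` with response group_size
#'   (required for encounter-rate fits).
#' @param covariates data.frame of prediction covariates.
#' @return Density in animals per km^2.
#' @export
predict_density <- function(count_fit, group_fit = NULL, covariates) {
  d <- predict(count_fit, covariates)
  if (count_fit$spec$response == "encounter_rate") {
    if (is.null(group_fit)) stop("encounter-rate models need a group-size model")
    d <- d * predict(group_fit, covariates)
  }
  pmax(d, 0)
}

#' Save / load a fitted SDM's contract as JSON
#'
#' Serializes the model's portable metadata: spec, retained terms,
#' coefficient vector, Tweedie power, log-scale residual variance and
#' deviances. The live prediction object is an in-session R object; the
#' JSON form documents and transports the fitted contract.
#'
#' @param fit A `cetsdm_fit`.
#' @param path Output path.
#' @export
sdm_save <- function(fit, path) {
  obj <- list(
    response = fit$spec$response,
    retained_terms = fit$retained,
    coefficients = as.list(stats::coef(fit$model)),
    tweedie_power = fit$tweedie_power,
    sigma2 = fit$sigma2,
    deviance = fit$model$deviance,
    null_deviance = fit$model$null.deviance,
    explained_deviance_pct = explained_deviance(fit))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname sdm_save
#' @export
sdm_load <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
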